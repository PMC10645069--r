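# Deposited coded data (not bundled)

The paper-number reproduction checks operate on the coded dataset of
original/replication pairs deposited by the study authors on OSF. That
dataset is third-party research data and is not redistributed with this
package.

To run those checks:

1. Download the coded data spreadsheet from the study's OSF repository and
   export it as CSV.
2. Either rename its headers to the canonical schema
   (`replistat::pair_schema_columns()`), or place a `mapping.yaml` next to
   the CSV with `foreign_header: canonical_name` entries.
3. Save the CSV as `inst/extdata/osf/coded_data.csv` in the package source
   and reinstall, then run the test suite.

Without the file, the corresponding acceptance test fails with a pointer to
this document; all synthetic-data checks are unaffected.
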