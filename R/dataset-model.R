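# Coded-dataset schema, validation and predictor transforms.
#
# A "study_pairs" object is a plain data.frame (one row per
# original/replication pair) carrying demographic and design predictors, the
# subjective replication score, and the reported key statistic of each study
# in flat columns with `orig_` / `rep_` prefixes.

#' Enumerated levels used by the coded-dataset schema
#' @name schema-levels
#' @keywords internal
NULL

SUBFIELD_LEVELS <- c("cognitive", "social", "other_psych", "non_psych")
CLOSENESS_LEVELS <- c("exact", "very_close", "close", "far")
TEST_TYPES <- c("means_between", "means_within", "t_between", "t_within",
                "f_test", "proportions", "beta_se", "none")
SCORE_GRID <- c(0, 0.25, 0.5, 0.75, 1)

STAT_FIELDS <- c("test_type", "statistic", "df1", "df2",
                 "m1", "s1", "n1", "m2", "s2", "n2",
                 "x1", "x2", "beta", "se")

# statistic fields that must be non-missing for each test type; for
# means_within, m1/s1 are the mean and SD of the paired differences
# (the cross-condition correlation is never reported, so per-condition
# summaries alone cannot standardize a within-participants change score)
required_stat_fields <- function(test_type) {
  switch(test_type,
    means_between = c("m1", "s1", "n1", "m2", "s2", "n2"),
    means_within  = c("m1", "s1", "n1"),
    t_between     = c("statistic", "n1", "n2"),
    t_within      = c("statistic", "n1"),
    f_test        = c("statistic", "df1", "df2", "n1"),
    proportions   = c("x1", "n1", "x2", "n2"),
    beta_se       = c("beta", "se"),
    none          = character(0),
    stop("unknown test_type: ", test_type)
  )
}

#' Canonical column names of the coded dataset
#'
#' The canonical flat-file schema: demographic/design predictors, outcome
#' codes, and one set of key-statistic fields per study role (`orig_*`,
#' `rep_*`).
#'
#' @return Character vector of column names in canonical order.
#' @export
pair_schema_columns <- function() {
  c("pair_id", "class_year", "subfield",
    "open_data", "open_materials", "original_online", "replication_online",
    "stanford_affiliation", "within_participants", "single_vignette",
    "n_trials", "publication_year", "n_original", "n_replication",
    "closeness", "subjective_score", "same_direction", "sensitivity_include",
    paste0("orig_", STAT_FIELDS), paste0("rep_", STAT_FIELDS))
}

#' Construct a study_pairs object from a data.frame
#'
#' Checks that all canonical columns are present, coerces types, and
#' validates every row with [validate_record()]. Validation issues are
#' attached as the `"issues"` attribute (a data.frame with `row`, `pair_id`,
#' `issue`), never silently dropped.
#'
#' @param df data.frame with the columns of [pair_schema_columns()].
#' @return A `study_pairs` data.frame with an `issues` attribute.
#' @export
study_pairs <- function(df) {
  missing_cols <- setdiff(pair_schema_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop_replistat(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      "replistat_schema_error")
  }
  extra <- setdiff(names(df), pair_schema_columns())
  df <- df[, c(pair_schema_columns(), extra), drop = FALSE]

  logical_cols <- c("open_data", "open_materials", "original_online",
                    "replication_online", "stanford_affiliation",
                    "within_participants", "single_vignette",
                    "same_direction", "sensitivity_include")
  for (cl in logical_cols) df[[cl]] <- as.logical(df[[cl]])
  int_cols <- c("class_year", "n_trials", "publication_year",
                "n_original", "n_replication")
  for (cl in int_cols) df[[cl]] <- as.integer(df[[cl]])
  num_cols <- c("subjective_score",
                paste0("orig_", setdiff(STAT_FIELDS, "test_type")),
                paste0("rep_", setdiff(STAT_FIELDS, "test_type")))
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  df$pair_id <- as.character(df$pair_id)
  df$subfield <- as.character(df$subfield)
  df$closeness <- as.character(df$closeness)
  df$orig_test_type <- as.character(df$orig_test_type)
  df$rep_test_type <- as.character(df$rep_test_type)

  issues <- collect_issues(df)
  structure(df, class = c("study_pairs", "data.frame"), issues = issues)
}

collect_issues <- function(df) {
  out <- list()
  for (i in seq_len(nrow(df))) {
    probs <- validate_record(df[i, , drop = FALSE])
    if (length(probs) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        row = i, pair_id = as.character(df$pair_id[i]), issue = probs,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    data.frame(row = integer(0), pair_id = character(0), issue = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Validate one coded record
#'
#' Returns human-readable descriptions of every schema invariant the record
#' violates: off-grid subjective scores, unknown enum levels, non-positive
#' sample sizes or SDs, and statistic fields required by the declared
#' `test_type` that are missing. Issues are returned, not raised.
#'
#' @param pair A single-row data.frame (or coercible list) in the canonical
#'   schema.
#' @return Character vector of issues; empty if the record is valid.
#' @export
validate_record <- function(pair) {
  p <- as.list(pair)
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)

  sc <- p$subjective_score
  if (is.null(sc) || is.na(sc)) {
    add("subjective_score is missing")
  } else if (!any(abs(sc - SCORE_GRID) < 1e-12)) {
    add(sprintf("subjective_score %s not on the five-level grid {0, 0.25, 0.5, 0.75, 1}", format(sc)))
  }
  if (is.na(p$subfield) || !(p$subfield %in% SUBFIELD_LEVELS)) {
    add(sprintf("subfield '%s' not one of {%s}", p$subfield,
                paste(SUBFIELD_LEVELS, collapse = ", ")))
  }
  if (is.na(p$closeness) || !(p$closeness %in% CLOSENESS_LEVELS)) {
    add(sprintf("closeness '%s' not one of {%s}", p$closeness,
                paste(CLOSENESS_LEVELS, collapse = ", ")))
  }
  for (cl in c("n_original", "n_replication", "n_trials")) {
    v <- p[[cl]]
    if (is.na(v) || v < 1) add(sprintf("%s must be a positive integer", cl))
  }
  for (role in c("orig", "rep")) {
    tt <- p[[paste0(role, "_test_type")]]
    if (is.na(tt) || !(tt %in% TEST_TYPES)) {
      add(sprintf("%s_test_type '%s' not one of {%s}", role, tt,
                  paste(TEST_TYPES, collapse = ", ")))
      next
    }
    for (f in required_stat_fields(tt)) {
      v <- p[[paste0(role, "_", f)]]
      if (is.null(v) || is.na(v)) {
        add(sprintf("%s_%s required for test_type %s but missing", role, f, tt))
      }
    }
    for (f in c("s1", "s2")) {
      v <- p[[paste0(role, "_", f)]]
      if (!is.null(v) && !is.na(v) && v <= 0) add(sprintf("%s_%s must be > 0", role, f))
    }
    sev <- p[[paste0(role, "_se")]]
    if (!is.null(sev) && !is.na(sev) && sev <= 0) add(sprintf("%s_se must be > 0", role))
    for (f in c("x1", "x2")) {
      v <- p[[paste0(role, "_", f)]]
      if (!is.null(v) && !is.na(v) && v < 0) add(sprintf("%s_%s must be non-negative", role, f))
    }
  }
  issues
}

#' Read a coded dataset of original/replication pairs
#'
#' Reads an RFC-4180 CSV with a header row. Column names may be mapped from a
#' foreign header to the canonical schema via `mapping`, a named character
#' vector or YAML file of `foreign_name: canonical_name` entries (useful for
#' externally deposited spreadsheets whose headers differ from
#' [pair_schema_columns()]).
#'
#' @param path Path to the CSV file.
#' @param mapping Optional named character vector, or path to a YAML file,
#'   renaming foreign columns to canonical ones.
#' @return A `study_pairs` object; per-row validation problems are in
#'   `attr(x, "issues")`.
#' @export
read_coded_dataset <- function(path, mapping = NULL) {
  if (!file.exists(path)) {
    stop_replistat(paste0("file not found: ", path), "replistat_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
      mapping <- unlist(yaml::read_yaml(mapping))
    }
    hit <- names(df) %in% names(mapping)
    names(df)[hit] <- unname(mapping[names(df)[hit]])
  }
  study_pairs(df)
}

#' Write a coded dataset in the canonical CSV dialect
#'
#' Numbers are formatted with up to 15 significant digits so that
#' write -> read -> write is byte-stable.
#'
#' @param pairs A `study_pairs` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coded_dataset <- function(pairs, path) {
  df <- as.data.frame(pairs)
  for (cl in names(df)) {
    if (is.numeric(df[[cl]]) && !is.integer(df[[cl]])) {
      df[[cl]] <- ifelse(is.na(df[[cl]]), NA_character_,
                         sprintf("%.15g", df[[cl]]))
    }
    if (is.logical(df[[cl]])) df[[cl]] <- ifelse(is.na(df[[cl]]), NA_character_,
                                                 ifelse(df[[cl]], "TRUE", "FALSE"))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Nested analysis subsets of a pair collection
#'
#' The three nested analysis sets: `full` (all valid pairs), `pi` (pairs whose
#' two studies yield effect estimates on a shared scale, so prediction
#' intervals and p-original are computable), and `smd` (pairs where both
#' estimates are standardized mean differences, so effect sizes are
#' comparable and usable as predictors). `smd` is always a subset of `pi`,
#' which is a subset of `full`.
#'
#' @param pairs A `study_pairs` object.
#' @return Named list of three `study_pairs` objects.
#' @export
analysis_subsets <- function(pairs) {
  pairs <- ensure_effects(pairs)
  has_pi <- !is.na(pairs$est_scale_match) & pairs$est_scale_match
  has_smd <- has_pi & !is.na(pairs$orig_scale) & pairs$orig_scale == "smd"
  list(full = pairs,
       pi = pairs[has_pi, , drop = FALSE],
       smd = pairs[has_smd, , drop = FALSE])
}

CONTINUOUS_PREDICTORS <- c("log_n_trials", "publication_year",
                           "log_n_original", "log_n_ratio",
                           "original_smd", "log_original_p")

#' Build the model design matrix from coded pairs
#'
#' Applies the predictor coding used throughout the analyses: subfield
#' dummies (cognitive psychology as the reference level), 0/1 design flags,
#' `switched_to_online` (original in-person AND replication online; all other
#' modality combinations are the "no change" condition), natural logs of
#' trial and participant counts, the log ratio of replication to original
#' sample size, and — when `include_statistics` — the original study's
#' standardized effect size and log p-value. All continuous columns are
#' z-scored after the log transforms; dummy columns stay 0/1.
#'
#' Rows with missing demographic predictors are dropped with a warning naming
#' their `pair_id`s (they cannot enter any model).
#'
#' @param pairs A `study_pairs` object.
#' @param include_statistics Add `original_smd` and `log_original_p` columns;
#'   errors (listing pair ids) if any pair lacks an SMD-scale original
#'   estimate.
#' @return A `design_matrix` object: list with elements `x` (numeric matrix),
#'   `column_names`, `scaling` (per-column center/scale used for z-scoring),
#'   `groups` (class-year factor for random effects), `pair_id`,
#'   `subjective_score` and `ordinal_score`.
#' @export
transform_predictors <- function(pairs, include_statistics = FALSE) {
  pairs <- ensure_effects(pairs)
  demo_cols <- c("subfield", "open_data", "open_materials", "original_online",
                 "replication_online", "stanford_affiliation",
                 "within_participants", "single_vignette", "n_trials",
                 "publication_year", "n_original", "n_replication")
  demo_ok <- stats::complete.cases(as.data.frame(pairs)[, demo_cols])
  if (any(!demo_ok)) {
    warning("dropping pair(s) with missing demographic predictors: ",
            paste(pairs$pair_id[!demo_ok], collapse = ", "))
    pairs <- pairs[demo_ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop_replistat("no usable rows", "replistat_domain_error")

  if (include_statistics) {
    bad <- is.na(pairs$orig_scale) | pairs$orig_scale != "smd" |
      is.na(pairs$orig_est) | is.na(pairs$orig_p)
    if (any(bad)) {
      stop_replistat(
        paste0("include_statistics requires an SMD-scale original estimate; missing for: ",
               paste(pairs$pair_id[bad], collapse = ", ")),
        "replistat_domain_error")
    }
  }

  x <- cbind(
    subfield_social      = as.numeric(pairs$subfield == "social"),
    subfield_other_psych = as.numeric(pairs$subfield == "other_psych"),
    subfield_non_psych   = as.numeric(pairs$subfield == "non_psych"),
    open_data            = as.numeric(pairs$open_data),
    open_materials       = as.numeric(pairs$open_materials),
    switched_to_online   = as.numeric(!pairs$original_online & pairs$replication_online),
    stanford_affiliation = as.numeric(pairs$stanford_affiliation),
    within_participants  = as.numeric(pairs$within_participants),
    single_vignette      = as.numeric(pairs$single_vignette),
    log_n_trials         = log(pairs$n_trials),
    publication_year     = as.numeric(pairs$publication_year),
    log_n_original       = log(pairs$n_original),
    log_n_ratio          = log(pairs$n_replication / pairs$n_original)
  )
  if (include_statistics) {
    x <- cbind(x,
               original_smd   = pairs$orig_est,
               log_original_p = log(pairs$orig_p))
  }

  cont <- intersect(colnames(x), CONTINUOUS_PREDICTORS)
  center <- stats::setNames(numeric(ncol(x)), colnames(x))
  scale_ <- stats::setNames(rep(1, ncol(x)), colnames(x))
  for (cl in cont) {
    mu <- mean(x[, cl])
    sd_ <- stats::sd(x[, cl])
    if (!is.finite(sd_) || sd_ == 0) sd_ <- 1  # degenerate column left centred
    x[, cl] <- (x[, cl] - mu) / sd_
    center[cl] <- mu
    scale_[cl] <- sd_
  }

  structure(list(
    x = x,
    column_names = colnames(x),
    scaling = data.frame(column = colnames(x), center = unname(center),
                         scale = unname(scale_), stringsAsFactors = FALSE),
    groups = factor(pairs$class_year),
    pair_id = pairs$pair_id,
    subjective_score = pairs$subjective_score,
    ordinal_score = score_to_ordinal(pairs$subjective_score),
    include_statistics = include_statistics
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d rows x %d predictors (%s statistics)\n",
              nrow(x$x), ncol(x$x),
              if (x$include_statistics) "with" else "without"))
  cat("columns:", paste(x$column_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.study_pairs <- function(x, ...) {
  n_iss <- nrow(attr(x, "issues")) %||% 0L
  cat(sprintf("study_pairs: %d original/replication pairs (%d validation issue%s)\n",
              nrow(x), n_iss, if (n_iss == 1) "" else "s"))
  NextMethod()
}
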