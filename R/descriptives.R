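# Descriptive layer: cohort descriptives, unadjusted Pearson correlations
# with the subjective replication score, the predictor correlation matrix,
# and effect-size shift summaries.

fmt_median_iqr <- function(x, qtype = 7) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = qtype, na.rm = TRUE)
  sprintf("%s (%s, %s)", format(signif(q[[2]], 3)),
          format(signif(q[[1]], 3)), format(signif(q[[3]], 3)))
}

#' Descriptive summary of a pair collection
#'
#' Counts and percentages for the categorical design features; median and
#' interquartile range (25th/75th percentiles, linear-interpolation
#' quantiles by default) for the continuous ones. Statistics-dependent rows
#' (original effect size, original p-value) are computed on the subset of
#' pairs where an SMD is derivable, with that subset's n reported.
#'
#' @param pairs A `study_pairs` object.
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (IQR endpoints are mildly sensitive to it); default 7.
#' @return A data.frame with columns `feature`, `summary`, `n`.
#' @export
summarize_dataset <- function(pairs, quantile_type = 7) {
  if (nrow(pairs) == 0) stop_replistat("empty dataset", "replistat_domain_error")
  pairs <- ensure_effects(pairs)
  n <- nrow(pairs)
  rows <- list()
  add <- function(feature, summary, n_used = n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, summary = summary, n = n_used,
      stringsAsFactors = FALSE)
  }
  cnt <- function(flag) sprintf("%d (%s%%)", sum(flag),
                                format(signif(100 * mean(flag), 2)))
  for (lev in SUBFIELD_LEVELS) {
    add(paste0("subfield: ", lev), cnt(pairs$subfield == lev))
  }
  add("open data", cnt(pairs$open_data))
  add("open materials", cnt(pairs$open_materials))
  add("switch from in-person to online",
      cnt(!pairs$original_online & pairs$replication_online))
  add("original authors at Stanford", cnt(pairs$stanford_affiliation))
  add("within participants design", cnt(pairs$within_participants))
  add("single vignette", cnt(pairs$single_vignette))
  add("number of trials", fmt_median_iqr(pairs$n_trials, quantile_type))
  add("publication year", fmt_median_iqr(pairs$publication_year, quantile_type))
  add("original sample size", fmt_median_iqr(pairs$n_original, quantile_type))
  add("replication sample size", fmt_median_iqr(pairs$n_replication, quantile_type))
  add("ratio of replication/original sample sizes",
      fmt_median_iqr(pairs$n_replication / pairs$n_original, quantile_type))
  smd <- !is.na(pairs$orig_scale) & pairs$orig_scale == "smd"
  if (any(smd)) {
    add("original effect size (SMD)",
        fmt_median_iqr(pairs$orig_est[smd], quantile_type), sum(smd))
    add("original p-value", fmt_median_iqr(pairs$orig_p[smd], quantile_type),
        sum(smd))
  }
  do.call(rbind, rows)
}

#' Unadjusted Pearson correlations with an outcome
#'
#' Per-predictor Pearson r and two-sided p-value against the outcome (the
#' raw 0-1 subjective score in the canonical analysis), with no multiplicity
#' adjustment. Binary predictors use ordinary Pearson r on the 0/1 coding
#' (the point-biserial correlation). Rows are sorted by descending r.
#' Zero-variance predictors are reported with `NA` r rather than dropped.
#'
#' @param matrix A `design_matrix` (z-scoring does not affect r).
#' @param outcome Numeric outcome vector; defaults to the design matrix's
#'   subjective scores.
#' @return A `correlation_table` data.frame: `predictor`, `r`, `p`, `n_used`.
#' @export
bivariate_correlations <- function(matrix, outcome = NULL) {
  outcome <- outcome %||% matrix$subjective_score
  stopifnot(length(outcome) == nrow(matrix$x))
  res <- lapply(colnames(matrix$x), function(cl) {
    xcol <- matrix$x[, cl]
    if (stats::sd(xcol) == 0 || stats::sd(outcome) == 0) {
      return(data.frame(predictor = cl, r = NA_real_, p = NA_real_,
                        n_used = length(xcol), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(xcol, outcome, method = "pearson")
    data.frame(predictor = cl, r = unname(ct$estimate), p = ct$p.value,
               n_used = length(xcol), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$r, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Correlation matrix of the predictors
#'
#' @param matrix A `design_matrix` with at least two predictors.
#' @return Symmetric matrix of Pearson r with unit diagonal; zero-variance
#'   columns give `NA` off-diagonals.
#' @export
predictor_correlation_matrix <- function(matrix) {
  stopifnot(ncol(matrix$x) >= 2)
  suppressWarnings(r <- stats::cor(matrix$x))
  diag(r) <- 1
  r
}

#' Effect-size shift from original to replication
#'
#' Medians and interquartile ranges of the original SMD, the replication
#' SMD, and the per-pair difference (original minus replication, summarized
#' per pair — not a difference of medians). Restricted to pairs with
#' SMD-scale estimates for both studies.
#'
#' @param pairs A `study_pairs` object.
#' @param subset_rule `"all"` or `"score_1"` (only pairs with subjective
#'   score 1).
#' @param quantile_type Quantile algorithm, default 7.
#' @return A `shift_summary` list with `original`, `replication`, `difference`
#'   (each `c(q25, median, q75)`), `n` and `subset`.
#' @export
effect_size_shift <- function(pairs, subset_rule = c("all", "score_1"),
                              quantile_type = 7) {
  subset_rule <- match.arg(subset_rule)
  pairs <- ensure_effects(pairs)
  keep <- !is.na(pairs$orig_scale) & pairs$orig_scale == "smd" &
    !is.na(pairs$rep_scale) & pairs$rep_scale == "smd"
  if (subset_rule == "score_1") keep <- keep & pairs$subjective_score == 1
  if (!any(keep)) stop_replistat("empty subset", "replistat_domain_error")
  o <- pairs$orig_est[keep]
  r <- pairs$rep_est[keep]
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type,
                                   names = FALSE)
  structure(list(original = q(o), replication = q(r), difference = q(o - r),
                 n = sum(keep), subset = subset_rule),
            class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  f <- function(v) sprintf("%.2f (%.2f, %.2f)", v[2], v[1], v[3])
  cat(sprintf("Effect-size shift (%s subset, n = %d)\n", x$subset, x$n))
  cat("  median original SMD:     ", f(x$original), "\n")
  cat("  median replication SMD:  ", f(x$replication), "\n")
  cat("  median pairwise diff:    ", f(x$difference), "\n")
  invisible(x)
}
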