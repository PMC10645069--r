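# Replication-consistency statistics for original/replication pairs:
# normal-theory prediction intervals, the p-original consistency p-value
# (optionally inflated by between-implementation heterogeneity tau), the
# tau-level consistency classification, and the ordinal recoding of the
# subjective score.

as_est_se <- function(x) {
  if (inherits(x, "effect_estimate")) c(x$estimate, x$se) else stop_replistat(
    "expected an effect_estimate", "replistat_domain_error")
}

check_scales <- function(original, replication) {
  if (!identical(original$scale, replication$scale)) {
    stop_replistat(sprintf("scale mismatch: original on '%s', replication on '%s'",
                           original$scale, replication$scale),
                   "replistat_scale_mismatch")
  }
}

#' Prediction interval for a replication estimate
#'
#' The normal-theory interval around the original estimate expected to
#' contain a consistent replication's point estimate with probability
#' `level`, accounting for sampling error in both studies:
#' \eqn{\hat\theta_o \pm z_{(1+level)/2}\sqrt{se_o^2 + se_r^2}}. A z (not t)
#' quantile is used because for many reported statistics only an estimate
#' and SE are recoverable.
#'
#' @param original An `effect_estimate` for the original study.
#' @param replication_se Standard error of the replication estimate.
#' @param level Coverage level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
prediction_interval <- function(original, replication_se, level = 0.95) {
  stopifnot(level > 0, level < 1, replication_se > 0)
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(original$se^2 + replication_se^2)
  c(lower = original$estimate - half, upper = original$estimate + half)
}

#' p-original: the consistency p-value of a replication
#'
#' Two-sided p-value on the null hypothesis that the original and
#' replication estimates are draws from the same underlying effect,
#' allowing a between-implementation heterogeneity SD `tau`:
#' \deqn{p = 2\,(1 - \Phi(|\hat\theta_r - \hat\theta_o| /
#'   \sqrt{\tau^2 + se_o^2 + se_r^2})).}
#'
#' With `tau = 0` and a 95% level this is exactly dual to
#' [prediction_interval()] membership: the replication is inside the 95% PI
#' iff \eqn{p \ge 0.05}.
#'
#' @param original,replication `effect_estimate` objects on the same scale.
#' @param tau Assumed heterogeneity SD (same scale as the estimates).
#' @return p-value in (0, 1].
#' @export
p_orig <- function(original, replication, tau = 0) {
  check_scales(original, replication)
  stopifnot(tau >= 0)
  z <- abs(replication$estimate - original$estimate) /
    sqrt(tau^2 + original$se^2 + replication$se^2)
  2 * stats::pnorm(-z)
}

#' Heterogeneity-adjusted consistency classification
#'
#' A pair is consistent at heterogeneity `tau` when
#' `p_orig(original, replication, tau) >= alpha`. `tau` is interpreted in
#' SMD units, so a nonzero `tau` requires both estimates on the SMD scale.
#'
#' @inheritParams p_orig
#' @param alpha Significance threshold, default 0.05.
#' @return Logical.
#' @export
consistency_at_tau <- function(original, replication, tau = 0.21, alpha = 0.05) {
  if (tau > 0 && !identical(original$scale, "smd")) {
    stop_replistat("nonzero tau is in SMD units; estimates are not SMDs",
                   "replistat_scale_mismatch")
  }
  p_orig(original, replication, tau) >= alpha
}

#' Map subjective replication scores to ordinal levels
#'
#' The subjective score grid \{0, 0.25, 0.5, 0.75, 1\} is remapped to the
#' ordinal levels 1-5 for cumulative-logit modelling.
#'
#' @param subjective_score Numeric vector on the five-level grid.
#' @return Integer vector in 1..5.
#' @export
score_to_ordinal <- function(subjective_score) {
  idx <- match(round(subjective_score * 4) / 4, SCORE_GRID)
  off <- !is.na(subjective_score) &
    (is.na(idx) | abs(subjective_score * 4 - round(subjective_score * 4)) > 1e-9)
  if (any(off)) {
    stop_replistat(sprintf("score(s) off the {0, 0.25, 0.5, 0.75, 1} grid: %s",
                           paste(subjective_score[off], collapse = ", ")),
                   "replistat_domain_error")
  }
  as.integer(idx)
}

#' Per-pair replication metrics
#'
#' Computes, for every pair whose two studies have effect estimates on a
#' shared scale: the 95% prediction interval and whether the replication
#' point estimate falls inside it, p-original at `tau = 0`, and — for
#' SMD-scale pairs — p-original and the consistency flag at each value of
#' `tau_grid`. Pairs without derivable estimates get `NA` metrics but keep
#' their ordinal score: unavailability is a state, not an error.
#'
#' @param pairs A `study_pairs` object.
#' @param tau_grid Heterogeneity values (SMD units) at which to classify
#'   consistency; default the conventional 0.21.
#' @param level Prediction-interval level.
#' @return A data.frame with one row per pair: `pair_id`, `available`,
#'   `scale`, `pi_lower`, `pi_upper`, `in_interval`, `p_orig`,
#'   `ordinal_score`, `subjective_score`, and `p_orig_tau_*` /
#'   `consistent_tau_*` columns per grid value.
#' @export
compute_pair_metrics <- function(pairs, tau_grid = 0.21, level = 0.95) {
  pairs <- ensure_effects(pairs)
  n <- nrow(pairs)
  out <- data.frame(
    pair_id = pairs$pair_id,
    available = pairs$est_scale_match,
    scale = pairs$orig_scale,
    pi_lower = NA_real_, pi_upper = NA_real_,
    in_interval = NA, p_orig = NA_real_,
    ordinal_score = score_to_ordinal(pairs$subjective_score),
    subjective_score = pairs$subjective_score,
    stringsAsFactors = FALSE)
  for (tau in tau_grid) {
    out[[sprintf("p_orig_tau_%s", format(tau))]] <- NA_real_
    out[[sprintf("consistent_tau_%s", format(tau))]] <- NA
  }
  for (i in seq_len(n)) {
    if (!isTRUE(pairs$est_scale_match[i])) next
    eo <- effect_estimate(pairs$orig_est[i], pairs$orig_se[i],
                          pairs$orig_scale[i], pairs$orig_p[i],
                          NA_integer_, "derived")
    er <- effect_estimate(pairs$rep_est[i], pairs$rep_se[i],
                          pairs$rep_scale[i], pairs$rep_p[i],
                          NA_integer_, "derived")
    pi <- prediction_interval(eo, er$se, level)
    out$pi_lower[i] <- pi[["lower"]]
    out$pi_upper[i] <- pi[["upper"]]
    out$in_interval[i] <- er$estimate >= pi[["lower"]] && er$estimate <= pi[["upper"]]
    out$p_orig[i] <- p_orig(eo, er, tau = 0)
    if (identical(eo$scale, "smd")) {
      for (tau in tau_grid) {
        p_t <- p_orig(eo, er, tau = tau)
        out[[sprintf("p_orig_tau_%s", format(tau))]][i] <- p_t
        out[[sprintf("consistent_tau_%s", format(tau))]][i] <- p_t >= 0.05
      }
    }
  }
  out
}

#' Cohort-level summary of replication metrics
#'
#' Aggregates [compute_pair_metrics()] output: mean subjective score, the
#' fraction of replications inside the prediction interval (always reported
#' as an explicit numerator/denominator, never a re-rounded percentage),
#' median p-original, and the consistency fraction at each heterogeneity
#' value in the metrics table.
#'
#' @param metrics Output of [compute_pair_metrics()].
#' @return A `cohort_summary` list.
#' @export
cohort_summary <- function(metrics) {
  has_pi <- !is.na(metrics$in_interval)
  taus <- grep("^consistent_tau_", names(metrics), value = TRUE)
  cons <- lapply(taus, function(cl) {
    ok <- !is.na(metrics[[cl]])
    list(tau = as.numeric(sub("^consistent_tau_", "", cl)),
         n_consistent = sum(metrics[[cl]][ok]), n = sum(ok))
  })
  structure(list(
    n_pairs = nrow(metrics),
    mean_subjective_score = mean(metrics$subjective_score),
    n_with_pi = sum(has_pi),
    n_in_pi = sum(metrics$in_interval[has_pi]),
    median_p_orig = stats::median(metrics$p_orig[has_pi]),
    consistency = cons
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Replication cohort: %d pairs\n", x$n_pairs))
  cat(sprintf("  mean subjective replication score: %.2f\n",
              x$mean_subjective_score))
  if (x$n_with_pi > 0) {
    cat(sprintf("  within 95%% prediction interval: %d%% (%d/%d)\n",
                round(100 * x$n_in_pi / x$n_with_pi), x$n_in_pi, x$n_with_pi))
    cat(sprintf("  median p-original: %.3g\n", x$median_p_orig))
  }
  for (cs in x$consistency) {
    if (cs$n > 0) {
      cat(sprintf("  consistent at tau = %.2f: %d%% (%d/%d)\n",
                  cs$tau, round(100 * cs$n_consistent / cs$n),
                  cs$n_consistent, cs$n))
    }
  }
  invisible(x)
}
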