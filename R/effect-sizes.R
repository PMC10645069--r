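# Conversion of reported key statistics into a common effect-size currency.
#
# Every route returns an `effect_estimate`: point estimate, standard error,
# scale (smd / log_odds / native), two-sided p-value and total n. SMDs are
# uncorrected Cohen's d (no Hedges small-sample correction); within-designs
# use change-score standardization (d_z), computable from t and n alone.

effect_estimate <- function(estimate, se, scale, p_value, n_total, source) {
  # extreme statistics underflow the two-sided p; clamp into (0, 1]
  p_value <- max(p_value, 1e-300)
  stopifnot(is_number(estimate), is_number(se), se > 0,
            is_number(p_value), p_value > 0, p_value <= 1)
  structure(list(estimate = estimate, se = se, scale = scale,
                 p_value = p_value, n_total = n_total, source = source),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("effect_estimate [%s, from %s]: %.4g (SE %.4g), p = %.3g, n = %s\n",
              x$scale, x$source, x$estimate, x$se, x$p_value, x$n_total))
  invisible(x)
}

smd_se <- function(d, n1, n2) {
  sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
}

#' Standardized mean difference from per-condition summaries
#'
#' Cohen's d with the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}, its large-
#' sample standard error \eqn{\sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}},
#' and the two-sided p-value of the corresponding t statistic on
#' \eqn{n_1+n_2-2} degrees of freedom.
#'
#' @param m1,s1,n1 Mean, SD and size of condition 1.
#' @param m2,s2,n2 Mean, SD and size of condition 2.
#' @return An `effect_estimate` on the SMD scale.
#' @export
smd_from_means <- function(m1, s1, n1, m2, s2, n2) {
  if (!is_number(s1) || !is_number(s2) || s1 <= 0 || s2 <= 0) {
    stop_replistat("per-condition SDs must be > 0", "replistat_domain_error")
  }
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  tval <- d / sqrt(1 / n1 + 1 / n2)
  p <- 2 * stats::pt(-abs(tval), df = n1 + n2 - 2)
  effect_estimate(d, smd_se(d, n1, n2), "smd", p, n1 + n2, "means_between")
}

#' Standardized mean difference from a between-participants t statistic
#'
#' \eqn{d = t\sqrt{1/n_1 + 1/n_2}}; SE and p as in [smd_from_means()].
#' @param t Reported t statistic (signed).
#' @param n1,n2 Per-condition sample sizes.
#' @export
smd_from_t_between <- function(t, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  d <- t * sqrt(1 / n1 + 1 / n2)
  p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
  effect_estimate(d, smd_se(d, n1, n2), "smd", p, n1 + n2, "t_between")
}

#' Change-score SMD from a paired (within-participants) t statistic
#'
#' \eqn{d_z = t/\sqrt{n}}, standardizing by the SD of the paired differences;
#' SE \eqn{\sqrt{1/n + d_z^2/(2n)}}; p two-sided on \eqn{n-1} df. Mixed
#' designs are treated as within-participants.
#'
#' @param t Reported paired t statistic.
#' @param n Number of participants.
#' @export
smd_from_t_within <- function(t, n) {
  stopifnot(n >= 2)
  d <- t / sqrt(n)
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  effect_estimate(d, sqrt(1 / n + d^2 / (2 * n)), "smd", p, n, "t_within")
}

#' SMD from a one-degree-of-freedom F statistic
#'
#' Converts \eqn{|t| = \sqrt{F}} and delegates to the between- or
#' within-participants t route (within when `n2` is missing). F statistics
#' carry no direction, so the sign must be supplied via
#' `direction_positive` (coded separately from the statistics).
#'
#' @param f_value F statistic (numerator df must be 1).
#' @param df2 Denominator degrees of freedom (consistency-checked only).
#' @param n1,n2 Per-condition sizes; omit `n2` (or pass `NA`) for a
#'   within-participants F.
#' @param direction_positive Is the effect in the positive (reference)
#'   direction?
#' @param df1 Numerator degrees of freedom, must be 1.
#' @export
smd_from_f <- function(f_value, df2, n1, n2 = NA, direction_positive = TRUE,
                       df1 = 1) {
  if (!is.na(df1) && df1 != 1) {
    stop_replistat("only 1-df F statistics are convertible to an SMD",
                   "replistat_unsupported_statistic")
  }
  stopifnot(f_value >= 0)
  tval <- sqrt(f_value) * if (isTRUE(direction_positive)) 1 else -1
  est <- if (is.na(n2)) smd_from_t_within(tval, n1) else smd_from_t_between(tval, n1, n2)
  est$source <- "f_test"
  est
}

#' Log odds ratio from a 2x2 proportion table
#'
#' Estimate \eqn{\log((x_1 (n_2-x_2)) / ((n_1-x_1) x_2))} with a 0.5
#' continuity correction applied to all four cells whenever any cell is
#' zero; SE \eqn{\sqrt{\sum 1/\mathrm{cell}}} on the (corrected) cells; p
#' from the normal approximation.
#'
#' @param success1,total1 Successes and total in group 1.
#' @param success2,total2 Successes and total in group 2.
#' @export
estimate_from_proportions <- function(success1, total1, success2, total2) {
  stopifnot(total1 >= 1, total2 >= 1,
            success1 >= 0, success2 >= 0,
            success1 <= total1, success2 <= total2)
  cells <- c(success1, total1 - success1, success2, total2 - success2)
  if (all(cells[1:2] == 0) || all(cells[3:4] == 0)) {
    stop_replistat("a group with zero total information", "replistat_domain_error")
  }
  if (any(cells == 0)) cells <- cells + 0.5
  lor <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  p <- 2 * stats::pnorm(-abs(lor / se))
  effect_estimate(lor, se, "log_odds", p, total1 + total2, "proportions")
}

#' Effect estimate from a reported coefficient and standard error
#'
#' Taken at face value on its native scale; p from the two-sided normal.
#' @param beta Reported coefficient.
#' @param se Its standard error (> 0).
#' @export
estimate_from_beta <- function(beta, se) {
  if (!is_number(se) || se <= 0) {
    stop_replistat("se must be > 0", "replistat_domain_error")
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  effect_estimate(beta, se, "native", p, NA_integer_, "beta_se")
}

# Derive the effect estimate for one study role of one pair row; NULL when
# the reported statistics are insufficient (test_type "none" or unsupported).
derive_one <- function(row, role) {
  g <- function(f) row[[paste0(role, "_", f)]]
  tt <- g("test_type")
  if (is.na(tt) || tt == "none") return(NULL)
  out <- tryCatch(switch(tt,
    means_between = smd_from_means(g("m1"), g("s1"), g("n1"),
                                   g("m2"), g("s2"), g("n2")),
    means_within  = {
      # m1/s1 = mean and SD of paired differences
      dz <- g("m1") / g("s1")
      smd_from_t_within(dz * sqrt(g("n1")), g("n1"))
    },
    t_between     = smd_from_t_between(g("statistic"), g("n1"), g("n2")),
    t_within      = smd_from_t_within(g("statistic"), g("n1")),
    f_test        = smd_from_f(g("statistic"), g("df2"), g("n1"), g("n2"),
                               direction_positive = TRUE, df1 = g("df1")),
    proportions   = estimate_from_proportions(g("x1"), g("n1"), g("x2"), g("n2")),
    beta_se       = estimate_from_beta(g("beta"), g("se")),
    NULL
  ), replistat_error = function(e) NULL, error = function(e) NULL)
  out
}

#' Derive effect estimates for every pair
#'
#' Runs the per-study conversion routes and appends `orig_est`, `orig_se`,
#' `orig_scale`, `orig_p`, `rep_est`, `rep_se`, `rep_scale`, `rep_p` and
#' `est_scale_match` columns. Direction coding follows the convention that
#' the original estimate is non-negative and the replication estimate is
#' positive when the separately coded `same_direction` flag says the two
#' effects point the same way (reported statistic signs are not trusted;
#' F statistics carry none). p-values are computed before alignment and are
#' sign-invariant.
#'
#' Pairs whose statistics are insufficient keep `NA` estimates — they remain
#' available for the subjective-score analyses.
#'
#' @param pairs A `study_pairs` object.
#' @return The same object with estimate columns appended.
#' @export
derive_effects <- function(pairs) {
  n <- nrow(pairs)
  cols <- list(orig_est = rep(NA_real_, n), orig_se = rep(NA_real_, n),
               orig_scale = rep(NA_character_, n), orig_p = rep(NA_real_, n),
               rep_est = rep(NA_real_, n), rep_se = rep(NA_real_, n),
               rep_scale = rep(NA_character_, n), rep_p = rep(NA_real_, n),
               est_scale_match = rep(FALSE, n))
  for (i in seq_len(n)) {
    row <- as.list(as.data.frame(pairs)[i, , drop = FALSE])
    eo <- derive_one(row, "orig")
    er <- derive_one(row, "rep")
    if (!is.null(eo)) {
      cols$orig_est[i] <- abs(eo$estimate)
      cols$orig_se[i] <- eo$se
      cols$orig_scale[i] <- eo$scale
      cols$orig_p[i] <- eo$p_value
    }
    if (!is.null(er)) {
      sgn <- if (isTRUE(row$same_direction)) 1 else -1
      cols$rep_est[i] <- sgn * abs(er$estimate)
      cols$rep_se[i] <- er$se
      cols$rep_scale[i] <- er$scale
      cols$rep_p[i] <- er$p_value
    }
    cols$est_scale_match[i] <- !is.null(eo) && !is.null(er) &&
      identical(eo$scale, er$scale)
  }
  for (cl in names(cols)) pairs[[cl]] <- cols[[cl]]
  pairs
}

# idempotent: derive effects only if the columns are not already present
ensure_effects <- function(pairs) {
  if (!("est_scale_match" %in% names(pairs))) derive_effects(pairs) else pairs
}
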