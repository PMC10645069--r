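# Regularized Bayesian regressions for replication outcomes: a
# cumulative-logit ordinal model for the 1-5 subjective score, a logistic
# model for prediction-interval membership, and a linear model for
# p-original. All share the prior structure: horseshoe shrinkage on the
# fixed-effect coefficients (local scales half-t(horseshoe_df), global scale
# half-Cauchy), and independent cohort-level (class-year) random effects for
# the intercept and each predictor with half-normal(0, 0.5) SD priors,
# non-centred. No interaction terms.
#
# All densities/gradients are written against the unconstrained
# parameterization (log scales, ordered cutpoints as first cutpoint + log
# gaps) and sampled with the built-in NUTS engine.

#' Model configuration for the Bayesian regressions
#'
#' @param horseshoe_df Degrees of freedom of the local shrinkage scales
#'   (half-t); default 3.
#' @param global_scale Scale of the half-Cauchy prior on the global
#'   shrinkage parameter.
#' @param slab_scale Finite value switches to the regularized horseshoe with
#'   a fixed slab of this scale; `Inf` (default) is the original horseshoe.
#' @param ranef_sd_prior SD of the half-normal prior on random-effect SDs
#'   (the conventional 0.5).
#' @param lkj_shape Accepted for interface compatibility; random effects are
#'   modelled as independent, so values other than 1 trigger a warning.
#' @param random_slopes Give every predictor (not just the intercept) a
#'   cohort-level random effect.
#' @param chains,iter,warmup,seed,adapt_delta,max_treedepth Sampler controls.
#' @param prior_only Drop the likelihood (prior-predictive sampling).
#' @param rhat_max Convergence gate on split-Rhat of reported coefficients.
#' @param ess_min Effective-sample-size level below which a warning is
#'   issued.
#' @param retries Refit budget (longer run, higher `adapt_delta`) before a
#'   convergence failure becomes an error.
#' @return A `model_config` list.
#' @export
model_config <- function(horseshoe_df = 3, global_scale = 1, slab_scale = Inf,
                         ranef_sd_prior = 0.5, lkj_shape = 1,
                         random_slopes = TRUE,
                         chains = 4, iter = 500, warmup = 500, seed = 1,
                         adapt_delta = 0.9, max_treedepth = 9,
                         prior_only = FALSE, rhat_max = 1.01, ess_min = 400,
                         retries = 1) {
  if (lkj_shape != 1) {
    warning("random-effect correlations are not modelled (independent ",
            "random effects); lkj_shape != 1 has no effect")
  }
  structure(as.list(environment()), class = "model_config")
}

# parameter index map for the shared layout
param_map <- function(p, G, q, model, K = NULL) {
  idx <- 0L
  take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
  m <- list(z = take(p), loglam = take(p), logtau = take(1L),
            u = take(G * q), logsig = take(q))
  if (model == "linear") { m$alpha <- take(1L); m$logsigma <- take(1L) }
  if (model == "logistic") m$alpha <- take(1L)
  if (model == "ordinal") { m$c1 <- take(1L); m$loggaps <- take(K - 2L) }
  m$n_par <- idx
  m
}

t_prior_lp <- function(x, nu, s) sum(-(nu + 1) / 2 * log1p(x^2 / (nu * s^2)))
t_prior_grad <- function(x, nu, s) -(nu + 1) * x / (nu * s^2 + x^2)

make_model_lp <- function(model, X, y, group, config, K = NULL) {
  n <- nrow(X); p <- ncol(X)
  G <- length(unique(group))
  Z <- if (config$random_slopes) cbind(1, X) else matrix(1, n, 1)
  q <- ncol(Z)
  map <- param_map(p, G, q, model, K)
  nu <- config$horseshoe_df
  gs <- config$global_scale
  slab <- config$slab_scale
  sr <- config$ranef_sd_prior
  prior_only <- isTRUE(config$prior_only)
  s0 <- if (model == "linear") max(1, stats::sd(y)) else NULL
  group <- as.integer(group)
  # 0/1 group indicator for fast per-group sums (replaces rowsum in the
  # sampler hot path)
  gmat <- matrix(0, n, G)
  gmat[cbind(seq_len(n), group)] <- 1
  y_idx <- if (model == "ordinal") lapply(seq_len(K), function(k) which(y == k))

  lp_grad <- function(theta) {
    z <- theta[map$z]
    loglam <- theta[map$loglam]; lam <- exp(loglam)
    logtau <- theta[map$logtau]; tau <- exp(logtau)
    if (is.finite(slab)) {
      A <- slab^2 + tau^2 * lam^2
      kap <- slab^2 / A
      mj <- tau * lam * sqrt(kap)
    } else {
      kap <- rep(1, p)
      mj <- tau * lam
    }
    beta <- z * mj
    u <- matrix(theta[map$u], G, q)
    sig <- exp(theta[map$logsig])
    b <- u * rep(sig, each = G)
    eta <- drop(X %*% beta) + rowSums(Z * b[group, , drop = FALSE])

    grad <- numeric(map$n_par)
    extra_lp <- 0

    if (model == "linear") {
      alpha <- theta[map$alpha]
      sigma <- exp(theta[map$logsigma])
      mu_i <- eta + alpha
      if (prior_only) {
        ll <- 0; r <- numeric(n); g_logsigma_data <- 0; g_alpha_data <- 0
      } else {
        resid <- y - mu_i
        ll <- -n * log(sigma) - sum(resid^2) / (2 * sigma^2)
        r <- resid / sigma^2
        g_logsigma_data <- -n + sum(resid^2) / sigma^2
        g_alpha_data <- sum(r)
      }
      extra_lp <- t_prior_lp(alpha, 3, 2.5) +
        t_prior_lp(sigma, 3, s0) + theta[map$logsigma]
      grad[map$alpha] <- g_alpha_data + t_prior_grad(alpha, 3, 2.5)
      grad[map$logsigma] <- g_logsigma_data +
        t_prior_grad(sigma, 3, s0) * sigma + 1
    } else if (model == "logistic") {
      alpha <- theta[map$alpha]
      eta_i <- eta + alpha
      if (prior_only) {
        ll <- 0; r <- numeric(n); g_alpha_data <- 0
      } else {
        ll <- sum(y * eta_i - log1pexp(eta_i))
        r <- y - inv_logit(eta_i)
        g_alpha_data <- sum(r)
      }
      extra_lp <- t_prior_lp(alpha, 3, 2.5)
      grad[map$alpha] <- g_alpha_data + t_prior_grad(alpha, 3, 2.5)
    } else { # ordinal
      c1 <- theta[map$c1]
      gaps <- exp(theta[map$loggaps])
      cuts <- c1 + cumsum(c(0, gaps))          # K-1 ordered cutpoints
      c_ext <- c(-Inf, cuts, Inf)
      if (prior_only) {
        ll <- 0; r <- numeric(n)
        Gk <- t_prior_grad(cuts, 3, 2.5)
      } else {
        a_up <- c_ext[y + 1L] - eta
        a_lo <- c_ext[y] - eta
        p_up <- inv_logit(a_up)
        p_lo <- inv_logit(a_lo)
        P <- pmax(p_up - p_lo, 1e-300)
        ll <- sum(log(P))
        f_up <- p_up * (1 - p_up)   # logistic density, 0 at +/-Inf
        f_lo <- p_lo * (1 - p_lo)
        r <- (f_lo - f_up) / P
        du <- f_up / P
        dl <- f_lo / P
        Gk <- vapply(seq_len(K - 1L), function(k) {
          sum(du[y_idx[[k]]]) - sum(dl[y_idx[[k + 1L]]])
        }, numeric(1))
        Gk <- Gk + t_prior_grad(cuts, 3, 2.5)
      }
      extra_lp <- t_prior_lp(cuts, 3, 2.5) + sum(theta[map$loggaps])
      grad[map$c1] <- sum(Gk)
      if (K > 2L) {
        tail_sums <- rev(cumsum(rev(Gk)))[-1]   # sum_{k' >= k} for k = 2..K-1
        grad[map$loggaps] <- gaps * tail_sums + 1
      }
    }

    # priors on the shared structure
    lp <- ll + extra_lp +
      -0.5 * sum(z^2) +
      sum(-(nu + 1) / 2 * log1p(lam^2 / nu) + loglam) +
      (-log1p(tau^2 / gs^2) + logtau) +
      -0.5 * sum(u^2) +
      sum(-sig^2 / (2 * sr^2) + theta[map$logsig])

    Xtr <- drop(crossprod(X, r))
    grad[map$z] <- Xtr * mj - z
    grad[map$loglam] <- Xtr * beta * kap +
      (1 - (nu + 1) * lam^2 / (nu + lam^2))
    grad[map$logtau] <- sum(Xtr * beta * kap) +
      1 - 2 * tau^2 / (gs^2 + tau^2)
    ru <- crossprod(gmat, Z * r)               # G x q per-group sums
    grad[map$u] <- as.vector(ru * rep(sig, each = G) - u)
    grad[map$logsig] <- colSums(ru * b) + 1 - sig^2 / sr^2

    list(lp = lp, grad = grad)
  }

  init_fn <- function(chain_id) {
    th <- numeric(map$n_par)
    th[map$z] <- stats::rnorm(p, 0, 0.1)
    th[map$loglam] <- stats::rnorm(p, 0, 0.1)
    th[map$logtau] <- log(0.1)
    th[map$u] <- stats::rnorm(G * q, 0, 0.1)
    th[map$logsig] <- log(0.1)
    if (model == "linear") {
      th[map$alpha] <- mean(y)
      th[map$logsigma] <- log(max(stats::sd(y), 0.05))
    }
    if (model == "logistic") th[map$alpha] <- stats::qlogis(pmin(pmax(mean(y), 0.05), 0.95))
    if (model == "ordinal") {
      props <- cumsum(tabulate(y, K) / length(y))[-K]
      props <- pmin(pmax(props, 0.02), 0.98)
      cuts0 <- stats::qlogis(props)
      cuts0 <- cummax(cuts0 + seq_along(cuts0) * 1e-3)
      th[map$c1] <- cuts0[1]
      if (K > 2L) th[map$loggaps] <- log(pmax(diff(cuts0), 0.05))
    }
    th
  }

  list(lp_grad = lp_grad, map = map, init = init_fn, p = p, G = G, q = q)
}

# extract fixed-effect coefficient draws (on the link scale) from the
# unconstrained draws array
beta_draws <- function(draws, map, config) {
  p <- length(map$z)
  iter <- dim(draws)[1]; chains <- dim(draws)[2]
  out <- array(NA_real_, c(iter, chains, p))
  slab <- config$slab_scale
  for (ch in seq_len(chains)) {
    z <- draws[, ch, map$z, drop = FALSE][, 1, ]
    lam <- exp(draws[, ch, map$loglam, drop = FALSE][, 1, ])
    tau <- exp(draws[, ch, map$logtau])
    if (is.finite(slab)) {
      tl <- lam * tau
      out[, ch, ] <- z * tl * slab / sqrt(slab^2 + tl^2)
    } else {
      out[, ch, ] <- z * lam * tau
    }
  }
  out
}

fit_bayes_model <- function(model, x, y, group, config, predictors) {
  stopifnot(inherits(config, "model_config"))
  K <- if (model == "ordinal") 5L else NULL
  if (model == "ordinal") {
    stopifnot(all(y %in% 1:5))
    y <- as.integer(y)
  }
  if (model == "logistic") {
    y <- as.numeric(y)
    stopifnot(all(y %in% c(0, 1)))
  }
  built <- make_model_lp(model, x, y, group, config, K)

  attempt <- 0L
  cfg <- config
  repeat {
    set.seed(cfg$seed)
    fit <- nuts_sample(built$lp_grad, built$map$n_par, chains = cfg$chains,
                       iter = cfg$iter, warmup = cfg$warmup,
                       seed = cfg$seed + attempt * 1000L,
                       init = built$init,
                       max_treedepth = cfg$max_treedepth,
                       adapt_delta = cfg$adapt_delta)
    bd <- beta_draws(fit$draws, built$map, cfg)
    rhats <- vapply(seq_len(built$p), function(j) split_rhat(bd[, , j]),
                    numeric(1))
    if (max(rhats) <= cfg$rhat_max || attempt >= cfg$retries) break
    attempt <- attempt + 1L
    cfg$warmup <- cfg$warmup * 2L
    cfg$iter <- cfg$iter * 2L
    cfg$adapt_delta <- min(0.99, cfg$adapt_delta + 0.05)
  }
  if (max(rhats) > cfg$rhat_max) {
    stop_replistat(sprintf(
      "model did not converge after %d attempt(s): max split-Rhat %.3f > %.2f (worst predictor: %s); divergences: %d",
      attempt + 1L, max(rhats), cfg$rhat_max, predictors[which.max(rhats)],
      fit$divergences), "replistat_convergence_error")
  }

  esss <- vapply(seq_len(built$p), function(j) ess_mean(bd[, , j]), numeric(1))
  if (min(esss) < cfg$ess_min) {
    warning(sprintf("minimum coefficient ESS %.0f below target %d",
                    min(esss), cfg$ess_min))
  }
  if (fit$divergences > 0) {
    warning(sprintf("%d divergent transition(s); estimates may be biased",
                    fit$divergences))
  }

  exp_link <- model %in% c("ordinal", "logistic")
  qs <- t(vapply(seq_len(built$p), function(j) {
    v <- as.vector(bd[, , j])
    stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
  }, numeric(3)))
  if (exp_link) qs <- exp(qs)
  summary <- data.frame(
    predictor = predictors,
    estimate = qs[, 1], lower = qs[, 2], upper = qs[, 3],
    rhat = rhats, ess = esss, stringsAsFactors = FALSE)
  names(summary)[2] <- if (exp_link) "odds_ratio" else "slope"

  out <- structure(list(
    model = model, summary = summary, divergences = fit$divergences,
    n = nrow(x), config = cfg, scale = if (exp_link) "odds_ratio" else "slope",
    beta_draws = bd, predictors = predictors
  ), class = "posterior_summary")

  if (model == "linear" && !isTRUE(config$prior_only)) {
    # report (never clamp) fitted values escaping the (0,1) outcome range
    beta_med <- apply(bd, 3, stats::median)
    alpha_med <- stats::median(fit$draws[, , built$map$alpha])
    fitted <- drop(x %*% beta_med) + alpha_med
    out$n_fitted_outside_unit <- sum(fitted < 0 | fitted > 1)
    out$fitted <- fitted
  }
  out
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Bayesian %s regression (horseshoe shrinkage), n = %d\n",
              x$model, x$n))
  cat(sprintf("  %d divergence(s); posterior %s with 95%% CrI\n",
              x$divergences, x$scale))
  df <- x$summary
  df[2:6] <- lapply(df[2:6], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  if (!is.null(x$n_fitted_outside_unit) && x$n_fitted_outside_unit > 0) {
    cat(sprintf("  note: %d fitted value(s) outside (0,1)\n",
                x$n_fitted_outside_unit))
  }
  invisible(x)
}

#' Ordinal (cumulative-logit) model of the subjective replication score
#'
#' Models P(score <= k) = logit^-1(c_k - x'beta - z'b_cohort) with horseshoe
#' shrinkage on beta and independent cohort-level random effects. Summaries
#' are odds ratios exp(beta) for higher-vs-lower scores. Fails loudly
#' (after the retry budget) if any reported coefficient has split-Rhat above
#' the configured gate.
#'
#' @param matrix A `design_matrix` from [transform_predictors()].
#' @param config A [model_config()].
#' @param outcome Optional integer 1-5 outcome; defaults to the design
#'   matrix's ordinal scores.
#' @return A `posterior_summary`.
#' @export
fit_ordinal <- function(matrix, config = model_config(), outcome = NULL) {
  y <- outcome %||% matrix$ordinal_score
  fit_bayes_model("ordinal", matrix$x, y, matrix$groups, config,
                  matrix$column_names)
}

#' Logistic model of prediction-interval membership
#'
#' @param matrix A `design_matrix`.
#' @param outcome Logical/0-1 vector (e.g. `in_interval` from
#'   [compute_pair_metrics()]), aligned with the design-matrix rows.
#' @param config A [model_config()].
#' @return A `posterior_summary` (odds ratios).
#' @export
fit_logistic <- function(matrix, outcome, config = model_config()) {
  fit_bayes_model("logistic", matrix$x, outcome, matrix$groups, config,
                  matrix$column_names)
}

#' Linear model of p-original
#'
#' Gaussian likelihood with identity link on the raw (0,1) p-original
#' values, matching the conventional analysis; fitted values outside (0,1)
#' are counted and reported (`n_fitted_outside_unit`), never clamped.
#'
#' @param matrix A `design_matrix`.
#' @param outcome Numeric outcome (e.g. `p_orig` from
#'   [compute_pair_metrics()]).
#' @param config A [model_config()].
#' @return A `posterior_summary` (raw slopes).
#' @export
fit_linear <- function(matrix, outcome, config = model_config()) {
  fit_bayes_model("linear", matrix$x, outcome, matrix$groups, config,
                  matrix$column_names)
}

#' Sensitivity-analysis subset
#'
#' Restricts to pairs coded for inclusion in the sensitivity analysis
#' (matching statistical tests, key result of primary importance, no major
#' replication issues).
#'
#' @param pairs A `study_pairs` object with `sensitivity_include` coded.
#' @return Filtered `study_pairs`; error if the subset is empty.
#' @export
sensitivity_subset <- function(pairs) {
  keep <- !is.na(pairs$sensitivity_include) & pairs$sensitivity_include
  if (!any(keep)) stop_replistat("sensitivity subset is empty",
                                 "replistat_domain_error")
  pairs[keep, , drop = FALSE]
}
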