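# Model machinery tests use deliberately small, fast sampler settings; the
# full-scale calibration lives in test-acceptance.R.

fast_cfg <- function(...) {
  model_config(chains = 2, iter = 250, warmup = 250, ess_min = 50,
               rhat_max = 1.05, retries = 1, ...)
}

test_that("model log-posterior gradients match finite differences", {
  set.seed(1)
  n <- 40; p <- 3
  X <- cbind(rbinom(n, 1, 0.5), rnorm(n), rnorm(n))
  grp <- sample(1:3, n, replace = TRUE)
  num_grad <- function(f, th, eps = 1e-6) {
    vapply(seq_along(th), function(j) {
      tp <- th; tm <- th
      tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
      (f(tp)$lp - f(tm)$lp) / (2 * eps)
    }, numeric(1))
  }
  for (model in c("linear", "logistic", "ordinal")) {
    for (slab in c(Inf, 2)) {
      y <- switch(model, linear = rnorm(n), logistic = rbinom(n, 1, 0.5),
                  ordinal = sample(1:5, n, TRUE))
      cfg <- fast_cfg(slab_scale = slab)
      built <- replistat:::make_model_lp(model, X, y, grp, cfg,
                                         if (model == "ordinal") 5L)
      set.seed(7)
      th <- built$init(1) + rnorm(built$map$n_par, 0, 0.3)
      g <- built$lp_grad(th)$grad
      ng <- num_grad(built$lp_grad, th)
      expect_lt(max(abs(g - ng) / (1 + abs(ng))), 1e-5)
    }
  }
})

test_that("NUTS recovers an exact Gaussian target", {
  lg <- function(th) list(lp = -0.5 * sum(th^2 / c(1, 4, 0.25)),
                          grad = -th / c(1, 4, 0.25))
  fit <- nuts_sample(lg, 3, chains = 2, iter = 400, warmup = 400, seed = 5)
  m <- apply(fit$draws, 3, mean)
  v <- apply(fit$draws, 3, function(d) var(as.vector(d)))
  expect_lt(max(abs(m)), 0.2)
  expect_equal(unname(v), c(1, 4, 0.25), tolerance = 0.25)
  expect_equal(fit$divergences, 0)
  rh <- vapply(1:3, function(j) split_rhat(fit$draws[, , j]), numeric(1))
  expect_lt(max(rh), 1.02)
})

test_that("prior-predictive odds ratios are centred at 1", {
  set.seed(2)
  n <- 50
  X <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
  grp <- sample(1:3, n, TRUE)
  y <- rbinom(n, 1, 0.5)
  fit <- fit_logistic(list(x = X, groups = grp, column_names = colnames(X)),
                      y, fast_cfg(prior_only = TRUE))
  expect_equal(fit$summary$odds_ratio, c(1, 1), tolerance = 0.2)
})

test_that("null synthetic data: CrIs cover OR = 1 / slope = 0", {
  set.seed(3)
  n <- 150
  X <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n), c = rnorm(n))
  grp <- sample(1:4, n, TRUE)
  dm <- list(x = X, groups = grp, column_names = colnames(X),
             ordinal_score = sample(1:5, n, TRUE))
  fit_o <- fit_ordinal(dm, fast_cfg(seed = 11))
  expect_true(all(fit_o$summary$lower <= 1 & fit_o$summary$upper >= 1))
  fit_lin <- fit_linear(dm, rnorm(n, 0.5, 0.2), fast_cfg(seed = 12))
  expect_true(all(fit_lin$summary$lower <= 0 & fit_lin$summary$upper >= 0))
})

test_that("a strongly planted logistic slope is recovered", {
  set.seed(4)
  n <- 300
  X <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n), c = rnorm(n))
  grp <- sample(1:5, n, TRUE)
  y <- rbinom(n, 1, plogis(1.2 * X[, "a"] - 0.1))
  dm <- list(x = X, groups = grp, column_names = colnames(X))
  fit <- fit_logistic(dm, y, fast_cfg(seed = 13))
  s <- fit$summary
  expect_gt(s$odds_ratio[s$predictor == "a"], 1.5)
  expect_true(s$lower[s$predictor == "a"] <= exp(1.2) &&
                s$upper[s$predictor == "a"] >= exp(1.2))
  # nulls shrink towards OR 1
  expect_lt(abs(log(s$odds_ratio[s$predictor == "b"])), 0.35)
})

test_that("horseshoe shrinks null coefficients harder than flat-prior ML", {
  set.seed(9)
  n <- 120
  X <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  grp <- sample(1:3, n, TRUE)
  y <- rbinom(n, 1, plogis(1.5 * X[, "a"]))
  dm <- list(x = X, groups = grp, column_names = colnames(X))
  fit <- fit_logistic(dm, y, fast_cfg(seed = 21))
  ml <- glm(y ~ X, family = binomial())
  hs_null <- abs(log(fit$summary$odds_ratio[fit$summary$predictor != "a"]))
  ml_null <- abs(coef(ml)[c("Xb", "Xc", "Xd")])
  expect_lt(mean(hs_null), mean(ml_null))
})

test_that("separable data keep a finite odds ratio under shrinkage", {
  set.seed(6)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  y <- x  # perfect separation
  X <- cbind(sep = x, noise = rnorm(n))
  dm <- list(x = X, groups = sample(1:3, n, TRUE), column_names = colnames(X))
  # original horseshoe: posterior proper, median OR finite (heavy tails)
  fit <- fit_logistic(dm, y, fast_cfg(seed = 14))
  expect_true(is.finite(fit$summary$odds_ratio[1]))
  # regularized variant (finite slab) bounds the separation blow-up
  fit2 <- fit_logistic(dm, y, fast_cfg(seed = 14, slab_scale = 2))
  expect_lt(fit2$summary$odds_ratio[1], 1e4)
})

test_that("row permutation leaves summaries unchanged at a fixed seed", {
  set.seed(8)
  n <- 100
  X <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
  grp <- sample(1:3, n, TRUE)
  y <- rbinom(n, 1, plogis(X[, "a"]))
  dm1 <- list(x = X, groups = grp, column_names = colnames(X))
  perm <- sample(n)
  dm2 <- list(x = X[perm, ], groups = grp[perm], column_names = colnames(X))
  f1 <- fit_logistic(dm1, y, fast_cfg(seed = 30))
  f2 <- fit_logistic(dm2, y[perm], fast_cfg(seed = 30))
  # same posterior up to MCMC noise: CrIs overlap and medians are close
  expect_equal(log(f1$summary$odds_ratio), log(f2$summary$odds_ratio),
               tolerance = 0.3)
  expect_true(all(pmax(f1$summary$lower, f2$summary$lower) <=
                    pmin(f1$summary$upper, f2$summary$upper)))
})

test_that("linear fit reports fitted values outside (0,1)", {
  set.seed(15)
  n <- 120
  X <- cbind(a = rnorm(n), b = rnorm(n))
  dm <- list(x = X, groups = sample(1:3, n, TRUE), column_names = colnames(X))
  y <- 0.5 + 0.4 * X[, "a"] + rnorm(n, 0, 0.05)  # drives fits past [0,1]
  fit <- fit_linear(dm, y, fast_cfg(seed = 16))
  expect_gt(fit$n_fitted_outside_unit, 0)
  expect_equal(length(fit$fitted), n)
})

test_that("sensitivity_subset filters and errors on empty subsets", {
  pairs <- make_pairs(4, sensitivity_include = c(TRUE, FALSE, TRUE, FALSE))
  sub <- sensitivity_subset(pairs)
  expect_equal(sub$pair_id, c("p1", "p3"))
  all_in <- make_pairs(3, sensitivity_include = TRUE)
  expect_equal(nrow(sensitivity_subset(all_in)), 3)
  none_in <- make_pairs(3, sensitivity_include = FALSE)
  expect_error(sensitivity_subset(none_in), class = "replistat_domain_error")
})

test_that("end-to-end: planted score-model signs recovered from simulated pairs", {
  cfg <- generator_config(n_pairs = 250,
                          score_coefs = c(within_participants = 1.2,
                                          single_vignette = -0.9,
                                          social = 0, evidence = 0))
  sim <- simulate_pairs(cfg, seed = 41)
  dm <- transform_predictors(sim$pairs)
  fit <- fit_ordinal(dm, fast_cfg(seed = 42))
  s <- fit$summary
  expect_gt(s$odds_ratio[s$predictor == "within_participants"], 1.3)
  expect_lt(s$odds_ratio[s$predictor == "single_vignette"], 0.8)
})
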