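# Conversion routes are checked against brute-force oracles on simulated raw
# data: the SMD recomputed directly from raw observations must agree with the
# summary-statistic and test-statistic routes to 1e-10.

test_that("trivial SMD cases", {
  expect_equal(smd_from_means(1, 1, 50, 0, 1, 50)$estimate, 1.0)
  eq <- smd_from_means(0.4, 1.2, 30, 0.4, 0.9, 25)
  expect_equal(eq$estimate, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(smd_from_t_between(0, 20, 25)$estimate, 0)
  expect_equal(smd_from_t_between(2, 50, 50)$estimate, 0.4)
  expect_equal(smd_from_t_within(3, 36)$estimate, 0.5)
  expect_error(smd_from_means(1, 0, 10, 0, 1, 10),
               class = "replistat_domain_error")
})

test_that("conversion routes agree with raw-data oracles to 1e-10", {
  set.seed(42)
  for (rep in 1:20) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    x1 <- rnorm(n1, 0.5, 1.3); x2 <- rnorm(n2, 0, 0.8)
    # oracle: d from raw data
    sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
    d_raw <- (mean(x1) - mean(x2)) / sp
    e_means <- smd_from_means(mean(x1), sd(x1), n1, mean(x2), sd(x2), n2)
    expect_equal(e_means$estimate, d_raw, tolerance = 1e-12)
    # t route must match the means route exactly
    tt <- t.test(x1, x2, var.equal = TRUE)
    e_t <- smd_from_t_between(unname(tt$statistic), n1, n2)
    expect_equal(e_t$estimate, e_means$estimate, tolerance = 1e-10)
    expect_equal(e_t$p_value, e_means$p_value, tolerance = 1e-10)
    expect_equal(e_t$p_value, unname(tt$p.value), tolerance = 1e-10)
    # F route: same magnitude via t^2
    e_f <- smd_from_f(unname(tt$statistic)^2, n1 + n2 - 2, n1, n2,
                      direction_positive = tt$statistic > 0)
    expect_equal(e_f$estimate, e_t$estimate, tolerance = 1e-10)
  }
})

test_that("paired-route d_z matches the raw paired-differences oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(8:60, 1)
    pre <- rnorm(n); post <- pre + rnorm(n, 0.3, 0.7)
    diffs <- post - pre
    d_oracle <- mean(diffs) / sd(diffs)
    tt <- t.test(diffs)
    e <- smd_from_t_within(unname(tt$statistic), n)
    expect_equal(e$estimate, d_oracle, tolerance = 1e-10)
    expect_equal(e$p_value, unname(tt$p.value), tolerance = 1e-10)
  }
})

test_that("F conversions respect the 1-df restriction and direction flag", {
  expect_error(smd_from_f(4, 98, 50, 50, TRUE, df1 = 2),
               class = "replistat_unsupported_statistic")
  expect_equal(smd_from_f(4, 98, 50, 50, TRUE)$estimate, 0.4)
  ep <- smd_from_f(4, 98, 50, 50, TRUE)
  en <- smd_from_f(4, 98, 50, 50, FALSE)
  expect_equal(en$estimate, -ep$estimate)
  expect_equal(en$se, ep$se)
  expect_equal(en$p_value, ep$p_value)
  e0 <- smd_from_f(0, 98, 50, 50, TRUE)
  expect_equal(e0$estimate, 0)
  expect_equal(e0$p_value, 1)
})

test_that("proportion and beta routes", {
  e <- estimate_from_proportions(30, 60, 30, 60)
  expect_equal(e$estimate, 0)
  expect_equal(e$p_value, 1)
  e2 <- estimate_from_proportions(40, 50, 20, 50)
  expect_equal(e2$estimate, log(6), tolerance = 1e-12)
  expect_equal(e2$se, sqrt(1 / 40 + 1 / 10 + 1 / 20 + 1 / 30), tolerance = 1e-12)
  # zero cell: continuity correction keeps the estimate finite
  e3 <- estimate_from_proportions(0, 20, 10, 20)
  expect_true(is.finite(e3$estimate))
  expect_error(estimate_from_proportions(0, 0, 5, 10))

  expect_equal(estimate_from_beta(0, 1)$p_value, 1)
  expect_equal(estimate_from_beta(1.96, 1)$p_value, 0.05, tolerance = 1e-3)
  expect_equal(estimate_from_beta(0.5, 0.1)$p_value, 2 * pnorm(-5),
               tolerance = 1e-15)
  expect_error(estimate_from_beta(1, 0), class = "replistat_domain_error")
})

test_that("p-values are sign-invariant and SE decreases in n", {
  set.seed(3)
  for (t in c(0.7, 1.9, 3.2)) {
    expect_equal(smd_from_t_between(t, 30, 30)$p_value,
                 smd_from_t_between(-t, 30, 30)$p_value)
  }
  ns <- c(10, 20, 50, 100, 400)
  ses <- sapply(ns, function(n) smd_from_means(0.5, 1, n, 0, 1, n)$se)
  expect_true(all(diff(ses) < 0))
})

test_that("derive_effects aligns direction to the same_direction flag", {
  pairs <- make_pairs(2,
                      orig_statistic = c(2.5, -2.5),
                      rep_statistic = c(-1.2, 1.2),
                      same_direction = c(TRUE, FALSE))
  pairs <- derive_effects(pairs)
  # originals always coded non-negative
  expect_true(all(pairs$orig_est >= 0))
  # replication sign follows the coded flag, not the raw statistic sign
  expect_gt(pairs$rep_est[1], 0)
  expect_lt(pairs$rep_est[2], 0)
  expect_true(all(pairs$est_scale_match))
})

test_that("pairs without statistics get NA estimates, not errors", {
  pairs <- make_pairs(2)
  pairs$orig_test_type[2] <- "none"
  pairs$orig_statistic[2] <- NA
  pairs <- derive_effects(pairs)
  expect_true(is.na(pairs$orig_est[2]))
  expect_false(pairs$est_scale_match[2])
  expect_true(pairs$est_scale_match[1])
})
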