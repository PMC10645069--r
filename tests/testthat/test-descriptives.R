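test_that("summarize_dataset matches generator truth within sampling error", {
  cfg <- generator_config(n_pairs = 600)
  sim <- simulate_pairs(cfg, seed = 31)
  tab <- summarize_dataset(sim$pairs)
  grab <- function(feature) {
    s <- tab$summary[tab$feature == feature]
    as.numeric(sub("^(\\d+) .*$", "\\1", s)) / nrow(sim$pairs)
  }
  expect_equal(grab("within participants design"), cfg$p_within,
               tolerance = 0.06)
  expect_equal(grab("single vignette"), cfg$p_single_vignette,
               tolerance = 0.06)
  expect_equal(grab("open data"), cfg$p_open_data, tolerance = 0.06)
  expect_error(summarize_dataset(make_pairs(1)[0, ]),
               class = "replistat_domain_error")
})

test_that("single-pair summaries are degenerate medians", {
  tab <- summarize_dataset(make_pairs(1))
  row <- tab$summary[tab$feature == "original sample size"]
  expect_equal(row, "100 (100, 100)")
})

test_that("bivariate correlations: identity, null, sorting, zero variance", {
  sim <- simulate_pairs(generator_config(n_pairs = 300), seed = 8)
  dm <- transform_predictors(sim$pairs)
  # predictor identical to outcome
  dm$x <- cbind(dm$x, clone = dm$subjective_score)
  ct <- bivariate_correlations(dm)
  expect_equal(ct$r[ct$predictor == "clone"], 1, tolerance = 1e-12)
  # independent noise column is near zero
  set.seed(1)
  dm$x[, "clone"] <- rnorm(nrow(dm$x))
  ct2 <- bivariate_correlations(dm)
  expect_lt(abs(ct2$r[ct2$predictor == "clone"]), 0.15)
  # sorted by descending r
  expect_true(all(diff(ct2$r[!is.na(ct2$r)]) <= 0))
  # zero-variance column reported as NA, not dropped
  dm$x[, "clone"] <- 1
  ct3 <- bivariate_correlations(dm)
  expect_true(is.na(ct3$r[ct3$predictor == "clone"]))
})

test_that("Pearson r is invariant to affine transforms", {
  set.seed(12)
  x <- rnorm(100); y <- 0.4 * x + rnorm(100)
  r0 <- cor(x, y)
  expect_equal(cor(3 * x - 7, y), r0, tolerance = 1e-12)
  expect_equal(cor(x, -2 * y + 1), -r0, tolerance = 1e-12)
})

test_that("predictor correlation matrix is symmetric with unit diagonal", {
  sim <- simulate_pairs(generator_config(n_pairs = 80), seed = 3)
  dm <- transform_predictors(sim$pairs)
  r <- predictor_correlation_matrix(dm)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  dm$x <- cbind(dm$x, dup = dm$x[, "within_participants"])
  r2 <- predictor_correlation_matrix(dm)
  expect_equal(r2["dup", "within_participants"], 1, tolerance = 1e-12)
})

test_that("a planted predictor correlation is recovered at n = 2000", {
  set.seed(77)
  n <- 2000
  z <- rnorm(n)
  x1 <- z; x2 <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)
  dm <- list(x = cbind(a = x1, b = x2))
  class(dm) <- "design_matrix"
  r <- predictor_correlation_matrix(dm)
  expect_equal(r["a", "b"], 0.5, tolerance = 0.05)
})

test_that("effect-size shift summarizes per-pair differences, not difference of medians", {
  # constructed counterexample where median(o - r) != median(o) - median(r)
  o <- c(0.1, 0.5, 0.9)
  r <- c(0.05, 0.1, 0.85)
  pairs <- make_pairs(3,
                      orig_test_type = "means_between", orig_m1 = o,
                      orig_s1 = 1, orig_n1 = 1000, orig_m2 = 0, orig_s2 = 1,
                      orig_n2 = 1000,
                      rep_test_type = "means_between", rep_m1 = abs(r),
                      rep_s1 = 1, rep_n1 = 1000, rep_m2 = 0, rep_s2 = 1,
                      rep_n2 = 1000,
                      same_direction = r >= 0)
  sh <- effect_size_shift(pairs)
  d_pair <- median(pairs_d <- derive_effects(pairs)$orig_est -
                     derive_effects(pairs)$rep_est)
  expect_equal(sh$difference[2], d_pair, tolerance = 1e-9)
  d_of_medians <- sh$original[2] - sh$replication[2]
  expect_gt(abs(sh$difference[2] - d_of_medians), 0.01)

  # identical replications: zero shift
  pairs2 <- make_pairs(3, orig_statistic = c(2, 3, 4),
                       rep_statistic = c(2, 3, 4),
                       rep_n1 = 50, rep_n2 = 50)
  sh2 <- effect_size_shift(pairs2)
  expect_equal(sh2$difference[2], 0, tolerance = 1e-12)

  expect_error(effect_size_shift(make_pairs(2, subjective_score = 0),
                                 subset_rule = "score_1"),
               class = "replistat_domain_error")
})

test_that("outcome inter-correlation ordering matches the expected structure", {
  # simulate a cohort where the subjective score tracks replication evidence;
  # PI membership and p_orig derive from the same statistic, so they should
  # correlate more strongly with each other than either does with the score
  sim <- simulate_pairs(generator_config(n_pairs = 400), seed = 55)
  met <- compute_pair_metrics(sim$pairs)
  ok <- !is.na(met$in_interval)
  r_pi_p <- cor(as.numeric(met$in_interval[ok]), met$p_orig[ok])
  r_s_pi <- cor(met$subjective_score[ok], as.numeric(met$in_interval[ok]))
  r_s_p <- cor(met$subjective_score[ok], met$p_orig[ok])
  expect_gt(r_pi_p, r_s_pi)
  expect_gt(r_s_pi, 0)
  expect_gt(r_s_p, 0)
})
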