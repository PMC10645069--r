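test_that("a valid fixture set round-trips with zero issues", {
  pairs <- make_pairs(5)
  expect_equal(nrow(attr(pairs, "issues")), 0)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_coded_dataset(pairs, f1)
  back <- read_coded_dataset(f1)
  expect_equal(nrow(back), 5)
  expect_equal(nrow(attr(back, "issues")), 0)
  expect_equal(as.data.frame(back)[pair_schema_columns()],
               as.data.frame(pairs)[pair_schema_columns()])
})

test_that("write -> read -> write is byte-stable", {
  sim <- simulate_pairs(generator_config(n_pairs = 25), seed = 11)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_coded_dataset(sim$pairs, f1)
  write_coded_dataset(read_coded_dataset(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulated datasets re-read field-for-field equal", {
  sim <- simulate_pairs(generator_config(n_pairs = 30), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_coded_dataset(sim$pairs, f)
  back <- read_coded_dataset(f)
  for (cl in pair_schema_columns()) {
    expect_equal(back[[cl]], sim$pairs[[cl]], info = cl)
  }
})

test_that("validation reports off-grid scores and missing required stats", {
  bad <- blank_pair_row()
  bad$subjective_score <- 0.3
  issues <- validate_record(bad)
  expect_length(issues, 1)
  expect_match(issues, "0.5, 0.75, 1", fixed = TRUE)

  bad2 <- blank_pair_row()
  bad2$orig_n2 <- NA
  expect_match(validate_record(bad2), "orig_n2")

  # a pair without statistics is valid: metrics are optional
  none <- blank_pair_row()
  none$orig_test_type <- "none"
  none$rep_test_type <- "none"
  none$orig_statistic <- NA
  none$rep_statistic <- NA
  expect_length(validate_record(none), 0)
})

test_that("reader surfaces schema errors and per-row issues", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- blank_pair_row()
  write.csv(df[, -2], f, row.names = FALSE)
  expect_error(read_coded_dataset(f), "class_year",
               class = "replistat_schema_error")

  df2 <- rbind(blank_pair_row(), blank_pair_row())
  df2$pair_id <- c("a", "b")
  df2$subjective_score[2] <- 0.33
  write.csv(df2, f, row.names = FALSE)
  got <- read_coded_dataset(f)
  iss <- attr(got, "issues")
  expect_equal(iss$row, 2L)
  expect_equal(iss$pair_id, "b")
})

test_that("column mapping renames foreign headers", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- blank_pair_row()
  names(df)[names(df) == "subfield"] <- "area"
  write.csv(df, f, row.names = FALSE)
  got <- read_coded_dataset(f, mapping = c(area = "subfield"))
  expect_equal(got$subfield, "cognitive")
})

test_that("switched_to_online is 1 only for in-person originals with online replications", {
  pairs <- make_pairs(4,
                      original_online = c(FALSE, TRUE, FALSE, TRUE),
                      replication_online = c(TRUE, TRUE, FALSE, FALSE))
  dm <- transform_predictors(pairs)
  expect_equal(unname(dm$x[, "switched_to_online"]), c(1, 0, 0, 0))
})

test_that("continuous predictors are z-scored and the log ratio is exact", {
  sim <- simulate_pairs(generator_config(n_pairs = 80), seed = 2)
  dm <- transform_predictors(sim$pairs)
  for (cl in intersect(colnames(dm$x),
                       c("log_n_trials", "publication_year",
                         "log_n_original", "log_n_ratio"))) {
    expect_lt(abs(mean(dm$x[, cl])), 1e-9)
    expect_lt(abs(sd(dm$x[, cl]) - 1), 1e-9)
  }
  dummies <- setdiff(colnames(dm$x), c("log_n_trials", "publication_year",
                                       "log_n_original", "log_n_ratio"))
  expect_true(all(dm$x[, dummies] %in% c(0, 1)))

  # equal sample sizes give a raw log-ratio of 0 before scaling
  pairs <- make_pairs(3, n_original = c(50L, 80L, 120L),
                      n_replication = c(50L, 40L, 120L))
  dm2 <- transform_predictors(pairs)
  sc <- dm2$scaling
  raw <- dm2$x[, "log_n_ratio"] * sc$scale[sc$column == "log_n_ratio"] +
    sc$center[sc$column == "log_n_ratio"]
  expect_equal(unname(raw), c(0, log(0.5), 0), tolerance = 1e-12)
})

test_that("transform_predictors is order-independent up to row permutation", {
  sim <- simulate_pairs(generator_config(n_pairs = 40), seed = 9)
  dm1 <- transform_predictors(sim$pairs)
  perm <- sample(nrow(sim$pairs))
  dm2 <- transform_predictors(sim$pairs[perm, ])
  expect_equal(dm2$x[order(perm), ], dm1$x)
})

test_that("include_statistics errors name the offending pairs", {
  pairs <- make_pairs(3)
  pairs$orig_test_type[2] <- "none"
  pairs$orig_statistic[2] <- NA
  expect_error(transform_predictors(pairs, include_statistics = TRUE),
               "p2", class = "replistat_domain_error")
})

test_that("analysis subsets are nested (full >= pi >= smd)", {
  sim <- simulate_pairs(generator_config(n_pairs = 150), seed = 13)
  subs <- analysis_subsets(sim$pairs)
  expect_gte(nrow(subs$full), nrow(subs$pi))
  expect_gte(nrow(subs$pi), nrow(subs$smd))
  expect_true(all(subs$smd$pair_id %in% subs$pi$pair_id))
  expect_true(all(subs$pi$pair_id %in% subs$full$pair_id))
  # every pair usable with statistics is usable without
  dm_small <- transform_predictors(subs$smd, include_statistics = TRUE)
  dm_large <- transform_predictors(subs$full, include_statistics = FALSE)
  expect_true(all(dm_small$pair_id %in% dm_large$pair_id))
})
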