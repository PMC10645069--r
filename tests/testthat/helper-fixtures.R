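# Fixtures are built in code: a minimal valid pair row and small pair sets.

blank_pair_row <- function() {
  df <- as.data.frame(setNames(as.list(rep(NA, length(pair_schema_columns()))),
                               pair_schema_columns()))
  df$pair_id <- "p1"
  df$class_year <- 2015L
  df$subfield <- "cognitive"
  df$open_data <- TRUE
  df$open_materials <- TRUE
  df$original_online <- FALSE
  df$replication_online <- TRUE
  df$stanford_affiliation <- FALSE
  df$within_participants <- FALSE
  df$single_vignette <- FALSE
  df$n_trials <- 10L
  df$publication_year <- 2013L
  df$n_original <- 100L
  df$n_replication <- 80L
  df$closeness <- "close"
  df$subjective_score <- 0.75
  df$same_direction <- TRUE
  df$sensitivity_include <- TRUE
  df$orig_test_type <- "t_between"
  df$orig_statistic <- 2.5
  df$orig_n1 <- 50
  df$orig_n2 <- 50
  df$rep_test_type <- "t_between"
  df$rep_statistic <- 1.2
  df$rep_n1 <- 40
  df$rep_n2 <- 40
  df
}

make_pairs <- function(n = 5, ...) {
  rows <- lapply(seq_len(n), function(i) {
    r <- blank_pair_row()
    r$pair_id <- sprintf("p%d", i)
    r
  })
  df <- do.call(rbind, rows)
  mods <- list(...)
  for (nm in names(mods)) df[[nm]] <- mods[[nm]]
  study_pairs(df)
}

# exact effect_estimate builder for metric tests
ee <- function(est, se, scale = "smd") {
  structure(list(estimate = est, se = se, scale = scale, p_value = 0.5,
                 n_total = 100L, source = "test"),
            class = "effect_estimate")
}
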