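test_that("percent change is signed, exact at the boundaries, undefined at zero", {
  expect_equal(percent_change(0.5, 0.25), -50)
  expect_equal(percent_change(2, 2), 0)
  expect_equal(percent_change(0.015, 0), -100)
  expect_true(is.na(percent_change(0, 0.3)))
  # printed-table arithmetic: 0.411 -> 0.355 is -13.6% on the rounded means
  expect_equal(round(percent_change(0.411, 0.355), 1), -13.6)
})

test_that("wave-comparison cells use the right tests", {
  # Fisher exact on the 2x2 table (3,1 / 1,3): two-sided p = 0.486
  cell <- equicare:::cell_stats("ins", "all", c(1, 1, 1, 0), c(1, 0, 0, 0),
                                binary = TRUE)
  expect_equal(cell$test, "fisher")
  expect_equal(round(cell$p.value, 3), 0.486)
  # identical wave distributions: no change, rank-sum p of 1
  x <- c(0, 0, 1, 2, 3, 5)
  cell2 <- equicare:::cell_stats("cnt", "1", x, x, binary = FALSE)
  expect_equal(cell2$pct_change, 0)
  expect_gt(cell2$p.value, 0.95)
  # empty cells are flagged, never dropped
  cell3 <- equicare:::cell_stats("cnt", "2", numeric(0), x, binary = FALSE)
  expect_identical(cell3$note, "empty cell")
  expect_true(is.na(cell3$p.value))
})

test_that("the descriptive table is a pure function with the documented layout", {
  d <- generate_survey(small_config(2500, 2500), seed = 19)
  a <- build_analysis_dataset(d)
  t1 <- descriptive_table(a)
  t2 <- descriptive_table(a)
  expect_identical(t1, t2)
  expect_setequal(unique(t1$quartile), c(as.character(1:4), "all"))
  # 4 services x 3 ownerships + medicines + insurance, 5 quartile groups
  expect_equal(nrow(t1), 14 * 5)
  expect_true(all(t1$p.value >= 0 & t1$p.value <= 1, na.rm = TRUE))
  expect_true(all(t1$test[t1$variable == "insurance"] == "fisher"))
  # percent change column is consistent with its definition
  expect_equal(t1$pct_change,
               percent_change(t1$mean_pre, t1$mean_post))
  f <- format_descriptive(t1)
  expect_equal(f$mean_pre, round(t1$mean_pre, 3))
  expect_equal(f$pct_change, round(t1$pct_change, 1))
  # raw recall-window variant is exposed
  t3 <- descriptive_table(a, annualized = FALSE)
  expect_false(identical(t1$mean_pre, t3$mean_pre))
})

test_that("the model sequence fits nested covariate sets and flags failures", {
  d <- generate_survey(small_config(2500, 2500), seed = 20)
  a <- build_analysis_dataset(d)
  ms <- run_model_sequence(a, "emergency", "public")
  expect_s3_class(ms, "model_sequence")
  expect_equal(length(ms$fits), 6)   # 2 waves x 3 models
  # covariate nesting: Model 1 quartiles only, Model 3 adds insurance + GHQ
  f1 <- ms$fits[["2006.1"]]
  f3 <- ms$fits[["2006.3"]]
  expect_setequal(names(f1$coefficients$use),
                  c("(Intercept)", paste0("quartileq", 2:4)))
  expect_true(all(c("insurance", "ghq12") %in% names(f3$coefficients$use)))
  expect_true(all(c("sexfemale") %in% names(f3$coefficients$use)))
  # table covers both parts, three quartile contrasts, both waves
  expect_equal(nrow(ms$table), 2 * 3 * 2 * 3)
  expect_true(all(is.na(ms$table$note)))
  g <- glance(ms)
  expect_equal(nrow(g), 6)

  # reference-quartile ratio is exactly one
  rr <- rate_ratio(f3, contrast = c(quartileq2 = 0), part = "use")
  expect_identical(rr$estimate, 1)

  # medicines are total-only
  expect_error(run_model_sequence(a, "medicines", "private"),
               class = "equicare_data_error")

  # a wave with no private users at all is flagged unavailable, not dropped
  a2 <- a
  a2$hospital_annual_private[a2$wave == 2011] <- 0L
  ms2 <- run_model_sequence(a2, "hospital", "private", models = 1)
  expect_true(length(ms2$errors) >= 1)
  bad_rows <- ms2$table[ms2$table$wave == 2011, ]
  expect_true(all(is.na(bad_rows$estimate)))
  expect_true(all(grepl("unavailable", bad_rows$note)))
})

test_that("confounder-free quartile effects agree between Model 1 and Model 3", {
  # income enters through quartile dummies only and no other covariate
  # affects utilisation, so all three models estimate the same contrast
  cfg <- small_config(3500, 3500)
  cfg$services <- drop_effects(cfg$services,
                               c("income_z", "ghq12", "female", "insurance",
                                 paste0("age_", c("36_45", "46_55", "56_65",
                                                  "66_75", "75p"))))
  cfg$services$emergency$beta1 <- c(cfg$services$emergency$beta1,
                                    income_q4 = -0.75)
  d <- generate_survey(cfg, seed = 21)
  a <- build_analysis_dataset(d)
  ms <- run_model_sequence(a, "emergency", "total", models = c(1, 3))
  t1 <- ms$table[ms$table$model == 1 & ms$table$part == "use" &
                   ms$table$term == "quartileq4" & ms$table$wave == 2006, ]
  t3 <- ms$table[ms$table$model == 3 & ms$table$part == "use" &
                   ms$table$term == "quartileq4" & ms$table$wave == 2006, ]
  se <- t3$std.error
  expect_lt(abs(log(t1$estimate) - log(t3$estimate)), 3 * se)
  # and the Model 3 interval covers the true effect
  expect_lt(t3$conf.low, exp(-0.75 + 3 * se))
  expect_gt(t3$conf.high, exp(-0.75 - 3 * se))
})
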