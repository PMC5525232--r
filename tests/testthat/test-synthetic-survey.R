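test_that("generation is deterministic under a fixed seed and varies across seeds", {
  cfg <- small_config(100, 100)
  d1 <- generate_survey(cfg, seed = 7)
  d2 <- generate_survey(cfg, seed = 7)
  expect_identical(d1, d2)
  d3 <- generate_survey(cfg, seed = 8)
  expect_false(identical(d1$income_band, d3$income_band))
})

test_that("income band dialects have 8 (2006) and 10 (2011) bands", {
  d <- generate_survey(small_config(6000, 6000), seed = 2)
  expect_setequal(unique(d$income_band[d$wave == 2006]), 1:8)
  expect_setequal(unique(d$income_band[d$wave == 2011]), 1:10)
})

test_that("an income exactly at a cut point falls in the upper band", {
  cuts <- c(100, 200, 300)
  expect_identical(equicare:::discretize_income(c(99.999, 100, 200, 300, 301), cuts),
                   c(1L, 2L, 3L, 4L, 4L))
  expect_error(equicare:::discretize_income(1, c(2, 2, 3)),
               class = "equicare_config_error")
})

test_that("a hurdle intercept at the minus-infinity limit yields all-zero counts", {
  cfg <- small_config(300, 300)
  cfg$services$primary$beta1 <- c("(Intercept)" = -Inf)
  d <- generate_survey(cfg, seed = 5)
  expect_true(all(d$primary_4wk == 0))
  expect_true(all(is.na(d$primary_private)))
})

test_that("positive counts match the closed-form truncated mean", {
  # sigma_u = 0, intercept-only emergency process: the mean of the positive
  # counts has closed form mu / (1 - P0), computed here by pmf summation
  cfg <- small_config(20000, 10, sigma_u = 0)
  cfg$services$emergency <- list(beta1 = c("(Intercept)" = 0.2),
                                 beta2 = c("(Intercept)" = log(2)),
                                 phi = 0.5)
  d <- generate_survey(cfg, seed = 11)
  y <- d$emergency_12m[d$wave == 2006]
  pos <- y[y > 0]
  m_true <- sum((1:2000) * dztnb(1:2000, 2, 0.5))
  expect_lt(abs(mean(pos) - m_true), 3 * sd(pos) / sqrt(length(pos)))
})

test_that("the generated zero fraction matches the averaged hurdle probability", {
  cfg <- small_config(20000, 10, sigma_u = 0)
  d <- generate_survey(cfg, seed = 13)
  d06 <- d[d$wave == 2006, ]
  D <- equicare:::utilization_design(d06$sex, d06$age_band, d06$ghq12,
                                     d06$insurance, d06$.true_income_z,
                                     d06$.true_quartile, 2006)
  p_use <- plogis(equicare:::lin_pred(D, cfg$services$emergency$beta1))
  zero_expected <- mean(1 - p_use)
  zero_observed <- mean(d06$emergency_12m == 0)
  se <- sqrt(zero_expected * (1 - zero_expected) / nrow(d06))
  expect_lt(abs(zero_observed - zero_expected), 3 * se)
})

test_that("survey files round-trip through CSV", {
  d <- generate_survey(small_config(150, 150), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(d, path)
  d2 <- read_survey(path)
  keep <- survey_schema()$column
  expect_equal(as.data.frame(d[, keep]), as.data.frame(d2), ignore_attr = TRUE)
})

test_that("schema violations are rejected with row and column named", {
  d <- generate_survey(small_config(50, 50), seed = 4)
  bad <- d
  bad$ghq12[3] <- 13L
  err <- expect_error(validate_survey(bad), class = "equicare_schema_error")
  expect_match(conditionMessage(err), "ghq12")
  expect_match(conditionMessage(err), "row 3")

  bad2 <- d
  i <- which(bad2$primary_4wk == 0)[1]
  bad2$primary_private[i] <- 1L
  err2 <- expect_error(validate_survey(bad2), class = "equicare_schema_error")
  expect_match(conditionMessage(err2), "primary_private")

  bad3 <- d
  bad3$extra_col <- 1
  expect_error(validate_survey(bad3), class = "equicare_schema_error")

  bad4 <- d
  bad4$income_band[bad4$wave == 2006][1] <- 9L
  expect_error(validate_survey(bad4), class = "equicare_schema_error")
})

test_that("invalid configurations are rejected", {
  expect_error(survey_config(income = utils::modifyList(
    survey_config()$income, list(cuts_2006 = c(5, 4, 3, 6, 7, 8, 9)))),
    class = "equicare_config_error")
  expect_error(survey_config(sigma_u = -1), class = "equicare_config_error")
  bad_services <- survey_config()$services
  bad_services$primary$phi <- 0
  expect_error(survey_config(services = bad_services),
               class = "equicare_config_error")
  bad_services2 <- survey_config()$services
  bad_services2$primary$beta1 <- c(nonexistent_term = 1)
  expect_error(survey_config(services = bad_services2),
               class = "equicare_config_error")
})
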