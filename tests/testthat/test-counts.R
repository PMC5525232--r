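split_frame <- function() {
  tibble::tibble(
    id = c("a", "b", "c"), wave = 2006,
    sex = "male", age_band = "15-35", sph = "good", chronic_count = 0L,
    primary_total = c(2L, 0L, 1L), primary_public = c(1L, 0L, 1L),
    primary_private_n = c(1L, 0L, 0L),
    specialist_total = 0L, specialist_public = 0L, specialist_private_n = 0L,
    emergency_total = c(3L, 0L, 1L), emergency_public = c(3L, 0L, 1L),
    emergency_private_n = 0L,
    hospital_total = c(3L, 1L, 0L), hospital_public = c(3L, 1L, 0L),
    hospital_private_n = 0L
  )
}

test_that("annualisation multiplies 4-week services by 12 and passes 12-month counts through", {
  a <- annualize_counts(split_frame())
  expect_identical(a$primary_annual_total, c(24L, 0L, 12L))
  expect_identical(a$primary_annual_public, c(12L, 0L, 12L))
  expect_identical(a$primary_annual_private, c(12L, 0L, 0L))
  # hospitalisations/emergencies are already annual
  expect_identical(a$hospital_annual_total, c(3L, 1L, 0L))
  expect_identical(a$emergency_annual_total, c(3L, 0L, 1L))
  d <- split_frame()
  d$primary_total[1] <- -1L
  expect_error(annualize_counts(d), class = "equicare_data_error")
})

test_that("delay fits require both indicator classes among users", {
  n <- 40
  d <- tibble::tibble(
    id = sprintf("r%02d", 1:n), wave = 2006, sex = "male", age_band = "15-35",
    sph = "good", chronic_count = 0L,
    primary_4wk = rep(1L, n), primary_delayed = rep(1L, n)
  )
  expect_error(fit_delay_model(d, "primary"), class = "equicare_fit_error")
  expect_error(fit_delay_model(d, "emergency"), class = "equicare_data_error")
})

test_that("delay-model recovery stays within three standard errors", {
  set.seed(7)
  n <- 5000
  sex <- rep(c("male", "female"), length.out = n)
  truth <- c(-1.0, 0.5)
  p <- plogis(truth[1] + truth[2] * (sex == "female"))
  d <- tibble::tibble(
    id = sprintf("r%05d", 1:n), wave = 2006, sex = sex, age_band = "15-35",
    sph = "good", chronic_count = 0L,
    primary_4wk = 1L, primary_delayed = rbinom(n, 1, p)
  )
  fit <- fit_delay_model(d, "primary", formula = ~ sex)
  se <- sqrt(diag(vcov(fit$fit)))
  expect_true(all(abs(coef(fit$fit) - truth) <= 3 * se))
})

test_that("zero reporters are imputed one contact only above probability one half", {
  base <- tibble::tibble(
    id = c("u", "v"), wave = 2006, sex = "male", age_band = "15-35",
    sph = "good", chronic_count = 0L,
    primary_4wk = c(0L, 2L), primary_delayed = c(NA, 0L)
  )
  for (case in list(list(p = 0.6, expect = 1L),
                    list(p = 0.5, expect = 0L),
                    list(p = 0.2, expect = 0L))) {
    fit <- crafted_binary_fit(case$p, "primary", 2006, "delay_fit")
    if (case$p == 0.5) fit$fit$coefficients[] <- 0  # exact boundary
    imp <- impute_zero_reporters(fit, base)
    expect_identical(nrow(imp), 1L)    # users are never touched
    expect_identical(imp$id, "u")
    expect_identical(imp$imputed, case$expect)
  }
})

test_that("medicine counts exclude the contraceptive item", {
  d <- tibble::tibble(!!!setNames(as.list(rep(1L, 22)), medicine_cols()))
  expect_identical(count_medicines(d), 21L)
  d0 <- tibble::tibble(!!!setNames(as.list(rep(0L, 22)), medicine_cols()))
  d0$med_22 <- 1L
  expect_identical(count_medicines(d0), 0L)
  alt <- tibble::tibble(!!!setNames(as.list(as.integer(seq_len(22) %% 2)),
                                    medicine_cols()))
  expect_identical(count_medicines(alt), 11L)
  expect_identical(count_medicines(d0, contraceptive = "med_01"), 1L)
  bad <- d
  bad$med_03 <- 2L
  err <- expect_error(count_medicines(bad), class = "equicare_data_error")
  expect_match(conditionMessage(err), "med_03")
})

test_that("all medicine flags zero give a zero downstream count", {
  d <- generate_survey(small_config(200, 200), seed = 16)
  d[, medicine_cols()] <- 0L
  expect_true(all(count_medicines(d) == 0L))
})

test_that("pipeline annual counts are multiples of 12 except imputed singletons", {
  d <- generate_survey(small_config(2500, 2500), seed = 17)
  a0 <- build_analysis_dataset(d, impute_delayed = FALSE)
  a1 <- build_analysis_dataset(d, impute_delayed = TRUE)
  for (s in c("primary", "specialist")) {
    col <- paste0(s, "_annual_total")
    expect_true(all(a0[[col]] %% 12 == 0))
    imputed <- a1[[col]] != a0[[col]]
    expect_true(all(a1[[col]][!imputed] %% 12 == 0))
    expect_true(all(a1[[col]][imputed] == 1L))
    # imputation touches only zero reporters
    raw <- d[[paste0(s, "_4wk")]]
    expect_true(all(raw[imputed] == 0))
    expect_identical(a1[[col]][raw > 0], a0[[col]][raw > 0])
    # imputed single contacts conserve the ownership split
    expect_identical(a1[[paste0(s, "_annual_public")]] +
                       a1[[paste0(s, "_annual_private")]], a1[[col]])
  }
})

test_that("the times-12 rule approximately inverts recall-window thinning", {
  d <- generate_survey(small_config(20000, 10), seed = 18)
  d06 <- d[d$wave == 2006, ]
  # annualise without the delayed-contact imputation: bias is documented
  ann <- 12 * d06$primary_4wk
  expect_lt(abs(mean(ann) - mean(d06$.true_primary_annual)) /
              mean(d06$.true_primary_annual), 0.10)
})
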