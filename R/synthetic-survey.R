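#' Survey schema constants
#'
#' Category levels and per-service column metadata for the synthetic survey
#' emulating two repeated cross-sectional health-survey waves: a pre-crisis
#' wave (2006, annual income asked in 8 bands) and a crisis wave (2011,
#' monthly income asked in 10 bands). Primary and specialist contacts are
#' reported over a 4-week recall window, emergencies and hospitalisations
#' over 12 months.
#'
#' @return `service_meta()` returns a tibble with one row per service:
#'   `service`, `count_col`, `private_col`, `delayed_col`, `window`.
#' @export
service_meta <- function() {
  tibble(
    service = c("primary", "specialist", "emergency", "hospital"),
    count_col = c("primary_4wk", "specialist_4wk", "emergency_12m", "hospital_12m"),
    private_col = c("primary_private", "specialist_private",
                    "emergency_private", "hospital_private"),
    delayed_col = c("primary_delayed", "specialist_delayed", NA, NA),
    window = c("4wk", "4wk", "12m", "12m")
  )
}

age_levels <- function() c("15-35", "36-45", "46-55", "56-65", "66-75", "75+")
occupation_levels <- function() c("working", "unemployed_lt1y", "unemployed_gt1y",
                                  "housework", "student", "retiree", "other")
education_levels <- function() c("insufficient", "primary", "secondary", "university")
sph_levels <- function() c("very_good", "good", "fair", "bad", "very_bad")
medicine_cols <- function() sprintf("med_%02d", 1:22)

# names of design columns available to generator effect vectors
design_terms <- function() {
  c("(Intercept)", "female", paste0("age_", c("36_45", "46_55", "56_65",
                                              "66_75", "75p")),
    "ghq12", "insurance", "income_z", "income_q2", "income_q3", "income_q4",
    "wave_2011")
}

# design columns for ownership/delay processes (matches the covariates the
# imputation models fit: sex, age, self-perceived health, chronic count)
ownership_terms <- function() {
  c("(Intercept)", "female", paste0("age_", c("36_45", "46_55", "56_65",
                                              "66_75", "75p")),
    paste0("sph_", c("good", "fair", "bad", "very_bad")), "chronic_count")
}

#' Configuration of the synthetic survey generator
#'
#' Houses every true parameter of the data-generating process so that
#' downstream estimators can be tested for recovery. Defaults emulate the
#' two survey waves the analysis targets: wave sample sizes 29,712 (2006)
#' and 19,935 (2011); sex and age-band composition per wave; interval
#' censored household income (8 annual bands in 2006, 10 monthly bands in
#' 2011, the monthly cut points annualised internally by multiplying by 12);
#' and, for each of four services, a two-part process: any use is Bernoulli
#' with a logistic linear predictor, frequency among users is zero-truncated
#' negative binomial (NB1 dispersion `phi`), both sharing a household-level
#' Gaussian random intercept with SD `sigma_u`. Annual primary/specialist
#' contacts are thinned into the 4-week recall window with probability 4/52
#' per contact, so the times-12 annualisation is an approximate inverse.
#' Ownership of each contact is drawn from a per-service logistic model in
#' sex, age, self-perceived health and chronic count; the delayed-contact
#' indicator for users comes from an analogous logistic model.
#'
#' Effect vectors are named numeric vectors over the design dictionary
#' `equicare:::design_terms()` (`income_z` is the standardised latent income,
#' `income_q2`..`income_q4` true within-wave quartile indicators,
#' `wave_2011` a crisis-wave shift); unnamed terms default to zero, so
#' configurations with no income or wave effects are expressed by dropping
#' those names.
#'
#' @param n named vector of respondents per wave.
#' @param age_min named lower age bound per wave (the first band's lower
#'   edge; surveys have differed on 15 vs 16).
#' @param female_p named probability of `sex == "female"` per wave.
#' @param age_probs named list of length-6 probability vectors per wave.
#' @param occupation_probs,education_probs,sph_probs category probabilities.
#' @param hh_lambda household size is `1 + Poisson(hh_lambda)`.
#' @param income list: `gamma` (latent-index coefficients over sex, age,
#'   occupation, education, household size), `log_location`, `log_scale`
#'   (euros = `exp(log_location + log_scale * index)`), `cuts_2006` (annual
#'   euros, 7 strictly increasing cut points), `cuts_2011` (monthly euros,
#'   9 cut points).
#' @param insurance `c(intercept, income_z)` on the logit scale.
#' @param ghq `c(shape1, shape2)` of the beta-binomial GHQ-12 score.
#' @param chronic_lambda Poisson mean of the chronic-condition count per
#'   age band (length 6).
#' @param services per-service lists with `beta1`, `beta2` (named effect
#'   vectors) and `phi > 0`.
#' @param ownership,delay named effect vectors over
#'   `equicare:::ownership_terms()` per service.
#' @param sigma_u household random-intercept SD (>= 0).
#' @param group_lambda sampled household cluster size is
#'   `1 + Poisson(group_lambda)` (default mean 2.5).
#' @param window_frac per-contact probability of falling in the 4-week
#'   recall window.
#' @param medicines list: `item_logits` (length 22), `ghq` slope,
#'   `frailty_sd`; item `contraceptive_item` is only available to
#'   younger women.
#' @param contraceptive_item index (1-22) of the contraceptive item.
#' @param miss_rate completely-at-random missingness rate applied to
#'   `ghq12`, `sph` and `chronic_count` (default 0).
#' @return a `survey_config` list, validated.
#' @export
survey_config <- function(
    n = c("2006" = 29712, "2011" = 19935),
    age_min = c("2006" = 15, "2011" = 15),
    female_p = c("2006" = 0.606, "2011" = 0.539),
    age_probs = list(
      "2006" = c(0.240, 0.198, 0.159, 0.136, 0.134, 0.118),
      "2011" = c(0.229, 0.187, 0.163, 0.107, 0.136, 0.145)
    ),
    occupation_probs = c(working = 0.45, unemployed_lt1y = 0.05,
                         unemployed_gt1y = 0.06, housework = 0.12,
                         student = 0.07, retiree = 0.22, other = 0.03),
    education_probs = c(insufficient = 0.12, primary = 0.30,
                        secondary = 0.38, university = 0.20),
    sph_probs = c(very_good = 0.16, good = 0.48, fair = 0.24,
                  bad = 0.09, very_bad = 0.03),
    hh_lambda = 1.8,
    income = list(
      gamma = c(female = -0.05, age_36_45 = 0.30, age_46_55 = 0.35,
                age_56_65 = 0.20, age_66_75 = 0.00, age_75p = -0.20,
                occ_unemployed_lt1y = -0.50, occ_unemployed_gt1y = -0.90,
                occ_housework = -0.50, occ_student = -0.20,
                occ_retiree = -0.40, occ_other = -0.50,
                edu_primary = 0.30, edu_secondary = 0.70,
                edu_university = 1.30, household_size = 0.05),
      log_location = 9.80, log_scale = 0.60,
      cuts_2006 = c(4800, 9600, 14400, 19200, 26400, 36000, 60000),
      cuts_2011 = c(550, 800, 1050, 1300, 1550, 1850, 2250, 2750, 3450)
    ),
    insurance = c(intercept = qlogis(0.125), income_z = 0.55),
    ghq = c(shape1 = 0.35, shape2 = 2.30),
    chronic_lambda = c(0.5, 0.8, 1.2, 1.8, 2.5, 3.2),
    services = list(
      primary = list(
        beta1 = c("(Intercept)" = 0.50, female = 0.25, age_66_75 = 0.50,
                  age_75p = 0.70, ghq12 = 0.06, income_z = -0.15,
                  wave_2011 = -0.20),
        beta2 = c("(Intercept)" = 1.60, ghq12 = 0.03, age_75p = 0.30,
                  income_z = -0.10),
        phi = 1.5),
      specialist = list(
        beta1 = c("(Intercept)" = -0.20, female = 0.20, ghq12 = 0.05,
                  insurance = 0.30, income_z = 0.25, wave_2011 = 0.50),
        beta2 = c("(Intercept)" = 1.30, income_z = 0.10),
        phi = 1.2),
      emergency = list(
        beta1 = c("(Intercept)" = -1.00, ghq12 = 0.05, age_75p = 0.30,
                  income_z = -0.25),
        beta2 = c("(Intercept)" = 0.50, income_z = -0.10),
        phi = 0.8),
      hospital = list(
        beta1 = c("(Intercept)" = -2.20, age_66_75 = 0.40, age_75p = 0.70,
                  ghq12 = 0.04, income_z = -0.15, wave_2011 = -0.10),
        beta2 = c("(Intercept)" = 0.20),
        phi = 0.5)
    ),
    ownership = list(
      primary = c("(Intercept)" = -2.60, sph_bad = -0.30, chronic_count = -0.05),
      specialist = c("(Intercept)" = -1.80, female = 0.10, sph_good = -0.10),
      emergency = c("(Intercept)" = -3.00, age_75p = -0.30),
      hospital = c("(Intercept)" = -3.20, chronic_count = -0.05)
    ),
    delay = list(
      primary = c("(Intercept)" = -1.20, sph_bad = 0.40, sph_very_bad = 0.60,
                  chronic_count = 0.05),
      specialist = c("(Intercept)" = -0.80, sph_bad = 0.30, chronic_count = 0.05)
    ),
    sigma_u = 0.3,
    group_lambda = 1.5,
    window_frac = 4 / 52,
    medicines = list(item_logits = qlogis(seq(0.02, 0.22, length.out = 22)),
                     ghq = 0.10, frailty_sd = 0.8),
    contraceptive_item = 22,
    miss_rate = 0) {
  cfg <- list(n = n, age_min = age_min, female_p = female_p,
              age_probs = age_probs, occupation_probs = occupation_probs,
              education_probs = education_probs, sph_probs = sph_probs,
              hh_lambda = hh_lambda, income = income, insurance = insurance,
              ghq = ghq, chronic_lambda = chronic_lambda, services = services,
              ownership = ownership, delay = delay, sigma_u = sigma_u,
              group_lambda = group_lambda, window_frac = window_frac,
              medicines = medicines, contraceptive_item = contraceptive_item,
              miss_rate = miss_rate)
  validate_config(cfg)
  structure(cfg, class = "survey_config")
}

validate_config <- function(cfg) {
  for (w in c("2006", "2011")) {
    cuts <- if (w == "2006") cfg$income$cuts_2006 else cfg$income$cuts_2011
    if (any(diff(cuts) <= 0)) {
      abort(sprintf("income cut points for wave %s must be strictly increasing.", w),
            class = "equicare_config_error")
    }
  }
  if (length(cfg$income$cuts_2006) != 7 || length(cfg$income$cuts_2011) != 9) {
    abort("dialects require 7 (2006, 8 bands) and 9 (2011, 10 bands) cut points.",
          class = "equicare_config_error")
  }
  for (s in names(cfg$services)) {
    if (cfg$services[[s]]$phi <= 0) {
      abort(sprintf("phi for service '%s' must be > 0.", s),
            class = "equicare_config_error")
    }
    bad1 <- setdiff(names(cfg$services[[s]]$beta1), design_terms())
    bad2 <- setdiff(names(cfg$services[[s]]$beta2), design_terms())
    if (length(c(bad1, bad2))) {
      abort(sprintf("unknown design term(s) for '%s': %s", s,
                    paste(c(bad1, bad2), collapse = ", ")),
            class = "equicare_config_error")
    }
  }
  if (cfg$sigma_u < 0) abort("sigma_u must be >= 0.", class = "equicare_config_error")
  invisible(cfg)
}

#' Generate a synthetic two-wave health survey
#'
#' Draws a full respondent-level microdata set from the process described in
#' [survey_config()]: covariates, latent household income discretised by the
#' wave's band dialect (half-open intervals: an income exactly at a cut
#' point falls in the upper band), two-part utilisation counts per service
#' with household random effects, per-contact public/private ownership,
#' recall-window thinning for primary/specialist care, last-contact
#' ownership and delayed-contact indicators, and 22 binary medicine items.
#'
#' Columns prefixed `.true_` carry generator truth (latent income, true
#' quartile, true annual and annual-private counts) for recovery tests;
#' [write_survey()] drops them.
#'
#' @param config a [survey_config()].
#' @param seed integer seed; the output is a deterministic function of
#'   `(config, seed)`.
#' @return a tibble, one row per respondent.
#' @export
generate_survey <- function(config = survey_config(), seed = 1) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(seed)
  out <- lapply(c("2006", "2011"), function(w) generate_wave(config, w))
  dplyr::bind_rows(out)
}

generate_wave <- function(cfg, w) {
  n <- as.integer(cfg$n[[w]])
  wave <- as.integer(w)
  sex <- ifelse(runif(n) < cfg$female_p[[w]], "female", "male")
  age_band <- sample(age_levels(), n, TRUE, prob = cfg$age_probs[[w]])
  occupation <- sample(occupation_levels(), n, TRUE, prob = cfg$occupation_probs)
  education <- sample(education_levels(), n, TRUE, prob = cfg$education_probs)
  household_size <- 1L + rpois(n, cfg$hh_lambda)
  sph <- sample(sph_levels(), n, TRUE, prob = cfg$sph_probs)
  ghq12 <- rbinom(n, 12, rbeta(n, cfg$ghq[["shape1"]], cfg$ghq[["shape2"]]))
  chronic_count <- rpois(n, cfg$chronic_lambda[match(age_band, age_levels())])

  # latent annual income (euros) from an ordered-probit style index
  Xi <- income_design(sex, age_band, occupation, education, household_size)
  idx <- drop(Xi %*% cfg$income$gamma[colnames(Xi)]) + rnorm(n)
  income_eur <- exp(cfg$income$log_location + cfg$income$log_scale * idx)
  cuts <- if (w == "2006") cfg$income$cuts_2006 else 12 * cfg$income$cuts_2011
  income_band <- discretize_income(income_eur, cuts)

  income_z <- as.numeric(scale(idx))
  qlab <- assign_quartiles(idx)

  insurance <- rbinom(n, 1, plogis(cfg$insurance[["intercept"]] +
                                     cfg$insurance[["income_z"]] * income_z))

  # household clusters carrying the shared random intercept
  gsize <- 1L + rpois(ceiling(n / (1 + cfg$group_lambda)) + n, cfg$group_lambda)
  gid <- rep.int(seq_along(gsize), gsize)[seq_len(n)]
  ueff <- (if (cfg$sigma_u > 0) rnorm(max(gid), 0, cfg$sigma_u) else numeric(max(gid)))[gid]
  group_id <- sprintf("w%s_h%06d", w, gid)

  D <- utilization_design(sex, age_band, ghq12, insurance, income_z, qlab, wave)
  Do <- ownership_design(sex, age_band, sph, chronic_count)

  rec <- tibble(
    id = sprintf("w%s_%06d", w, seq_len(n)), wave = wave, sex = sex,
    age_band = age_band, income_band = income_band, occupation = occupation,
    education = education, household_size = household_size,
    insurance = insurance, ghq12 = ghq12, sph = sph,
    chronic_count = chronic_count, group_id = group_id,
    .true_income_eur = income_eur, .true_income_z = income_z,
    .true_quartile = qlab
  )

  meta <- service_meta()
  for (i in seq_len(nrow(meta))) {
    s <- meta$service[i]
    sv <- cfg$services[[s]]
    eta1 <- lin_pred(D, sv$beta1) + ueff
    use <- rbinom(n, 1, plogis(eta1))
    annual <- integer(n)
    if (any(use == 1)) {
      mu2 <- exp(pmin(lin_pred(D, sv$beta2)[use == 1] + ueff[use == 1], 35))
      annual[use == 1] <- rztnb(sum(use), mu2, sv$phi)
    }
    p_own <- plogis(lin_pred(Do, cfg$ownership[[s]]))
    priv_annual <- rbinom(n, annual, p_own)

    if (meta$window[i] == "4wk") {
      obs_priv <- rbinom(n, priv_annual, cfg$window_frac)
      obs_pub <- rbinom(n, annual - priv_annual, cfg$window_frac)
      obs <- obs_priv + obs_pub
    } else {
      obs <- annual
      obs_priv <- priv_annual
    }
    last_priv <- rep(NA_integer_, n)
    pos <- obs > 0
    last_priv[pos] <- rbinom(sum(pos), 1, obs_priv[pos] / obs[pos])

    rec[[meta$count_col[i]]] <- as.integer(obs)
    rec[[meta$private_col[i]]] <- last_priv
    if (!is.na(meta$delayed_col[i])) {
      del <- rep(NA_integer_, n)
      p_del <- plogis(lin_pred(Do, cfg$delay[[s]]))
      del[pos] <- rbinom(sum(pos), 1, p_del[pos])
      rec[[meta$delayed_col[i]]] <- del
    }
    rec[[paste0(".true_", s, "_annual")]] <- as.integer(annual)
    rec[[paste0(".true_", s, "_private")]] <- as.integer(priv_annual)
  }

  # medicine items with a shared per-person frailty
  frail <- rnorm(n, 0, cfg$medicines$frailty_sd)
  for (k in 1:22) {
    if (k == cfg$contraceptive_item) {
      p <- ifelse(sex == "female" & age_band %in% c("15-35", "36-45"),
                  plogis(-2), 0)
    } else {
      p <- plogis(cfg$medicines$item_logits[k] + cfg$medicines$ghq * ghq12 + frail)
    }
    rec[[sprintf("med_%02d", k)]] <- rbinom(n, 1, p)
  }

  if (cfg$miss_rate > 0) {
    for (cl in c("ghq12", "sph", "chronic_count")) {
      rec[[cl]][runif(n) < cfg$miss_rate] <- NA
    }
  }
  rec
}

income_design <- function(sex, age_band, occupation, education, household_size) {
  cbind(
    female = as.numeric(sex == "female"),
    band_dummies(age_band, age_levels(), "age_"),
    band_dummies(occupation, occupation_levels(), "occ_"),
    band_dummies(education, education_levels(), "edu_"),
    household_size = household_size
  )
}

utilization_design <- function(sex, age_band, ghq12, insurance, income_z,
                               quartile, wave) {
  n <- length(sex)
  cbind(`(Intercept)` = rep(1, n),
        female = as.numeric(sex == "female"),
        band_dummies(age_band, age_levels(), "age_"),
        ghq12 = ghq12, insurance = insurance, income_z = income_z,
        income_q2 = as.numeric(quartile == 2),
        income_q3 = as.numeric(quartile == 3),
        income_q4 = as.numeric(quartile == 4),
        wave_2011 = as.numeric(wave == 2011))
}

ownership_design <- function(sex, age_band, sph, chronic_count) {
  n <- length(sex)
  cbind(`(Intercept)` = rep(1, n),
        female = as.numeric(sex == "female"),
        band_dummies(age_band, age_levels(), "age_"),
        band_dummies(sph, sph_levels(), "sph_"),
        chronic_count = chronic_count)
}

band_dummies <- function(x, levels, prefix) {
  out <- vapply(levels[-1], function(l) as.numeric(x == l), numeric(length(x)))
  colnames(out) <- paste0(prefix, sanitize_level(levels[-1]))
  out
}

sanitize_level <- function(l) gsub("\\+", "p", gsub("-", "_", l))

# half-open banding: an income exactly at a cut point falls in the upper band
discretize_income <- function(eur, cuts) {
  if (any(diff(cuts) <= 0)) {
    abort("income cut points must be strictly increasing.",
          class = "equicare_config_error")
  }
  1L + findInterval(eur, cuts)
}

# linear predictor from a named effect vector over design columns
lin_pred <- function(D, beta) {
  if (is.null(beta) || !length(beta)) return(numeric(nrow(D)))
  miss <- setdiff(names(beta), colnames(D))
  if (length(miss)) {
    abort(sprintf("unknown design term(s): %s", paste(miss, collapse = ", ")),
          class = "equicare_config_error")
  }
  drop(D[, names(beta), drop = FALSE] %*% beta)
}
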