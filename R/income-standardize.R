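#' Harmonize interval-censored income across survey waves
#'
#' The two waves ask household income in incompatible dialects (8 annual
#' bands in 2006, 10 monthly bands in 2011), so band indices are not
#' comparable. [fit_income_probit()] fits, per wave, an ordered probit of
#' the observed band on sex, age band, occupation, education and household
#' size: for observed band \eqn{k} the likelihood contribution is
#' \eqn{\Phi(c_k - X'\gamma) - \Phi(c_{k-1} - X'\gamma)} with strictly
#' increasing thresholds \eqn{c}. [score_income()] places every respondent
#' on a common continuous scale using the fitted latent index
#' \eqn{X'\hat\gamma}; any strictly monotone transform of the index (for
#' example the expected band, or \eqn{\Phi} of the index) yields identical
#' quartiles, which are the only downstream use of the score.
#' [assign_quartiles()] then labels within-wave quartiles (1 = poorest =
#' reference).
#'
#' @param data survey records of a single wave (see [generate_survey()]).
#' @param formula model formula; the default matches the harmonisation
#'   covariates: sex, age band, occupation, education, household size.
#' @return `fit_income_probit()`: an `income_probit_fit` with elements
#'   `coefficients`, `thresholds` (strictly increasing), `wave`, `fit` (the
#'   underlying ordered-probit fit), `converged`.
#' @export
fit_income_probit <- function(data,
                              formula = income_band ~ sex + age_band +
                                occupation + education + household_size) {
  wave <- unique(data$wave)
  if (length(wave) != 1) {
    abort("fit one wave at a time: `data` contains multiple waves.",
          class = "equicare_data_error")
  }
  bands <- data[[as.character(formula[[2]])]]
  seen <- sort(unique(bands))
  empty <- setdiff(seq_len(max(seen)), seen)
  if (length(empty)) {
    abort(sprintf("wave %s: no observations in income band(s) %s.",
                  wave, paste(empty, collapse = ", ")),
          class = "equicare_fit_error")
  }
  if (length(seen) < 2) {
    abort("need at least two observed income bands.",
          class = "equicare_fit_error")
  }
  d <- as.data.frame(data)
  d[[as.character(formula[[2]])]] <- factor(bands, levels = seen,
                                            ordered = TRUE)
  d <- set_reference_levels(d)
  if (length(seen) == 2) {
    # two observed bands: the ordered probit reduces to probit regression
    # with threshold c1 = -intercept
    f2 <- stats::as.formula(paste0("I(", as.character(formula[[2]]),
                                   " == ", max(seen), ") ~ ",
                                   deparse(formula[[3]])))
    fit <- tryCatch(glm(f2, family = binomial("probit"), data = d),
                    error = function(e) abort(
                      sprintf("probit fit failed for wave %s: %s", wave,
                              conditionMessage(e)),
                      class = "equicare_fit_error"))
    cf <- coef(fit)
    return(structure(list(coefficients = cf[-1],
                          thresholds = setNames(-cf[1], "1|2"),
                          wave = wave, fit = fit, formula = formula,
                          converged = fit$converged),
                     class = "income_probit_fit"))
  }
  fit <- tryCatch(
    MASS::polr(formula, data = d, method = "probit", Hess = TRUE),
    error = function(e) abort(sprintf("ordered probit failed for wave %s: %s",
                                      wave, conditionMessage(e)),
                              class = "equicare_fit_error")
  )
  structure(list(coefficients = coef(fit), thresholds = fit$zeta,
                 wave = wave, fit = fit, formula = formula,
                 converged = fit$convergence == 0),
            class = "income_probit_fit")
}

# reference categories fixed across the package: male, 15-35, working,
# insufficient instruction, very good health
set_reference_levels <- function(d) {
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, c("male", "female"))
  if ("age_band" %in% names(d)) d$age_band <- factor(d$age_band, age_levels())
  if ("occupation" %in% names(d)) d$occupation <- factor(d$occupation, occupation_levels())
  if ("education" %in% names(d)) d$education <- factor(d$education, education_levels())
  if ("sph" %in% names(d)) d$sph <- factor(d$sph, sph_levels())
  d
}

#' @rdname fit_income_probit
#' @param fit an `income_probit_fit`.
#' @return `score_income()`: a numeric vector, the fitted latent index
#'   \eqn{X'\hat\gamma} per respondent.
#' @export
score_income <- function(fit, data) {
  stopifnot(inherits(fit, "income_probit_fit"))
  d <- set_reference_levels(as.data.frame(data))
  tt <- delete.response(terms(fit$formula))
  for (v in all.vars(tt)) {
    if (is.factor(d[[v]])) {
      bad <- is.na(d[[v]]) & !is.na(data[[v]])
      if (any(bad)) {
        abort(sprintf("unseen level in '%s' (first at row %d).",
                      v, which(bad)[1]),
              class = "equicare_scoring_error")
      }
    }
  }
  mf <- stats::model.frame(tt, d, na.action = stats::na.fail)
  X <- model.matrix(tt, mf)[, -1, drop = FALSE]
  drop(X %*% fit$coefficients[colnames(X)])
}

#' Assign within-sample quartile labels
#'
#' Quartile cut points are type-1 (inverted-CDF, left-continuous) sample
#' quartiles; a score exactly at a boundary is assigned to the lower
#' quartile. Labels run 1 (poorest) to 4.
#'
#' @param scores numeric vector with at least 4 distinct values.
#' @return integer vector of labels in 1:4.
#' @export
assign_quartiles <- function(scores) {
  if (anyNA(scores)) abort("scores contain NA.", class = "equicare_data_error")
  if (length(unique(scores)) < 4) {
    abort("need at least 4 distinct scores to form quartiles.",
          class = "equicare_data_error")
  }
  q <- quantile(scores, c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  1L + (scores > q[1]) + (scores > q[2]) + (scores > q[3])
}

#' Standardize income for a two-wave survey and attach quartiles
#'
#' Convenience wrapper: fits the per-wave ordered probit, scores every
#' respondent on the latent index and assigns within-wave quartiles.
#'
#' @param data two-wave survey records.
#' @param formula passed to [fit_income_probit()].
#' @return `data` with columns `income_score` and `income_quartile` added;
#'   the per-wave fits are attached as attribute `"income_fits"`.
#' @export
standardize_income <- function(data,
                               formula = income_band ~ sex + age_band +
                                 occupation + education + household_size) {
  fits <- list()
  data$income_score <- NA_real_
  data$income_quartile <- NA_integer_
  for (w in sort(unique(data$wave))) {
    sel <- data$wave == w
    fit <- fit_income_probit(data[sel, , drop = FALSE], formula)
    sc <- score_income(fit, data[sel, , drop = FALSE])
    data$income_score[sel] <- sc
    data$income_quartile[sel] <- assign_quartiles(sc)
    fits[[as.character(w)]] <- fit
  }
  attr(data, "income_fits") <- fits
  data
}
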