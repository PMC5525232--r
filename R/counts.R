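#' Annualize recall-window contact counts
#'
#' Primary and specialist contacts are reported over a 4-week recall window
#' and are extrapolated to a year by multiplying by 12 — but only for
#' respondents who reported at least one contact; zero reporters are left at
#' zero and handled by the delayed-contact imputation
#' ([impute_zero_reporters()]). Hospitalisations and emergencies are already
#' asked over 12 months and pass through unchanged. The total, public and
#' private components are all annualised the same way, so annualised 4-week
#' counts are multiples of 12 except for imputed single contacts.
#'
#' @param data records with the split-count columns of [impute_ownership()].
#' @return `data` with `<service>_annual_total`, `<service>_annual_public`,
#'   `<service>_annual_private` columns added.
#' @export
annualize_counts <- function(data) {
  meta <- service_meta()
  for (i in seq_len(nrow(meta))) {
    s <- meta$service[i]
    for (part in c("total", "public", "private")) {
      src <- paste0(s, "_", if (part == "private") "private_n" else part)
      if (!src %in% names(data)) {
        abort(sprintf("column '%s' not found: run impute_ownership() first.", src),
              class = "equicare_data_error")
      }
      x <- data[[src]]
      if (any(x < 0, na.rm = TRUE)) {
        abort(sprintf("negative count in '%s'.", src), class = "equicare_data_error")
      }
      mult <- if (meta$window[i] == "4wk") 12L else 1L
      data[[paste0(s, "_annual_", part)]] <- as.integer(mult * x)
    }
  }
  data
}

#' Model the delay between perceived need and contact
#'
#' Among respondents who used a 4-week-recall service at least once, fits a
#' logistic regression of the indicator "sought care more than 4 weeks after
#' perceiving a problem" on sex, age band, self-perceived health and
#' chronic-condition count, per wave. The fit is used to decide whether a
#' zero reporter plausibly had a contact that fell outside the recall
#' window.
#'
#' @param data survey records of a single wave.
#' @param service `"primary"` or `"specialist"`.
#' @param formula covariates (right-hand side only).
#' @return a `delay_fit` with the underlying `glm`, `service`, `wave`.
#' @export
fit_delay_model <- function(data, service,
                            formula = ~ sex + age_band + sph + chronic_count) {
  meta <- service_meta()
  m <- meta[meta$service == service, ]
  if (nrow(m) == 0 || is.na(m$delayed_col)) {
    abort(sprintf("service '%s' has no 4-week recall window.", service),
          class = "equicare_data_error")
  }
  wave <- unique(data$wave)
  if (length(wave) != 1) {
    abort("fit one wave at a time: `data` contains multiple waves.",
          class = "equicare_data_error")
  }
  d <- data[data[[m$count_col]] >= 1, , drop = FALSE]
  if (!nrow(d)) abort(sprintf("no users of service '%s' in wave %s.", service, wave),
                      class = "equicare_data_error")
  yy <- d[[m$delayed_col]]
  if (length(unique(yy)) < 2) {
    abort(sprintf("separation: all users of '%s' (wave %s) are %s.",
                  service, wave, if (all(yy == 1)) "delayed" else "not delayed"),
          class = "equicare_fit_error")
  }
  d <- set_reference_levels(as.data.frame(d))
  f <- stats::as.formula(paste(m$delayed_col, "~", deparse(formula[[2]])))
  fit <- suppressWarnings(glm(f, family = binomial(), data = d))
  if (!fit$converged || anyNA(coef(fit))) {
    abort(sprintf("delay fit for '%s' (wave %s) shows separation or aliasing.",
                  service, wave),
          class = "equicare_fit_error")
  }
  structure(list(fit = fit, service = service, wave = wave, formula = f,
                 n_users = nrow(d)),
            class = "delay_fit")
}

#' Impute a single annual contact for zero reporters
#'
#' For respondents reporting zero contacts in the 4-week window, predicts
#' from a [fit_delay_model()] the probability that they sought care more
#' than 4 weeks after perceiving a problem, and imputes one annual contact
#' if that probability strictly exceeds 0.5 (a probability of exactly 0.5
#' imputes nothing). The imputed contact is recorded as 1 contact per year,
#' not 12.
#'
#' @param fit a `delay_fit`.
#' @param data records of the matching wave; only rows with a zero reported
#'   count for the fit's service are imputed.
#' @return a tibble `id`, `p_delay`, `imputed` (0/1), one row per zero
#'   reporter.
#' @export
impute_zero_reporters <- function(fit, data) {
  stopifnot(inherits(fit, "delay_fit"))
  m <- service_meta()[service_meta()$service == fit$service, ]
  nonusers <- data[data[[m$count_col]] == 0, , drop = FALSE]
  d <- set_reference_levels(as.data.frame(nonusers))
  vars <- all.vars(delete.response(terms(fit$formula)))
  if (nrow(d) && anyNA(d[, vars])) {
    bad <- which(!complete.cases(d[, vars]))
    abort(sprintf("missing covariate value(s) for scoring (first at row %d).",
                  bad[1]),
          class = "equicare_scoring_error")
  }
  p <- if (nrow(d)) predict(fit$fit, newdata = d, type = "response") else numeric(0)
  tibble(id = nonusers$id, p_delay = unname(p),
         imputed = as.integer(p > 0.5))
}

#' Count distinct medicines used, excluding contraceptives
#'
#' Sums the positive responses over the 22 binary medicine-use items,
#' excluding the contraceptive item, yielding a count in 0-21.
#'
#' @param data records with the 22 `med_*` columns.
#' @param contraceptive column name of the contraceptive item.
#' @return integer vector of counts.
#' @export
count_medicines <- function(data, contraceptive = "med_22") {
  cols <- medicine_cols()
  if (!contraceptive %in% cols) {
    abort(sprintf("'%s' is not one of the 22 medicine items.", contraceptive),
          class = "equicare_data_error")
  }
  M <- as.matrix(data[, cols])
  if (any(!(M %in% c(0, 1)))) {
    bad <- which(matrix(!(M %in% c(0, 1)), nrow(M)), arr.ind = TRUE)[1, ]
    abort(sprintf("non-binary medicine flag in column '%s' (row %d).",
                  cols[bad[2]], bad[1]),
          class = "equicare_data_error")
  }
  as.integer(rowSums(M[, setdiff(cols, contraceptive), drop = FALSE]))
}

#' Build the analysis dataset: income quartiles, ownership split, annual counts
#'
#' Runs the full construction pipeline on raw survey records:
#' income standardisation and within-wave quartiles
#' ([standardize_income()]), per-service/per-wave ownership fits and count
#' splits ([impute_ownership()]), times-12 annualisation of the 4-week
#' services ([annualize_counts()]), delayed-contact imputation of a single
#' annual contact for zero reporters — allocated to public or private by the
#' ownership model's predicted probability with the same round-half-to-even
#' rule as multi-visit splits — and the medicine count
#' ([count_medicines()], exposed as `medicines_annual_total`).
#'
#' @param data two-wave survey records.
#' @param impute_delayed apply the zero-reporter imputation? (default TRUE)
#' @return an analysis tibble; component fits are attached as attributes
#'   `"income_fits"`, `"ownership_fits"`, `"delay_fits"`.
#' @export
build_analysis_dataset <- function(data, impute_delayed = TRUE) {
  validate_survey(data)
  data <- standardize_income(data)
  inc_fits <- attr(data, "income_fits")
  data <- impute_ownership(data)
  own_fits <- attr(data, "ownership_fits")
  data <- annualize_counts(data)

  delay_fits <- list()
  if (impute_delayed) {
    meta <- service_meta()
    for (w in sort(unique(data$wave))) {
      sel <- data$wave == w
      for (s in c("primary", "specialist")) {
        dfit <- fit_delay_model(data[sel, , drop = FALSE], s)
        imp <- impute_zero_reporters(dfit, data[sel, , drop = FALSE])
        hit <- imp$id[imp$imputed == 1]
        rows <- which(data$id %in% hit & sel)
        if (length(rows)) {
          ofit <- own_fits[[paste(s, w, sep = ".")]]
          d <- set_reference_levels(as.data.frame(data[rows, , drop = FALSE]))
          p_own <- predict(ofit$fit, newdata = d, type = "response")
          priv <- as.integer(round(p_own))
          data[[paste0(s, "_annual_total")]][rows] <- 1L
          data[[paste0(s, "_annual_private")]][rows] <- priv
          data[[paste0(s, "_annual_public")]][rows] <- 1L - priv
        }
        delay_fits[[paste(s, w, sep = ".")]] <- dfit
      }
    }
  }
  data$medicines_annual_total <- count_medicines(data)
  attr(data, "income_fits") <- inc_fits
  attr(data, "ownership_fits") <- own_fits
  attr(data, "delay_fits") <- delay_fits
  data
}
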