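#' Impute the public/private split of health-service contacts
#'
#' Surveys report the total number of contacts per service but the
#' ownership (public vs private) of the *last* contact only. Following the
#' single-visit strategy, [fit_ownership_model()] fits a logistic regression
#' of the last-contact ownership flag on sex, age band, self-perceived
#' health and chronic-condition count, using only respondents who reported
#' exactly one contact with the service (for whom the flag identifies the
#' ownership of their full utilisation). [split_counts()] then carries the
#' split to everyone: single-visit respondents keep their observed
#' ownership exactly; multi-visit respondents get `private =
#' round(total * p_hat)` with round-half-to-even and `public = total -
#' private`; zero-visit respondents get zeros. Fits are always per service
#' and per wave.
#'
#' @param data survey records of a single wave.
#' @param service one of `"primary"`, `"specialist"`, `"emergency"`,
#'   `"hospital"`.
#' @param formula covariates of the ownership model (right-hand side only).
#' @return `fit_ownership_model()`: an `ownership_fit` with the underlying
#'   `glm`, `service` and `wave`.
#' @export
fit_ownership_model <- function(data, service,
                                formula = ~ sex + age_band + sph + chronic_count) {
  meta <- service_meta()
  if (!service %in% meta$service) {
    abort(sprintf("unknown service '%s'.", service), class = "equicare_data_error")
  }
  wave <- unique(data$wave)
  if (length(wave) != 1) {
    abort("fit one wave at a time: `data` contains multiple waves.",
          class = "equicare_data_error")
  }
  m <- meta[meta$service == service, ]
  single <- data[[m$count_col]] == 1
  d <- data[single, , drop = FALSE]
  if (!nrow(d)) {
    abort(sprintf("no single-visit respondents for service '%s', wave %s.",
                  service, wave),
          class = "equicare_data_error")
  }
  yy <- d[[m$private_col]]
  if (length(unique(yy)) < 2) {
    abort(sprintf(
      "complete separation: all single-visit contacts for '%s' (wave %s) are %s.",
      service, wave, if (all(yy == 1)) "private" else "public"),
      class = "equicare_fit_error")
  }
  d <- set_reference_levels(as.data.frame(d))
  f <- stats::as.formula(paste(m$private_col, "~", deparse(formula[[2]])))
  fit <- suppressWarnings(glm(f, family = binomial(), data = d))
  if (!fit$converged || anyNA(coef(fit))) {
    abort(sprintf("ownership fit for '%s' (wave %s) shows separation or aliasing.",
                  service, wave),
          class = "equicare_fit_error")
  }
  structure(list(fit = fit, service = service, wave = wave, formula = f,
                 n_single = nrow(d)),
            class = "ownership_fit")
}

#' @rdname fit_ownership_model
#' @param fit an `ownership_fit` for the same service and wave as `data`.
#' @return `split_counts()`: a tibble with columns `id`, `total`, `private`,
#'   `public` (integers, `public + private == total` for every respondent)
#'   and `p_private`, the predicted private probability.
#' @export
split_counts <- function(fit, data) {
  stopifnot(inherits(fit, "ownership_fit"))
  m <- service_meta()[service_meta()$service == fit$service, ]
  total <- data[[m$count_col]]
  d <- set_reference_levels(as.data.frame(data))
  vars <- all.vars(delete.response(terms(fit$formula)))
  if (anyNA(d[, vars])) {
    bad <- which(!complete.cases(d[, vars]))
    abort(sprintf("missing covariate value(s) for scoring (first at row %d).",
                  bad[1]),
          class = "equicare_scoring_error")
  }
  p <- predict(fit$fit, newdata = d, type = "response")
  private <- integer(length(total))
  single <- total == 1
  multi <- total > 1
  private[single] <- as.integer(data[[m$private_col]][single])
  private[multi] <- as.integer(round(total[multi] * p[multi]))
  tibble(id = data$id, total = as.integer(total),
         private = private, public = as.integer(total) - private,
         p_private = unname(p))
}

#' Fit all ownership models and split every service's counts
#'
#' Runs [fit_ownership_model()] and [split_counts()] for the four services
#' within each wave and binds the result onto the records as
#' `<service>_total`, `<service>_public`, `<service>_private_n` columns (on
#' the reported recall-window scale).
#'
#' @param data two-wave survey records.
#' @return `data` with 12 split-count columns added; fits attached as
#'   attribute `"ownership_fits"` (named `service.wave`).
#' @export
impute_ownership <- function(data) {
  meta <- service_meta()
  fits <- list()
  for (s in meta$service) {
    data[[paste0(s, "_total")]] <- NA_integer_
    data[[paste0(s, "_public")]] <- NA_integer_
    data[[paste0(s, "_private_n")]] <- NA_integer_
  }
  for (w in sort(unique(data$wave))) {
    sel <- data$wave == w
    for (s in meta$service) {
      fit <- fit_ownership_model(data[sel, , drop = FALSE], s)
      sp <- split_counts(fit, data[sel, , drop = FALSE])
      data[[paste0(s, "_total")]][sel] <- sp$total
      data[[paste0(s, "_public")]][sel] <- sp$public
      data[[paste0(s, "_private_n")]][sel] <- sp$private
      fits[[paste(s, w, sep = ".")]] <- fit
    }
  }
  attr(data, "ownership_fits") <- fits
  data
}
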