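#' Signed percent change between two wave means
#'
#' `(post - pre) / pre * 100`. A pre-crisis mean of zero leaves the change
#' undefined and returns `NA`; a positive pre-crisis mean with a zero
#' post-crisis mean gives exactly -100.
#'
#' @param pre,post numeric vectors (recycled).
#' @return numeric vector of signed percentages.
#' @examples
#' percent_change(0.5, 0.25)   # -50
#' percent_change(0.015, 0)    # -100
#' @export
percent_change <- function(pre, post) {
  out <- (post - pre) / pre * 100
  out[pre == 0] <- NA_real_
  out
}

#' Descriptive utilisation table by income quartile and wave
#'
#' For each utilisation variable (annual total/public/private counts per
#' service, the medicine count, and the private-insurance flag) and each
#' income quartile (plus an overall row), reports per-wave n, mean and SD,
#' the percent change between waves, and a p-value comparing the waves:
#' a two-sample Wilcoxon rank-sum (Mann-Whitney) test for count variables,
#' Fisher's exact test for binary ones. No multiple-testing adjustment is
#' applied; raw p-values are reported. Cells with no observations are
#' flagged in `note`, never dropped silently.
#'
#' @param data analysis records from [build_analysis_dataset()] (two waves,
#'   quartiles assigned).
#' @param annualized use annualised counts (default) or the raw
#'   recall-window splits?
#' @param by_quartile include per-quartile rows (default) in addition to the
#'   overall rows?
#' @return a tibble: `variable`, `quartile` ("1".."4", "all"), `n_pre`,
#'   `mean_pre`, `sd_pre`, `n_post`, `mean_post`, `sd_post`, `pct_change`,
#'   `p.value`, `test`, `note`.
#' @export
descriptive_table <- function(data, annualized = TRUE, by_quartile = TRUE) {
  waves <- sort(unique(data$wave))
  if (length(waves) != 2) {
    abort("descriptive_table() needs exactly two waves.",
          class = "equicare_data_error")
  }
  if (!"income_quartile" %in% names(data)) {
    abort("quartiles not assigned: run build_analysis_dataset() first.",
          class = "equicare_data_error")
  }
  meta <- service_meta()
  vars <- list()
  for (i in seq_len(nrow(meta))) {
    s <- meta$service[i]
    for (own in c("total", "public", "private")) {
      col <- if (annualized) paste0(s, "_annual_", own) else {
        paste0(s, "_", if (own == "private") "private_n" else own)
      }
      vars[[paste(s, own, sep = "_")]] <- list(col = col, binary = FALSE)
    }
  }
  vars[["medicines_total"]] <- list(col = "medicines_annual_total", binary = FALSE)
  vars[["insurance"]] <- list(col = "insurance", binary = TRUE)

  groups <- if (by_quartile) c(as.character(1:4), "all") else "all"
  rows <- list()
  for (vn in names(vars)) {
    v <- vars[[vn]]
    if (!v$col %in% names(data)) {
      abort(sprintf("column '%s' not found.", v$col), class = "equicare_data_error")
    }
    for (g in groups) {
      sel <- if (g == "all") rep(TRUE, nrow(data)) else data$income_quartile == as.integer(g)
      x_pre <- data[[v$col]][sel & data$wave == waves[1]]
      x_post <- data[[v$col]][sel & data$wave == waves[2]]
      rows[[length(rows) + 1]] <- cell_stats(vn, g, x_pre, x_post, v$binary)
    }
  }
  dplyr::bind_rows(rows)
}

cell_stats <- function(variable, quartile, x_pre, x_post, binary) {
  note <- NA_character_
  if (!length(x_pre) || !length(x_post)) note <- "empty cell"
  m_pre <- if (length(x_pre)) mean(x_pre) else NA_real_
  m_post <- if (length(x_post)) mean(x_post) else NA_real_
  p <- NA_real_
  test <- if (binary) "fisher" else "wilcoxon"
  if (is.na(note)) {
    if (binary) {
      tab <- rbind(c(sum(x_pre == 1), sum(x_pre == 0)),
                   c(sum(x_post == 1), sum(x_post == 0)))
      p <- tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
    } else {
      p <- tryCatch(
        suppressWarnings(wilcox.test(x_pre, x_post)$p.value),
        error = function(e) NA_real_)
    }
    if (is.na(p)) note <- "test unavailable"
  }
  tibble(variable = variable, quartile = quartile,
         n_pre = length(x_pre), mean_pre = m_pre,
         sd_pre = if (length(x_pre) > 1) sd(x_pre) else NA_real_,
         n_post = length(x_post), mean_post = m_post,
         sd_post = if (length(x_post) > 1) sd(x_post) else NA_real_,
         pct_change = percent_change(m_pre, m_post),
         p.value = p, test = test, note = note)
}

#' Round a descriptive table the way it is printed
#'
#' Means and SDs to 3 decimals, percent changes to 1, p-values to 3.
#'
#' @param tab output of [descriptive_table()].
#' @return the rounded tibble.
#' @export
format_descriptive <- function(tab) {
  for (col in c("mean_pre", "sd_pre", "mean_post", "sd_post")) {
    tab[[col]] <- round(tab[[col]], 3)
  }
  tab$pct_change <- round(tab$pct_change, 1)
  tab$p.value <- round(tab$p.value, 3)
  tab
}

# covariate sets of the nested model sequence: Model 1 income quartiles
# only; Model 2 adds gender and age; Model 3 adds private insurance and the
# GHQ-12 mental-health score
model_formula <- function(model, response) {
  rhs <- switch(model,
                "1" = "quartile",
                "2" = "quartile + sex + age_band",
                "3" = "quartile + sex + age_band + insurance + ghq12",
                abort("`model` must be 1, 2 or 3."))
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit the nested hurdle-model sequence for one service and ownership
#'
#' Fits, per wave, three nested two-part hurdle models of the annual contact
#' count: Model 1 with income quartiles only (quartile 1 = reference),
#' Model 2 adding sex and age band, Model 3 adding private insurance and
#' GHQ-12. The same covariates enter both parts. Medicines are fitted as
#' total only. Quartile odds ratios (use part) and rate ratios (frequency
#' part) against quartile 1 are tabulated for every fit; a wave whose fit
#' fails (for example no private users at all) is flagged in `errors` and
#' its table rows are marked unavailable rather than dropped.
#'
#' @param data analysis records from [build_analysis_dataset()].
#' @param service a service name or `"medicines"`.
#' @param ownership `"total"`, `"public"` or `"private"`.
#' @param models subset of 1:3.
#' @param group optional grouping column for household random effects,
#'   passed to [fit_hurdle()].
#' @param conf.level interval level for the ratios.
#' @return a `model_sequence` object: `fits` (named `wave.model`), `table`
#'   (tidy quartile ratios), `errors`, plus the service/ownership labels.
#'   `tidy()` returns the table; `glance()` one row per fit.
#' @export
run_model_sequence <- function(data, service, ownership = "total",
                               models = 1:3, group = NULL, conf.level = 0.95) {
  if (service == "medicines" && ownership != "total") {
    abort("medicine consumption is analysed as total only.",
          class = "equicare_data_error")
  }
  response <- if (service == "medicines") "medicines_annual_total" else {
    paste0(service, "_annual_", ownership)
  }
  if (!response %in% names(data)) {
    abort(sprintf("column '%s' not found: run build_analysis_dataset() first.",
                  response),
          class = "equicare_data_error")
  }
  d <- as.data.frame(data)
  d$quartile <- factor(paste0("q", d$income_quartile), paste0("q", 1:4))
  d <- set_reference_levels(d)
  fits <- list()
  errors <- list()
  rows <- list()
  for (w in sort(unique(d$wave))) {
    dw <- d[d$wave == w, , drop = FALSE]
    for (m in models) {
      key <- paste(w, m, sep = ".")
      f <- model_formula(as.character(m), response)
      fit <- tryCatch(fit_hurdle(f, dw, group = group),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        errors[[key]] <- conditionMessage(fit)
        rows[[length(rows) + 1]] <- tidyr::expand_grid(
          wave = w, model = m, part = c("use", "count"),
          term = paste0("quartileq", 2:4)) |>
          dplyr::mutate(estimate = NA_real_, std.error = NA_real_,
                        conf.low = NA_real_, conf.high = NA_real_,
                        note = sprintf("unavailable: %s", conditionMessage(fit)))
        next
      }
      fits[[key]] <- fit
      for (part in c("use", "count")) {
        for (term in paste0("quartileq", 2:4)) {
          rr <- rate_ratio(fit, term, part, conf.level = conf.level)
          rows[[length(rows) + 1]] <- dplyr::mutate(rr, wave = w, model = m,
                                                    note = NA_character_,
                                                    .before = 1)
        }
      }
    }
  }
  structure(list(fits = fits, errors = errors,
                 table = dplyr::bind_rows(rows),
                 service = service, ownership = ownership),
            class = "model_sequence")
}

#' @export
print.model_sequence <- function(x, ...) {
  cat(sprintf("Hurdle model sequence: %s (%s), %d fit(s), %d failure(s)\n",
              x$service, x$ownership, length(x$fits), length(x$errors)))
  print(x$table, n = 24)
  invisible(x)
}

#' @export
tidy.model_sequence <- function(x, ...) x$table

#' @export
glance.model_sequence <- function(x, ...) {
  if (!length(x$fits)) return(tibble())
  dplyr::bind_rows(lapply(names(x$fits), function(k) {
    dplyr::mutate(glance(x$fits[[k]]),
                  wave = as.integer(sub("\\..*", "", k)),
                  model = as.integer(sub(".*\\.", "", k)), .before = 1)
  }))
}
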