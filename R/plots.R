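#' Plot quartile-by-wave mean utilisation
#'
#' Dot-and-line display of the per-quartile mean annual counts from a
#' [descriptive_table()], one panel per variable, waves distinguished by
#' colour.
#'
#' @param tab output of [descriptive_table()].
#' @param variables optional subset of `tab$variable`.
#' @return a ggplot object.
#' @export
plot_quartile_means <- function(tab, variables = NULL) {
  d <- tab[tab$quartile != "all", ]
  if (!is.null(variables)) d <- d[d$variable %in% variables, ]
  d <- tidyr::pivot_longer(d, c("mean_pre", "mean_post"),
                           names_to = "wave", values_to = "mean")
  d$wave <- ifelse(d$wave == "mean_pre", "pre-crisis", "crisis")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quartile, y = .data$mean,
                                  colour = .data$wave, group = .data$wave)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "income quartile (1 = poorest)",
                  y = "mean annual contacts", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_hurdle Coefficient plot of a fitted hurdle model, one
#'   facet per part, with Wald 95% intervals.
#' @param object a `hurdle_fit`.
#' @param ... unused.
#' @export
autoplot.hurdle_fit <- function(object, ...) {
  d <- tidy(object, conf.int = TRUE)
  d <- d[d$part %in% c("use", "count") & d$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::facet_wrap(~part, labeller = ggplot2::labeller(
      part = c(use = "any use (log-odds)", count = "frequency (log-rate)"))) +
    ggplot2::labs(x = "coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_model_sequence Quartile ratio plot across the model
#'   sequence: odds/rate ratios vs quartile 1, by wave and model.
#' @param object a `model_sequence`.
#' @param ... unused.
#' @export
autoplot.model_sequence <- function(object, ...) {
  d <- object$table[!is.na(object$table$estimate), ]
  d$quartile <- sub("quartileq", "Q", d$term)
  d$model <- factor(paste("Model", d$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quartile, y = .data$estimate,
                                  colour = factor(.data$wave))) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_grid(part ~ model) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = sprintf("%s (%s)", object$service, object$ownership),
                  x = "income quartile vs Q1", y = "ratio (log scale)",
                  colour = "wave") +
    ggplot2::theme_minimal()
}
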