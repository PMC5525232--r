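# shared generator configurations for the test-suite

# desk-scale version of the default study conditions
small_config <- function(n2006 = 2000, n2011 = 2000, ...) {
  survey_config(n = c("2006" = n2006, "2011" = n2011), ...)
}

# strip a named effect from every service's linear predictors
drop_effects <- function(services, terms) {
  lapply(services, function(sv) {
    sv$beta1 <- sv$beta1[!names(sv$beta1) %in% terms]
    sv$beta2 <- sv$beta2[!names(sv$beta2) %in% terms]
    sv
  })
}

# null study conditions for calibration checks: utilisation carries no
# income and no wave effects, and respondents are exchangeable (no household
# heterogeneity) as the rank-sum test assumes
null_config <- function(n2006 = 500, n2011 = 500, sigma_u = 0, ...) {
  base <- survey_config()
  survey_config(n = c("2006" = n2006, "2011" = n2011),
                services = drop_effects(base$services,
                                        c("income_z", "income_q2", "income_q3",
                                          "income_q4", "wave_2011")),
                sigma_u = sigma_u, ...)
}

# intercept-only two-part data simulated straight from the model (the
# simulation oracle for recovery tests): returns a data frame with y and a
# binary covariate x
simulate_hurdle_data <- function(n, b1, b2, phi, sigma_u = 0, n_groups = NULL) {
  x <- rbinom(n, 1, 0.5)
  g <- if (!is.null(n_groups)) rep_len(seq_len(n_groups), n) else seq_len(n)
  u <- if (sigma_u > 0) rnorm(max(g), 0, sigma_u)[g] else 0
  eta1 <- b1[1] + if (length(b1) > 1) b1[2] * x else 0
  eta2 <- b2[1] + if (length(b2) > 1) b2[2] * x else 0
  y <- rbinom(n, 1, plogis(eta1 + u))
  idx <- y == 1
  y[idx] <- rztnb(sum(idx), exp(eta2 + u)[idx], phi)
  data.frame(y = y, x = x, g = g)
}

# intercept-only glm whose fitted probability is exactly `p` (the MLE of an
# intercept-only logistic model is the sample mean), wrapped as a crafted
# ownership/delay fit for deterministic split rules
crafted_binary_fit <- function(p, service, wave, class) {
  k <- round(p * 1000)
  d <- data.frame(flag = rep(c(1L, 0L), c(k, 1000 - k)))
  fit <- glm(flag ~ 1, family = binomial(), data = d)
  structure(list(fit = fit, service = service, wave = wave,
                 formula = flag ~ 1, n_single = 1000L, n_users = 1000L),
            class = class)
}
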