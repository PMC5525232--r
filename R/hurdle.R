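#' Jointly estimate a two-part hurdle model for health-service contact counts
#'
#' Fits the two-part ("hurdle") count model used throughout the package:
#' part 1 is a logistic regression for any use,
#' \eqn{\mathrm{logit}(\mu_{1i}) = X_{1i}'\beta_1}, with the Bernoulli
#' variance \eqn{\mu_{1i}(1-\mu_{1i})} taken as exact (no part-1 dispersion
#' is ever estimated); part 2 models the frequency of use among users as a
#' zero-truncated negative binomial with mean \eqn{\mu_{2i} =
#' \exp(X_{2i}'\beta_2)} and NB1 dispersion `phi` (shape
#' \eqn{\psi_{2i} = \mu_{2i}/\phi}). The two parts enter the likelihood
#' multiplicatively and all parameters are estimated simultaneously.
#'
#' The two design matrices may contain different covariates; when they share
#' no parameters and there are no random effects the joint maximum coincides
#' with the two independent maxima (a property the test-suite asserts).
#'
#' With `group` set, a Gaussian random intercept \eqn{\upsilon_j \sim
#' N(0, \sigma_\upsilon^2)} shared by both parts is integrated out of each
#' group's likelihood contribution by Gauss-Hermite quadrature, and an
#' exponential penalty on \eqn{\sigma_\upsilon} emulating a
#' penalised-complexity prior is added to the log-likelihood, calibrated by
#' \eqn{P(\sigma_\upsilon > u) = \alpha} so that the penalty rate is
#' \eqn{\lambda = -\log(\alpha)/u}.
#'
#' @param formula model formula `response ~ covariates` for part 1 (and for
#'   part 2 unless `part2` is given).
#' @param data a data frame; the response must be a non-negative integer
#'   count.
#' @param part2 optional right-hand-side formula (`~ covariates`) for the
#'   frequency part; defaults to the part-1 covariates.
#' @param group optional name of a grouping column for the shared Gaussian
#'   random intercept; `NULL` (default) fits fixed effects only.
#' @param pc_u,pc_alpha calibration of the penalty on the random-effect SD:
#'   prior mass `pc_alpha` above `pc_u`. Ignored without `group`.
#' @param quad_points number of Gauss-Hermite nodes for the random-effect
#'   integral.
#' @param start optional named starting vector on the working scale.
#' @param control passed to [stats::optim()] (BFGS with analytic gradients);
#'   defaults allow at most 500 iterations at `reltol = 1e-12`.
#' @return an object of class `hurdle_fit` with components `coefficients`
#'   (lists `use` and `count`), `phi`, `sigma_u`, `vcov` (working scale:
#'   coefficients, `log_phi`, `log_sigma_u`), `logLik`, `converged`,
#'   `grad_norm`, sample sizes and the matched call. Methods: [tidy()],
#'   [glance()], `print()`, [rate_ratio()], [ggplot2::autoplot()].
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(500))
#' p <- plogis(0.3 + 0.5 * d$x)
#' d$y <- rbinom(500, 1, p) * rztnb(500, mu = exp(0.8 - 0.2 * d$x), phi = 0.6)
#' f <- fit_hurdle(y ~ x, d)
#' tidy(f)
#' @export
fit_hurdle <- function(formula, data, part2 = NULL, group = NULL,
                       pc_u = 1, pc_alpha = 0.01, quad_points = 20,
                       start = NULL, control = list()) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  check_count_response(y)
  X1 <- model.matrix(formula, mf)
  f2 <- if (is.null(part2)) formula else {
    stats::as.formula(paste(deparse(formula[[2]]), "~", deparse(part2[[2]])),
                      env = environment(formula))
  }
  mf2 <- stats::model.frame(f2, data, na.action = stats::na.fail)
  X2 <- model.matrix(f2, mf2)
  if (all(y == 0)) abort("all responses are zero: part 2 cannot be fitted.",
                         class = "equicare_data_error")
  if (all(y > 0)) abort("no zero responses: part 1 cannot be fitted.",
                        class = "equicare_data_error")

  gidx <- NULL
  pc_lambda <- NULL
  if (!is.null(group)) {
    if (!group %in% names(data)) {
      abort(sprintf("grouping column '%s' not found.", group),
            class = "equicare_data_error")
    }
    gidx <- as.integer(factor(data[[group]]))
    stopifnot(pc_u > 0, pc_alpha > 0, pc_alpha < 1)
    pc_lambda <- -log(pc_alpha) / pc_u
  }

  obj <- hurdle_objective(y, X1, X2, gidx, pc_lambda, quad_points)
  if (is.null(start)) start <- hurdle_start(y, X1, X2, grouped = !is.null(gidx))
  ctl <- modify_list(list(maxit = 500, reltol = 1e-12), control)
  opt <- stats::optim(start, obj$fn, obj$gr, method = "BFGS", control = ctl)

  p1 <- ncol(X1); p2 <- ncol(X2)
  par <- opt$par
  names(par) <- obj$par_names(colnames(X1), colnames(X2))
  gnorm <- grad_norm(obj, par)
  conv <- opt$convergence == 0 && gnorm < 1e-2 * max(1, sqrt(length(y)))
  if (!conv) {
    warn(sprintf("hurdle fit did not converge (code %d; |grad| = %.3g).",
                 opt$convergence, gnorm))
  }
  H <- tryCatch(optimHess(par, obj$fn, obj$gr), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (!is.null(V)) dimnames(V) <- list(names(par), names(par))

  structure(list(
    coefficients = list(use = setNames(par[seq_len(p1)], colnames(X1)),
                        count = setNames(par[p1 + seq_len(p2)], colnames(X2))),
    phi = unname(exp(par[p1 + p2 + 1])),
    sigma_u = if (is.null(gidx)) NULL else unname(exp(par[p1 + p2 + 2])),
    par = par, vcov = V, logLik = -opt$value,
    penalized = !is.null(pc_lambda),
    pc = if (is.null(pc_lambda)) NULL else c(u = pc_u, alpha = pc_alpha, lambda = pc_lambda),
    converged = conv, iterations = unname(opt$counts[1]), grad_norm = gnorm,
    n = length(y), n_users = sum(y > 0), n_groups = if (is.null(gidx)) NA_integer_ else max(gidx),
    response_name = deparse(formula[[2]]),
    formula_use = formula, formula_count = f2, group = group,
    call = match.call()
  ), class = "hurdle_fit")
}

check_count_response <- function(y) {
  if (!is.numeric(y) || any(y < 0) || any(y != floor(y)) || anyNA(y)) {
    abort("response must be a complete non-negative integer count.",
          class = "equicare_data_error")
  }
}

modify_list <- function(base, new) { base[names(new)] <- new; base }

# working-scale parameter vector: [beta1, beta2, log_phi, (log_sigma_u)]
hurdle_objective <- function(y, X1, X2, gidx = NULL, pc_lambda = NULL,
                             quad_points = 20) {
  z <- as.numeric(y > 0)
  users <- y > 0
  yu <- y[users]
  X2u <- X2[users, , drop = FALSE]
  p1 <- ncol(X1); p2 <- ncol(X2)

  if (is.null(gidx)) {
    fn <- function(theta) {
      b1 <- theta[seq_len(p1)]
      b2 <- theta[p1 + seq_len(p2)]
      phi <- exp(theta[p1 + p2 + 1])
      eta1 <- drop(X1 %*% b1)
      ll1 <- sum(plogis(eta1[users], log.p = TRUE)) +
        sum(plogis(eta1[!users], lower.tail = FALSE, log.p = TRUE))
      mu <- exp(pmin(drop(X2u %*% b2), 35))
      ll2 <- sum(ztnb_logpmf(yu, mu, phi))
      -(ll1 + ll2)
    }
    gr <- function(theta) {
      b1 <- theta[seq_len(p1)]
      b2 <- theta[p1 + seq_len(p2)]
      phi <- exp(theta[p1 + p2 + 1])
      eta1 <- drop(X1 %*% b1)
      g1 <- drop(crossprod(X1, z - plogis(eta1)))
      mu <- exp(pmin(drop(X2u %*% b2), 35))
      psi <- mu / phi
      a <- log1p(phi)
      r <- 1 / (-expm1(-psi * a))           # (1+phi)^psi / ((1+phi)^psi - 1)
      dldpsi <- digamma(yu + psi) - digamma(psi) - a * r
      g2 <- drop(crossprod(X2u, psi * dldpsi))
      glphi <- sum(-psi * dldpsi + yu / (1 + phi) - r * psi * phi / (1 + phi))
      -c(g1, g2, glphi)
    }
    list(fn = fn, gr = gr, p1 = p1, p2 = p2, grouped = FALSE,
         par_names = function(n1, n2) c(paste0("use:", n1),
                                        paste0("count:", n2), "log_phi"))
  } else {
    gh <- gauss_hermite(quad_points)
    lw <- log(gh$weights) - 0.5 * log(pi)
    G <- max(gidx)
    gidx_u <- gidx[users]
    node_S <- function(theta) {
      b1 <- theta[seq_len(p1)]
      b2 <- theta[p1 + seq_len(p2)]
      phi <- exp(theta[p1 + p2 + 1])
      sigma <- exp(theta[p1 + p2 + 2])
      eta1 <- drop(X1 %*% b1)
      eta2 <- drop(X2u %*% b2)
      S <- matrix(0, G, quad_points)
      for (k in seq_len(quad_points)) {
        u <- sqrt(2) * sigma * gh$nodes[k]
        ld <- numeric(length(y))
        e1 <- eta1 + u
        ld[users] <- plogis(e1[users], log.p = TRUE)
        ld[!users] <- plogis(e1[!users], lower.tail = FALSE, log.p = TRUE)
        mu <- exp(pmin(eta2 + u, 35))
        ld[users] <- ld[users] + ztnb_logpmf(yu, mu, phi)
        S[, k] <- rowsum_vec(ld, gidx, G)
      }
      sweep(S, 2, lw, "+")
    }
    fn <- function(theta) {
      S <- node_S(theta)
      m <- apply(S, 1, max)
      ll <- sum(m + log(rowSums(exp(S - m))))
      if (!is.null(pc_lambda)) {
        sigma <- exp(theta[p1 + p2 + 2])
        ll <- ll + log(pc_lambda) - pc_lambda * sigma
      }
      -ll
    }
    gr <- function(theta) {
      b1 <- theta[seq_len(p1)]
      b2 <- theta[p1 + seq_len(p2)]
      phi <- exp(theta[p1 + p2 + 1])
      sigma <- exp(theta[p1 + p2 + 2])
      eta1 <- drop(X1 %*% b1)
      eta2 <- drop(X2u %*% b2)
      S <- node_S(theta)
      m <- apply(S, 1, max)
      P <- exp(S - m)
      P <- P / rowSums(P)                  # posterior node weights per group
      a <- log1p(phi)
      g1 <- numeric(p1); g2 <- numeric(p2); glphi <- 0; glsig <- 0
      for (k in seq_len(quad_points)) {
        u <- sqrt(2) * sigma * gh$nodes[k]
        w <- P[gidx, k]
        wu <- P[gidx_u, k]
        pi1 <- plogis(eta1 + u)
        d1 <- z - pi1
        g1 <- g1 + drop(crossprod(X1, w * d1))
        mu <- exp(pmin(eta2 + u, 35))
        psi <- mu / phi
        r <- 1 / (-expm1(-psi * a))
        dldpsi <- digamma(yu + psi) - digamma(psi) - a * r
        g2 <- g2 + drop(crossprod(X2u, wu * psi * dldpsi))
        glphi <- glphi + sum(wu * (-psi * dldpsi + yu / (1 + phi) -
                                     r * psi * phi / (1 + phi)))
        dldu <- d1
        dldu[users] <- dldu[users] + psi * dldpsi
        glsig <- glsig + u * sum(w * dldu)
      }
      if (!is.null(pc_lambda)) glsig <- glsig - pc_lambda * sigma
      -c(g1, g2, glphi, glsig)
    }
    list(fn = fn, gr = gr, p1 = p1, p2 = p2, grouped = TRUE,
         par_names = function(n1, n2) c(paste0("use:", n1),
                                        paste0("count:", n2),
                                        "log_phi", "log_sigma_u"))
  }
}

rowsum_vec <- function(x, g, G) {
  out <- numeric(G)
  r <- rowsum(x, g)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

grad_norm <- function(obj, par) {
  if (!is.null(obj$gr)) return(sqrt(sum(obj$gr(par)^2)))
  eps <- 1e-5
  g <- vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- eps
    (obj$fn(par + e) - obj$fn(par - e)) / (2 * eps)
  }, numeric(1))
  sqrt(sum(g^2))
}

# part 1 from a plain logistic fit, part 2 from a Poisson fit on users,
# phi from the method-of-moments excess variance floored at 1e-3
hurdle_start <- function(y, X1, X2, grouped = FALSE) {
  z <- as.numeric(y > 0)
  b1 <- tryCatch(coef(glm.fit2(X1, z, binomial())), error = function(e) {
    c(qlogis(pmin(pmax(mean(z), 0.01), 0.99)), numeric(ncol(X1) - 1))
  })
  yu <- y[y > 0]
  X2u <- X2[y > 0, , drop = FALSE]
  b2 <- tryCatch(coef(glm.fit2(X2u, yu, poisson())), error = function(e) {
    c(log(mean(yu)), numeric(ncol(X2) - 1))
  })
  phi0 <- max(stats::var(yu) / mean(yu) - 1, 1e-3)
  st <- c(b1, b2, log(phi0))
  if (grouped) st <- c(st, log(0.3))
  st
}

glm.fit2 <- function(X, y, family) {
  f <- stats::glm.fit(X, y, family = family)
  if (anyNA(f$coefficients)) stop("aliased coefficients")
  f
}

#' Evaluate the joint hurdle log-likelihood at given parameters
#'
#' The likelihood is \eqn{\sum_{y_i = 0} \log(1-\mu_{1i}) + \sum_{y_i > 0}
#' [\log \mu_{1i} + \log f_2(y_i \mid \mu_{2i}, \phi)]} with
#' \eqn{\mu_{1i} = \mathrm{logit}^{-1}(X_{1i}'\beta_1)}, \eqn{\mu_{2i} =
#' \exp(X_{2i}'\beta_2)} and \eqn{f_2} the zero-truncated negative binomial
#' pmf of [dztnb()]. With `sigma_u > 0` and a `group` index, each group's
#' contribution integrates a shared Gaussian random intercept by
#' Gauss-Hermite quadrature.
#'
#' @param y non-negative integer response vector.
#' @param X1,X2 design matrices for the two parts (rows match `y`).
#' @param beta1,beta2 coefficient vectors.
#' @param phi positive NB1 dispersion.
#' @param sigma_u random-intercept SD (0 for none).
#' @param group integer/factor group index when `sigma_u > 0`.
#' @param quad_points Gauss-Hermite nodes.
#' @return the scalar log-likelihood.
#' @export
hurdle_loglik <- function(y, X1, X2, beta1, beta2, phi, sigma_u = 0,
                          group = NULL, quad_points = 20) {
  check_count_response(y)
  gidx <- if (sigma_u > 0) {
    if (is.null(group)) abort("`group` required when sigma_u > 0.",
                              class = "equicare_data_error")
    as.integer(factor(group))
  } else NULL
  obj <- hurdle_objective(y, X1, X2, gidx, pc_lambda = NULL,
                          quad_points = quad_points)
  theta <- c(beta1, beta2, log(phi))
  if (!is.null(gidx)) theta <- c(theta, log(sigma_u))
  -obj$fn(theta)
}

#' Fit a zero-truncated negative binomial regression alone
#'
#' Maximum-likelihood fit of the frequency part only, on strictly positive
#' counts. Used on the users' subsample; the joint [fit_hurdle()] reduces to
#' this fit for its part-2 block when the two parts share no parameters.
#'
#' @inheritParams fit_hurdle
#' @return a list with `coefficients`, `phi`, `vcov` (working scale),
#'   `logLik` and `converged`.
#' @export
fit_ztnb <- function(formula, data, control = list()) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (any(y < 1) || any(y != floor(y))) {
    abort("fit_ztnb requires strictly positive integer responses.",
          class = "equicare_data_error")
  }
  X <- model.matrix(formula, mf)
  p <- ncol(X)
  fn <- function(theta) {
    mu <- exp(pmin(drop(X %*% theta[seq_len(p)]), 35))
    -sum(ztnb_logpmf(y, mu, exp(theta[p + 1])))
  }
  gr <- function(theta) {
    phi <- exp(theta[p + 1])
    mu <- exp(pmin(drop(X %*% theta[seq_len(p)]), 35))
    psi <- mu / phi
    a <- log1p(phi)
    r <- 1 / (-expm1(-psi * a))
    dldpsi <- digamma(y + psi) - digamma(psi) - a * r
    -c(drop(crossprod(X, psi * dldpsi)),
       sum(-psi * dldpsi + y / (1 + phi) - r * psi * phi / (1 + phi)))
  }
  b0 <- tryCatch(coef(glm.fit2(X, y, poisson())),
                 error = function(e) c(log(mean(y)), numeric(p - 1)))
  st <- c(b0, log(max(stats::var(y) / mean(y) - 1, 1e-3)))
  ctl <- modify_list(list(maxit = 500, reltol = 1e-12), control)
  opt <- stats::optim(st, fn, gr, method = "BFGS", control = ctl)
  par <- setNames(opt$par, c(colnames(X), "log_phi"))
  H <- tryCatch(optimHess(par, fn, gr), error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  list(coefficients = par[seq_len(p)], phi = unname(exp(par[p + 1])),
       par = par, vcov = V, logLik = -opt$value,
       converged = opt$convergence == 0)
}

# Gauss-Hermite nodes/weights for integr. of exp(-t^2) g(t) (Golub-Welsch)
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Rate and odds ratios from a fitted hurdle model
#'
#' Exponentiated contrasts of fitted coefficients with delta-method
#' confidence intervals: odds ratios for the use part (part 1), rate ratios
#' for the frequency part (part 2). A zero contrast returns exactly 1.
#'
#' @param fit a `hurdle_fit`.
#' @param term coefficient name (as in `tidy(fit)`), or `NULL` if `contrast`
#'   is supplied.
#' @param part `"use"` or `"count"`.
#' @param contrast optional named numeric vector of coefficient weights
#'   within `part`.
#' @param conf.level confidence level for the interval.
#' @return a tibble with columns `part`, `term`, `estimate`, `std.error`
#'   (log scale), `conf.low`, `conf.high`.
#' @export
rate_ratio <- function(fit, term = NULL, part = c("use", "count"),
                       contrast = NULL, conf.level = 0.95) {
  stopifnot(inherits(fit, "hurdle_fit"))
  part <- match.arg(part)
  cf <- fit$coefficients[[part]]
  if (is.null(contrast)) {
    if (is.null(term)) abort("supply `term` or `contrast`.")
    if (!term %in% names(cf)) {
      abort(sprintf("unknown coefficient '%s' in part '%s'.", term, part),
            class = "equicare_contrast_error")
    }
    contrast <- setNames(1, term)
  }
  if (!all(names(contrast) %in% names(cf))) {
    abort(sprintf("unknown coefficient(s): %s",
                  paste(setdiff(names(contrast), names(cf)), collapse = ", ")),
          class = "equicare_contrast_error")
  }
  cvec <- setNames(numeric(length(fit$par)), names(fit$par))
  cvec[paste0(part, ":", names(contrast))] <- contrast
  est <- sum(cvec * fit$par)
  se <- if (!is.null(fit$vcov)) sqrt(drop(t(cvec) %*% fit$vcov %*% cvec)) else NA_real_
  zq <- qnorm(1 - (1 - conf.level) / 2)
  tibble(part = part,
         term = if (!is.null(term)) term else paste(names(contrast), collapse = "+"),
         estimate = exp(est), std.error = se,
         conf.low = exp(est - zq * se), conf.high = exp(est + zq * se))
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("Two-part hurdle fit:", x$response_name, "\n")
  cat(sprintf("  n = %d (%d users), logLik = %.3f%s\n", x$n, x$n_users,
              x$logLik, if (x$penalized) " (penalised)" else ""))
  cat(sprintf("  dispersion phi = %.4f%s\n", x$phi,
              if (!is.null(x$sigma_u)) sprintf(", sigma_u = %.4f", x$sigma_u) else ""))
  cat("  use part: ", paste(sprintf("%s=%.3f", names(x$coefficients$use),
                                    x$coefficients$use), collapse = ", "), "\n")
  cat("  count part:", paste(sprintf("%s=%.3f", names(x$coefficients$count),
                                     x$coefficients$count), collapse = ", "), "\n")
  if (!x$converged) cat("  WARNING: fit flagged as not converged\n")
  invisible(x)
}

#' @export
logLik.hurdle_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$par), class = "logLik")
}

#' Tidy a hurdle fit into one row per coefficient
#'
#' @param x a `hurdle_fit`.
#' @param exponentiate report `exp(estimate)` (odds/rate ratios)?
#' @param conf.int,conf.level add Wald confidence bounds?
#' @param ... unused.
#' @return a tibble with `part` (`use`, `count`, `dispersion`,
#'   `ranef_sd`), `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.hurdle_fit <- function(x, exponentiate = FALSE, conf.int = FALSE,
                            conf.level = 0.95, ...) {
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, length(x$par))
  part <- sub(":.*$", "", names(x$par))
  part[names(x$par) == "log_phi"] <- "dispersion"
  part[names(x$par) == "log_sigma_u"] <- "ranef_sd"
  term <- sub("^[a-z_]+:", "", names(x$par))
  out <- tibble(part = part, term = term, estimate = unname(x$par),
                std.error = unname(se),
                statistic = unname(x$par / se),
                p.value = 2 * pnorm(-abs(unname(x$par / se))))
  if (conf.int) {
    zq <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  if (exponentiate) {
    sel <- out$part %in% c("use", "count")
    out$estimate[sel] <- exp(out$estimate[sel])
    if (conf.int) {
      out$conf.low[sel] <- exp(out$conf.low[sel])
      out$conf.high[sel] <- exp(out$conf.high[sel])
    }
  }
  out
}

#' One-row model summary of a hurdle fit
#'
#' @param x a `hurdle_fit`.
#' @param ... unused.
#' @return a tibble with log-likelihood, AIC, dispersion, random-effect SD,
#'   sample sizes and the convergence flag.
#' @export
glance.hurdle_fit <- function(x, ...) {
  k <- length(x$par)
  tibble(logLik = x$logLik, AIC = 2 * k - 2 * x$logLik, df = k,
         phi = x$phi, sigma_u = x$sigma_u %||% NA_real_,
         nobs = x$n, n_users = x$n_users, converged = x$converged)
}
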