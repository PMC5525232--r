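test_that("the joint log-likelihood is the sum of per-observation terms", {
  X <- cbind(1, c(-1, 0, 2))
  y <- c(0, 2, 5)
  b1 <- c(0.2, 0.5)
  b2 <- c(0.7, -0.3)
  phi <- 0.8
  # each observation's contribution computed independently
  eta1 <- X %*% b1
  mu2 <- exp(X %*% b2)
  terms <- c(log(1 - plogis(eta1[1])),
             log(plogis(eta1[2])) + dztnb(2, mu2[2], phi, log = TRUE),
             log(plogis(eta1[3])) + dztnb(5, mu2[3], phi, log = TRUE))
  expect_equal(hurdle_loglik(y, X, X, b1, b2, phi), sum(terms), tolerance = 1e-12)
})

test_that("the likelihood matches brute-force gamma-function arithmetic", {
  # six-point fixture evaluated by direct Gamma arithmetic, no log tricks
  y <- c(0, 1, 1, 3, 0, 6)
  x <- c(0, 1, 0, 1, 1, 0)
  X <- cbind(1, x)
  b1 <- c(-0.1, 0.6)
  b2 <- c(0.4, 0.3)
  phi <- 1.3
  brute <- 0
  for (i in seq_along(y)) {
    p1 <- 1 / (1 + exp(-(b1[1] + b1[2] * x[i])))
    if (y[i] == 0) {
      brute <- brute + log(1 - p1)
    } else {
      mu <- exp(b2[1] + b2[2] * x[i])
      psi <- mu / phi
      f <- (gamma(y[i] + psi) / (gamma(psi) * gamma(y[i] + 1))) *
        (mu / (mu + psi))^y[i] / (((mu + psi) / psi)^psi - 1)
      brute <- brute + log(p1) + log(f)
    }
  }
  expect_equal(hurdle_loglik(y, X, X, b1, b2, phi), brute, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  set.seed(11)
  d <- simulate_hurdle_data(400, b1 = c(0.3, 0.4), b2 = c(0.8, -0.3), phi = 0.7)
  X <- cbind(1, d$x)
  fd_grad <- function(fn, th, eps = 1e-6) {
    vapply(seq_along(th), function(j) {
      e <- numeric(length(th)); e[j] <- eps
      (fn(th + e) - fn(th - e)) / (2 * eps)
    }, numeric(1))
  }
  obj <- equicare:::hurdle_objective(d$y, X, X)
  th <- c(0.1, 0.2, 0.5, -0.1, log(0.4))
  expect_equal(obj$gr(th), fd_grad(obj$fn, th), tolerance = 1e-5)

  gi <- rep(1:80, each = 5)
  obj2 <- equicare:::hurdle_objective(d$y, X, X, gidx = gi, pc_lambda = 4.6)
  th2 <- c(th, log(0.35))
  expect_equal(obj2$gr(th2), fd_grad(obj2$fn, th2), tolerance = 1e-4)
})

test_that("with disjoint parts the joint fit separates into its two blocks", {
  set.seed(21)
  d <- simulate_hurdle_data(600, b1 = c(0.2, 0.5), b2 = c(0.9, -0.4), phi = 1.1)
  joint <- fit_hurdle(y ~ x, d)
  part1 <- glm(I(y > 0) ~ x, family = binomial(), data = d)
  part2 <- fit_ztnb(y ~ x, d[d$y > 0, ])
  expect_equal(unname(joint$coefficients$use), unname(coef(part1)),
               tolerance = 1e-4)
  expect_equal(unname(joint$coefficients$count), unname(part2$coefficients),
               tolerance = 1e-4)
  expect_equal(joint$phi, part2$phi, tolerance = 1e-4)
})

test_that("degenerate responses are rejected with data errors", {
  d <- data.frame(y = c(0, 0, 0, 0), x = 1:4)
  expect_error(fit_hurdle(y ~ x, d), class = "equicare_data_error")
  d2 <- data.frame(y = c(1, 2, 3, 4), x = 1:4)
  expect_error(fit_hurdle(y ~ x, d2), class = "equicare_data_error")
  d3 <- data.frame(y = c(0, 1.5, 2), x = 1:3)
  expect_error(fit_hurdle(y ~ x, d3), class = "equicare_data_error")
})

test_that("single-fit parameter recovery stays within three standard errors", {
  set.seed(31)
  truth <- list(b1 = c(0.3, 0.4), b2 = c(0.8, -0.3), phi = 0.7)
  d <- simulate_hurdle_data(5000, truth$b1, truth$b2, truth$phi)
  f <- fit_hurdle(y ~ x, d)
  se <- sqrt(diag(f$vcov))
  est <- f$par
  tr <- c(truth$b1, truth$b2, log(truth$phi))
  expect_true(all(abs(est - tr) <= 3 * se))
  expect_true(f$converged)
})

test_that("rate ratios follow the delta method", {
  set.seed(41)
  d <- simulate_hurdle_data(800, c(0.2, 0.4), c(0.7, -0.2), 0.9)
  f <- fit_hurdle(y ~ x, d)
  # zero contrast: ratio exactly one
  rr0 <- rate_ratio(f, contrast = c(x = 0), part = "use")
  expect_identical(rr0$estimate, 1)
  # a coefficient of -0.105 maps to a ratio of exp(-0.105)
  f2 <- f
  f2$par["use:x"] <- -0.105
  f2$coefficients$use["x"] <- -0.105
  rr <- rate_ratio(f2, "x", "use")
  expect_equal(rr$estimate, exp(-0.105), tolerance = 1e-12)
  # interval width on the log scale is 2 * z * SE, monotone in the SE
  rr1 <- rate_ratio(f, "x", "count")
  width <- log(rr1$conf.high) - log(rr1$conf.low)
  expect_equal(width, 2 * qnorm(0.975) * rr1$std.error, tolerance = 1e-10)
  expect_error(rate_ratio(f, "nope", "use"), class = "equicare_contrast_error")
})

test_that("random-effect likelihood approaches the fixed-effect one as sigma vanishes", {
  set.seed(51)
  d <- simulate_hurdle_data(300, c(0.2, 0.3), c(0.6, -0.2), 0.8)
  X <- cbind(1, d$x)
  fe <- hurdle_loglik(d$y, X, X, c(0.2, 0.3), c(0.6, -0.2), 0.8)
  re <- hurdle_loglik(d$y, X, X, c(0.2, 0.3), c(0.6, -0.2), 0.8,
                      sigma_u = 1e-6, group = rep(1:60, each = 5))
  expect_equal(re, fe, tolerance = 1e-6)
})

test_that("tidy and glance summarise the fit faithfully", {
  set.seed(61)
  d <- simulate_hurdle_data(600, c(0.2, 0.3), c(0.8, -0.2), 0.9)
  f <- fit_hurdle(y ~ x, d)
  td <- tidy(f)
  expect_setequal(td$part, c("use", "count", "dispersion"))
  expect_equal(nrow(td), 5)
  expect_equal(td$estimate[td$part == "dispersion"], log(f$phi))
  te <- tidy(f, exponentiate = TRUE, conf.int = TRUE)
  expect_equal(te$estimate[1], exp(td$estimate[1]))
  g <- glance(f)
  expect_equal(g$nobs, 600)
  expect_equal(g$logLik, f$logLik)
})
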