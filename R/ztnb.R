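#' Zero-truncated negative binomial distribution (NB1 dispersion)
#'
#' Density and random generation for the negative binomial distribution
#' conditioned on a strictly positive outcome, in the NB1-style
#' parameterisation used throughout this package: mean parameter `mu` and
#' dispersion `phi`, with shape `psi = mu / phi` so that the untruncated
#' variance is `mu * (1 + phi)`. The truncated pmf is
#' \deqn{f(y \mid y > 0) = \frac{\Gamma(y+\psi)}{\Gamma(\psi)\,\Gamma(y+1)}
#'   \left(\frac{\mu}{\mu+\psi}\right)^{y} \Big/
#'   \left[\left(\frac{\mu+\psi}{\psi}\right)^{\psi} - 1\right],}
#' which equals the standard negative binomial pmf renormalised by
#' \eqn{1 - P(0)}. As `phi` tends to zero the distribution converges to the
#' zero-truncated Poisson with mean parameter `mu`.
#'
#' All computation is on the log scale; the denominator uses
#' `log(expm1())` / `log1p(-exp())` identities so that extreme `mu` and
#' `phi` values stay finite.
#'
#' @param x vector of positive integer counts.
#' @param n number of draws.
#' @param mu positive mean parameter of the untruncated distribution.
#' @param phi positive NB1 dispersion (`psi = mu / phi`).
#' @param log logical; return log-density?
#' @return `dztnb()` a numeric vector of (log-)probabilities; `rztnb()` an
#'   integer vector of draws `>= 1`.
#' @examples
#' dztnb(1, mu = 2, phi = 1)   # 1/3
#' sum(dztnb(1:500, mu = 3, phi = 0.7))
#' @export
dztnb <- function(x, mu, phi, log = FALSE) {
  if (any(mu <= 0) || any(phi <= 0)) {
    abort("`mu` and `phi` must be strictly positive.", class = "equicare_domain_error")
  }
  if (any(x < 1) || any(x != floor(x))) {
    abort("zero-truncated support: `x` must be integer and >= 1.",
          class = "equicare_domain_error")
  }
  out <- ztnb_logpmf(x, mu, phi)
  if (log) out else exp(out)
}

# unchecked vectorised log-pmf; recycled arguments
ztnb_logpmf <- function(y, mu, phi) {
  psi <- mu / phi
  a <- log1p(phi)                      # log((mu+psi)/psi) = log(1+phi)
  # log[(1+phi)^psi - 1] = psi*a + log(1 - exp(-psi*a)), stable at both ends
  pa <- psi * a
  log_denom <- pa + log(-expm1(-pa))
  lgr <- lgamma_ratio(y, psi)
  lgr - lgamma(y + 1) + y * (log(phi) - a) - log_denom
}

# log Gamma(y+psi) - log Gamma(psi); for very large psi the direct lgamma
# difference cancels catastrophically, so small integer y uses the exact
# product sum(log(psi + 0:(y-1)))
lgamma_ratio <- function(y, psi) {
  n <- max(length(y), length(psi))
  y <- rep_len(y, n)
  psi <- rep_len(psi, n)
  out <- lgamma(y + psi) - lgamma(psi)
  big <- psi > 1e6 & y <= 1e4
  if (any(big)) {
    out[big] <- mapply(function(yi, pi) sum(log(pi + seq_len(yi) - 1)),
                       y[big], psi[big])
  }
  out
}

# P(Y = 0) of the untruncated NB, log scale: -psi * log(1+phi)
ztnb_logp0 <- function(mu, phi) -(mu / phi) * log1p(phi)

#' @rdname dztnb
#' @export
rztnb <- function(n, mu, phi) {
  if (any(mu <= 0) || any(phi <= 0)) {
    abort("`mu` and `phi` must be strictly positive.", class = "equicare_domain_error")
  }
  mu <- rep_len(mu, n)
  phi <- rep_len(phi, n)
  psi <- mu / phi
  p0 <- exp(ztnb_logp0(mu, phi))
  # inverse-cdf: uniform on (P0, 1) then untruncated quantile
  u <- p0 + runif(n) * (1 - p0)
  as.integer(qnbinom(pmin(u, 1 - 1e-16), size = psi, mu = mu))
}

# truncated mean mu / (1 - P0)
ztnb_mean <- function(mu, phi) mu / (-expm1(ztnb_logp0(mu, phi)))
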