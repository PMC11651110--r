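#' Zero-inflated negative binomial distribution
#'
#' Density and random generation for the zero-inflated negative binomial
#' (ZINB) distribution with mean `mu` of the negative binomial component,
#' size `theta` (overdispersion is `1/theta`) and extra-zero weight `phi`:
#' \deqn{P(Y=0) = \phi + (1-\phi)\left(\frac{\theta}{\theta+\mu}\right)^\theta}
#' \deqn{P(Y=y) = (1-\phi)\,\mathrm{NB}(y;\mu,\theta), \quad y > 0.}
#'
#' The zero mass mixes structural ("extra") zeros — biological absence plus
#' technical dropout — with sampling zeros of the count component. `theta =
#' Inf` is accepted and gives the zero-inflated Poisson limit.
#'
#' @param x vector of non-negative integer counts.
#' @param n number of draws.
#' @param mu positive mean of the negative binomial component.
#' @param theta positive size parameter; `1/theta` is the overdispersion.
#' @param phi extra-zero probability in `[0, 1]`.
#' @param log logical; return log-density?
#' @return `dzinb` a numeric vector of (log-)probabilities; `rzinb` an
#'   integer-valued numeric vector of draws.
#' @examples
#' dzinb(0, mu = 1, theta = 1, phi = 0.5)  # 0.75
#' mean(rzinb(1e4, mu = 10, theta = 1, phi = 0.3) == 0)
#' @export
dzinb <- function(x, mu, theta, phi, log = FALSE) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))
    stop("'x' must contain non-negative integers")
  stopifnot(all(mu > 0), all(theta > 0), all(phi >= 0), all(phi <= 1))
  k <- max(length(x), length(mu), length(theta), length(phi))
  x <- rep_len(x, k); mu <- rep_len(mu, k)
  theta <- rep_len(theta, k); phi <- rep_len(phi, k)
  lnb <- ifelse(is.finite(theta),
                stats::dnbinom(x, size = theta, mu = mu, log = TRUE),
                stats::dpois(x, lambda = mu, log = TRUE))
  lp <- log1p(-phi) + lnb
  at0 <- x == 0
  if (any(at0)) {
    # log-sum-exp of {log phi, log(1-phi) + NB(0)} guards phi at 0 and 1
    a <- log(phi[at0])
    b <- lp[at0]
    m <- pmax(a, b)
    m[!is.finite(m)] <- 0
    lp[at0] <- m + log(exp(a - m) + exp(b - m))
  }
  if (log) lp else exp(lp)
}

#' @rdname dzinb
#' @export
rzinb <- function(n, mu, theta, phi) {
  stopifnot(n >= 0, all(mu > 0), all(theta > 0), all(phi >= 0), all(phi <= 1))
  extra <- stats::rbinom(n, 1L, prob = rep_len(phi, n))
  counts <- if (all(is.finite(theta)))
    stats::rnbinom(n, size = rep_len(theta, n), mu = rep_len(mu, n))
  else
    stats::rpois(n, lambda = rep_len(mu, n))
  counts * (1L - extra)
}

#' Zero-inflation probability under the tau link
#'
#' The tau link ties the extra-zero probability to the count mean through
#' `logit(phi) = -tau * log(mu)`, i.e. `phi = 1 / (1 + mu^tau)`. With
#' `tau > 0`, abundant taxa (large `mu`) get fewer structural zeros.
#'
#' @param mu positive mean of the count component.
#' @param tau real shape parameter of the link.
#' @return zero-inflation probabilities in `(0, 1)`.
#' @examples
#' phiFromTau(4, 1)  # 0.2
#' @export
phiFromTau <- function(mu, tau) {
  stopifnot(all(mu > 0))
  stats::plogis(-tau * log(mu))
}

#' ZINB regression log-likelihood under the tau link
#'
#' Log-likelihood of counts `y` under the ZINB regression model with
#' `log(mu_i) = B_i beta` and `logit(phi_i) = -tau * B_i beta`. The
#' expression is evaluated in the `(tau, eta)` parameterization throughout,
#' using the identities `1 - phi_i = (1 + e^{-tau eta_i})^{-1}` and
#' `phi_i/(1 - phi_i) = e^{-tau eta_i}`, with a log-sum-exp for the zero
#' term, so it stays finite for all finite inputs.
#'
#' @param beta regression coefficient vector (intercept first).
#' @param theta positive negative-binomial size.
#' @param tau shape parameter of the zero-inflation link.
#' @param B design matrix, one row per observation.
#' @param y non-negative integer counts, `length(y) == nrow(B)`.
#' @return the scalar log-likelihood; `0` for empty `y`.
#' @export
zinbLoglik <- function(beta, theta, tau, B, y) {
  B <- as.matrix(B)
  if (nrow(B) != length(y))
    stop("nrow(B) must equal length(y)")
  if (ncol(B) != length(beta))
    stop("ncol(B) must equal length(beta)")
  stopifnot(theta > 0)
  if (length(y) == 0L) return(0)
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must contain non-negative integers")
  eta <- drop(B %*% beta)
  # log(1 - phi_i) = -log(1 + e^{-tau*eta}) for every observation
  ll <- sum(-log1p(exp(-tau * eta)))
  z <- y == 0
  if (any(z)) {
    # log( phi/(1-phi) + (theta/(theta+mu))^theta ), phi/(1-phi) = e^{-tau*eta}
    a <- -tau * eta[z]
    b <- theta * (log(theta) - log(theta + exp(eta[z])))
    m <- pmax(a, b)
    ll <- ll + sum(m + log(exp(a - m) + exp(b - m)))
  }
  if (any(!z)) {
    yp <- y[!z]; ep <- eta[!z]; mup <- exp(ep)
    ll <- ll + sum(lgamma(yp + theta) - lgamma(theta) - lfactorial(yp) +
                     theta * (log(theta) - log(theta + mup)) +
                     yp * (ep - log(theta + mup)))
  }
  ll
}
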