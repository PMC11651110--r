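#' Two-part hurdle model by maximum likelihood
#'
#' Frequentist counterpart used as a benchmark comparator: a logistic model
#' for the zero indicator with `logit(phi) = -(G gamma)` (same negated sign
#' convention as the Bayesian zero models), and a zero-truncated negative
#' binomial for the positive counts with `log(mu) = B beta`. Standard errors
#' come from the observed information; Wald-style 2.5/97.5 bounds fill the
#' interval columns so hurdle fits can be tabulated next to posterior fits.
#' Non-convergence of the truncated-count optimization yields a fit with
#' `isFailed(fit) = TRUE`, not an error.
#'
#' @param B design matrix for the count mean, intercept included.
#' @param y counts containing both zero and positive values.
#' @param G zero-model design matrix; defaults to `B`.
#' @param spec a [ZinbModelSpec-class]; recorded in the result.
#' @return a [ZinbFit-class] with `variant = "HURDLE"`.
#' @export
fitHurdleMle <- function(B, y, G = NULL, spec = zinbModelSpec("HURDLE")) {
  B <- as.matrix(B)
  if (is.null(colnames(B))) colnames(B) <- paste0("V", seq_len(ncol(B)))
  if (nrow(B) != length(y)) stop("nrow(B) must equal length(y)")
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must contain non-negative integer counts")
  if (all(y == 0))
    stop("count part degenerate: no positive observations")
  if (all(y > 0))
    stop("zero part degenerate: no zero observations")
  if (is.null(G)) G <- B else {
    G <- as.matrix(G)
    if (is.null(colnames(G))) colnames(G) <- paste0("V", seq_len(ncol(G)))
  }
  spec@variant <- "HURDLE"
  nms <- c(paste0("beta[", colnames(B), "]"),
           paste0("gamma[", colnames(G), "]"), "theta")

  # zero part: glm estimates logit P(zero) = G %*% (-gamma); with very few
  # zeros the fit can quasi-separate, which is expected and handled by the
  # information-based standard errors, so the fitted-probability warning is
  # muffled
  zeroFit <- withCallingHandlers(
    stats::glm.fit(G, as.numeric(y == 0), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  gammaHat <- -zeroFit$coefficients
  gammaSe <- sqrt(diag(chol2inv(chol(
    crossprod(G * sqrt(zeroFit$weights), G)))))

  # positive part: zero-truncated NB on y > 0
  pos <- y > 0
  Bp <- B[pos, , drop = FALSE]
  yp <- y[pos]
  negll <- function(par) {
    beta <- par[seq_len(ncol(Bp))]
    theta <- exp(par[length(par)])
    mu <- exp(drop(Bp %*% beta))
    lp0 <- theta * (log(theta) - log(theta + mu))   # log P(0) under NB
    ll <- sum(stats::dnbinom(yp, size = theta, mu = mu, log = TRUE) -
                log1p(-exp(lp0)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  init <- tryCatch(
    stats::glm.fit(Bp, yp, family = stats::poisson())$coefficients,
    error = function(e) c(log(mean(yp)), rep(0, ncol(Bp) - 1L)))
  init[!is.finite(init)] <- 0
  opt <- tryCatch(
    stats::optim(c(init, 0), negll, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0L)
    return(.failedFit("HURDLE", nms, spec,
                      "truncated negative binomial MLE did not converge"))
  est <- opt$par
  se <- tryCatch({
    co <- chol2inv(chol(opt$hessian))
    sqrt(pmax(diag(co), 0))
  }, error = function(e) rep(NA_real_, length(est)))
  betaHat <- est[seq_len(ncol(Bp))]
  thetaHat <- exp(est[length(est)])
  thetaSe <- se[length(se)] * thetaHat   # delta method from the log scale
  means <- c(betaHat, gammaHat, thetaHat)
  sds <- c(se[seq_len(ncol(Bp))], gammaSe, thetaSe)
  zq <- stats::qnorm(0.975)
  smry <- data.frame(parameter = nms, mean = means, sd = sds,
                     q2.5 = means - zq * sds, q97.5 = means + zq * sds,
                     ess = NA_real_, rhat = NA_real_,
                     row.names = NULL, stringsAsFactors = FALSE)
  new("ZinbFit", variant = "HURDLE", summary = smry,
      draws = matrix(numeric(), 0, 0), failed = FALSE, converged = TRUE,
      message = "", spec = spec)
}
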