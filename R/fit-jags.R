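# JAGS model templates for the Bayesian count-model family.
#
# Zero inflation uses a latent Bernoulli indicator z[i] per observation:
# marginalizing z recovers the mixture pmf exactly, and the construction is
# the standard JAGS encoding of zero-inflated counts. The zero-model linear
# predictors are negated so that a positive tau (or gamma) means fewer
# structural zeros for more abundant taxa.
.jagsTemplates <- list(
  P = "
model {
  eta <- B %*% beta
  for (i in 1:n) {
    y[i] ~ dpois(mu[i])
    log(mu[i]) <- eta[i]
  }
  for (j in 1:p) { beta[j] ~ dnorm(0, betaPrec) }
}",
  NB = "
model {
  eta <- B %*% beta
  for (i in 1:n) {
    y[i] ~ dnegbin(pr[i], theta)
    pr[i] <- theta / (theta + mu[i])
    log(mu[i]) <- eta[i]
  }
  for (j in 1:p) { beta[j] ~ dnorm(0, betaPrec) }
  theta ~ dgamma(a, b)
}",
  ZIP_tau = "
model {
  eta <- B %*% beta
  for (i in 1:n) {
    y[i] ~ dpois(muEff[i])
    muEff[i] <- (1 - z[i]) * mu[i] + 1.0E-10
    z[i] ~ dbern(phi[i])
    logit(phi[i]) <- -tau * eta[i]
    log(mu[i]) <- eta[i]
  }
  for (j in 1:p) { beta[j] ~ dnorm(0, betaPrec) }
  tau ~ dgamma(a, b)
}",
  MZIP = "
model {
  eta <- B %*% beta
  zeta <- G %*% gamma
  for (i in 1:n) {
    y[i] ~ dpois(muEff[i])
    muEff[i] <- (1 - z[i]) * mu[i] + 1.0E-10
    z[i] ~ dbern(phi[i])
    logit(phi[i]) <- -zeta[i]
    log(mu[i]) <- eta[i]
  }
  for (j in 1:p) { beta[j] ~ dnorm(0, betaPrec) }
  for (k in 1:q) { gamma[k] ~ dnorm(0, betaPrec) }
}",
  ZIP_inter = "
model {
  eta <- B %*% beta
  for (i in 1:n) {
    y[i] ~ dpois(muEff[i])
    muEff[i] <- (1 - z[i]) * mu[i] + 1.0E-10
    z[i] ~ dbern(phi[i])
    logit(phi[i]) <- theta0
    log(mu[i]) <- eta[i]
  }
  for (j in 1:p) { beta[j] ~ dnorm(0, betaPrec) }
  theta0 ~ dnorm(0, betaPrec)
}",
  ZINB_tau = "
model {
  eta <- B %*% beta
  for (i in 1:n) {
    y[i] ~ dnegbin(pr[i], theta)
    pr[i] <- theta / (theta + muEff[i])
    muEff[i] <- (1 - z[i]) * mu[i] + 1.0E-10
    z[i] ~ dbern(phi[i])
    logit(phi[i]) <- -tau * eta[i]
    log(mu[i]) <- eta[i]
  }
  for (j in 1:p) { beta[j] ~ dnorm(0, betaPrec) }
  theta ~ dgamma(a, b)
  tau ~ dgamma(a, b)
}",
  MZINB = "
model {
  eta <- B %*% beta
  zeta <- G %*% gamma
  for (i in 1:n) {
    y[i] ~ dnegbin(pr[i], theta)
    pr[i] <- theta / (theta + muEff[i])
    muEff[i] <- (1 - z[i]) * mu[i] + 1.0E-10
    z[i] ~ dbern(phi[i])
    logit(phi[i]) <- -zeta[i]
    log(mu[i]) <- eta[i]
  }
  for (j in 1:p) { beta[j] ~ dnorm(0, betaPrec) }
  for (k in 1:q) { gamma[k] ~ dnorm(0, betaPrec) }
  theta ~ dgamma(a, b)
}",
  ZINB_inter = "
model {
  eta <- B %*% beta
  for (i in 1:n) {
    y[i] ~ dnegbin(pr[i], theta)
    pr[i] <- theta / (theta + muEff[i])
    muEff[i] <- (1 - z[i]) * mu[i] + 1.0E-10
    z[i] ~ dbern(phi[i])
    logit(phi[i]) <- theta0
    log(mu[i]) <- eta[i]
  }
  for (j in 1:p) { beta[j] ~ dnorm(0, betaPrec) }
  theta ~ dgamma(a, b)
  theta0 ~ dnorm(0, betaPrec)
}")

.monitorFor <- function(variant) {
  switch(variant,
         P = "beta",
         NB = c("beta", "theta"),
         ZIP_tau = c("beta", "tau"),
         MZIP = c("beta", "gamma"),
         ZIP_inter = c("beta", "theta0"),
         ZINB_tau = c("beta", "theta", "tau"),
         MZINB = c("beta", "gamma", "theta"),
         ZINB_inter = c("beta", "theta", "theta0"),
         stop("unknown variant '", variant, "'"))
}

.paramNames <- function(variant, B, G) {
  bn <- colnames(B)
  if (is.null(bn)) bn <- as.character(seq_len(ncol(B)))
  nms <- paste0("beta[", bn, "]")
  if (variant %in% c("MZIP", "MZINB")) {
    gn <- colnames(G)
    if (is.null(gn)) gn <- as.character(seq_len(ncol(G)))
    nms <- c(nms, paste0("gamma[", gn, "]"))
  }
  if (variant %in% c("NB", "ZINB_tau", "MZINB", "ZINB_inter", "HURDLE"))
    nms <- c(nms, "theta")
  if (variant %in% c("ZIP_tau", "ZINB_tau")) nms <- c(nms, "tau")
  if (variant %in% c("ZIP_inter", "ZINB_inter")) nms <- c(nms, "theta0")
  nms
}

# Split-R-hat: each chain is halved, then the classical between/within
# variance ratio is computed across the split sequences.
.splitRhat <- function(chainList) {
  pieces <- list()
  for (ch in chainList) {
    m <- nrow(ch)
    h <- m %/% 2L
    pieces <- c(pieces, list(ch[seq_len(h), , drop = FALSE],
                             ch[(m - h + 1L):m, , drop = FALSE]))
  }
  vapply(seq_len(ncol(chainList[[1]])), function(j) {
    xs <- lapply(pieces, function(p) p[, j])
    nIter <- length(xs[[1]])
    means <- vapply(xs, mean, 0)
    vars <- vapply(xs, stats::var, 0)
    W <- mean(vars)
    Bv <- nIter * stats::var(means)
    if (!is.finite(W) || W <= 0) return(NA_real_)
    sqrt(((nIter - 1) / nIter * W + Bv / nIter) / W)
  }, 0)
}

.failedFit <- function(variant, paramNames, spec, message) {
  new("ZinbFit", variant = variant,
      summary = data.frame(parameter = paramNames, mean = NA_real_,
                           sd = NA_real_, q2.5 = NA_real_, q97.5 = NA_real_,
                           ess = NA_real_, rhat = NA_real_,
                           stringsAsFactors = FALSE),
      draws = matrix(numeric(), 0, 0), failed = TRUE, converged = FALSE,
      message = message, spec = spec)
}

.checkDesign <- function(B, y, spec) {
  B <- as.matrix(B)
  if (is.null(colnames(B)))
    colnames(B) <- paste0("V", seq_len(ncol(B)))
  if (nrow(B) != length(y)) stop("nrow(B) must equal length(y)")
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must contain non-negative integer counts")
  if (length(y) < ncol(B) + 2L)
    stop("need at least p + 2 observations (n = ", length(y),
         ", p = ", ncol(B), ")")
  if (all(y == 0))
    stop("'y' is all zeros; the count model is not identifiable")
  B
}

#' Sample the posterior of a ZINB-family regression model
#'
#' Runs JAGS with the schedule in `spec` (adaptation, burn-in, retained
#' samples, chains) and returns per-parameter posterior summaries: mean, sd,
#' equal-tailed 2.5/97.5 percent credible bounds, effective sample size and
#' split-R-hat. Structural problems (dimension mismatch, all-zero counts,
#' too few observations) raise errors before sampling; sampler degeneracy —
#' a JAGS runtime error such as a stuck slice sampler, non-finite summaries,
#' or split-R-hat above 1.2 on every parameter — is returned as a fit with
#' `isFailed(fit) = TRUE` and missing-coded summaries, never an exception.
#' Identical `spec` (including seed) and data reproduce the fit exactly.
#'
#' @param spec a [ZinbModelSpec-class] (its `variant` selects the model).
#' @param B design matrix for the count mean, intercept column included.
#' @param y non-negative integer counts.
#' @param G zero-model design matrix for `MZIP`/`MZINB`; defaults to `B`.
#' @return a [ZinbFit-class].
#' @export
samplePosterior <- function(spec, B, y, G = NULL) {
  variant <- spec@variant
  if (variant == "HURDLE")
    return(fitHurdleMle(B, y, G = G, spec = spec))
  if (!variant %in% names(.jagsTemplates))
    stop("unknown variant '", variant, "'; valid names: ",
         paste(.zinbVariants, collapse = ", "))
  B <- .checkDesign(B, y, spec)
  if (is.null(G)) G <- B else {
    G <- as.matrix(G)
    if (nrow(G) != length(y)) stop("nrow(G) must equal length(y)")
    if (is.null(colnames(G))) colnames(G) <- paste0("V", seq_len(ncol(G)))
  }
  nms <- .paramNames(variant, B, G)
  data <- list(y = as.integer(y), B = B, n = length(y), p = ncol(B),
               betaPrec = spec@betaPrecision)
  if (variant %in% c("MZIP", "MZINB")) { data$G <- G; data$q <- ncol(G) }
  if (variant %in% c("NB", "ZIP_tau", "ZINB_tau", "MZINB", "ZINB_inter")) {
    data$a <- spec@priorA; data$b <- spec@priorB
  }
  mkInits <- function(chain) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (abs(spec@seed) %% 20000000L) * 100L + chain,
                beta = c(log(mean(y) + 0.5), rep(0, ncol(B) - 1L)))
    if (variant %in% c("NB", "ZINB_tau", "MZINB", "ZINB_inter")) ini$theta <- 1
    if (variant %in% c("ZIP_tau", "ZINB_tau")) ini$tau <- 1
    if (variant %in% c("MZIP", "MZINB")) ini$gamma <- rep(0, ncol(G))
    if (variant %in% c("ZIP_inter", "ZINB_inter")) ini$theta0 <- 0
    if (!variant %in% c("P", "NB")) ini$z <- rep(0L, length(y))
    ini
  }
  fit <- tryCatch({
    model <- rjags::jags.model(textConnection(.jagsTemplates[[variant]]),
                               data = data,
                               inits = lapply(seq_len(spec@chains), mkInits),
                               n.chains = spec@chains, n.adapt = spec@adapt,
                               quiet = TRUE)
    stats::update(model, spec@burnin, progress.bar = "none")
    samp <- rjags::coda.samples(model, .monitorFor(variant),
                                n.iter = spec@samples, progress.bar = "none")
    chainList <- lapply(samp, function(ch) {
      m <- as.matrix(ch)
      colnames(m) <- .renameJagsColumns(colnames(m), B, G)
      m[, nms, drop = FALSE]
    })
    draws <- do.call(rbind, chainList)
    ess <- tryCatch(coda::effectiveSize(samp), error = function(e) NULL)
    if (!is.null(ess)) names(ess) <- .renameJagsColumns(names(ess), B, G)
    rhat <- .splitRhat(chainList)
    smry <- data.frame(
      parameter = nms,
      mean = colMeans(draws),
      sd = apply(draws, 2, stats::sd),
      q2.5 = apply(draws, 2, stats::quantile, probs = 0.025),
      q97.5 = apply(draws, 2, stats::quantile, probs = 0.975),
      ess = if (is.null(ess)) NA_real_ else unname(ess[nms]),
      rhat = rhat, row.names = NULL, stringsAsFactors = FALSE)
    if (any(!is.finite(smry$mean)))
      stop("non-finite posterior summary")
    if (all(rhat > 1.2, na.rm = TRUE) && any(is.finite(rhat)))
      stop("split-R-hat above 1.2 on all parameters")
    converged <- !any(rhat > 1.1, na.rm = TRUE)
    new("ZinbFit", variant = variant, summary = smry, draws = draws,
        failed = FALSE, converged = converged,
        message = if (converged) "" else "split-R-hat above 1.1 on some parameters",
        spec = spec)
  }, error = function(e) .failedFit(variant, nms, spec, conditionMessage(e)))
  fit
}

.renameJagsColumns <- function(cn, B, G) {
  bn <- colnames(B); gn <- colnames(G)
  for (j in seq_along(bn))
    cn[cn == paste0("beta[", j, "]")] <- paste0("beta[", bn[j], "]")
  if (length(bn) == 1L) cn[cn == "beta"] <- paste0("beta[", bn[1], "]")
  for (k in seq_along(gn))
    cn[cn == paste0("gamma[", k, "]")] <- paste0("gamma[", gn[k], "]")
  if (length(gn) == 1L) cn[cn == "gamma"] <- paste0("gamma[", gn[1], "]")
  cn
}

#' Fit one named variant of the count-model family
#'
#' Dispatches on the variant name: `P` and `NB` have no zero model;
#' `ZIP_tau`/`ZINB_tau` tie the zero probability to the mean
#' (`logit(phi) = -tau * B beta`); `MZIP`/`MZINB` give the zero model its own
#' coefficients on `G` (`logit(phi) = -(G gamma)`, `G = B` by default);
#' `ZIP_inter`/`ZINB_inter` use a single free zero-inflation intercept; and
#' `HURDLE` is the two-part maximum-likelihood model. Coefficients are
#' returned on the log-mean scale in every case.
#'
#' @param variant one of the nine variant names.
#' @param B design matrix (intercept first column).
#' @param y non-negative integer counts.
#' @param spec a [ZinbModelSpec-class] carrying priors and the MCMC schedule;
#'   its own `variant` slot is overridden by `variant`.
#' @param G optional zero-model design matrix for `MZIP`/`MZINB`.
#' @return a [ZinbFit-class].
#' @export
fitVariant <- function(variant, B, y, spec = zinbModelSpec(), G = NULL) {
  if (length(variant) != 1L || !variant %in% .zinbVariants)
    stop("unknown variant '", paste(variant, collapse = ","),
         "'; valid names: ", paste(.zinbVariants, collapse = ", "))
  spec@variant <- variant
  samplePosterior(spec, B, y, G = G)
}
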