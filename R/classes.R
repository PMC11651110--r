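#' @import methods
NULL

.zinbVariants <- c("P", "NB", "ZIP_tau", "MZIP", "ZIP_inter",
                   "ZINB_tau", "MZINB", "ZINB_inter", "HURDLE")

#' Model specification for the ZINB regression family
#'
#' An S4 container naming one of the nine implemented variants together with
#' prior hyperparameters and the MCMC schedule. The variants are: `P`
#' (Poisson), `NB` (negative binomial), `ZIP_tau`/`ZINB_tau` (zero model tied
#' to the mean via `logit(phi) = -tau * B beta`), `MZIP`/`MZINB` (zero model
#' on its own covariates, `logit(phi) = -(G gamma)`), `ZIP_inter`/`ZINB_inter`
#' (a single free zero-inflation intercept), and `HURDLE` (two-part maximum
#' likelihood: logistic zero part plus zero-truncated negative binomial).
#'
#' @slot variant one of the nine variant names.
#' @slot priorA,priorB gamma hyperparameters for `theta` and `tau`
#'   (default 0.001, 0.001).
#' @slot betaPrecision normal-prior precision for each regression coefficient
#'   (default 1e-6, i.e. variance 1e6).
#' @slot adapt,burnin,samples MCMC schedule: adaptation, burn-in and retained
#'   iterations (defaults 10000, 2000, 2000).
#' @slot chains number of MCMC chains.
#' @slot seed integer seed for the sampler RNG.
#' @export
setClass("ZinbModelSpec",
  representation(variant = "character", priorA = "numeric", priorB = "numeric",
                 betaPrecision = "numeric", adapt = "integer",
                 burnin = "integer", samples = "integer", chains = "integer",
                 seed = "integer"),
  prototype(variant = "ZINB_tau", priorA = 0.001, priorB = 0.001,
            betaPrecision = 1e-6, adapt = 10000L, burnin = 2000L,
            samples = 2000L, chains = 2L, seed = 1L))

setValidity("ZinbModelSpec", function(object) {
  msg <- character()
  if (length(object@variant) != 1L || !object@variant %in% .zinbVariants)
    msg <- c(msg, paste0("variant must be one of: ",
                         paste(.zinbVariants, collapse = ", ")))
  for (s in c("adapt", "burnin", "samples", "chains"))
    if (slot(object, s) <= 0L) msg <- c(msg, paste(s, "must be positive"))
  if (object@priorA <= 0 || object@priorB <= 0)
    msg <- c(msg, "gamma hyperparameters must be positive")
  if (object@betaPrecision <= 0)
    msg <- c(msg, "betaPrecision must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ZinbModelSpec
#'
#' @param variant model variant name; see [ZinbModelSpec-class].
#' @param priorA,priorB gamma prior hyperparameters for `theta` and `tau`.
#' @param betaPrecision normal-prior precision for regression coefficients.
#' @param adapt,burnin,samples MCMC schedule.
#' @param chains number of chains.
#' @param seed integer RNG seed.
#' @return a validated [ZinbModelSpec-class] object.
#' @examples
#' zinbModelSpec("ZINB_tau", adapt = 500, burnin = 500, samples = 1000)
#' @export
zinbModelSpec <- function(variant = "ZINB_tau", priorA = 0.001,
                          priorB = 0.001, betaPrecision = 1e-6,
                          adapt = 10000, burnin = 2000, samples = 2000,
                          chains = 2, seed = 1) {
  if (length(variant) != 1L || !variant %in% .zinbVariants)
    stop("unknown variant '", paste(variant, collapse = ","),
         "'; valid names: ", paste(.zinbVariants, collapse = ", "))
  new("ZinbModelSpec", variant = variant, priorA = priorA, priorB = priorB,
      betaPrecision = betaPrecision, adapt = as.integer(adapt),
      burnin = as.integer(burnin), samples = as.integer(samples),
      chains = as.integer(chains), seed = as.integer(seed))
}

#' Fitted ZINB-family model
#'
#' Posterior (or, for the hurdle variant, maximum-likelihood) summary of one
#' model fit. When the sampler degenerates — a JAGS error such as the slice
#' sampler getting stuck, non-finite summaries, or split-R-hat above 1.2 on
#' every parameter — the fit is flagged `failed` and all numeric summaries
#' are `NA`; a failed fit is data, not an exception.
#'
#' @slot variant the fitted variant name.
#' @slot summary `data.frame` with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `ess`, `rhat`.
#' @slot draws matrix of retained posterior draws (columns = parameters;
#'   empty for MLE fits and failed fits).
#' @slot failed logical failure flag.
#' @slot converged logical; `TRUE` when no convergence warning applies.
#' @slot message diagnostic message for failed or non-converged fits.
#' @slot spec the [ZinbModelSpec-class] used.
#' @export
setClass("ZinbFit",
  representation(variant = "character", summary = "data.frame",
                 draws = "matrix", failed = "logical", converged = "logical",
                 message = "character", spec = "ZinbModelSpec"))

setValidity("ZinbFit", function(object) {
  need <- c("parameter", "mean", "sd", "q2.5", "q97.5", "ess", "rhat")
  if (!all(need %in% names(object@summary)))
    return("summary must have columns parameter, mean, sd, q2.5, q97.5, ess, rhat")
  ok <- is.na(object@summary$q2.5) | is.na(object@summary$q97.5) |
    object@summary$q2.5 <= object@summary$q97.5
  if (!all(ok)) return("q2.5 must not exceed q97.5")
  if (object@failed && any(!is.na(object@summary$mean)))
    return("failed fits must have missing-coded summaries")
  TRUE
})

#' @describeIn ZinbFit-class posterior summary table accessor.
#' @param object,x a `ZinbFit`.
#' @export
setGeneric("posteriorSummary", function(object) standardGeneric("posteriorSummary"))

#' @rdname ZinbFit-class
#' @export
setMethod("posteriorSummary", "ZinbFit", function(object) object@summary)

#' @describeIn ZinbFit-class `TRUE` when the fit degenerated.
#' @export
setGeneric("isFailed", function(object) standardGeneric("isFailed"))

#' @rdname ZinbFit-class
#' @export
setMethod("isFailed", "ZinbFit", function(object) object@failed)

#' @describeIn ZinbFit-class posterior draws matrix accessor.
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname ZinbFit-class
#' @export
setMethod("posteriorDraws", "ZinbFit", function(object) object@draws)

#' @describeIn ZinbFit-class named vector of posterior-mean regression
#'   coefficients (parameters named `beta[...]`), on the log-mean scale.
#' @param ... ignored.
#' @export
setMethod("coef", "ZinbFit", function(object, ...) {
  s <- object@summary
  b <- grepl("^beta", s$parameter)
  stats::setNames(s$mean[b], s$parameter[b])
})

setMethod("show", "ZinbFit", function(object) {
  cat("ZinbFit:", object@variant,
      if (object@failed) "[FAILED]" else if (!object@converged) "[not converged]"
      else "", "\n")
  if (nzchar(object@message)) cat("  ", object@message, "\n", sep = "")
  print(format(object@summary, digits = 3), row.names = FALSE)
  invisible(object)
})

setMethod("show", "ZinbModelSpec", function(object) {
  cat("ZinbModelSpec:", object@variant, "\n")
  cat("  priors: theta,tau ~ Gamma(", object@priorA, ",", object@priorB,
      "); beta ~ Normal(0, precision ", object@betaPrecision, ")\n", sep = "")
  cat("  schedule: adapt=", object@adapt, " burnin=", object@burnin,
      " samples=", object@samples, " chains=", object@chains,
      " seed=", object@seed, "\n", sep = "")
  invisible(object)
})

#' Joint log prior density of a ZINB parameter bundle
#'
#' Sum of the log prior densities actually in the model: Gamma(`priorA`,
#' `priorB`) on `theta` and (tau-link only) on `tau`; Normal with mean 0 and
#' precision `betaPrecision` on each regression coefficient, on each
#' zero-model coefficient `gamma`, and on the free zero-inflation intercept
#' `theta0`. Terms for parameters absent from the bundle are omitted. A
#' non-positive value under a gamma prior yields `-Inf`, not an error.
#'
#' @param params named list with any of `beta`, `theta`, `tau`, `gamma`,
#'   `theta0`.
#' @param spec a [ZinbModelSpec-class].
#' @return scalar log prior density.
#' @export
logPrior <- function(params, spec = zinbModelSpec()) {
  stopifnot(is.list(params))
  lp <- 0
  sdBeta <- 1 / sqrt(spec@betaPrecision)
  for (nm in c("beta", "gamma", "theta0"))
    if (!is.null(params[[nm]]))
      lp <- lp + sum(stats::dnorm(params[[nm]], 0, sdBeta, log = TRUE))
  for (nm in c("theta", "tau"))
    if (!is.null(params[[nm]])) {
      x <- params[[nm]]
      lp <- lp + if (x <= 0) -Inf else
        stats::dgamma(x, shape = spec@priorA, rate = spec@priorB, log = TRUE)
    }
  lp
}
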