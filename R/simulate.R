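# Simulation engine for the accuracy benchmark: covariate tables mimicking a
# school-age children cohort, ZINB count responses under three zero-inflation
# mechanisms, and the scenario grids.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic cohort covariate table
#'
#' Emulates the covariate structure of a multi-ethnic children cohort: age
#' uniform on 3.0–15.0 years; sex and ethnicity (Uyghur `U` / Kazakh `K`)
#' balanced; geography uniform over four locations `S`, `W`, `H`, `N`; a
#' BMI-for-age z-score (`bmiaz`) standard normal. Height and weight grow
#' linearly with age plus noise (and are clipped to 0.90–1.50 m and
#' 17.0–27.0 kg), so the raw anthropometry is strongly collinear with age —
#' the situation the z-score screening workflow is designed to resolve.
#'
#' @param n number of samples.
#' @param seed integer seed; identical `(n, seed)` give identical tables.
#' @return a `data.frame` with columns `sample_id`, `age_years`, `sex`,
#'   `ethnic`, `geography`, `height_m`, `weight_kg`, `bmiaz`.
#' @examples
#' head(generateCovariates(10, seed = 1))
#' @export
generateCovariates <- function(n, seed = 1) {
  if (length(n) != 1L || n <= 0) stop("'n' must be a positive integer")
  .withSeed(seed, {
    age <- stats::runif(n, 3.0, 15.0)
    height <- pmin(1.50, pmax(0.90,
      0.90 + 0.05 * (age - 3) + stats::rnorm(n, 0, 0.02)))
    weight <- pmin(27.0, pmax(17.0,
      17.0 + (10 / 12) * (age - 3) + stats::rnorm(n, 0, 0.5)))
    data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      age_years = age,
      sex = sample(c("F", "M"), n, replace = TRUE),
      ethnic = sample(c("U", "K"), n, replace = TRUE),
      geography = sample(c("S", "W", "H", "N"), n, replace = TRUE),
      height_m = height,
      weight_kg = weight,
      bmiaz = stats::rnorm(n),
      stringsAsFactors = FALSE)
  })
}

#' Design matrix used by the simulation scenarios
#'
#' Intercept; age standardized to mean 0 and unit variance of its uniform
#' range (so effect magnitudes are comparable across covariates); ethnicity
#' indicator (`K` vs reference `U`); geography dummies (`W`, `H`, `N` vs
#' reference `S`); and the BMI-for-age z-score.
#'
#' @param cov a covariate table from [generateCovariates()].
#' @return a numeric design matrix with named columns.
#' @export
simulationDesign <- function(cov) {
  B <- cbind(
    intercept = 1,
    ageZ = (cov$age_years - 9) / (12 / sqrt(12)),
    ethnicK = as.numeric(cov$ethnic == "K"),
    geoW = as.numeric(cov$geography == "W"),
    geoH = as.numeric(cov$geography == "H"),
    geoN = as.numeric(cov$geography == "N"),
    bmiaz = cov$bmiaz)
  rownames(B) <- cov$sample_id
  B
}

#' True coefficient vector for one effect level
#'
#' Non-intercept coefficients are set to plus/minus `effect` with an
#' alternating sign pattern; the intercept is chosen so the median of the
#' count mean `mu` over the given design is `muMedian` (default 10).
#'
#' @param B design matrix from [simulationDesign()].
#' @param effect coefficient magnitude (the benchmark's effect level).
#' @param muMedian target median of `exp(B beta)`.
#' @return named coefficient vector, intercept first.
#' @export
simulationCoefficients <- function(B, effect, muMedian = 10) {
  p <- ncol(B) - 1L
  betaRest <- effect * rep_len(c(1, -1), p)
  eta <- drop(B[, -1, drop = FALSE] %*% betaRest)
  beta <- c(log(muMedian) - stats::median(eta), betaRest)
  names(beta) <- colnames(B)
  beta
}

.solveTau <- function(mu, target) {
  f <- function(tau) mean(stats::plogis(-tau * log(mu))) - target
  lo <- -50; hi <- 50
  if (f(lo) * f(hi) > 0)
    stop("target zero-inflation ", target,
         " is unattainable under the tau mechanism for this mean structure")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

.solveGamma0 <- function(x, slope, target) {
  f <- function(g0) mean(stats::plogis(-(g0 + slope * x))) - target
  stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
}

#' Simulate ZINB counts for a covariate table
#'
#' Draws counts with mean `mu_i = exp(B_i beta)` (`B` from
#' [simulationDesign()]): Poisson when `invTheta = 0`, otherwise negative
#' binomial with size `1/invTheta`. Structural zeros are injected at marginal
#' probability `phi` by one of three mechanisms: `"tau"` solves the shape
#' parameter so the average of `1/(1 + mu_i^tau)` hits `phi` (zero
#' probability then varies with abundance); `"covariate"` solves the
#' intercept of `logit(phi_i) = -(g0 + 0.5 bmiaz_i)`; `"intercept"` uses a
#' constant `phi`. The realized per-observation zero probabilities, the
#' count mean and any solved link parameter are attached as attributes.
#'
#' @param cov covariate table from [generateCovariates()].
#' @param beta coefficient vector matching [simulationDesign()] columns.
#' @param scenario list (or [scenarioGrid()] row) with fields `phi` and
#'   `invTheta`.
#' @param zeroMech `"tau"`, `"covariate"` or `"intercept"`.
#' @param seed optional integer seed.
#' @return integer count vector of length `nrow(cov)` with attributes `mu`,
#'   `phi` and (tau mechanism) `tau`.
#' @export
simulateCounts <- function(cov, beta, scenario, zeroMech = c("tau", "covariate", "intercept"),
                           seed = NULL) {
  zeroMech <- match.arg(zeroMech)
  B <- simulationDesign(cov)
  if (length(beta) != ncol(B))
    stop("'beta' must have ", ncol(B), " entries to match the design")
  phi <- scenario$phi
  invTheta <- scenario$invTheta
  stopifnot(phi >= 0, phi < 1, invTheta >= 0)
  mu <- exp(drop(B %*% beta))
  .withSeed(seed, {
    y <- if (invTheta == 0) stats::rpois(length(mu), mu)
         else stats::rnbinom(length(mu), size = 1 / invTheta, mu = mu)
    tau <- NULL
    if (phi > 0) {
      phiVec <- switch(zeroMech,
        tau = {
          tau <- .solveTau(mu, phi)
          phiFromTau(mu, tau)
        },
        covariate = stats::plogis(-(.solveGamma0(cov$bmiaz, 0.5, phi) +
                                      0.5 * cov$bmiaz)),
        intercept = rep(phi, length(mu)))
      y <- y * (1L - stats::rbinom(length(mu), 1L, phiVec))
    } else phiVec <- rep(0, length(mu))
    structure(as.integer(y), mu = mu, phi = phiVec, tau = tau)
  })
}

#' One simulation scenario cell
#'
#' @param n sample size; one of 100, 200, 500, 1000, 2000.
#' @param effect coefficient magnitude level.
#' @param phi marginal zero-inflation probability in `[0, 1)`.
#' @param invTheta overdispersion `1/theta`, non-negative.
#' @param replicate replicate index.
#' @param seed integer seed for the cell.
#' @return a validated list with the same fields.
#' @export
scenarioConfig <- function(n, effect, phi, invTheta, replicate = 1L, seed = 1L) {
  if (!n %in% c(100, 200, 500, 1000, 2000))
    stop("'n' must be one of 100, 200, 500, 1000, 2000")
  stopifnot(phi >= 0, phi < 1, invTheta >= 0, replicate >= 1)
  list(n = as.integer(n), effect = effect, phi = phi, invTheta = invTheta,
       replicate = as.integer(replicate), seed = as.integer(seed))
}

#' Benchmark scenario grids
#'
#' The base grid crosses sample size \{100, 200, 500, 1000\}, effect level
#' \{0.5, 1, 1.5\} (low, moderate, high), zero inflation \{0, 0.2, 0.5\} and
#' overdispersion `1/theta` \{0, 1, 2\} — 108 cells. The extended
#' overdispersion-tolerance grid adds sample size 2000 and crosses
#' \{100, 200, 500, 1000, 2000\} with `1/theta` \{2, 5, 10\} at effect 1 and
#' zero inflation 0.5 — 15 cells.
#'
#' @param extended logical; return the tolerance grid?
#' @return a `data.frame` with columns `n`, `effect`, `phi`, `invTheta`.
#' @examples
#' nrow(scenarioGrid())          # 108
#' nrow(scenarioGrid(TRUE))      # 15
#' @export
scenarioGrid <- function(extended = FALSE) {
  g <- if (extended)
    expand.grid(n = c(100, 200, 500, 1000, 2000), effect = 1, phi = 0.5,
                invTheta = c(2, 5, 10), KEEP.OUT.ATTRS = FALSE)
  else
    expand.grid(n = c(100, 200, 500, 1000), effect = c(0.5, 1, 1.5),
                phi = c(0, 0.2, 0.5), invTheta = c(0, 1, 2),
                KEEP.OUT.ATTRS = FALSE)
  g$n <- as.integer(g$n)
  g
}
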