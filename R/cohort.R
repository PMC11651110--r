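# Built-in synthetic cohorts with known truth, used by the test-suite and by
# worked examples. They emulate the moment structure of real ASV tables
# (log-normal baselines, negative binomial counts, a zero-inflated subset)
# but not compositionality, taxon-taxon correlation, or library-size
# variation.

.lineageFor <- function(i) {
  sprintf("d:Bacteria,p:Phylum%d,c:Class%d,o:Order%d,f:Family%d,g:Genus%d",
          (i - 1) %/% 20 + 1, (i - 1) %/% 14 + 1, (i - 1) %/% 8 + 1,
          (i - 1) %/% 4 + 1, (i - 1) %/% 2 + 1)
}

#' Synthetic cohort for count-complexity characterization
#'
#' `nNb` taxa follow plain negative binomial counts and `nZinb` taxa are
#' zero inflated with extra-zero probability `phi`; baselines and dispersions
#' vary across taxa. ASVs are nested two-per-genus, four-per-family and so
#' on up to phylum, interleaving zero-inflated and plain taxa, so pooling to
#' a coarser rank dilutes the structural zeros — the zero-inflated fraction
#' is non-increasing in rank by construction.
#'
#' @param nSamples samples per taxon.
#' @param nNb number of plain negative binomial taxa.
#' @param nZinb number of zero-inflated taxa.
#' @param phi extra-zero probability of the zero-inflated taxa.
#' @param seed integer seed.
#' @return list with `counts` (taxa-by-samples matrix), `taxonomy`
#'   (`taxon`, `lineage`) and `truth` (`taxon`, `zeroInflated`).
#' @export
makeCharacterizationCohort <- function(nSamples = 1000, nNb = 30, nZinb = 10,
                                       phi = 0.9, seed = 1) {
  nTaxa <- nNb + nZinb
  .withSeed(seed, {
    zi <- rep(c(rep(FALSE, max(1, nNb %/% nZinb)), TRUE),
              length.out = nTaxa)
    zi[sample(which(!zi), max(0, sum(zi) - nZinb))] <- FALSE
    while (sum(zi) < nZinb) zi[sample(which(!zi), 1)] <- TRUE
    counts <- t(vapply(seq_len(nTaxa), function(t) {
      mu <- exp(stats::runif(1, log(5), log(80)))
      theta <- stats::runif(1, 0.5, 2)
      rzinb(nSamples, mu = mu, theta = theta, phi = if (zi[t]) phi else 0)
    }, numeric(nSamples)))
    rownames(counts) <- sprintf("ASV%02d", seq_len(nTaxa))
    colnames(counts) <- sprintf("S%04d", seq_len(nSamples))
    list(counts = counts,
         taxonomy = data.frame(taxon = rownames(counts),
                               lineage = .lineageFor(seq_len(nTaxa)),
                               stringsAsFactors = FALSE),
         truth = data.frame(taxon = rownames(counts), zeroInflated = zi,
                            stringsAsFactors = FALSE))
  })
}

#' Synthetic cohort for the differential-abundance pipeline
#'
#' Covariates come from [generateCovariates()]; counts are zero-inflated
#' negative binomial per taxon with per-taxon log-normal baselines. Taxa in
#' `ageEffectTaxa` get a true age coefficient `ageEffect` (per centered year
#' of age) and taxa in `bmiazEffectTaxa` a true `bmiazEffect` per z-score
#' unit; every other coefficient is zero, so pipeline flags can be scored
#' against built-in truth.
#'
#' @param nSamples number of samples.
#' @param nTaxa number of taxa.
#' @param ageEffectTaxa indices of taxa with a true age effect.
#' @param ageEffect true age coefficient.
#' @param bmiazEffectTaxa indices of taxa with a true BMI-z effect.
#' @param bmiazEffect true BMI-z coefficient.
#' @param phi constant extra-zero probability of every taxon.
#' @param invTheta overdispersion `1/theta` of every taxon.
#' @param baselineLogMean mean of the per-taxon log baseline.
#' @param seed integer seed.
#' @return list with `counts`, `metadata`, `taxonomy` and `truth`
#'   (`taxon`, `ageEffect`, `bmiazEffect`).
#' @export
makeDaCohort <- function(nSamples = 150, nTaxa = 40, ageEffectTaxa = 1:5,
                         ageEffect = 0.8, bmiazEffectTaxa = integer(0),
                         bmiazEffect = 0.5, phi = 0.15, invTheta = 1,
                         baselineLogMean = log(8), seed = 1) {
  if (length(ageEffectTaxa) && max(ageEffectTaxa) > nTaxa)
    stop("'ageEffectTaxa' indices exceed nTaxa")
  if (length(bmiazEffectTaxa) && max(bmiazEffectTaxa) > nTaxa)
    stop("'bmiazEffectTaxa' indices exceed nTaxa")
  metadata <- generateCovariates(nSamples, seed = seed)
  .withSeed(seed + 1L, {
    ageC <- metadata$age_years - mean(metadata$age_years)
    aEff <- bEff <- rep(0, nTaxa)
    aEff[ageEffectTaxa] <- ageEffect
    bEff[bmiazEffectTaxa] <- bmiazEffect
    counts <- t(vapply(seq_len(nTaxa), function(t) {
      b0 <- stats::rnorm(1, baselineLogMean, 0.4)
      mu <- exp(b0 + aEff[t] * ageC + bEff[t] * metadata$bmiaz)
      rzinb(nSamples, mu = mu, theta = 1 / max(invTheta, 1e-8), phi = phi)
    }, numeric(nSamples)))
    rownames(counts) <- sprintf("ASV%03d", seq_len(nTaxa))
    colnames(counts) <- metadata$sample_id
    list(counts = counts, metadata = metadata,
         taxonomy = data.frame(taxon = rownames(counts),
                               lineage = .lineageFor(seq_len(nTaxa)),
                               stringsAsFactors = FALSE),
         truth = data.frame(taxon = rownames(counts), ageEffect = aEff,
                            bmiazEffect = bEff, stringsAsFactors = FALSE))
  })
}
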