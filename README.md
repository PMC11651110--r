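# zinbiome

Bayesian zero-inflated negative binomial (ZINB) regression for microbiome
count data, for researchers who need per-taxon effect sizes — not just group
tests — from ASV/OTU tables with the two pathologies such tables always
have: overdispersion and an excess of zeros.

## The model

For a taxon's counts *y*, a point mass at zero with weight φ (biological
absence plus technical dropout) mixes with a negative binomial of mean μ
and size θ (overdispersion 1/θ):

    P(y = 0) = φ + (1 − φ) (θ / (θ + μ))^θ
    P(y = k) = (1 − φ) NB(k; μ, θ),   k > 0

Covariates enter through log(μ) = Bβ, and the extra-zero probability
through one of three links: the **τ link** logit(φ) = −τ·Bβ (so
φ = 1/(1 + μ^τ): abundant taxa get fewer structural zeros), a **covariate
link** logit(φ) = −(Gγ), or a **free intercept**. Priors are
Gamma(0.001, 0.001) on θ and τ and essentially-flat normals
(precision 10⁻⁶) on coefficients; posteriors are sampled with JAGS
(rjags), and every fit is bit-reproducible from its integer seed. Nine
variants are available (`P`, `NB`, `ZIP_tau`, `MZIP`, `ZIP_inter`,
`ZINB_tau`, `MZINB`, `ZINB_inter`, and a maximum-likelihood `HURDLE`
comparator), plus:

* a simulation benchmark scoring variants by absolute relative bias (ARB)
  across sample size, effect level, zero inflation and overdispersion,
  with sampler failures recorded as data;
* moment-based per-taxon estimation of φ and 1/θ, rank aggregation, and
  the standard preprocessing (rarefaction to fixed depth, strict total-count
  filters);
* LMS growth-reference z-scores and GVIF collinearity screening of
  candidate designs (acceptable below 3 on the GVIF^(1/2df) scale);
* an end-to-end differential-abundance pipeline with ethnic-by-geography
  interaction reporting, using 95% credible intervals (no p-values, no
  multiplicity correction) and a 0.35 effect-size highlight rule.

See `vignette("zinb-count-models")` for the full methods account.

## Worked example

Simulate a 200-sample cohort at effect level 1 with 30% marginal zero
inflation and overdispersion 1/θ = 1, then fit the τ-link ZINB:

```r
library(zinbiome)
cov  <- generateCovariates(200, seed = 1)
B    <- simulationDesign(cov)
beta <- simulationCoefficients(B, effect = 1)   # truth: ±1, median mu = 10
y    <- simulateCounts(cov, beta, list(phi = 0.3, invTheta = 1),
                       zeroMech = "tau", seed = 2)
spec <- zinbModelSpec("ZINB_tau", adapt = 1000, burnin = 1000,
                      samples = 2000, chains = 2, seed = 7)
samplePosterior(spec, B, y)
```

```
ZinbFit: ZINB_tau
       parameter   mean     sd   q2.5  q97.5  ess rhat
 beta[intercept]  2.468 0.2551  1.996  2.999  205 1.01
      beta[ageZ]  1.105 0.1146  0.875  1.332 1271 1.00
   beta[ethnicK] -0.786 0.2061 -1.199 -0.393  629 1.01
      beta[geoW]  0.915 0.2947  0.337  1.481  423 1.00
      beta[geoH] -1.126 0.2940 -1.709 -0.563  469 1.00
      beta[geoN]  1.091 0.2845  0.522  1.649  497 1.00
     beta[bmiaz] -0.936 0.0919 -1.125 -0.761 1573 1.00
           theta  1.017 0.1934  0.674  1.428  890 1.00
             tau  0.266 0.0728  0.130  0.421 1173 1.00
```

The true coefficients were (2.59, 1, −1, 1, −1, 1, −1) with θ = 1: every
95% credible interval covers its truth, the NB size is recovered
(1.02 ± 0.19), and split-R̂ ≈ 1 with healthy effective sample sizes. The
positive τ says zero inflation decays with abundance, as simulated.

The same objects drive the rest of the toolkit, e.g.
`runBenchmark(scenarioGrid(), ...)` for the accuracy study,
`estimateZinbMoments(y)` for per-taxon φ and 1/θ, and
`runDaPipeline(counts, metadata, taxonomy)` for the cohort workflow. A
command-line wrapper ships at `inst/scripts/zinbiome` with subcommands
`simulate`, `benchmark`, `characterize`, `gvif`, `zscore`, `fit`, `da`.

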