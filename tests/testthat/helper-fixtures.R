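# Shared fixtures. All data are generated in code under fixed seeds; MCMC
# schedules are kept short — the posteriors here are unimodal and the checks
# are on flags, coverage and ordering, not on third-digit accuracy.

quickSpec <- function(variant = "ZINB_tau", seed = 1, chains = 1,
                      adapt = 400, burnin = 400, samples = 800) {
  zinbModelSpec(variant, adapt = adapt, burnin = burnin, samples = samples,
                chains = chains, seed = seed)
}

# a seeded tau-link regression fixture: design, truth, counts
tauFixture <- function(n = 100, effect = 1, phi = 0.3, invTheta = 1,
                       seed = 1) {
  cov <- generateCovariates(n, seed = seed)
  B <- simulationDesign(cov)
  beta <- simulationCoefficients(B, effect)
  y <- simulateCounts(cov, beta, list(phi = phi, invTheta = invTheta),
                      zeroMech = "tau", seed = seed + 1000L)
  list(cov = cov, B = B, beta = beta, y = y)
}

# tiny deterministic count table used by the preprocessing tests
toyCounts <- function() {
  m <- matrix(c(1, 0, 0,
                9, 10, 10,
                10, 10, 10,
                11, 10, 10,
                200, 150, 150), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:3)))
  storage.mode(m) <- "integer"
  m
}
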