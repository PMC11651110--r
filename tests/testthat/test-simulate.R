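test_that("covariate tables satisfy their ranges and are reproducible", {
  cov <- generateCovariates(100, seed = 1)
  expect_equal(nrow(cov), 100)
  expect_true(all(cov$age_years >= 3 & cov$age_years <= 15))
  expect_true(all(cov$height_m >= 0.90 & cov$height_m <= 1.50))
  expect_true(all(cov$weight_kg >= 17 & cov$weight_kg <= 27))
  expect_true(all(cov$ethnic %in% c("U", "K")))
  expect_lte(length(unique(cov$geography)), 4)
  expect_identical(cov, generateCovariates(100, seed = 1))
  expect_false(identical(cov, generateCovariates(100, seed = 2)))
  expect_error(generateCovariates(0), "positive")
})

test_that("bmiaz is standard normal at Monte-Carlo precision", {
  cov <- generateCovariates(1e5, seed = 2)
  expect_lt(abs(mean(cov$bmiaz)), 0.01)
  expect_lt(abs(sd(cov$bmiaz) - 1), 0.01)
})

test_that("scenario grids have the stated shape", {
  base <- scenarioGrid()
  expect_equal(nrow(base), 108)   # 4 x 3 x 3 x 3
  expect_setequal(unique(base$n), c(100, 200, 500, 1000))
  expect_setequal(unique(base$effect), c(0.5, 1, 1.5))
  expect_setequal(unique(base$phi), c(0, 0.2, 0.5))
  expect_setequal(unique(base$invTheta), c(0, 1, 2))
  ext <- scenarioGrid(extended = TRUE)
  expect_equal(nrow(ext), 15)     # 5 sample sizes x 3 dispersion levels
  expect_setequal(unique(ext$n), c(100, 200, 500, 1000, 2000))
  expect_setequal(unique(ext$invTheta), c(2, 5, 10))
  for (g in list(base, ext)) {
    expect_true(all(g$phi >= 0 & g$phi < 1))
    expect_true(all(g$invTheta >= 0))
  }
  expect_error(scenarioConfig(300, 1, 0.2, 1), "must be one of")
})

test_that("simulated counts obey the configured moments", {
  cov <- generateCovariates(1e5, seed = 3)
  B <- simulationDesign(cov)
  # mean-only model: beta = (log 5, 0, ..., 0), NB dispersion 1
  beta <- c(log(5), rep(0, ncol(B) - 1))
  y <- simulateCounts(cov, beta, list(phi = 0, invTheta = 1), seed = 4)
  se <- sqrt(5 * (1 + 5) / length(y))
  expect_lt(abs(mean(y) - 5), 3 * se)
  # Poisson limit: variance equals mean; the sampling sd of s^2/lambda for
  # Poisson(lambda) uses mu4 = lambda + 3 lambda^2, i.e. sqrt((2 + 1/lambda)/n)
  yp <- simulateCounts(cov, beta, list(phi = 0, invTheta = 0), seed = 5)
  expect_lt(abs(var(yp) / mean(yp) - 1),
            4 * sqrt((2 + 1 / 5) / length(yp)))
  # extra zeros only add zeros
  yz <- simulateCounts(cov, beta, list(phi = 0.5, invTheta = 1),
                       zeroMech = "intercept", seed = 6)
  expect_gte(mean(yz == 0), 0.5 - 3 * sqrt(0.25 / length(yz)))
})

test_that("each zero mechanism hits the target marginal inflation", {
  cov <- generateCovariates(2e4, seed = 7)
  B <- simulationDesign(cov)
  beta <- simulationCoefficients(B, 1)
  mu <- exp(drop(B %*% beta))
  for (mech in c("tau", "covariate", "intercept")) {
    y <- simulateCounts(cov, beta, list(phi = 0.2, invTheta = 1),
                        zeroMech = mech, seed = 8)
    expect_equal(mean(attr(y, "phi")), 0.2, tolerance = 1e-6)
    # realized count mean matches (1 - phi_i) mu_i
    expect_equal(mean(y), mean((1 - attr(y, "phi")) * mu), tolerance = 0.05)
  }
  # tau mechanism: per-observation inflation follows the link exactly
  y <- simulateCounts(cov, beta, list(phi = 0.2, invTheta = 1),
                      zeroMech = "tau", seed = 9)
  expect_equal(attr(y, "phi"), phiFromTau(mu, attr(y, "tau")),
               tolerance = 1e-12)
})

test_that("the effect-level coefficients center the mean at the target median", {
  cov <- generateCovariates(5000, seed = 10)
  B <- simulationDesign(cov)
  for (effect in c(0.5, 1, 1.5)) {
    beta <- simulationCoefficients(B, effect)
    expect_true(all(abs(beta[-1]) == effect))
    # with an even n the sample median averages two order statistics, so the
    # exp/median exchange is only approximate
    expect_equal(median(exp(drop(B %*% beta))), 10, tolerance = 1e-4)
  }
})
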