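# Short MCMC schedules: these checks concern reproducibility, structural
# error handling and gross posterior behaviour, not third-digit accuracy.

test_that("identical spec and seed reproduce the fit exactly", {
  fx <- tauFixture(n = 100, seed = 21)
  spec <- quickSpec(seed = 77, adapt = 300, burnin = 300, samples = 400)
  f1 <- samplePosterior(spec, fx$B, fx$y)
  f2 <- samplePosterior(spec, fx$B, fx$y)
  expect_false(isFailed(f1))
  expect_identical(posteriorSummary(f1), posteriorSummary(f2))
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
})

test_that("structural problems error before sampling", {
  fx <- tauFixture(n = 50, seed = 22)
  expect_error(samplePosterior(quickSpec(), fx$B, rep(0L, 50)), "all zeros")
  expect_error(samplePosterior(quickSpec(), fx$B, fx$y[-1]), "nrow")
  expect_error(samplePosterior(quickSpec(), fx$B[1:5, ], fx$y[1:5]),
               "p \\+ 2")
  expect_error(fitVariant("NOT_A_MODEL", fx$B, fx$y), "valid names")
})

test_that("posterior summaries expose interval, ess and split-R-hat columns", {
  fx <- tauFixture(n = 100, seed = 23)
  fit <- samplePosterior(quickSpec(seed = 5), fx$B, fx$y)
  s <- posteriorSummary(fit)
  expect_setequal(
    s$parameter,
    c(paste0("beta[", colnames(fx$B), "]"), "theta", "tau"))
  expect_true(all(s$q2.5 <= s$q97.5))
  expect_true(all(is.finite(s$ess)))
  expect_true(all(is.finite(s$rhat)))
  expect_s4_class(fit, "ZinbFit")
  expect_named(coef(fit), paste0("beta[", colnames(fx$B), "]"))
})

test_that("free zero-inflation intercept collapses when there is no inflation", {
  # phi_true = 0: the ZINB_inter zero intercept must sit at a clearly
  # negative logit (phi near zero)
  fx <- tauFixture(n = 200, phi = 0, invTheta = 0.5, seed = 24)
  fit <- fitVariant("ZINB_inter", fx$B, fx$y,
                    spec = quickSpec(seed = 9))
  expect_false(isFailed(fit))
  s <- posteriorSummary(fit)
  theta0 <- s$mean[s$parameter == "theta0"]
  expect_lt(theta0, -1)   # plogis(-1) < 0.27, posterior mass at small phi
})

test_that("ignoring heavy zero inflation biases the NB intercept downward", {
  fx <- tauFixture(n = 300, phi = 0.5, invTheta = 1, seed = 25)
  nb <- fitVariant("NB", fx$B, fx$y, spec = quickSpec(seed = 3))
  zinb <- fitVariant("ZINB_tau", fx$B, fx$y, spec = quickSpec(seed = 4))
  expect_false(isFailed(nb)); expect_false(isFailed(zinb))
  b0nb <- coef(nb)[["beta[intercept]"]]
  b0z <- coef(zinb)[["beta[intercept]"]]
  expect_lt(b0nb, b0z)
})

test_that("covariate-link and Poisson variants run and name their parameters", {
  fx <- tauFixture(n = 100, phi = 0.2, invTheta = 0, seed = 26)
  m <- fitVariant("MZIP", fx$B, fx$y, spec = quickSpec(seed = 6),
                  G = fx$B[, 1:2])
  expect_false(isFailed(m))
  expect_true(all(paste0("gamma[", colnames(fx$B)[1:2], "]") %in%
                    posteriorSummary(m)$parameter))
  p <- fitVariant("P", fx$B, fx$y, spec = quickSpec(seed = 7, samples = 400))
  expect_false(isFailed(p))
  expect_false("theta" %in% posteriorSummary(p)$parameter)
})
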