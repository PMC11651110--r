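lmsRef <- readLmsReference(
  system.file("extdata", "lms_reference_synthetic.csv", package = "zinbiome"))

test_that("LMS z-score closed forms and monotonicity", {
  expect_equal(lmsZscore(16, L = -1.5, M = 16, S = 0.09), 0)
  # L = 1 reduces to the plain coefficient-of-variation score
  expect_equal(lmsZscore(18, L = 1, M = 16, S = 0.1), (18 / 16 - 1) / 0.1)
  # L = 0 log branch: x = M e^S maps to exactly 1
  expect_equal(lmsZscore(16 * exp(0.09), L = 0, M = 16, S = 0.09), 1)
  xs <- seq(10, 30, by = 0.5)
  expect_true(all(diff(lmsZscore(xs, -1.6, 15.8, 0.09)) > 0))
  expect_true(all(diff(lmsZscore(xs, 0, 15.8, 0.09)) > 0))
  expect_error(lmsZscore(-1, 1, 16, 0.1), "positive")
})

test_that("reference lookup interpolates between bracketing ages", {
  tab <- lmsRef[lmsRef$measure == "bmi" & lmsRef$sex == "F", ]
  mid <- (tab$age_months[1] + tab$age_months[2]) / 2
  zMid <- growthZscore(16, mid, "F", lmsRef, "bmi")
  Lm <- mean(tab$L[1:2]); Mm <- mean(tab$M[1:2]); Sm <- mean(tab$S[1:2])
  expect_equal(zMid, lmsZscore(16, Lm, Mm, Sm))
  # the reference median maps to zero at a tabulated age
  expect_equal(growthZscore(tab$M[3], tab$age_months[3], "F", lmsRef, "bmi"),
               0, tolerance = 1e-12)
})

test_that("z-BMI bands use the stated boundary closures", {
  expect_equal(as.character(classifyZbmi(c(-2.5, -2, 0, 2, 2.1, 4, 4.1, 5))),
               c("underweight", "normal", "normal", "normal", "overweight",
                 "overweight", "obese", "obese"))
  # WHO school-age convention via the configurable cutoff
  expect_equal(as.character(classifyZbmi(3.5, cutObese = 3)), "obese")
  expect_error(classifyZbmi(NaN), "finite")
  expect_error(classifyZbmi(0, cutOverweight = 4, cutObese = 2))
})

test_that("design matrix has treatment coding against the stated references", {
  cov <- generateCovariates(500, seed = 51)
  dm <- buildDesignMatrix(cov)
  # intercept + age + bmiaz + 1 ethnic + 3 geography + 3 interaction
  expect_equal(ncol(dm$design), 10)
  expect_equal(sum(dm$groups == "ethnic:geography"), 3)
  # a reference observation has zeros in every non-intercept factor column
  ref <- cov[cov$ethnic == "U" & cov$geography == "H", ][1, ]
  i <- which(cov$sample_id == ref$sample_id)
  factorCols <- names(dm$groups)[dm$groups %in%
                                   c("ethnic", "geography", "ethnic:geography")]
  expect_true(all(dm$design[i, factorCols] == 0))
  expect_equal(dm$design[i, "age_c"], ref$age_years - mean(cov$age_years))
  expect_error(buildDesignMatrix(cov, referenceGeography = "X"), "absent")
  # idempotent and column-order stable
  dm2 <- buildDesignMatrix(cov)
  expect_identical(dm$design, dm2$design)
})

test_that("GVIF matches the brute-force regression oracle for 1-df terms", {
  set.seed(52)
  n <- 300
  x1 <- rnorm(n); x2 <- 0.8 * x1 + 0.6 * rnorm(n); x3 <- rnorm(n)
  X <- cbind(intercept = 1, x1 = x1, x2 = x2, x3 = x3)
  groups <- c(x1 = "x1", x2 = "x2", x3 = "x3")
  rep <- gvif(X, groups)
  for (v in c("x1", "x2", "x3")) {
    r2 <- summary(lm(X[, v] ~ X[, setdiff(c("x1", "x2", "x3"), v)]))$r.squared
    expect_equal(rep$gvif[rep$term == v], 1 / (1 - r2), tolerance = 1e-8)
  }
  # columns orthogonal after centering have GVIF exactly 1
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 3), n), scale = FALSE)))
  colnames(Q) <- paste0("q", 1:3)
  repQ <- gvif(Q, setNames(colnames(Q), colnames(Q)))
  expect_equal(repQ$gvif, rep(1, 3), tolerance = 1e-10)
})

test_that("GVIF agrees with the car implementation on a multi-df design", {
  skip_if_not_installed("car")
  cov <- generateCovariates(400, seed = 53)
  d <- data.frame(y = rnorm(400), age = cov$age_years, bmiaz = cov$bmiaz,
                  geo = factor(cov$geography))
  fit <- lm(y ~ age + bmiaz + geo, data = d)
  ours <- gvif(model.matrix(fit),
               setNames(c("age", "bmiaz", rep("geo", 3)),
                        colnames(model.matrix(fit))[-1]))
  theirs <- car::vif(fit)
  expect_equal(ours$gvif[ours$term == "age"], unname(theirs["age", "GVIF"]),
               tolerance = 1e-8)
  expect_equal(ours$gvif[ours$term == "geo"], unname(theirs["geo", "GVIF"]),
               tolerance = 1e-8)
})

test_that("GVIF is invariant to affine rescaling and detects rank deficiency", {
  set.seed(54)
  X <- cbind(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  X[, 2] <- X[, 1] * 0.7 + X[, 2]
  groups <- setNames(colnames(X), colnames(X))
  g1 <- gvif(X, groups)
  X2 <- X; X2[, 1] <- 1000 * X2[, 1] + 7
  expect_equal(g1$gvif, gvif(X2, groups)$gvif, tolerance = 1e-8)
  Xbad <- cbind(X, d = X[, 1] + X[, 2])
  expect_error(gvif(Xbad, setNames(colnames(Xbad), colnames(Xbad))),
               "rank deficient")
})

test_that("z-score replacement de-collinearizes the anthropometric design", {
  md <- generateCovariates(400, seed = 55)
  md$bmi <- md$weight_kg / md$height_m^2
  sc <- screenInteractions(md, list(
    "height*weight" = ~ age_years + height_m * weight_kg,
    "bmi" = ~ age_years + bmi,
    "bmiaz" = ~ age_years + bmiaz))
  # monotone decreasing collinearity along the replacement chain
  expect_true(all(diff(sc$maxGvifScaled) < 0))
  expect_gt(sc$maxGvifScaled[sc$candidate == "height*weight"], 3)
  expect_true(sc$acceptable[sc$candidate == "bmiaz"])
  expect_lt(sc$maxGvifScaled[sc$candidate == "bmiaz"], 3)
  # duplicated predictor is flagged rank deficient, not raised
  dup <- screenInteractions(md, list(dup = ~ age_years + I(age_years * 1)))
  expect_true(dup$rankDeficient)
})
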