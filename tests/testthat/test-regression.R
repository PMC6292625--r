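test_that("OLS fitting reports the standard statistics", {
  d <- data.frame(x = 1:5, y = c(2, 4, 6, 8, 10))
  f <- suppressWarnings(fitMlr(y ~ x, d))  # perfect fit warns in summary()
  expect_equal(f$r2, 1)
  expect_equal(unname(coef(f$lm)), c(0, 2), tolerance = 1e-12)

  set.seed(1)
  d <- data.frame(x1 = rnorm(5), x2 = rnorm(5))
  d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(5, 0, 0.1)
  f <- fitMlr(y ~ x1 + x2, d)
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)   # normal equations oracle
  expect_equal(unname(coef(f$lm)), as.vector(beta), tolerance = 1e-9)

  d$x3 <- d$x1   # exact collinearity
  expect_error(fitMlr(y ~ x1 + x2 + x3, d), "collinear")
})

test_that("pseudo-R2 is the squared correlation with the expected limits", {
  y <- runif(50)
  expect_equal(pseudoR2(y, y), 1)
  expect_equal(pseudoR2(0.2 + 3 * y, y), 1)
  set.seed(2)
  expect_lt(pseudoR2(rnorm(10000), rnorm(10000)), 0.01)
  expect_warning(pseudoR2(rep(1, 10), runif(10)), "constant")
})

test_that("univariate screening keeps strong effects and gates at p < 0.1", {
  set.seed(3)
  n <- 500
  x <- data.frame(strong = rnorm(n), noise = rnorm(n))
  y <- 1 + 2 * x$strong + rnorm(n)
  scr <- univariateScreen(y, x, "MLR")
  expect_true(scr$kept[scr$covariate == "strong"])
  expect_lt(scr$p_value[scr$covariate == "strong"], 1e-10)

  # inflated-beta screening finds a mu-slope effect
  yb <- rbeinf(n, plogis(-0.3 + 0.8 * x$strong), plogis(-0.5), 0.3, 0.05)
  scrb <- univariateScreen(yb, x, "MIBR")
  expect_true(scrb$kept[scrb$covariate == "strong"])

  expect_equal(nrow(univariateScreen(y, x[, 0, drop = FALSE], "MLR")), 0)
})

test_that("pure-noise covariates pass the p < 0.1 gate at the nominal rate", {
  set.seed(4)
  hits <- vapply(1:200, function(i) {
    y <- rnorm(120)
    x <- data.frame(z = rnorm(120))
    univariateScreen(y, x, "MLR")$kept[1]
  }, TRUE)
  # binomial(200, 0.1): 3 SE band around 20
  expect_lt(abs(sum(hits) - 20), 3 * sqrt(200 * 0.1 * 0.9) + 1e-9)
})

test_that("VIF screening drops collinear covariates", {
  set.seed(5)
  n <- 300
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  v <- vifScreen(x)
  expect_setequal(v$retained, c("a", "b"))
  expect_true(all(v$vif < 1.2))

  x$c <- x$a + x$b + rnorm(n, 0, 0.05)
  v <- vifScreen(x)
  expect_equal(length(v$dropped), 1)
  expect_true(all(v$vif < 10))
  # recompute VIF of survivors directly as oracle
  for (nm in v$retained) {
    others <- setdiff(v$retained, nm)
    r2 <- summary(lm(reformulate(others, nm), x))$r.squared
    expect_lt(1 / (1 - r2), 10)
  }

  x$dup <- x$a
  v <- suppressWarnings(vifScreen(x[, c("a", "dup")]))
  expect_equal(length(v$retained), 1)
})

test_that("stepwise selection finds the active covariate and is deterministic", {
  set.seed(6)
  n <- 600
  covs <- as.data.frame(matrix(rnorm(n * 4), n,
                               dimnames = list(NULL, c("act", "n1", "n2", "n3"))))
  hits <- 0
  for (rep in 1:8) {
    y <- rbeinf(n, plogis(-0.4 + 1.2 * covs$act), plogis(-0.8), 0.25, 0.03)
    f <- stepwiseSelect(y, covs, "MIBR")
    if ("act" %in% attr(f, "selected")$mu) hits <- hits + 1
  }
  expect_gte(hits, 7)

  # determinism under fixed data
  y <- rbeinf(n, plogis(-0.4 + 1.2 * covs$act), plogis(-0.8), 0.25, 0.03)
  f1 <- stepwiseSelect(y, covs, "MIBR")
  f2 <- stepwiseSelect(y, covs, "MIBR")
  expect_equal(f1@aic, f2@aic, tolerance = 1e-9)
  expect_identical(f1@trace, f2@trace)
})

test_that("all-noise stepwise never beats the intercept model by force", {
  set.seed(7)
  n <- 400
  covs <- as.data.frame(matrix(rnorm(n * 3), n,
                               dimnames = list(NULL, c("n1", "n2", "n3"))))
  y <- rbeinf(n, 0.4, 0.5, 0.3, 0.05)
  f <- stepwiseSelect(y, covs, "MIBR")
  f0 <- fitBeinf(y, family = "MIBR")
  expect_lte(f@aic, f0@aic + 2)
})

test_that("the simplification rule follows p and AIC gates", {
  set.seed(8)
  n <- 800
  covs <- data.frame(strong = rnorm(n), weak = rnorm(n))
  y <- rbeinf(n, plogis(-0.4 + 1.5 * covs$strong), plogis(-0.8), 0.25, 0.03)
  f <- stepwiseSelect(y, covs, "MIBR")
  out <- simplifyBeinf(f, y, covs)
  # whatever the decision, the returned model must be one of the two fits
  expect_true(out$decision$outcome %in%
    c("no removable coefficient", "kept (p rule not met)",
      "rejected (AIC worsens by > threshold)", "simplified accepted"))
  # a strong last term is kept under the corrected rule
  if (length(f@trace) > 0) {
    last <- f@trace[length(f@trace)]
    if (grepl("strong", last) && out$decision$p < 0.1)
      expect_identical(out$model@trace, f@trace)
  }
  # no removable coefficient: intercept-only model passes through
  f0 <- fitBeinf(y, family = "MIBR")
  out0 <- simplifyBeinf(f0, y, covs)
  expect_identical(out0$model@coefficients, f0@coefficients)
  expect_equal(out0$decision$outcome, "no removable coefficient")
})

test_that("EVHR nesting never lowers in-sample R2 for the linear model", {
  set.seed(9)
  n <- 300
  d <- data.frame(ev = rnorm(n), hr1 = rnorm(n), hr2 = rnorm(n))
  d$y <- 1 + d$ev + 0.3 * d$hr1 + rnorm(n)
  ev <- fitMlr(y ~ ev, d)
  evhr <- fitMlr(y ~ ev + hr1 + hr2, d)
  expect_gte(evhr$r2, ev$r2)
})

test_that("prediction surfaces agree with point predictions", {
  st <- makeTestStack(seed = 31)
  cc <- cellCentres(st)
  covs <- sampleAtPoints(st, cc)
  set.seed(10)
  y <- rbeinf(nrow(cc), plogis(-0.5 + (covs$RAIN - 1200) / 300),
              plogis(-0.6), 0.3, 0.05)
  f <- fitBeinf(y, covs, mu = ~RAIN, family = "MIBR")
  surf <- predictSurface(f, st)
  expect_true(all(gridValues(surf) >= 0 & gridValues(surf) <= 1))
  ptPred <- predict(f, covs)$expectation
  expect_equal(famap:::gridVector(surf), ptPred, tolerance = 1e-12)

  # intercept-only inflated-beta model gives a constant surface at E(y)
  f0 <- fitBeinf(y, family = "MIBR")
  s0 <- predictSurface(f0, st)
  expect_equal(max(gridValues(s0)) - min(gridValues(s0)), 0)
  expect_equal(gridValues(s0)[1, 1], mean(f0@fitted), tolerance = 1e-9)

  # missing layer errors
  f2 <- fitBeinf(y, data.frame(Z = rnorm(nrow(cc))), mu = ~Z, family = "MIBR")
  expect_error(predictSurface(f2, st), "missing covariate")
})
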