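test_that("log density matches the closed form and the direct-formula oracle", {
  m1 <- ggm(precision = diag(1))
  expect_equal(logDensity(m1, 0), -0.5 * log(2 * pi), tolerance = 1e-12)

  for (seed in 1:5) {
    m <- randomModel(3, seed)
    expect_equal(logDensity(m, modelMean(m)), freeEnergy(m), tolerance = 1e-12)
    set.seed(seed + 50)
    x <- rnorm(3)
    expect_equal(logDensity(m, x),
                 directLogDensity(modelMean(m), covarianceMatrix(m), x),
                 tolerance = 1e-10)
  }
  expect_error(logDensity(m1, c(1, 2)), "dimension")
})

test_that("free energy and entropy agree with their closed forms", {
  expect_equal(freeEnergy(ggm(precision = diag(1))), -0.5 * log(2 * pi))
  expect_equal(freeEnergy(ggm(precision = diag(2))), -log(2 * pi))
  expect_equal(differentialEntropy(ggm(precision = diag(1))),
               0.5 * log(2 * pi * exp(1)))
  expect_equal(differentialEntropy(ggm(precision = diag(2))),
               log(2 * pi * exp(1)))
})

test_that("entropy equals minus the expected log density (Monte Carlo)", {
  m <- randomModel(4, 7)
  x <- sampleModel(m, 1e5, seed = 42)
  ld <- logDensity(m, x)
  se <- sd(ld) / sqrt(length(ld))
  expect_lt(abs(differentialEntropy(m) - (-mean(ld))), 3 * se)
})

test_that("KL divergence matches closed forms and the sampling oracle", {
  m <- randomModel(3, 11)
  expect_lt(abs(klDivergence(m, m)), 1e-12)
  # N(0,1) vs N(1,1): KL = mu^2 / 2
  a <- ggm(precision = diag(1), mean = 0)
  b <- ggm(precision = diag(1), mean = 1)
  expect_equal(klDivergence(a, b), 0.5, tolerance = 1e-12)
  expect_equal(symmetricKL(a, b), 1.0, tolerance = 1e-12)

  m0 <- randomModel(3, 21); m1 <- randomModel(3, 22)
  x <- sampleModel(m0, 1e5, seed = 43)
  diffs <- logDensity(m0, x) - logDensity(m1, x)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(klDivergence(m0, m1) - mean(diffs)), 3 * se)
})

test_that("KL is non-negative, zero on itself, and symmetrized KL is symmetric", {
  for (i in 1:100) {
    n <- (i %% 7) + 2   # dimensions 2..8
    m0 <- randomModel(n, 3 * i + 1)
    m1 <- randomModel(n, 3 * i + 2)
    expect_gte(klDivergence(m0, m1), -1e-10)
    expect_lt(abs(klDivergence(m0, m0)), 1e-10)
    expect_equal(symmetricKL(m0, m1), symmetricKL(m1, m0), tolerance = 1e-10)
  }
})

test_that("conditioning reproduces the textbook closed forms", {
  # diagonal covariance: conditioning changes nothing about the free vars
  d <- ggm(covariance = diag(c(1, 2, 3)), mean = c(1, 2, 3))
  cond <- conditionModel(d, 2, 5)
  expect_equal(modelMean(cond), c(1, 3))
  expect_equal(covarianceMatrix(cond), diag(c(1, 3)),
               ignore_attr = TRUE, tolerance = 1e-12)

  # bivariate with correlation rho, condition X2 = v
  s1 <- 1.5; s2 <- 0.7; rho <- 0.6; v <- 2; mu <- c(0.3, -0.4)
  S <- matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2)
  m <- ggm(covariance = S, mean = mu)
  cond <- conditionModel(m, 2, v)
  expect_equal(modelMean(cond), mu[1] + rho * (s1 / s2) * (v - mu[2]),
               tolerance = 1e-10)
  expect_equal(covarianceMatrix(cond)[1, 1], s1^2 * (1 - rho^2),
               tolerance = 1e-10)
})

test_that("conditioning matches grid-based numerical conditioning", {
  m <- randomModel(3, 31)
  cond <- conditionModel(m, 3, 0.7)
  oracle <- gridCondition(m, 3, 0.7)
  expect_equal(modelMean(cond), oracle$mean, tolerance = 1e-6)
  expect_equal(covarianceMatrix(cond), oracle$cov,
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("conditioning obeys the chain rule and rejects degenerate partitions", {
  m <- randomModel(5, 41)
  both <- conditionModel(m, c(1, 4), c(0.5, -0.2))
  stepwise <- conditionModel(conditionModel(m, 1, 0.5), "V4", -0.2)
  expect_equal(modelMean(both), modelMean(stepwise), tolerance = 1e-8)
  expect_equal(covarianceMatrix(both), covarianceMatrix(stepwise),
               tolerance = 1e-8)

  expect_error(conditionModel(m, 1:5, rep(0, 5)), "remain free")
  expect_error(conditionModel(m, integer(0), numeric(0)), "conditioned")
  expect_error(conditionModel(m, "nope", 1), "unknown variable")
})

test_that("sampling is seed-deterministic and converges to the model", {
  m <- randomModel(3, 51)
  expect_identical(sampleModel(m, 10, seed = 9), sampleModel(m, 10, seed = 9))

  x <- sampleModel(m, 1e5, seed = 10)
  sds <- sqrt(diag(covarianceMatrix(m)))
  expect_true(all(abs(colMeans(x) - modelMean(m)) < 4 * sds / sqrt(1e5)))
  # sample covariance converges in max-abs norm
  expect_lt(max(abs(sampleCovariance(x) - covarianceMatrix(m))), 0.05)

  # degenerate limit: tiny variance pins all draws at the mean
  tiny <- ggm(covariance = matrix(1e-12), mean = 3)
  expect_true(all(abs(sampleModel(tiny, 100, seed = 1) - 3) < 1e-4))
})

test_that("data log likelihood sums frame densities under each normalization", {
  m <- randomModel(3, 61)
  one <- covariateMatrix(rbind(modelMean(m), modelMean(m)))
  expect_equal(dataLogLikelihood(m, one), 2 * freeEnergy(m), tolerance = 1e-12)

  d <- covariateMatrix(sampleModel(m, 50, seed = 3))
  tot <- dataLogLikelihood(m, d)
  expect_equal(dataLogLikelihood(m, d, "per_frame"), tot / 50)
  expect_equal(dataLogLikelihood(m, d, "per_frame_per_dim"), tot / 150)
})

test_that("a model explains its own data better than a rival's data", {
  # two distinct generators, a model fitted to each: the likelihood table
  # must prefer the matched model on both data sets
  pA <- randomSparsePrecision(5, 0.3, seed = 71)
  pB <- randomSparsePrecision(5, 0.3, seed = 72)
  dA <- ggmDataset(ggm(precision = pA), 2000, seed = 73)$data
  dB <- ggmDataset(ggm(precision = pB, mean = rep(1, 5)), 2000, seed = 74)$data
  mA <- learnGGM(dA, lambda = 0.05)
  mB <- learnGGM(dB, lambda = 0.05)
  expect_gt(dataLogLikelihood(mA, dA, "per_frame"),
            dataLogLikelihood(mA, dB, "per_frame"))
  expect_gt(dataLogLikelihood(mB, dB, "per_frame"),
            dataLogLikelihood(mB, dA, "per_frame"))
})

test_that("edge lists contain exactly the suprathreshold off-diagonal couplings", {
  P <- diag(3)
  P[1, 2] <- P[2, 1] <- 0.3
  P[1, 3] <- P[3, 1] <- 1e-10   # below threshold: structural zero
  m <- ggm(precision = P, labels = c("a", "b", "c"))
  e <- edgeList(m)
  expect_equal(nrow(e), 1L)
  expect_equal(e$i_label, "a")
  expect_equal(e$j_label, "b")
  expect_equal(e$weight, 0.3)
  expect_true(all(e$i < e$j))
  # threshold is overridable
  expect_equal(nrow(edgeList(m, threshold = 1e-11)), 2L)
})

test_that("model validity rejects inconsistent parameterizations", {
  expect_error(ggm(precision = matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(ggm(precision = diag(c(1, -1))), "positive definite")
  expect_error(new("GaussianGraphicalModel", mean = c(0, 0),
                   precision = diag(2), covariance = 2 * diag(2),
                   naturalParam = c(0, 0), labels = c("a", "b"),
                   lambda = numeric()),
               "invert")
})
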