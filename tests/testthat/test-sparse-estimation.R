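test_that("sample mean and covariance match their defining formulas", {
  const <- covariateMatrix(matrix(2, 5, 3))
  expect_equal(sampleMean(const), rep(2, 3), ignore_attr = TRUE)
  expect_equal(sampleCovariance(const), matrix(0, 3, 3), ignore_attr = TRUE)

  two <- covariateMatrix(rbind(rep(0, 3), rep(2, 3)))
  expect_equal(sampleMean(two), rep(1, 3), ignore_attr = TRUE)

  expect_equal(sampleCovariance(matrix(c(-1, 1), 2, 1)), matrix(1),
               ignore_attr = TRUE)

  set.seed(5)
  x <- matrix(rnorm(30), 10, 3)
  mu <- rep(0, 3)
  for (i in 1:10) mu <- mu + x[i, ] / 10           # independent summation
  S <- matrix(0, 3, 3)
  for (i in 1:10) S <- S + tcrossprod(x[i, ] - mu) / 10
  expect_equal(sampleMean(x), mu, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sampleCovariance(x), S, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(sampleCovariance(matrix(1, 1, 3)), "2 frames")
})

test_that("degenerate penalties solve in closed form", {
  S <- randomSPD(4, 1)
  # lambda = 0: the feasible set is the single point S
  fit0 <- bcdSolve(S, 0)
  expect_equal(fit0$W, S, tolerance = 1e-12, ignore_attr = TRUE)
  # diagonal S: each column subproblem attains the bound, W = S + lambda I
  D <- diag(c(1, 2, 3))
  fitd <- bcdSolve(D, 0.3)
  expect_equal(fitd$W, D + 0.3 * diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fitd$precision, diag(1 / (c(1, 2, 3) + 0.3)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(nrow(edgeList(ggm(precision = fitd$precision))), 0L)

  expect_error(bcdSolve(matrix(c(1, 2, 0, 1), 2), 0.1), "symmetric")
  expect_error(bcdSolve(diag(c(1, -1)), 0), "positive-definite")
})

test_that("solver iterates stay feasible, positive definite, and ascending", {
  for (seed in 1:4) {
    S <- randomSPD(5, 100 + seed)
    lam <- c(0.02, 0.1, 0.3, 0.6)[seed]
    fit <- bcdSolve(S, lam, keepPath = TRUE)
    expect_true(fit$converged)
    expect_lte(fit$gap, 1e-6 * 5)
    for (W in fit$path) {
      expect_lte(max(abs(W - S)), lam + 1e-8)          # dual feasibility
      expect_no_error(chol(W))                         # strictly PD
    }
    expect_true(all(diff(fit$logdetPath) >= -1e-12))   # monotone dual objective
    # returned W inverts the assembled precision
    expect_lt(max(abs(fit$W %*% fit$precision - diag(5))), 1e-5)
  }
})

test_that("solver warns and flags when the sweep budget is exhausted", {
  S <- randomSPD(6, 33)
  expect_warning(fit <- bcdSolve(S, 0.2, epsilon = 1e-12, maxSweeps = 1L),
                 "budget")
  expect_false(fit$converged)
  expect_gt(fit$gap, 1e-12)
})

test_that("solver agrees with an independent convex-programming oracle", {
  set.seed(77)
  for (i in 1:6) {
    n <- sample(2:6, 1)
    S <- crossprod(matrix(rnorm(n * n), n)) / n + 0.2 * diag(n)
    lam <- sample(c(0.01, 0.1, 0.5), 1)
    fit <- bcdSolve(S, lam, epsilon = 1e-10)
    W_oracle <- pgdMaxLogDet(S, lam)
    expect_lt(max(abs(fit$W - W_oracle)), 1e-5)
  }
})

test_that("the fitted model recovers a known sparse graph", {
  P <- randomSparsePrecision(8, 0.25, seed = 91)
  ds <- ggmDataset(ggm(precision = P), 5000, seed = 92)
  fit <- learnGGM(ds$data)
  rep <- recoveryReport(ds$truth, fit)
  expect_gte(rep$precision, 0.8)
  expect_gte(rep$recall, 0.8)
})

test_that("a very large penalty shrinks away every edge", {
  ds <- ggmDataset(ggm(precision = randomSparsePrecision(5, 0.4, seed = 95)),
                   500, seed = 96)
  fit <- learnGGM(ds$data, lambda = 100)
  expect_equal(nrow(edgeList(fit)), 0L)
})

test_that("the penalized objective is computed term by term and prefers the optimum", {
  expect_equal(penalizedObjective(matrix(1), matrix(1), 0), -1)
  # identity precision, n = 3: the penalty term contributes -3 lambda
  expect_equal(penalizedObjective(diag(3), diag(3) * 0, 0.2) -
               penalizedObjective(diag(3), diag(3) * 0, 0), -3 * 0.2)
  set.seed(7)
  Pm <- randomSPD(4, 8); S <- randomSPD(4, 9); lam <- 0.17
  direct <- log(det(Pm)) - sum(diag(S %*% Pm)) - lam * sum(abs(Pm))
  expect_equal(penalizedObjective(Pm, S, lam), direct, tolerance = 1e-12)
  expect_error(penalizedObjective(diag(c(1, -1)), diag(2), 0.1),
               "positive definite")

  # optimality: the L1 fit beats the thresholded sample-precision baseline
  # at equal edge count
  ds <- ggmDataset(ggm(precision = randomSparsePrecision(6, 0.3, seed = 97)),
                   2000, seed = 98)
  lam <- 0.1
  fit <- learnGGM(ds$data, lambda = lam)
  k <- nrow(edgeList(fit))
  base <- thresholdBaseline(ds$data, k)
  S <- sampleCovariance(ds$data)
  Pbase <- chol2inv(chol(S))
  keep <- matrix(FALSE, 6, 6)
  keep[cbind(base$i, base$j)] <- TRUE
  keep <- keep | t(keep); diag(keep) <- TRUE
  Pbase[!keep] <- 0
  expect_gte(penalizedObjective(precisionMatrix(fit), S, lam),
             penalizedObjective(Pbase, S, lam))
})

test_that("thresholding the sample precision behaves at its extremes", {
  # diagonal generator: no off-diagonal structure survives estimation noise
  # at edgeCount = 0, and all pairs at full edgeCount
  ds <- ggmDataset(ggm(precision = diag(4)), 1000, seed = 99)
  expect_equal(nrow(thresholdBaseline(ds$data, 0)), 0L)
  full <- thresholdBaseline(ds$data, 6)
  expect_equal(nrow(full), 6L)
  expect_true(all(full$i < full$j))

  # overlap with the regularized fit is a fraction in [0, 1]
  ds2 <- ggmDataset(ggm(precision = randomSparsePrecision(6, 0.3, seed = 101)),
                    3000, seed = 102)
  fit <- learnGGM(ds2$data, lambda = 0.08)
  e <- edgeList(fit)
  base <- thresholdBaseline(ds2$data, nrow(e))
  overlap <- length(intersect(paste(e$i, e$j), paste(base$i, base$j))) / nrow(e)
  expect_gte(overlap, 0)
  expect_lte(overlap, 1)

  expect_error(thresholdBaseline(matrix(rnorm(6), 2, 3), 1), "singular")
})

test_that("the solution path sparsifies monotonically in lambda", {
  for (seed in c(3, 7)) {
    ds <- ggmDataset(ggm(precision = randomSparsePrecision(6, 0.4, seed = seed)),
                     800, seed = seed + 500)
    lams <- c(0.02, 0.05, 0.1, 0.3, 1)
    counts <- vapply(lams, function(l)
      nrow(edgeList(learnGGM(ds$data, lambda = l))), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the analytic penalty follows its formula and monotonicity contracts", {
  expect_gte(defaultLambda(100, 8), defaultLambda(10000, 8))
  expect_gt(defaultLambda(100, 8, alpha = 0.001), defaultLambda(100, 8, alpha = 0.1))
  # frozen hand-computed instance of the formula
  expect_equal(defaultLambda(100, 5, 0.05), 0.305443, tolerance = 1e-6)
  # scale: max sigma_i sigma_j over distinct pairs
  expect_equal(defaultLambda(100, 3, 0.05, sigma = c(1, 2, 5)),
               10 * defaultLambda(100, 3, 0.05), tolerance = 1e-12)
  expect_error(defaultLambda(2, 5), "exceed")
})
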