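# Independent oracles. Each one solves the same problem as the package by
# a different route (direct formula, brute-force optimization, numeric
# integration), and is deliberately kept independent of the code paths it
# checks.

# Direct-formula multivariate normal log density via explicit determinant
# and linear solve (no precision matrix, no Cholesky shortcut).
directLogDensity <- function(mu, Sigma, x) {
  n <- length(mu)
  d <- x - mu
  -0.5 * (n * log(2 * pi) + log(det(Sigma))) -
    0.5 * sum(d * solve(Sigma, d))
}

# Independent solver for the dual problem max{log|W| : ||W-S||inf <= lam}:
# projected gradient ascent with backtracking; the projection is an
# elementwise clip to the box, which is trivially correct.
pgdMaxLogDet <- function(S, lambda, maxIter = 100000L, tol = 1e-11) {
  n <- nrow(S)
  lo <- S - lambda
  hi <- S + lambda
  W <- S + lambda * diag(n)
  logdet <- function(W) {
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) -Inf else 2 * sum(log(diag(ch)))
  }
  f <- logdet(W)
  step <- 0.1
  for (it in seq_len(maxIter)) {
    G <- chol2inv(chol(W))
    repeat {
      Wn <- pmin(pmax(W + step * G, lo), hi)
      fn <- logdet(Wn)
      if (fn > -Inf && fn >= f - 1e-14) break
      step <- step / 2
    }
    moved <- max(abs(Wn - W))
    W <- Wn
    if (fn > f) step <- step * 1.05
    f <- fn
    if (moved < tol) break
  }
  W
}

# Conditioning by numeric normalization of the joint density on a grid:
# condition variable `vIdx` of a 3-variable model at value v, integrate
# out nothing, and read the conditional mean/covariance of the two free
# variables off the normalized grid weights.
gridCondition <- function(model, vIdx, v, half = 8, points = 401) {
  stopifnot(modelDim(model) == 3, length(vIdx) == 1)
  free <- setdiff(1:3, vIdx)
  mu <- modelMean(model)
  sd <- sqrt(diag(covarianceMatrix(model)))
  g1 <- seq(mu[free[1]] - half * sd[free[1]], mu[free[1]] + half * sd[free[1]],
            length.out = points)
  g2 <- seq(mu[free[2]] - half * sd[free[2]], mu[free[2]] + half * sd[free[2]],
            length.out = points)
  g <- expand.grid(a = g1, b = g2)
  x <- matrix(0, nrow(g), 3)
  x[, free[1]] <- g$a
  x[, free[2]] <- g$b
  x[, vIdx] <- v
  w <- exp(logDensity(model, x))
  w <- w / sum(w)
  m1 <- sum(w * g$a); m2 <- sum(w * g$b)
  list(mean = c(m1, m2),
       cov = matrix(c(sum(w * (g$a - m1)^2), sum(w * (g$a - m1) * (g$b - m2)),
                      sum(w * (g$a - m1) * (g$b - m2)), sum(w * (g$b - m2)^2)),
                    2, 2))
}

# Hand-executed complete-linkage dendrogram for the 5-point line fixture
# {0, 1, 10, 11, 30} with d(i,j) = |x_i - x_j|:
#   merge {1,2} at 1; merge {3,4} at 1; merge {1,2}+{3,4} at 11
#   (max linkage 11 < 20 to point 5 for {3,4}, < 30 for {1,2});
#   final merge brings in point 5 at 30.
lineDistance5 <- function() {
  x <- c(0, 1, 10, 11, 30)
  abs(outer(x, x, "-"))
}
lineClusters5 <- function(k) {
  switch(as.character(k),
         "3" = c(1L, 1L, 2L, 2L, 3L),
         "2" = c(1L, 1L, 1L, 1L, 2L),
         stop("hand oracle only prepared for k in {2, 3}"))
}

# Empirical transition matrix of an observed state sequence
countTransitions <- function(states, k) {
  counts <- matrix(0, k, k)
  for (i in seq_len(length(states) - 1))
    counts[states[i], states[i + 1]] <- counts[states[i], states[i + 1]] + 1
  sweep(counts, 1, pmax(rowSums(counts), 1), "/")
}
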