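# Small reusable fixtures, all generated in code under fixed seeds.

# Random symmetric positive-definite matrix (well conditioned)
randomSPD <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + 0.5 * diag(n)
}

# Random valid model of dimension n
randomModel <- function(n, seed, meanScale = 1) {
  set.seed(seed)
  mu <- rnorm(n) * meanScale
  ggm(covariance = randomSPD(n, seed + 1000), mean = mu)
}

# Three well-separated conformational states of dimension n: distinct
# sparse precisions and distinct means.
makeStates <- function(n, seed, shifts = c(0, 3, -3)) {
  lapply(seq_along(shifts), function(i)
    ggm(precision = randomSparsePrecision(n, 0.3, seed = seed + i),
        mean = rep(shifts[i], n)))
}

# The 3-state transition matrix used by the kinetics fixtures
threeStateTransition <- function() {
  matrix(c(0.80, 0.15, 0.05,
           0.10, 0.80, 0.10,
           0.05, 0.15, 0.80), 3, 3, byrow = TRUE)
}

# Two-state trajectory differing only in covariance, switching after
# `switchAt` of `windows` windows; returns data plus the switch window.
changePointFixture <- function(n, windows, framesPerWindow, switchAt, seed) {
  mA <- ggm(precision = randomSparsePrecision(n, 0.3, seed = seed))
  mB <- ggm(precision = randomSparsePrecision(n, 0.3, seed = seed + 5000))
  states <- c(rep(1L, switchAt), rep(2L, windows - switchAt))
  set.seed(seed + 9000)
  x <- do.call(rbind, lapply(states, function(s)
    sampleModel(if (s == 1L) mA else mB, framesPerWindow)))
  list(data = covariateMatrix(x), switchAt = switchAt)
}
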