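# Shared fixtures and independent oracles used across test files.

# Direct-inverse GP posterior: the brute-force linear-algebra oracle the
# factorised implementation is checked against (kept independent of gpFit).
directGPPredict <- function(X, y, theta, xstar, center = TRUE,
                            jitter = 1e-8) {
  sf <- theta[["sigma_f"]]; sl <- theta[["sigma_l"]]; sn <- theta[["sigma_n"]]
  k <- function(u, v) sf * exp(-sum((u - v)^2) / (2 * sl))
  n <- length(y)
  ym <- if (center) mean(y) else 0
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- k(X[i, ], X[j, ])
  Kn <- K + (sn + jitter) * diag(n)
  ks <- vapply(seq_len(n), function(i) k(X[i, ], xstar), numeric(1))
  Ki <- solve(Kn)
  list(mean = ym + drop(ks %*% Ki %*% (y - ym)),
       variance = sf + sn - drop(ks %*% Ki %*% ks))
}

# Direct multivariate-normal log density (zero mean), the LML oracle.
directMVNLogDensity <- function(y, S) {
  n <- length(y)
  -0.5 * (drop(t(y) %*% solve(S) %*% y) + determinant(S)$modulus + n * log(2 * pi))
}

# Draw scores from a GP prior with known hyperparameters.
simulateGPScores <- function(X, theta, seed) {
  withr::with_seed(seed, {
    sf <- theta[["sigma_f"]]; sl <- theta[["sigma_l"]]; sn <- theta[["sigma_n"]]
    d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
    K <- sf * exp(-pmax(d2, 0) / (2 * sl))
    diag(K) <- diag(K) + sn
    drop(t(chol(K)) %*% rnorm(nrow(X)))
  })
}

# Small two-setting search space used by the param-space tests.
twoSpecSpace <- function() {
  searchSpace(
    parameterSpec("window", "integer", 1, 3, 1),
    parameterSpec("factor", "float", 0.6, 1.5, 0.1))
}

# A tiny image with one bright disk of the given diameter.
diskImage <- function(side = 64, diameter = 20, centre = c(32, 32),
                      bg = 0.1, fg = 0.9) {
  r <- matrix(seq_len(side), side, side)
  c <- matrix(seq_len(side), side, side, byrow = TRUE)
  img <- matrix(bg, side, side)
  img[(r - centre[1])^2 + (c - centre[2])^2 <= (diameter / 2)^2] <- fg
  img
}

referenceTheta <- c(sigma_n = 0.1, sigma_f = 2, sigma_l = 0.5)
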