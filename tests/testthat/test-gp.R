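test_that("squared-exponential kernel matches its closed form", {
  th <- referenceTheta   # sigma_f = 2, sigma_l = 0.5
  expect_equal(sqExpKernel(c(0.3, 0.7), c(0.3, 0.7), th), 2)
  # squared distance equal to 2 * sigma_l gives sigma_f / e
  u <- c(0, 0); v <- c(1, 0)   # ||u-v||^2 = 1 = 2 * 0.5
  expect_equal(sqExpKernel(u, v, th), 2 * exp(-1))
  # monotone decay to zero with distance
  d <- seq(0, 20, by = 0.5)
  vals <- vapply(d, function(x) sqExpKernel(0, x, th), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_lt(vals[length(vals)], 1e-12)
  expect_error(sqExpKernel(c(0, 0), 0, th), "dimension")
})

test_that("kernel matrices are symmetric positive semi-definite", {
  withr::with_seed(21, {
    for (i in 1:10) {
      X <- matrix(runif(8 * 3), 8, 3)
      K <- outer(seq_len(8), seq_len(8), Vectorize(function(i, j)
        sqExpKernel(X[i, ], X[j, ], referenceTheta)))
      expect_equal(K, t(K))
      expect_true(all(eigen(K, symmetric = TRUE,
                            only.values = TRUE)$values >= -1e-8))
    }
  })
})

test_that("prior-only model predicts mean 0 and variance sigma_f + sigma_n", {
  m <- gpFit(matrix(numeric(0), 0, 2), numeric(0), referenceTheta)
  p <- gpPredict(m, rbind(c(0.1, 0.9), c(0.5, 0.5)))
  expect_equal(p$mean, c(0, 0))
  expect_equal(p$variance, rep(2.1, 2))
})

test_that("single-point posterior matches the closed form and the noise-free limit", {
  th <- c(sigma_n = 0.3, sigma_f = 2, sigma_l = 0.5)
  x <- c(0.4, 0.6)
  m <- gpFit(rbind(x), 5, th, center = FALSE)
  p <- gpPredict(m, x)
  expect_equal(p$mean, 5 * 2 / 2.3, tolerance = 1e-7)

  th0 <- c(sigma_n = 1e-12, sigma_f = 2, sigma_l = 0.5)
  p0 <- gpPredict(gpFit(rbind(x), 5, th0, center = FALSE), x)
  expect_equal(p0$mean, 5, tolerance = 1e-5)
  expect_equal(p0$variance, th0[["sigma_n"]], tolerance = 1e-6)
})

test_that("factorised posterior equals the direct-inverse oracle on small sets", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(1:5, 1)
      X <- matrix(runif(n * 2), n, 2)
      y <- runif(n, 1, 10)
      m <- gpFit(X, y, referenceTheta)
      for (j in 1:3) {
        xs <- runif(2)
        got <- gpPredict(m, xs)
        want <- directGPPredict(X, y, referenceTheta, xs)
        expect_equal(got$mean, want$mean, tolerance = 1e-8)
        expect_equal(got$variance, want$variance, tolerance = 1e-8)
      }
    }
  })
})

test_that("fit handles duplicates, rejects bad input, and is deterministic", {
  X <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  m <- gpFit(X, c(4, 6), c(sigma_n = 0.2, sigma_f = 1, sigma_l = 0.5))
  expect_s4_class(m, "GPModel")
  expect_error(gpFit(rbind(c(0, 0)), NaN, referenceTheta), "finite")
  m1 <- gpFit(X, c(4, 6), referenceTheta)
  m2 <- gpFit(X, c(4, 6), referenceTheta)
  expect_identical(gpPredict(m1, c(0.2, 0.8)), gpPredict(m2, c(0.2, 0.8)))
  expect_error(gpPredict(m1, c(0.2, 0.8, 0.1)), "dimension")
})

test_that("predictive variance is bounded by the prior and predictions revert far away", {
  withr::with_seed(41, {
    X <- matrix(runif(12), 6, 2)
    y <- runif(6, 1, 10)
    m <- gpFit(X, y, referenceTheta, center = FALSE)
    prior <- 2.1
    pTrain <- gpPredict(m, X)
    expect_true(all(pTrain$variance <= prior + 1e-9))
    expect_true(all(pTrain$variance >= 0))
    far <- matrix(100 + runif(6), 3, 2)
    pFar <- gpPredict(m, far)
    expect_equal(pFar$mean, rep(0, 3), tolerance = 1e-6)
    expect_equal(pFar$variance, rep(prior, 3), tolerance = 1e-6)
  })
})

test_that("log marginal likelihood matches closed forms and a density oracle", {
  th <- c(sigma_n = 0.4, sigma_f = 1.5, sigma_l = 0.3)
  y1 <- 3.7
  expect_equal(gpLogMarginalLikelihood(rbind(c(0.2, 0.2)), y1, th, jitter = 0),
               -0.5 * (log(2 * pi * 1.9) + y1^2 / 1.9), tolerance = 1e-9)
  expect_error(gpLogMarginalLikelihood(matrix(numeric(0), 0, 2), numeric(0), th),
               "at least one")

  withr::with_seed(51, {
    X <- matrix(runif(8), 4, 2)
    y <- runif(4, 1, 10)
    K <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j)
      sqExpKernel(X[i, ], X[j, ], th)))
    S <- K + (th[["sigma_n"]] + 1e-8) * diag(4)
    expect_equal(gpLogMarginalLikelihood(X, y, th),
                 as.numeric(directMVNLogDensity(y, S)), tolerance = 1e-8)
    # invariance under permutation of the training order
    p <- sample(4)
    expect_equal(gpLogMarginalLikelihood(X[p, ], y[p], th),
                 gpLogMarginalLikelihood(X, y, th), tolerance = 1e-10)
  })
})

test_that("hyperparameter optimisation never worsens the marginal likelihood", {
  withr::with_seed(61, {
    X <- matrix(runif(20), 10, 2)
    y <- runif(10, 1, 10)
  })
  theta0 <- c(sigma_n = 0.5, sigma_f = 1, sigma_l = 1)
  out <- gpOptimiseHyperparams(X, y, theta0, seed = 1)
  yc <- y - mean(y)
  expect_gte(gpLogMarginalLikelihood(X, yc, out),
             gpLogMarginalLikelihood(X, yc, theta0) - 1e-9)
  expect_error(gpOptimiseHyperparams(X[1, , drop = FALSE], y[1], theta0),
               "at least 2")

  # degenerate bounds pin every parameter at theta0
  pin <- list(sigma_n = c(0.5, 0.5), sigma_f = c(1, 1), sigma_l = c(1, 1))
  expect_equal(gpOptimiseHyperparams(X, y, theta0, bounds = pin), theta0)
})
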