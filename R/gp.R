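#' Squared-exponential covariance between two encoded points
#'
#' `k(u, v) = sigma_f * exp(-||u - v||^2 / (2 * sigma_l))`. Note that
#' `sigma_l` divides the squared distance directly, i.e. it is the
#' *squared* length-scale; this matches the kernel as parameterised
#' throughout the package.
#'
#' @param u,v Numeric vectors of equal length (encoded configurations).
#' @param theta Named numeric `c(sigma_n=, sigma_f=, sigma_l=)`; only
#'   `sigma_f` and `sigma_l` enter the kernel.
#' @return Positive covariance value; `sigma_f` when `u == v`.
#' @examples
#' th <- c(sigma_n = 0.1, sigma_f = 2, sigma_l = 0.5)
#' sqExpKernel(c(0, 0), c(0, 0), th)  # sigma_f
#' @export
sqExpKernel <- function(u, v, theta) {
  if (length(u) != length(v))
    stop("points have mismatched dimensions (", length(u), " vs ",
         length(v), ")")
  checkTheta(theta)
  theta[["sigma_f"]] * exp(-sum((u - v)^2) / (2 * theta[["sigma_l"]]))
}

checkTheta <- function(theta) {
  if (!all(c("sigma_n", "sigma_f", "sigma_l") %in% names(theta)))
    stop("theta must be named (sigma_n, sigma_f, sigma_l)")
  if (theta[["sigma_f"]] <= 0 || theta[["sigma_l"]] <= 0 ||
      theta[["sigma_n"]] < 0)
    stop("require sigma_f > 0, sigma_l > 0, sigma_n >= 0")
  invisible(theta)
}

# Cross-covariance matrix between row sets of X1 (n x d) and X2 (m x d).
kernelMatrix <- function(X1, X2, theta) {
  if (ncol(X1) != ncol(X2)) stop("points have mismatched dimensions")
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  theta[["sigma_f"]] * exp(-d2 / (2 * theta[["sigma_l"]]))
}

asPointMatrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Fit the GP surrogate to a training set
#'
#' Factorises `K + (sigma_n + jitter) I` by Cholesky decomposition and
#' caches everything [gpPredict()] needs. Scores are centred by
#' subtracting their mean before fitting (the mean is added back to
#' predictions), so the zero-mean prior does not drag predictions of 1-10
#' scores toward zero. `N = 0` is permitted and yields a prior-only model.
#'
#' @param X Numeric matrix of encoded configurations (N x d), or a single
#'   point as a vector.
#' @param y Numeric quality scores, length N.
#' @param theta Named numeric `c(sigma_n=, sigma_f=, sigma_l=)`.
#' @param center Centre the scores (default TRUE).
#' @param jitter Unconditional diagonal jitter (default 1e-8), keeping the
#'   factorisation stable with duplicated points.
#' @return A [GPModel-class].
#' @examples
#' th <- c(sigma_n = 0.1, sigma_f = 1, sigma_l = 0.5)
#' m <- gpFit(rbind(c(0.2, 0.2), c(0.8, 0.4)), c(4, 7), th)
#' gpPredict(m, c(0.5, 0.3))
#' @export
gpFit <- function(X, y, theta, center = TRUE, jitter = 1e-8) {
  checkTheta(theta)
  if (length(y) == 0L) {
    X <- matrix(numeric(0), nrow = 0L, ncol = if (is.matrix(X)) ncol(X) else length(X))
    return(new("GPModel", X = X, y = numeric(0), theta = theta,
               U = matrix(numeric(0), 0, 0), alpha = numeric(0),
               yMean = 0, jitter = jitter))
  }
  X <- asPointMatrix(X)
  if (nrow(X) != length(y)) stop("X and y lengths differ")
  if (!all(is.finite(y))) stop("scores must be finite")
  if (!all(is.finite(X))) stop("points must be finite")
  yMean <- if (center) mean(y) else 0
  yc <- y - yMean
  K <- kernelMatrix(X, X, theta)
  diag(K) <- diag(K) + theta[["sigma_n"]] + jitter
  U <- tryCatch(chol(K), error = function(e)
    stop("covariance factorisation failed (", conditionMessage(e),
         "); increase sigma_n or the jitter", call. = FALSE))
  alpha <- backsolve(U, forwardsolve(t(U), yc))
  new("GPModel", X = X, y = y, theta = theta, U = U, alpha = alpha,
      yMean = yMean, jitter = jitter)
}

#' Posterior prediction of the (noisy) quality score
#'
#' Standard GP-regression posterior for the observed score `y*`: mean
#' `k*' (K + sigma_n I)^-1 y` (plus the centring mean) and variance
#' `sigma_f + sigma_n - k*' (K + sigma_n I)^-1 k*`. The variance is
#' predictive of the *observable* score, so it includes the noise
#' variance; a prior-only model returns mean equal to the centring mean
#' (0 when nothing was fitted) and variance `sigma_f + sigma_n`
#' everywhere.
#'
#' @param model A [GPModel-class] from [gpFit()].
#' @param xstar A single encoded point (vector) or a matrix of points
#'   (rows).
#' @return Data frame with columns `mean` and `variance`, one row per
#'   query point.
#' @export
gpPredict <- function(model, xstar) {
  Xs <- asPointMatrix(xstar)
  th <- model@theta
  priorVar <- th[["sigma_f"]] + th[["sigma_n"]]
  if (length(model@y) == 0L) {
    if (ncol(model@X) > 0L && ncol(Xs) != ncol(model@X))
      stop("query dimension mismatch")
    return(data.frame(mean = rep(model@yMean, nrow(Xs)),
                      variance = rep(priorVar, nrow(Xs))))
  }
  if (ncol(Xs) != ncol(model@X))
    stop("query dimension (", ncol(Xs), ") does not match training (",
         ncol(model@X), ")")
  Ks <- kernelMatrix(model@X, Xs, th)     # N x M
  mean <- model@yMean + drop(crossprod(Ks, model@alpha))
  V <- forwardsolve(t(model@U), Ks)
  variance <- pmax(priorVar - colSums(V^2), 0)
  data.frame(mean = mean, variance = variance)
}

#' Log marginal likelihood of scores under the GP prior
#'
#' `log N(y | 0, K + sigma_n I)`, evaluated on the scores exactly as
#' given. The hyperparameter optimiser applies it to centred scores,
#' consistent with [gpFit()]'s centring.
#'
#' @inheritParams gpFit
#' @return Log marginal likelihood (scalar).
#' @export
gpLogMarginalLikelihood <- function(X, y, theta, jitter = 1e-8) {
  checkTheta(theta)
  n <- length(y)
  if (n < 1L) stop("log marginal likelihood needs at least one observation")
  X <- asPointMatrix(X)
  if (nrow(X) != n) stop("X and y lengths differ")
  K <- kernelMatrix(X, X, theta)
  diag(K) <- diag(K) + theta[["sigma_n"]] + jitter
  U <- tryCatch(chol(K), error = function(e)
    stop("covariance factorisation failed; increase sigma_n or the jitter",
         call. = FALSE))
  a <- forwardsolve(t(U), y)
  -0.5 * (sum(a^2) + n * log(2 * pi)) - sum(log(diag(U)))
}

#' Default box bounds for GP hyperparameter optimisation
#'
#' @return List of `c(lower, upper)` ranges for `sigma_n`, `sigma_f` and
#'   `sigma_l`.
#' @export
defaultGPBounds <- function() {
  list(sigma_n = c(1e-6, 4), sigma_f = c(1e-3, 100), sigma_l = c(1e-3, 10))
}

#' Maximise the marginal likelihood over the GP hyperparameters
#'
#' Multi-start bounded maximisation (`optim` L-BFGS-B) of the log marginal
#' likelihood of the centred scores, over log-transformed
#' `(sigma_n, sigma_f, sigma_l)`. The returned hyperparameters never
#' achieve a lower marginal likelihood than `theta0`: if no restart
#' improves on it, `theta0` is returned unchanged.
#'
#' @inheritParams gpFit
#' @param theta0 Starting hyperparameters.
#' @param bounds Per-parameter `c(lower, upper)` ranges, as
#'   [defaultGPBounds()].
#' @param restarts Number of starts (the first is `theta0`, clamped into
#'   the bounds; the rest are drawn log-uniformly within them).
#' @param seed Optional seed for the restart draws.
#' @return Named optimised hyperparameter vector.
#' @export
gpOptimiseHyperparams <- function(X, y, theta0, bounds = defaultGPBounds(),
                                  restarts = 5, seed = NULL, jitter = 1e-8) {
  checkTheta(theta0)
  if (length(y) < 2L)
    stop("hyperparameter optimisation needs at least 2 observations ",
         "(bootstrap incomplete)")
  X <- asPointMatrix(X)
  yc <- y - mean(y)
  ord <- c("sigma_n", "sigma_f", "sigma_l")
  lower <- log(vapply(bounds[ord], `[`, numeric(1), 1L))
  upper <- log(vapply(bounds[ord], `[`, numeric(1), 2L))
  if (any(lower > upper)) stop("invalid bounds")
  lml0 <- gpLogMarginalLikelihood(X, yc, theta0, jitter = jitter)
  if (all(upper - lower < 1e-12)) return(theta0)

  obj <- function(lp) {
    th <- exp(lp); names(th) <- ord
    -gpLogMarginalLikelihood(X, yc, th, jitter = jitter)
  }
  start0 <- pmin(pmax(log(theta0[ord]), lower), upper)
  starts <- withSeed(seed, {
    extra <- lapply(seq_len(max(restarts - 1L, 0L)), function(i)
      stats::runif(3, lower, upper))
    c(list(start0), extra)
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || -best$value < lml0 - 1e-9) return(theta0)
  th <- exp(best$par)
  names(th) <- ord
  th
}
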