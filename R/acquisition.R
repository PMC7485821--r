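#' Expected Improvement of a predicted quality score
#'
#' Maximisation convention: with `s = sqrt(variance)` and
#' `delta = mean - yBest - xi`, EI is `max(delta, 0)` when `s = 0` and
#' `delta * pnorm(delta / s) + s * dnorm(delta / s)` otherwise. Always
#' non-negative, and non-decreasing in the variance at fixed mean.
#'
#' @param mean,variance Posterior prediction (vectors recycle together);
#'   `variance >= 0`.
#' @param yBest Best observed quality score so far.
#' @param xi Exploration offset (>= 0), subtracted from the improvement.
#' @return Expected improvement value(s), >= 0.
#' @examples
#' expectedImprovement(5, 1, 5)  # dnorm(0) = 0.3989...
#' @export
expectedImprovement <- function(mean, variance, yBest, xi = 0) {
  if (any(variance < 0)) stop("variance must be >= 0")
  if (xi < 0) stop("xi must be >= 0")
  s <- sqrt(variance)
  delta <- mean - yBest - xi
  out <- ifelse(s == 0, pmax(delta, 0),
                delta * stats::pnorm(delta / s) + s * stats::dnorm(delta / s))
  pmax(out, 0)
}

#' Acquisition settings
#'
#' @param xi Exploration offset on the QS scale. The default, 0.5, is
#'   half a rating step: ratings are integers, so Expected Improvement
#'   should not chase improvements smaller than half a rating unit.
#' @param candidateCount Number of quasi-random candidate points scored
#'   per iteration (default 2048).
#' @return Validated list of settings.
#' @export
acquisitionSettings <- function(xi = 0.5, candidateCount = 2048) {
  if (xi < 0) stop("xi must be >= 0")
  if (candidateCount < 1) stop("candidateCount must be >= 1")
  list(xi = xi, candidateCount = as.integer(candidateCount))
}

#' Select the candidate with maximal Expected Improvement
#'
#' Scores every candidate under the surrogate's posterior and returns the
#' one maximising EI; ties break toward the lowest candidate index, so the
#' step is deterministic given the candidate set.
#'
#' @param model A [GPModel-class].
#' @param candidates Matrix of encoded candidate points (rows), non-empty.
#' @param yBest Best observed quality score.
#' @param xi Exploration offset.
#' @return List with `point` (the chosen encoded point), `index` (its row
#'   in `candidates`) and `ei` (its EI value).
#' @export
proposeNext <- function(model, candidates, yBest, xi = 0.5) {
  candidates <- asPointMatrix(candidates)
  if (nrow(candidates) < 1L) stop("candidate set must be non-empty")
  pred <- gpPredict(model, candidates)
  ei <- expectedImprovement(pred$mean, pred$variance, yBest, xi)
  i <- which.max(ei)   # first maximum = lowest index on ties
  list(point = candidates[i, ], index = i, ei = ei[i])
}

# Candidate set for one acquisition step: seeded stratified quasi-random
# points covering the hypercube, plus the grid neighbours of every
# configuration already evaluated (local refinement).
makeCandidates <- function(space, nCandidates = 2048, evaluated = NULL) {
  d <- spaceDim(space)
  cand <- lhs::randomLHS(as.integer(nCandidates), d)
  if (length(evaluated)) {
    nb <- unlist(lapply(evaluated, gridNeighbours, space = space),
                 recursive = FALSE)
    if (length(nb)) cand <- rbind(cand, do.call(rbind, nb))
  }
  unname(cand)
}
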