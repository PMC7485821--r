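#' Declare a tolerance-range criterion on one object measurement
#'
#' @param measurement Measurement name (e.g. `"area"`, `"perimeter"`,
#'   `"solidity"`, `"eccentricity"`).
#' @param lower,upper Bounds; at least one must be finite, and
#'   `lower < upper` when both are.
#' @return A criterion (list) for [automatedCriteria()].
#' @export
measurementCriterion <- function(measurement, lower = -Inf, upper = Inf) {
  if (!is.character(measurement) || length(measurement) != 1L)
    stop("measurement must be a single name")
  if (is.infinite(lower) && is.infinite(upper))
    stop("criterion '", measurement, "' needs at least one bound")
  if (lower >= upper)
    stop("criterion '", measurement, "': lower bound must be < upper bound")
  structure(list(measurement = measurement, lower = lower, upper = upper),
            class = "segbo_criterion")
}

#' Bundle 1-4 measurement criteria for automated evaluation
#'
#' At most four object measurements may be judged; the per-criterion pass
#' fractions are aggregated into the quality score by [automatedQS()].
#'
#' @param ... Criteria from [measurementCriterion()], or one list of them.
#' @param targetObject Name of the object class whose measurements are
#'   judged (default `"primary"`).
#' @return Validated criteria bundle.
#' @export
automatedCriteria <- function(..., targetObject = "primary") {
  criteria <- list(...)
  if (length(criteria) == 1L && is.list(criteria[[1]]) &&
      !inherits(criteria[[1]], "segbo_criterion"))
    criteria <- criteria[[1]]
  if (length(criteria) < 1L)
    stop("at least one measurement criterion required")
  if (length(criteria) > 4L)
    stop("at most 4 measurement criteria are allowed (got ",
         length(criteria), ")")
  if (!all(vapply(criteria, inherits, logical(1), "segbo_criterion")))
    stop("criteria must come from measurementCriterion()")
  structure(list(criteria = criteria, targetObject = targetObject),
            class = "segbo_criteria")
}

#' Automated quality score from tolerance-range criteria
#'
#' For each criterion the fraction of objects whose measurement lies
#' within its bounds is computed; the score is `1 + 9 * mean(pass
#' fractions)`, mapping all-fail to 1 and all-pass to 10 so that automated
#' and manual scores share one scale. A segmentation with zero objects
#' scores 1 (worst) with a warning rather than erroring, so the optimiser
#' can move away from configurations that produce empty masks.
#'
#' @param measurements Per-object measurement data frame (one row per
#'   object), e.g. from [measureObjects()].
#' @param criteria An [automatedCriteria()] bundle.
#' @return Quality score in `[1, 10]`.
#' @examples
#' m <- data.frame(solidity = c(0.95, 0.7), area = c(120, 80))
#' crit <- automatedCriteria(measurementCriterion("solidity", lower = 0.9))
#' automatedQS(m, crit)  # pass fraction 0.5 -> 5.5
#' @export
automatedQS <- function(measurements, criteria) {
  if (!inherits(criteria, "segbo_criteria"))
    stop("criteria must come from automatedCriteria()")
  if (nrow(measurements) == 0L) {
    warning("no objects to evaluate; scoring worst quality (1)")
    return(1)
  }
  fracs <- vapply(criteria$criteria, function(cr) {
    if (!cr$measurement %in% names(measurements))
      stop("measurement '", cr$measurement, "' not found in the table")
    v <- measurements[[cr$measurement]]
    mean(v >= cr$lower & v <= cr$upper)
  }, numeric(1))
  1 + 9 * mean(fracs)
}

#' Manual quality score via a rating callback
#'
#' Passes the display payload (typically an overlay of object outlines on
#' the input image) to the rating provider and returns its integer rating
#' on the 1 (poor) to 10 (excellent) scale. An interactive session wires a
#' prompt in as the provider; tests and headless runs substitute a
#' simulated rater. Invalid ratings (non-integer or outside 1-10) cause
#' the provider to be re-queried up to 3 times before aborting.
#'
#' @param ratingProvider Function of one argument (the payload) returning
#'   an integer rating.
#' @param payload Object shown to the rater (e.g. an overlay image or a
#'   file path); passed through unmodified.
#' @return Integer quality score in 1-10.
#' @export
manualQS <- function(ratingProvider, payload = NULL) {
  for (attempt in 1:4) {
    r <- ratingProvider(payload)
    ok <- is.numeric(r) && length(r) == 1L && is.finite(r) &&
      isWhole(r) && r >= 1 && r <= 10
    if (ok) return(as.integer(round(r)))
    if (attempt < 4)
      warning("invalid rating (must be an integer in 1-10); re-querying")
  }
  stop("no valid rating obtained after 4 attempts")
}

#' Weighted composite of several quality scores
#'
#' Weighted arithmetic mean with internally normalised non-negative
#' weights; the result is bounded by the smallest and largest input score.
#'
#' @param scores Numeric quality scores in `[1, 10]`.
#' @param weights Non-negative weights, same length, not all zero.
#' @return Composite quality score in `[1, 10]`.
#' @examples
#' compositeQS(c(4, 8), c(1, 1))  # 6
#' @export
compositeQS <- function(scores, weights) {
  if (length(scores) != length(weights))
    stop("scores and weights must have the same length")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) == 0) stop("weights must not all be zero")
  sum(scores * weights / sum(weights))
}

#' Quality gap between target and current score
#'
#' `max(target - current, 0)`: zero exactly when the current quality
#' score matches or exceeds the target, which is the optimiser's stopping
#' condition.
#'
#' @param target Target quality score in `[1, 10]`.
#' @param current Current quality score.
#' @return Non-negative gap.
#' @export
qualityGap <- function(target, current) {
  if (target < 1 || target > 10)
    stop("target QS must lie in [1, 10]")
  max(target - current, 0)
}
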