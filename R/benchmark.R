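#' Intersection-over-union of two binary masks
#'
#' `|A intersect B| / |A union B|`, the pixel-wise agreement between a
#' predicted and a ground-truth mask. Symmetric, in `[0, 1]`. When both
#' masks are empty the ratio is 0/0; it is defined here as 1 (perfect
#' agreement) with a warning.
#'
#' @param maskA,maskB Logical (or 0/1) matrices of equal shape.
#' @return IoU in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 2, 3); a[1, 1:2] <- TRUE
#' b <- matrix(FALSE, 2, 3); b[1, 2:3] <- TRUE
#' maskIoU(a, b)  # 1/3
#' @export
maskIoU <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB)))
    stop("masks have different shapes")
  a <- maskA > 0; b <- maskB > 0
  un <- sum(a | b)
  if (un == 0) {
    warning("both masks are empty; IoU defined as 1")
    return(1)
  }
  sum(a & b) / un
}

#' Evaluate a fixed configuration on a test set
#'
#' Runs the reference pipeline at `config` on every sample, binarises the
#' predicted label mask (any label > 0), and scores it against the
#' sample's ground truth for the requested object class.
#'
#' @param config Named numeric configuration.
#' @param samples List of [SyntheticSample-class] (e.g.
#'   `generateDataset(...)$samples`).
#' @param objectClass `"nucleus"` (primary mask) or `"cell"` (secondary).
#' @param smoothingSigma Passed to [runPipeline()].
#' @return List with `perImage` (data frame of per-image IoU), `mean` and
#'   `sd`.
#' @export
evaluateOnTestset <- function(config, samples,
                              objectClass = c("nucleus", "cell"),
                              smoothingSigma = 1) {
  objectClass <- match.arg(objectClass)
  if (length(samples) == 0L) stop("test set is empty")
  slot <- if (objectClass == "nucleus") "primary" else "secondary"
  ious <- vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (!objectClass %in% names(s@masks))
      stop("sample ", i, " has no ground truth for class '", objectClass, "'")
    res <- tryCatch(
      runPipeline(sampleImage(s), config, smoothingSigma = smoothingSigma),
      error = function(e) NULL)
    pred <- if (is.null(res)) matrix(0L, nrow(sampleImage(s)),
                                     ncol(sampleImage(s)))
            else methods::slot(res, slot)
    maskIoU(pred > 0, sampleMasks(s, objectClass))
  }, numeric(1))
  list(perImage = data.frame(image = seq_along(samples), iou = ious),
       mean = mean(ious), sd = stats::sd(ious))
}

#' Random-search baseline with the optimiser's loop contract
#'
#' Identical bootstrap, evaluation, stopping rules, trace and persistence
#' to [runBO()], but every post-bootstrap proposal is an independent
#' uniform draw from the setting grid instead of an Expected-Improvement
#' choice. Used as the comparison baseline for optimisation efficiency.
#'
#' @inheritParams runBO
#' @return A [BOResult-class] (phase column says `"random"`).
#' @export
runRandomSearch <- function(space, pipeline, evaluator,
                            settings = boSettings(), traceDir = NULL) {
  runOptimisationLoop(space, pipeline, evaluator, settings,
                      method = "random", traceDir = traceDir)
}

# Evaluations needed to first reach best-so-far gap <= threshold;
# censored at the run's total budget when never reached.
iterationsToGap <- function(result, threshold, budget) {
  trace <- boTrace(result)
  hit <- which(trace$best_gap <= threshold)
  if (length(hit)) trace$evaluation[hit[1]] else budget
}

#' Compare Bayesian optimisation against random search
#'
#' Runs both methods on the same task over paired replicate seeds (each
#' replicate shares its master seed, hence its bootstrap, between the two
#' methods) and summarises the best-so-far quality gap per iteration and
#' the number of evaluations needed to reach a gap of at most
#' `gapThreshold`, censored at the full budget.
#'
#' @param space A [SearchSpace-class].
#' @param pipeline,evaluator As in [runBO()].
#' @param settings A [boSettings()] list (its seed is replaced per
#'   replicate).
#' @param nReplicates Number of paired replicates (>= 2).
#' @param baseSeed Replicate r uses master seed `baseSeed + r - 1`.
#' @param gapThreshold Gap level defining "reached the target region".
#' @return List with `perIteration` (method, evaluation, mean_gap,
#'   sd_gap), `itersToTarget` (method, replicate, evaluations) and
#'   `summary` (per-method mean/sd of evaluations-to-target).
#' @export
compareMethods <- function(space, pipeline, evaluator,
                           settings = boSettings(), nReplicates = 20,
                           baseSeed = 1L, gapThreshold = 1) {
  if (nReplicates < 2) stop("nReplicates must be >= 2")
  budget <- settings$bootstrapCount + settings$maxIterations
  perIter <- list(); toTarget <- list()
  for (r in seq_len(nReplicates)) {
    s <- settings
    s$seed <- as.integer(baseSeed + r - 1L)
    runs <- list(bo = runBO(space, pipeline, evaluator, s),
                 random = runRandomSearch(space, pipeline, evaluator, s))
    for (m in names(runs)) {
      trace <- boTrace(runs[[m]])
      # pad to the full budget with the terminal best-so-far gap
      g <- trace$best_gap
      g <- c(g, rep(g[length(g)], budget - length(g)))
      perIter[[length(perIter) + 1L]] <-
        data.frame(method = m, replicate = r, evaluation = seq_len(budget),
                   gap = g)
      toTarget[[length(toTarget) + 1L]] <-
        data.frame(method = m, replicate = r,
                   evaluations = iterationsToGap(runs[[m]], gapThreshold,
                                                 budget))
    }
  }
  perIter <- do.call(rbind, perIter)
  agg <- stats::aggregate(gap ~ method + evaluation, perIter,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  perIteration <- data.frame(method = agg$method, evaluation = agg$evaluation,
                             mean_gap = agg$gap[, "mean"],
                             sd_gap = agg$gap[, "sd"])
  toTarget <- do.call(rbind, toTarget)
  summary <- do.call(rbind, lapply(split(toTarget, toTarget$method),
    function(d) data.frame(method = d$method[1],
                           mean_evaluations = mean(d$evaluations),
                           sd_evaluations = stats::sd(d$evaluations))))
  rownames(summary) <- NULL
  list(perIteration = perIteration, itersToTarget = toTarget,
       summary = summary)
}

#' Plot a method comparison
#'
#' Mean best-so-far quality gap per evaluation for each method, with a
#' shaded +/- sd band.
#'
#' @param comparison Result of [compareMethods()].
#' @param file Optional PNG path; NULL plots to the current device.
#' @return Invisibly, NULL.
#' @export
plotComparison <- function(comparison, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  pi <- comparison$perIteration
  cols <- c(bo = "steelblue", random = "darkorange")
  graphics::plot(NULL, xlim = range(pi$evaluation),
                 ylim = c(0, max(pi$mean_gap + pi$sd_gap)),
                 xlab = "Evaluation", ylab = "Best-so-far quality gap",
                 main = "Bayesian optimisation vs random search")
  for (m in unique(pi$method)) {
    d <- pi[pi$method == m, ]
    graphics::polygon(c(d$evaluation, rev(d$evaluation)),
                      c(pmax(d$mean_gap - d$sd_gap, 0),
                        rev(d$mean_gap + d$sd_gap)),
                      col = grDevices::adjustcolor(cols[[m]], 0.2),
                      border = NA)
    graphics::lines(d$evaluation, d$mean_gap, col = cols[[m]], lwd = 2)
  }
  graphics::legend("topright", legend = unique(pi$method),
                   col = cols[unique(pi$method)], lwd = 2, bty = "n")
  invisible(NULL)
}
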