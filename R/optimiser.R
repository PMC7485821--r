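#' Optimiser settings
#'
#' @param targetQS Minimum acceptable quality score in `[1, 10]`; the run
#'   stops as soon as the current QS matches or exceeds it.
#' @param maxIterations Iteration budget *after* the bootstrap phase.
#' @param bootstrapCount Randomly drawn configurations evaluated before
#'   the first surrogate fit (>= 2, since hyperparameter estimation needs
#'   at least two points).
#' @param xi,candidateCount Acquisition settings, see
#'   [acquisitionSettings()].
#' @param gpBounds Hyperparameter box bounds, see [defaultGPBounds()].
#' @param gpRestarts Multi-start count for the marginal-likelihood
#'   optimisation.
#' @param refitEvery Re-optimise the hyperparameters every this many
#'   iterations (default 1, i.e. every iteration after bootstrap).
#' @param seed Master seed making the whole run reproducible (given a
#'   deterministic evaluator).
#' @return Validated list of settings.
#' @export
boSettings <- function(targetQS = 9, maxIterations = 30, bootstrapCount = 2,
                       xi = 0.5, candidateCount = 2048,
                       gpBounds = defaultGPBounds(), gpRestarts = 5,
                       refitEvery = 1, seed = 1L) {
  if (targetQS < 1 || targetQS > 10) stop("targetQS must lie in [1, 10]")
  if (maxIterations < 1) stop("maxIterations must be >= 1")
  if (bootstrapCount < 2)
    stop("bootstrapCount must be >= 2 (surrogate estimation needs two points)")
  acquisitionSettings(xi, candidateCount)   # validates
  list(targetQS = targetQS, maxIterations = as.integer(maxIterations),
       bootstrapCount = as.integer(bootstrapCount), xi = xi,
       candidateCount = as.integer(candidateCount), gpBounds = gpBounds,
       gpRestarts = as.integer(gpRestarts),
       refitEvery = as.integer(refitEvery), seed = as.integer(seed))
}

# Shared evaluation loop for BO and random search. `proposeFun(model,
# evaluatedConfigs, yBest)` returns list(config, raw) for the next
# configuration; model is NULL when method = "random".
runOptimisationLoop <- function(space, pipeline, evaluator, settings,
                                method = c("bo", "random"),
                                traceDir = NULL) {
  method <- match.arg(method)
  validObject(space)
  nms <- specNames(space)
  rows <- list()
  configs <- list()
  scores <- numeric(0)
  theta <- c(sigma_n = 0.1, sigma_f = 1, sigma_l = 0.5)

  evaluateOne <- function(config, raw, phase, evalIdx) {
    result <- tryCatch(pipeline(config), error = function(e) e)
    crashed <- inherits(result, "error")
    qs <- if (crashed) 1 else {
      qs <- tryCatch(evaluator(result), error = function(e) e)
      if (inherits(qs, "error")) {
        if (!is.null(traceDir) && length(rows))
          try(utils::write.csv(do.call(rbind, rows),
                               file.path(traceDir, "trace_partial.csv"),
                               row.names = FALSE), silent = TRUE)
        stop("evaluator failed at evaluation ", evalIdx, ": ",
             conditionMessage(qs), call. = FALSE)
      }
      qs
    }
    gap <- qualityGap(settings$targetQS, qs)
    configs[[length(configs) + 1L]] <<- config
    scores[length(scores) + 1L] <<- qs
    row <- data.frame(evaluation = evalIdx, phase = phase, qs = qs,
                      gap = gap, best_qs = max(scores),
                      best_gap = qualityGap(settings$targetQS, max(scores)),
                      crashed = crashed,
                      sigma_n = theta[["sigma_n"]],
                      sigma_f = theta[["sigma_f"]],
                      sigma_l = theta[["sigma_l"]],
                      check.names = FALSE)
    for (k in seq_along(nms)) row[[nms[k]]] <- config[[k]]
    for (k in seq_along(nms))
      row[[paste0(nms[k], " (proposed)")]] <- raw[[k]]
    rows[[length(rows) + 1L]] <<- row
    gap
  }

  withSeed(settings$seed, {
    boot <- sampleConfigurations(space, settings$bootstrapCount)
    evalIdx <- 0L
    gap <- NA_real_
    for (config in boot) {
      evalIdx <- evalIdx + 1L
      gap <- evaluateOne(config, config, "bootstrap", evalIdx)
      if (gap == 0) break
    }
    iter <- 0L
    while (gap > 0 && iter < settings$maxIterations) {
      iter <- iter + 1L
      evalIdx <- evalIdx + 1L
      if (method == "bo") {
        X <- do.call(rbind, lapply(configs, encodeConfiguration, space = space))
        if (iter == 1L || iter %% settings$refitEvery == 0L)
          theta <- gpOptimiseHyperparams(X, scores, theta0 = theta,
                                         bounds = settings$gpBounds,
                                         restarts = settings$gpRestarts)
        model <- gpFit(X, scores, theta)
        cand <- makeCandidates(space, settings$candidateCount,
                               evaluated = configs)
        prop <- proposeNext(model, cand, yBest = max(scores),
                            xi = settings$xi)
        raw <- decodeConfiguration(prop$point, space, snap = FALSE)
        config <- decodeConfiguration(prop$point, space, snap = TRUE)
      } else {
        config <- sampleConfigurations(space, 1L)[[1]]
        raw <- config
      }
      gap <- evaluateOne(config, raw, method, evalIdx)
    }
  })

  trace <- do.call(rbind, rows)
  bestIdx <- which.max(scores)
  best <- list(configuration = configs[[bestIdx]], qs = scores[bestIdx],
               evaluation = bestIdx)
  reason <- if (trace$gap[nrow(trace)] == 0) "target_met" else
    "budget_exhausted"
  final <- tryCatch(pipeline(best$configuration), error = function(e) NULL)
  new("BOResult", trace = trace, best = best, terminatedReason = reason,
      space = space, settings = settings, final = final)
}

#' Bayesian optimisation of a pipeline configuration
#'
#' The loop: evaluate `bootstrapCount` randomly drawn configurations; then
#' repeatedly fit the GP surrogate to all (configuration, QS) pairs,
#' re-optimise its hyperparameters by marginal likelihood, propose the
#' next configuration by Expected Improvement over a seeded candidate
#' set, snap it to the interval grid, execute the pipeline, and obtain the
#' current QS from the evaluator. Stops as soon as the quality gap reaches
#' 0 (current QS meets or exceeds the target, including during bootstrap)
#' or when `maxIterations` proposals beyond the bootstrap have been
#' evaluated. A pipeline error on a configuration scores QS 1 and is
#' flagged, so the optimiser can learn away from crashing regions; an
#' evaluator error aborts the run (persisting a partial trace when
#' `traceDir` is given).
#'
#' @param space A [SearchSpace-class].
#' @param pipeline Function taking a named configuration and returning a
#'   pipeline result (e.g. wraps [runPipeline()]).
#' @param evaluator Function taking the pipeline result and returning a
#'   quality score in 1-10 (e.g. [makeSimulatedRater()], or a manual
#'   prompt via [manualQS()]).
#' @param settings A [boSettings()] list.
#' @param traceDir Optional directory for a partial trace on abort.
#' @return A [BOResult-class].
#' @examples
#' \donttest{
#' sample <- generateSample(defaultSceneSpec(seed = 7))
#' res <- runBO(defaultSearchSpace(),
#'              function(cfg) runPipeline(sampleImage(sample), cfg),
#'              makeSimulatedRater(sample),
#'              boSettings(targetQS = 7, maxIterations = 15, seed = 7))
#' terminatedReason(res)
#' }
#' @export
runBO <- function(space, pipeline, evaluator, settings = boSettings(),
                  traceDir = NULL) {
  runOptimisationLoop(space, pipeline, evaluator, settings, method = "bo",
                      traceDir = traceDir)
}

#' Iteration report of queried and best-known settings
#'
#' One row per setting with the value currently known to be best (from
#' evaluations before this one), the previously evaluated value, and the
#' newly proposed value (the optimiser's continuous proposal; bootstrap
#' rows show the executed value).
#'
#' @param result A [BOResult-class].
#' @param evaluation Which evaluation to report (default: the last).
#' @return Data frame with columns `setting`, `best_so_far`, `old_value`,
#'   `new_value`.
#' @export
iterationReport <- function(result, evaluation = nrow(boTrace(result))) {
  trace <- boTrace(result)
  if (evaluation < 1 || evaluation > nrow(trace))
    stop("no such evaluation")
  nms <- specNames(result@space)
  prev <- max(evaluation - 1L, 1L)
  upto <- trace[seq_len(prev), , drop = FALSE]
  bestRow <- which.max(upto$qs)
  data.frame(
    setting = nms,
    best_so_far = vapply(nms, function(n) upto[[n]][bestRow], numeric(1)),
    old_value = vapply(nms, function(n) trace[[n]][prev], numeric(1)),
    new_value = vapply(nms, function(n)
      trace[[paste0(n, " (proposed)")]][evaluation], numeric(1)),
    row.names = NULL)
}

#' Persist an optimisation trace to disk
#'
#' Writes (a) a plain-text tab-separated evaluations file with one line
#' per evaluation (index, executed setting values, QS, quality gap) at
#' full precision so the training set can be reconstructed exactly, (b)
#' the full trace as CSV, and (c) a quality-gap-versus-iteration scatter
#' plot (PNG).
#'
#' @param result A [BOResult-class].
#' @param dir Writable output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
persistTrace <- function(result, dir) {
  if (!dir.exists(dir)) {
    ok <- tryCatch({dir.create(dir, recursive = TRUE); TRUE},
                   warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory ", dir)
  }
  trace <- boTrace(result)
  nms <- specNames(result@space)
  txt <- file.path(dir, "evaluations.txt")
  header <- c("evaluation", nms, "qs", "gap")
  lines <- vapply(seq_len(nrow(trace)), function(i) {
    vals <- vapply(nms, function(n) trace[[n]][i], numeric(1))
    paste(c(trace$evaluation[i],
            formatC(c(vals, trace$qs[i], trace$gap[i]), format = "g",
                    digits = 17)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), txt)

  csv <- file.path(dir, "trace.csv")
  utils::write.csv(trace, csv, row.names = FALSE)

  plotPath <- file.path(dir, "quality_gap.png")
  grDevices::png(plotPath, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  plotQualityGap(result)
  invisible(c(evaluations = txt, trace = csv, plot = plotPath))
}

#' Plot the quality gap across iterations
#'
#' Scatter of the per-evaluation quality gap (and the best-so-far gap as
#' a line) against the evaluation index, mirroring the optimiser's
#' progress display.
#'
#' @param result A [BOResult-class].
#' @return Invisibly, NULL.
#' @export
plotQualityGap <- function(result) {
  trace <- boTrace(result)
  graphics::plot(trace$evaluation, trace$gap, pch = 19, col = "steelblue",
                 xlab = "Evaluation", ylab = "Quality gap",
                 ylim = c(0, max(trace$gap, 1)),
                 main = "Quality gap between current and target QS")
  graphics::lines(trace$evaluation, trace$best_gap, col = "grey40", lwd = 2)
  graphics::abline(h = 0, lty = 2)
  graphics::legend("topright", c("current", "best so far"),
                   pch = c(19, NA), lty = c(NA, 1),
                   col = c("steelblue", "grey40"), bty = "n")
  invisible(NULL)
}

#' Reload a persisted evaluations file
#'
#' Round-trips the tab-separated evaluations file written by
#' [persistTrace()] back into the in-memory (configuration, QS) training
#' set.
#'
#' @param path Path to `evaluations.txt`.
#' @return Data frame with one row per evaluation.
#' @export
readEvaluations <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
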