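#' @import methods
NULL

#' A single tunable pipeline setting
#'
#' Declares one setting of the image-processing pipeline to be optimised:
#' its name, whether it takes integer or float values, its range, and the
#' interval (step) on which values are laid out.
#'
#' @slot name Character scalar, unique within a [SearchSpace-class].
#' @slot kind Either `"integer"` or `"float"`.
#' @slot minimum,maximum Numeric range bounds, `minimum < maximum`.
#' @slot interval Positive step; at most `maximum - minimum`. For integer
#'   settings all three must be whole-valued.
#'
#' @seealso [parameterSpec()], [gridValues()]
#' @exportClass ParameterSpec
setClass("ParameterSpec",
  representation(name = "character", kind = "character",
                 minimum = "numeric", maximum = "numeric",
                 interval = "numeric"))

setValidity("ParameterSpec", function(object) {
  msg <- character()
  nm <- if (length(object@name) == 1L && nzchar(object@name)) object@name else "<unnamed>"
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty character scalar")
  if (length(object@kind) != 1L || !object@kind %in% c("integer", "float"))
    msg <- c(msg, sprintf("spec '%s': 'kind' must be \"integer\" or \"float\"", nm))
  if (!is.finite(object@minimum) || !is.finite(object@maximum) ||
      !is.finite(object@interval))
    return(sprintf("spec '%s': bounds and interval must be finite", nm))
  if (object@minimum >= object@maximum)
    msg <- c(msg, sprintf("spec '%s': minimum (%g) must be < maximum (%g)",
                          nm, object@minimum, object@maximum))
  if (object@interval <= 0)
    msg <- c(msg, sprintf("spec '%s': interval must be positive", nm))
  if (object@interval > (object@maximum - object@minimum))
    msg <- c(msg, sprintf("spec '%s': interval exceeds the range", nm))
  if (identical(object@kind, "integer") &&
      !(isWhole(object@minimum) && isWhole(object@maximum) && isWhole(object@interval)))
    msg <- c(msg, sprintf("spec '%s': integer settings need whole-valued min/max/interval", nm))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' The pipeline-setting search space
#'
#' An ordered collection of [ParameterSpec-class] objects. Encoded points
#' live in the unit hypercube `[0,1]^d` with `d = length(specs)`; every
#' setting is normalised by its own range before any kernel computation so
#' that settings with different units contribute comparably to distances.
#'
#' @slot specs List of [ParameterSpec-class] objects, length >= 1, with
#'   unique names.
#'
#' @seealso [searchSpace()], [encodeConfiguration()], [decodeConfiguration()]
#' @exportClass SearchSpace
setClass("SearchSpace", representation(specs = "list"))

setValidity("SearchSpace", function(object) {
  if (length(object@specs) < 1L)
    return("at least one parameter required")
  for (s in object@specs) {
    if (!is(s, "ParameterSpec")) return("'specs' must contain ParameterSpec objects")
    v <- validObject(s, test = TRUE)
    if (!isTRUE(v)) return(v)
  }
  nms <- vapply(object@specs, function(s) s@name, character(1))
  if (anyDuplicated(nms))
    return(sprintf("duplicate setting name: '%s'", nms[duplicated(nms)][1]))
  TRUE
})

#' Gaussian-process surrogate model
#'
#' Holds the training set of encoded configurations and their quality
#' scores, the kernel hyperparameters `theta = (sigma_n, sigma_f, sigma_l)`,
#' and the cached Cholesky factorisation of the covariance-plus-noise
#' matrix used for prediction. Built by [gpFit()].
#'
#' @slot X Numeric matrix of encoded configurations (N x d); N = 0 gives a
#'   prior-only model.
#' @slot y Numeric quality scores, length N.
#' @slot theta Named numeric vector `c(sigma_n=, sigma_f=, sigma_l=)`:
#'   noise variance, signal variance, and squared length-scale of the
#'   squared-exponential kernel.
#' @slot U Upper-triangular Cholesky factor of `K + (sigma_n + jitter) I`.
#' @slot alpha Cached solve of the factorised system against the centred
#'   scores.
#' @slot yMean Mean subtracted from `y` before fitting (added back to
#'   predictions).
#' @slot jitter Diagonal jitter added unconditionally for stability.
#'
#' @seealso [gpFit()], [gpPredict()]
#' @exportClass GPModel
setClass("GPModel",
  representation(X = "matrix", y = "numeric", theta = "numeric",
                 U = "matrix", alpha = "numeric", yMean = "numeric",
                 jitter = "numeric"))

setValidity("GPModel", function(object) {
  th <- object@theta
  if (!all(c("sigma_n", "sigma_f", "sigma_l") %in% names(th)))
    return("theta must be named (sigma_n, sigma_f, sigma_l)")
  if (th[["sigma_f"]] <= 0 || th[["sigma_l"]] <= 0 || th[["sigma_n"]] < 0)
    return("require sigma_f > 0, sigma_l > 0, sigma_n >= 0")
  if (nrow(object@X) != length(object@y))
    return("X and y lengths differ")
  if (length(object@y) && !all(is.finite(object@y)))
    return("scores must be finite")
  TRUE
})

#' Result of one reference-pipeline execution
#'
#' @slot primary Integer label mask of primary objects (nuclei); 0 is
#'   background, labels are contiguous from 1 in raster (column-major
#'   first-pixel) order.
#' @slot secondary Integer label mask of secondary objects (cells); each
#'   secondary label equals the label of the primary seed it grew from.
#' @slot measurements Named list of per-object measurement data frames
#'   (`$primary`, `$secondary`) with columns label, area, perimeter,
#'   solidity, eccentricity.
#' @slot configuration Named numeric configuration the pipeline ran at.
#'
#' @seealso [runPipeline()]
#' @exportClass PipelineResult
setClass("PipelineResult",
  representation(primary = "matrix", secondary = "matrix",
                 measurements = "list", configuration = "numeric"))

#' Scene description for the synthetic image generator
#'
#' Declares what a generated fluorescence-like scene contains: how many
#' cells, their nucleus sizes, the intensity levels of the four rendered
#' classes, background gradient and noise, and the seed that makes
#' generation reproducible.
#'
#' @slot imageSize Integer (height, width) in pixels.
#' @slot nCells Number of cells to place (>= 0).
#' @slot nucleusAxes Range (min, max) of nucleus semi-axes, pixels.
#' @slot cellScale Cell semi-axes as a multiple of the nucleus semi-axes.
#' @slot punctaPerCell Integer range (min, max) of adhesion-like puncta
#'   rendered near each cell border.
#' @slot intensities Named numeric `c(background=, cell=, nucleus=,
#'   puncta=)`, strictly increasing background < cell < nucleus <= puncta.
#' @slot noiseSigma Additive Gaussian noise scale.
#' @slot gradientStrength Peak-to-peak amplitude of the linear background
#'   gradient.
#' @slot seed Integer seed.
#'
#' @seealso [sceneSpec()], [generateSample()]
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(imageSize = "integer", nCells = "integer",
                 nucleusAxes = "numeric", cellScale = "numeric",
                 punctaPerCell = "integer", intensities = "numeric",
                 noiseSigma = "numeric", gradientStrength = "numeric",
                 seed = "integer"))

setValidity("SceneSpec", function(object) {
  it <- object@intensities
  need <- c("background", "cell", "nucleus", "puncta")
  if (!all(need %in% names(it)))
    return("intensities must be named background/cell/nucleus/puncta")
  if (!(it[["background"]] < it[["cell"]] && it[["cell"]] < it[["nucleus"]] &&
        it[["nucleus"]] <= it[["puncta"]]))
    return("intensities must satisfy background < cell < nucleus <= puncta")
  if (object@nCells < 0L) return("nCells must be >= 0")
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    return("imageSize must be two integers >= 16")
  if (object@nucleusAxes[1] <= 0 || object@nucleusAxes[2] < object@nucleusAxes[1])
    return("nucleusAxes must be an increasing positive range")
  if (object@cellScale * object@nucleusAxes[2] * 2 >= min(object@imageSize))
    return("cells too large for the image")
  if (object@punctaPerCell[1] < 0L || object@punctaPerCell[2] < object@punctaPerCell[1])
    return("punctaPerCell must be a non-negative range")
  if (object@noiseSigma < 0 || object@gradientStrength < 0)
    return("noiseSigma and gradientStrength must be >= 0")
  TRUE
})

#' One generated synthetic sample
#'
#' @slot image Numeric matrix in `[0,1]`.
#' @slot masks Named list of binary (logical) ground-truth masks for the
#'   `nucleus`, `cell` and `puncta` classes; nucleus is pixelwise contained
#'   in cell.
#' @slot metadata List: the generating [SceneSpec-class], per-object
#'   placement records, and the oracle pipeline configuration recorded for
#'   the scene.
#'
#' @seealso [generateSample()]
#' @exportClass SyntheticSample
setClass("SyntheticSample",
  representation(image = "matrix", masks = "list", metadata = "list"))

#' Result of an optimisation run
#'
#' @slot trace Data frame with one row per evaluation: evaluation index,
#'   phase (bootstrap or a proposal method), executed setting values,
#'   continuous proposal values, quality score, quality gap, best score so
#'   far, crash flag, and the GP hyperparameters in force.
#' @slot best List: `configuration` (named numeric), `qs`, `evaluation`
#'   (index of the best evaluation).
#' @slot terminatedReason `"target_met"` or `"budget_exhausted"`.
#' @slot space The [SearchSpace-class] searched.
#' @slot settings The [boSettings()] list used.
#' @slot final The [PipelineResult-class] of the best configuration, or
#'   NULL.
#'
#' @seealso [runBO()], [runRandomSearch()], [persistTrace()]
#' @exportClass BOResult
setClass("BOResult",
  representation(trace = "data.frame", best = "list",
                 terminatedReason = "character", space = "SearchSpace",
                 settings = "list", final = "ANY"))

setValidity("BOResult", function(object) {
  if (!object@terminatedReason %in% c("target_met", "budget_exhausted"))
    return("terminatedReason must be target_met or budget_exhausted")
  if (nrow(object@trace)) {
    b <- object@trace$best_qs
    if (any(diff(b) < -1e-12)) return("best QS so far must be non-decreasing")
    gap <- object@trace$gap[nrow(object@trace)]
    if ((object@terminatedReason == "target_met") != (gap == 0))
      return("terminated_reason must be target_met iff the final quality gap is 0")
  }
  TRUE
})

setMethod("show", "ParameterSpec", function(object) {
  cat(sprintf("ParameterSpec '%s' (%s): [%g, %g] step %g\n",
              object@name, object@kind, object@minimum, object@maximum,
              object@interval))
})

setMethod("show", "SearchSpace", function(object) {
  cat(sprintf("SearchSpace with %d setting(s):\n", length(object@specs)))
  for (s in object@specs)
    cat(sprintf("  %-32s %-7s [%g, %g] step %g\n", s@name, s@kind,
                s@minimum, s@maximum, s@interval))
})

setMethod("show", "GPModel", function(object) {
  cat(sprintf(paste0("GPModel: N = %d, d = %d\n",
                     "  theta: sigma_n = %.4g, sigma_f = %.4g, sigma_l = %.4g\n"),
              nrow(object@X), ncol(object@X), object@theta[["sigma_n"]],
              object@theta[["sigma_f"]], object@theta[["sigma_l"]]))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0("SceneSpec: %d x %d image, %d cell(s), nucleus semi-axes ",
                     "[%g, %g] px, cell scale %g, seed %d\n"),
              object@imageSize[1], object@imageSize[2], object@nCells,
              object@nucleusAxes[1], object@nucleusAxes[2], object@cellScale,
              object@seed))
})

setMethod("show", "SyntheticSample", function(object) {
  counts <- vapply(object@masks, sum, numeric(1))
  cat(sprintf("SyntheticSample: %d x %d image; foreground px: %s\n",
              nrow(object@image), ncol(object@image),
              paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                    collapse = ", ")))
})

setMethod("show", "PipelineResult", function(object) {
  cat(sprintf("PipelineResult: %d primary, %d secondary object(s)\n",
              max(object@primary), max(object@secondary)))
})

setMethod("show", "BOResult", function(object) {
  cat(sprintf(paste0("BOResult (%s): %d evaluation(s), best QS %.3g ",
                     "(evaluation %d)\n"),
              object@terminatedReason, nrow(object@trace), object@best$qs,
              object@best$evaluation))
})
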