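#' Canonical names of the reference pipeline's tunable settings
#'
#' The four settings the optimiser exposes: size of the adaptive
#' thresholding window (pixels), the multiplier on the local-mean
#' threshold of the primary stage, the diameter below which detected
#' components are discarded as artifacts, and the multiplier on the global
#' (Otsu) threshold of the secondary stage.
#'
#' @return Character vector of the four setting names.
#' @export
pipelineSettingNames <- function() {
  c("Size of adaptive window",
    "Threshold correction factor I",
    "Typical artifact diameter",
    "Threshold correction factor II")
}

#' Fixed-form configuration of the reference segmentation pipeline
#'
#' @param adaptiveWindow Local-mean window size, pixels (>= 3; even values
#'   are widened to the next odd size).
#' @param thresholdCorrection1 Multiplier on the primary stage's local-mean
#'   threshold (> 0).
#' @param artifactDiameter Components with equivalent diameter (diameter of
#'   the circle of equal area) below this are removed (>= 0).
#' @param thresholdCorrection2 Multiplier on the secondary stage's global
#'   Otsu threshold (> 0).
#' @param smoothingSigma Gaussian pre-smoothing sigma, pixels; fixed, not
#'   optimised by default.
#' @return Validated list of pipeline settings.
#' @export
pipelineConfig <- function(adaptiveWindow, thresholdCorrection1,
                           artifactDiameter, thresholdCorrection2,
                           smoothingSigma = 1) {
  adaptiveWindow <- as.integer(round(adaptiveWindow))
  if (adaptiveWindow < 3L) stop("adaptiveWindow must be >= 3 pixels")
  if (thresholdCorrection1 <= 0 || thresholdCorrection2 <= 0)
    stop("threshold correction factors must be > 0")
  if (artifactDiameter < 0) stop("artifactDiameter must be >= 0")
  if (smoothingSigma < 0) stop("smoothingSigma must be >= 0")
  list(adaptiveWindow = adaptiveWindow,
       thresholdCorrection1 = thresholdCorrection1,
       artifactDiameter = artifactDiameter,
       thresholdCorrection2 = thresholdCorrection2,
       smoothingSigma = smoothingSigma)
}

# 8-connected labelling in deterministic raster order: EBImage::bwlabel is
# 4-connected, so diagonally adjacent components are merged afterwards and
# labels reassigned by column-major first-pixel order.
labelComponents <- function(bw) {
  lbl <- asMatrix(EBImage::bwlabel(bw))
  storage.mode(lbl) <- "integer"
  L <- max(lbl)
  if (L > 1L) {
    parent <- seq_len(L)
    findRoot <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    nr <- nrow(lbl); nc <- ncol(lbl)
    diag1 <- cbind(as.vector(lbl[-nr, -nc]), as.vector(lbl[-1, -1]))
    diag2 <- cbind(as.vector(lbl[-nr, -1]), as.vector(lbl[-1, -nc]))
    pairs <- rbind(diag1, diag2)
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- unique(pairs)
      for (k in seq_len(nrow(pairs))) {
        ri <- findRoot(pairs[k, 1]); rj <- findRoot(pairs[k, 2])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      map <- vapply(seq_len(L), findRoot, integer(1))
      lbl[lbl > 0L] <- map[lbl[lbl > 0L]]
    }
  }
  relabelRaster(lbl)
}

relabelRaster <- function(lbl) {
  storage.mode(lbl) <- "integer"
  if (max(lbl) == 0L) return(lbl)
  ids <- unique(lbl[lbl > 0L])          # column-major first-occurrence order
  map <- integer(max(lbl))
  map[ids] <- seq_along(ids)
  lbl[lbl > 0L] <- map[lbl[lbl > 0L]]
  lbl
}

checkImage <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  invisible(image)
}

#' Segment primary objects (nuclei) by adaptive local-mean thresholding
#'
#' The image is Gaussian-smoothed, binarised where it exceeds the local
#' mean (box window of `adaptiveWindow` pixels, replicated borders) times
#' `thresholdCorrection1`, holes are filled, components with equivalent
#' diameter below `artifactDiameter` are removed, and the rest are
#' labelled (8-connectivity, raster-order labels).
#'
#' @param image Numeric matrix in `[0,1]`, at least `adaptiveWindow`
#'   pixels in both dimensions.
#' @param config A [pipelineConfig()].
#' @return Integer label mask (0 background, labels contiguous from 1).
#' @export
segmentPrimary <- function(image, config) {
  checkImage(image)
  w <- config$adaptiveWindow
  if (any(dim(image) < w))
    stop("image (", nrow(image), "x", ncol(image),
         ") is smaller than the adaptive window (", w, ")")
  sm <- if (config$smoothingSigma > 0)
    asMatrix(EBImage::gblur(image, config$smoothingSigma)) else image
  w <- max(3L, as.integer(2L * (w %/% 2L) + 1L))  # odd window
  localMean <- asMatrix(EBImage::filter2(sm, matrix(1 / (w * w), w, w),
                                         boundary = "replicate"))
  bw <- sm > localMean * config$thresholdCorrection1
  bw <- asMatrix(EBImage::fillHull(bw)) > 0
  lbl <- labelComponents(bw)
  if (max(lbl) > 0L && config$artifactDiameter > 0) {
    areas <- tabulate(lbl[lbl > 0L], nbins = max(lbl))
    drop <- which(2 * sqrt(areas / pi) < config$artifactDiameter)
    if (length(drop)) {
      lbl[lbl %in% drop] <- 0L
      lbl <- relabelRaster(lbl)
    }
  }
  lbl
}

#' Grow secondary objects (cells) from primary seeds
#'
#' The cell foreground is the image above a global Otsu threshold times
#' `thresholdCorrection2` (always including the seed pixels); the Otsu
#' split is computed on non-primary pixels so the bright primary objects
#' cannot drag it above the cell/background boundary. Secondary
#' objects are grown from the primary seeds by intensity-guided seeded
#' propagation restricted to that foreground. Each secondary label equals
#' its seed's primary label, and every primary pixel is contained in its
#' secondary object.
#'
#' @param image Numeric matrix in `[0,1]`.
#' @param primary Integer label mask from [segmentPrimary()], same shape.
#' @param config A [pipelineConfig()].
#' @return Integer label mask of secondary objects.
#' @export
segmentSecondary <- function(image, primary, config) {
  checkImage(image)
  if (!all(dim(image) == dim(primary)))
    stop("primary mask shape does not match the image")
  if (max(primary) == 0L)
    return(matrix(0L, nrow(image), ncol(image)))
  # Otsu on non-primary pixels: the cell/background split must not be
  # dragged to the bright-nucleus mode
  bgpx <- image[primary == 0L]
  base <- if (length(bgpx) > 256L)
    EBImage::otsu(matrix(bgpx, nrow = 1L), range = c(0, 1))
  else EBImage::otsu(image, range = c(0, 1))
  thr <- base * config$thresholdCorrection2
  fg <- image > thr | primary > 0L
  sec <- asMatrix(EBImage::propagate(image, primary, mask = fg,
                                     lambda = 1e-4))
  storage.mode(sec) <- "integer"
  sec
}

#' Per-object shape measurements of a label mask
#'
#' Computes, per label: `area` (pixel count), `perimeter` (number of
#' exposed pixel edges), `solidity` (area divided by the area of the
#' convex hull of the pixel corner points, in `(0, 1]`), and
#' `eccentricity` (from the eigenvalues of the pixel-coordinate covariance,
#' in `[0, 1)`; 0 for single-pixel objects).
#'
#' @param mask Integer label mask.
#' @return Data frame with one row per label (empty mask gives zero rows).
#' @examples
#' m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L
#' measureObjects(m)  # area 25, solidity 1
#' @export
measureObjects <- function(mask) {
  L <- max(mask)
  if (L == 0L)
    return(data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), solidity = numeric(0),
                      eccentricity = numeric(0)))
  areas <- tabulate(mask[mask > 0L], nbins = L)

  # exposed 4-neighbour edges per label
  nr <- nrow(mask); nc <- ncol(mask)
  P <- matrix(0L, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- mask
  C <- mask
  perim <- numeric(L)
  shifts <- list(P[1:nr, 2:(nc + 1L)], P[3:(nr + 2L), 2:(nc + 1L)],
                 P[2:(nr + 1L), 1:nc], P[2:(nr + 1L), 3:(nc + 2L)])
  for (S in shifts) {
    sel <- C > 0L & C != S
    if (any(sel)) {
      t <- tabulate(C[sel], nbins = L)
      perim <- perim + t
    }
  }

  sol <- numeric(L); ecc <- numeric(L)
  idx <- which(mask > 0L)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  lab <- mask[idx]
  for (l in seq_len(L)) {
    sel <- lab == l
    r <- rr[sel]; c <- cc[sel]
    n <- length(r)
    # convex hull of pixel corners; shoelace area
    pts <- cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
                 c(c - 0.5, c + 0.5, c - 0.5, c + 0.5))
    h <- grDevices::chull(pts)
    hp <- pts[h, , drop = FALSE]
    m <- nrow(hp)
    j <- c(2:m, 1)
    hullArea <- abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
    sol[l] <- if (hullArea > 0) min(1, n / hullArea) else 1
    if (n > 1L) {
      cv <- stats::cov(cbind(r, c)) * (n - 1) / n
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      ecc[l] <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
    }
  }
  data.frame(label = seq_len(L), area = as.numeric(areas),
             perimeter = perim, solidity = sol, eccentricity = ecc)
}

#' Run the full reference pipeline at one configuration
#'
#' Binds a named configuration (the four settings of
#' [pipelineSettingNames()]) to the pipeline, segments primary then
#' secondary objects, and measures both. Deterministic: the same image and
#' configuration always produce identical masks.
#'
#' @param image Numeric matrix in `[0,1]`.
#' @param config Named numeric vector supplying all four settings.
#' @param smoothingSigma Fixed Gaussian pre-smoothing sigma.
#' @return A [PipelineResult-class].
#' @export
runPipeline <- function(image, config, smoothingSigma = 1) {
  nms <- pipelineSettingNames()
  if (is.null(names(config)))
    stop("config must be named; expected: ", paste(sQuote(nms), collapse = ", "))
  missing <- setdiff(nms, names(config))
  if (length(missing))
    stop("config is missing setting(s): ",
         paste(sQuote(missing), collapse = ", "),
         "; expected: ", paste(sQuote(nms), collapse = ", "))
  unknown <- setdiff(names(config), nms)
  if (length(unknown))
    stop("unknown setting(s): ", paste(sQuote(unknown), collapse = ", "),
         "; expected: ", paste(sQuote(nms), collapse = ", "))
  pc <- pipelineConfig(adaptiveWindow = config[[nms[1]]],
                       thresholdCorrection1 = config[[nms[2]]],
                       artifactDiameter = config[[nms[3]]],
                       thresholdCorrection2 = config[[nms[4]]],
                       smoothingSigma = smoothingSigma)
  primary <- segmentPrimary(image, pc)
  secondary <- segmentSecondary(image, primary, pc)
  new("PipelineResult", primary = primary, secondary = secondary,
      measurements = list(primary = measureObjects(primary),
                          secondary = measureObjects(secondary)),
      configuration = unlist(config[nms]))
}
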