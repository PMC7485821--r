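#' Describe a synthetic fluorescence-like scene
#'
#' Declares the content of a generated image of adherent cells: bright
#' elliptical nuclei inside dimmer elliptical cell bodies, small bright
#' elongated puncta (adhesion-like spots) near the cell borders, a linear
#' background gradient, and additive Gaussian noise. Geometry is
#' deliberately simple (ellipses, hard edges): the generator exists to
#' exercise the optimiser with known ground truth, not to be
#' photorealistic.
#'
#' @param imageSize (height, width) in pixels.
#' @param nCells Number of cells to place.
#' @param nucleusAxes (min, max) nucleus semi-axis range, pixels.
#' @param cellScale Cell semi-axes as a multiple of nucleus semi-axes.
#' @param punctaPerCell (min, max) puncta per cell.
#' @param intensities Named levels `background < cell < nucleus <= puncta`.
#' @param noiseSigma Additive Gaussian noise scale.
#' @param gradientStrength Peak-to-peak linear background gradient.
#' @param seed Integer seed; the same spec is bit-reproducible.
#' @return A validated [SceneSpec-class].
#' @export
sceneSpec <- function(imageSize = c(144L, 144L), nCells = 4L,
                      nucleusAxes = c(7, 10), cellScale = 1.9,
                      punctaPerCell = c(2L, 5L),
                      intensities = c(background = 0.06, cell = 0.35,
                                      nucleus = 0.85, puncta = 0.95),
                      noiseSigma = 0.015, gradientStrength = 0.05,
                      seed = 1L) {
  new("SceneSpec", imageSize = as.integer(imageSize),
      nCells = as.integer(nCells), nucleusAxes = as.numeric(nucleusAxes),
      cellScale = as.numeric(cellScale),
      punctaPerCell = as.integer(punctaPerCell),
      intensities = intensities, noiseSigma = as.numeric(noiseSigma),
      gradientStrength = as.numeric(gradientStrength),
      seed = as.integer(seed))
}

#' The default scene of the reference nucleus-segmentation task
#'
#' @param seed Integer seed.
#' @return A [SceneSpec-class] with the package's reference defaults.
#' @export
defaultSceneSpec <- function(seed = 1L) sceneSpec(seed = seed)

#' Search space of the reference nucleus-segmentation task
#'
#' The four tunable settings of the reference pipeline laid out on
#' explicit min/max/interval grids sized for the default synthetic scene.
#'
#' @return A [SearchSpace-class] over [pipelineSettingNames()].
#' @export
defaultSearchSpace <- function() {
  searchSpace(
    parameterSpec("Size of adaptive window", "integer", 17, 97, 8),
    parameterSpec("Threshold correction factor I", "float", 0.6, 2.0, 0.1),
    parameterSpec("Typical artifact diameter", "float", 0, 15, 1),
    parameterSpec("Threshold correction factor II", "float", 0.6, 1.5, 0.1))
}

#' A pipeline configuration known to segment the default scene well
#'
#' Recorded in every generated sample's metadata; it anchors
#' parameter-recovery tests (at this configuration the primary mask's IoU
#' against the nucleus ground truth exceeds 0.8 on default scenes).
#'
#' @return Named numeric configuration on the [defaultSearchSpace()] grid.
#' @export
oracleConfiguration <- function() {
  stats::setNames(c(25, 1.5, 7, 1.0), pipelineSettingNames())
}

ellipseMask <- function(RR, CC, cx, cy, a, b, phi) {
  dx <- RR - cx; dy <- CC - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic sample with ground-truth masks
#'
#' Places `nCells` non-overlapping cell ellipses by rejection sampling
#' (at most 1000 attempts per object), each containing a smaller nucleus
#' ellipse and a few small elongated puncta near the cell border; renders
#' the intensity levels, adds the background gradient and Gaussian noise,
#' and clips to `[0,1]`. The same seed is bit-reproducible.
#'
#' @param spec A [SceneSpec-class].
#' @return A [SyntheticSample-class] with `nucleus`, `cell` and `puncta`
#'   ground-truth masks (nucleus pixelwise inside cell) and placement
#'   metadata.
#' @export
generateSample <- function(spec) {
  validObject(spec)
  H <- spec@imageSize[1]; W <- spec@imageSize[2]
  RR <- matrix(seq_len(H), H, W)
  CC <- matrix(seq_len(W), H, W, byrow = TRUE)

  withSeed(spec@seed, {
    cells <- list()
    for (i in seq_len(spec@nCells)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        a <- stats::runif(1, spec@nucleusAxes[1], spec@nucleusAxes[2])
        b <- stats::runif(1, spec@nucleusAxes[1], a)
        phi <- stats::runif(1, 0, pi)
        Rmax <- spec@cellScale * a
        if (2 * (Rmax + 2) >= min(H, W)) next
        cx <- stats::runif(1, Rmax + 2, H - Rmax - 2)
        cy <- stats::runif(1, Rmax + 2, W - Rmax - 2)
        ok <- TRUE
        for (cl in cells) {
          if (sqrt((cx - cl$cx)^2 + (cy - cl$cy)^2) <
              Rmax + cl$Rmax + 2) { ok <- FALSE; break }
        }
        if (!ok) next
        # nucleus offset inside the cell, capped to keep it contained
        om <- 0.25 * (spec@cellScale - 1) * b
        oang <- stats::runif(1, 0, 2 * pi)
        orad <- stats::runif(1, 0, om)
        cells[[i]] <- list(cx = cx, cy = cy, a = a, b = b, phi = phi,
                           Rmax = Rmax,
                           nx = cx + orad * cos(oang),
                           ny = cy + orad * sin(oang))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place cell ", i, " after 1000 attempts; ",
             "use fewer or smaller cells")
    }

    nucleusMask <- matrix(FALSE, H, W)
    cellMask <- matrix(FALSE, H, W)
    punctaMask <- matrix(FALSE, H, W)
    puncta <- list()
    for (cl in cells) {
      A <- spec@cellScale * cl$a; B <- spec@cellScale * cl$b
      cellMask <- cellMask | ellipseMask(RR, CC, cl$cx, cl$cy, A, B, cl$phi)
      nucleusMask <- nucleusMask |
        ellipseMask(RR, CC, cl$nx, cl$ny, cl$a, cl$b, cl$phi)
      k <- if (spec@punctaPerCell[2] > spec@punctaPerCell[1])
        sample(spec@punctaPerCell[1]:spec@punctaPerCell[2], 1L)
      else spec@punctaPerCell[1]
      placedPts <- list()
      for (p in seq_len(k)) {
        done <- FALSE
        for (attempt in seq_len(1000L)) {
          pa <- stats::runif(1, 1.8, 2.6)
          pb <- stats::runif(1, 0.7, 1.1)
          t <- stats::runif(1, 0, 2 * pi)
          umax <- 1 - (pb + 1) / min(A, B)   # radial extent is the short axis
          if (umax <= 0.45) next
          u <- stats::runif(1, max(0.45, umax - 0.25), umax)
          lx <- u * A * cos(t); ly <- u * B * sin(t)
          px <- cl$cx + lx * cos(cl$phi) - ly * sin(cl$phi)
          py <- cl$cy + lx * sin(cl$phi) + ly * cos(cl$phi)
          # outside the nucleus, and clear of already-placed puncta
          ndx <- px - cl$nx; ndy <- py - cl$ny
          nu <- ndx * cos(cl$phi) + ndy * sin(cl$phi)
          nv <- -ndx * sin(cl$phi) + ndy * cos(cl$phi)
          if ((nu / (cl$a + pb + 0.5))^2 + (nv / (cl$b + pb + 0.5))^2 <= 1)
            next
          ok <- TRUE
          for (q in placedPts)
            if (sqrt((px - q$px)^2 + (py - q$py)^2) < 6) { ok <- FALSE; break }
          if (!ok) next
          pphi <- atan2(ly, lx) + cl$phi + pi / 2  # roughly tangential
          placedPts[[length(placedPts) + 1L]] <-
            list(px = px, py = py, pa = pa, pb = pb, pphi = pphi)
          done <- TRUE
          break
        }
        if (!done)
          stop("could not place punctum after 1000 attempts; ",
               "use fewer puncta or larger cells")
      }
      for (q in placedPts)
        punctaMask <- punctaMask |
          ellipseMask(RR, CC, q$px, q$py, q$pa, q$pb, q$pphi)
      puncta <- c(puncta, placedPts)
    }
    cellMask <- cellMask | nucleusMask   # containment by construction

    it <- spec@intensities
    img <- matrix(it[["background"]], H, W) +
      spec@gradientStrength * ((CC - 1) / max(W - 1, 1) - 0.5)
    img[cellMask] <- it[["cell"]]
    img[nucleusMask] <- it[["nucleus"]]
    img[punctaMask] <- it[["puncta"]]
    if (spec@noiseSigma > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec@noiseSigma), H, W)
    img <- pmin(pmax(img, 0), 1)

    new("SyntheticSample", image = img,
        masks = list(nucleus = nucleusMask, cell = cellMask,
                     puncta = punctaMask),
        metadata = list(spec = spec, cells = cells, puncta = puncta,
                        oracleConfig = oracleConfiguration()))
  })
}

#' Generate a dataset of synthetic samples
#'
#' Samples use consecutive seeds `baseSeed, baseSeed + 1, ...`. When
#' `dir` is given, images (16-bit TIFF) and per-class masks (8-bit 0/255
#' TIFF) are written there with a CSV manifest (path, class, seed).
#'
#' @param spec A [SceneSpec-class] (its own seed is ignored).
#' @param nImages Number of samples (>= 1).
#' @param baseSeed First seed.
#' @param dir Optional output directory.
#' @return List with `samples` (list of [SyntheticSample-class]) and
#'   `manifest` (data frame).
#' @export
generateDataset <- function(spec, nImages, baseSeed = 1L, dir = NULL) {
  if (nImages < 1) stop("nImages must be >= 1")
  nImages <- as.integer(nImages)
  seeds <- as.integer(baseSeed) + seq_len(nImages) - 1L
  samples <- lapply(seeds, function(s) {
    sp <- spec
    sp@seed <- s
    generateSample(sp)
  })
  rows <- list()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nImages)) {
      base <- sprintf("sample_%03d", i)
      ip <- file.path(dir, paste0(base, "_image.tif"))
      writeImageGray(samples[[i]]@image, ip)
      rows[[length(rows) + 1L]] <-
        data.frame(path = ip, class = "image", seed = seeds[i])
      for (cls in names(samples[[i]]@masks)) {
        mp <- file.path(dir, paste0(base, "_", cls, "_mask.tif"))
        writeMask(samples[[i]]@masks[[cls]], mp)
        rows[[length(rows) + 1L]] <-
          data.frame(path = mp, class = cls, seed = seeds[i])
      }
    }
  } else {
    rows <- lapply(seq_len(nImages), function(i)
      data.frame(path = NA_character_, class = "image", seed = seeds[i]))
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(samples = samples, manifest = manifest)
}

#' Simulated rating of a predicted mask against ground truth
#'
#' Stands in for the human rater: the rating is
#' `clamp(1 + round(9 * IoU), 1, 10)` with half-values rounded away from
#' zero, so IoU 0 maps to 1 (poor) and IoU 1 to 10 (excellent).
#' Optionally the rating is perturbed by +/-1 with probability
#' `noiseProb`, emulating human rating variability (and exercising the
#' surrogate's noise variance).
#'
#' @param predicted,truth Binary masks of equal shape.
#' @param noiseProb Probability of a +/-1 rating flip (default 0).
#' @param seed Optional seed for the flip.
#' @return Integer rating in 1-10.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, 1:2] <- TRUE
#' oracleRating(m, m)  # 10
#' @export
oracleRating <- function(predicted, truth, noiseProb = 0, seed = NULL) {
  r <- 1 + roundHalfAway(9 * maskIoU(predicted, truth))
  if (noiseProb > 0) {
    r <- withSeed(seed, {
      if (stats::runif(1) < noiseProb) r + sample(c(-1, 1), 1L) else r
    })
  }
  as.integer(min(max(r, 1), 10))
}

#' Build a simulated-rater evaluator for the optimiser
#'
#' Returns a function taking a [PipelineResult-class] and returning the
#' [oracleRating()] of the chosen predicted mask (primary objects vs the
#' nucleus truth, or secondary vs the cell truth) against the sample's
#' ground truth. Drop-in replacement for a human in [runBO()].
#'
#' @param sample A [SyntheticSample-class].
#' @param objectClass `"nucleus"` (rates the primary mask) or `"cell"`
#'   (rates the secondary mask).
#' @param noiseProb Probability of a +/-1 rating flip per call.
#' @return Evaluator `function(result) -> integer QS`.
#' @export
makeSimulatedRater <- function(sample, objectClass = c("nucleus", "cell"),
                               noiseProb = 0) {
  objectClass <- match.arg(objectClass)
  truth <- sampleMasks(sample, objectClass)
  slot <- if (objectClass == "nucleus") "primary" else "secondary"
  function(result) {
    pred <- methods::slot(result, slot) > 0
    oracleRating(pred, truth, noiseProb = noiseProb)
  }
}
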