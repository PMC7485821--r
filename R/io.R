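#' Read a single-channel grayscale image
#'
#' Reads TIFF or PNG (by extension), normalises integer images to
#' `[0,1]`, and collapses multi-channel files to their first channel with
#' a warning.
#'
#' @param path File path (.tif/.tiff/.png).
#' @return Numeric matrix in `[0,1]`.
#' @export
readImageGray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "' (use TIFF or PNG)"))
  if (length(dim(img)) == 3L) {
    warning("multi-channel image; using the first channel")
    img <- img[, , 1]
  }
  if (max(img) > 1) img <- img / max(img)
  img
}

#' Write a grayscale image as 16-bit TIFF (or PNG)
#'
#' @param image Numeric matrix in `[0,1]`.
#' @param path Output path (.tif/.tiff/.png).
#' @return Invisibly, `path`.
#' @export
writeImageGray <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
    png = png::writePNG(image, path),
    stop("unsupported image format '.", ext, "'"))
  invisible(path)
}

#' Write a mask image
#'
#' Binary masks are written 8-bit 0/255; label masks (maximum label > 1)
#' are written as 16-bit TIFF with the label as the stored intensity.
#'
#' @param mask Logical or integer matrix.
#' @param path Output path (.tif/.tiff/.png).
#' @return Invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  mx <- max(mask)
  if (is.logical(mask) || mx <= 1) {
    img <- (mask > 0) * 1.0
    bits <- 8L
  } else {
    img <- mask / 65535
    bits <- 16L
  }
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = bits),
    png = png::writePNG(img, path),
    stop("unsupported image format '.", ext, "'"))
  invisible(path)
}

#' Read a mask image
#'
#' @param path File path.
#' @param label If TRUE, de-quantise a 16-bit label TIFF back to integer
#'   labels; otherwise return a logical mask of non-zero pixels.
#' @return Logical or integer matrix.
#' @export
readMask <- function(path, label = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "'"))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (label) {
    m <- round(img * 65535)
    storage.mode(m) <- "integer"
    m
  } else img > 0
}

#' Write an outline overlay for rating
#'
#' Paints object outlines from a label mask over the grayscale input and
#' writes the result as PNG: the display payload shown to a rater before
#' each manual rating.
#'
#' @param image Numeric matrix in `[0,1]`.
#' @param mask Integer label mask, same shape.
#' @param path Output PNG path.
#' @param col Outline colour.
#' @return Invisibly, `path`.
#' @export
writeOverlay <- function(image, mask, path, col = "#FFFF00") {
  if (!all(dim(image) == dim(mask)))
    stop("mask shape does not match the image")
  rgb <- EBImage::rgbImage(red = image, green = image, blue = image)
  ov <- EBImage::paintObjects(mask, rgb, col = col)
  EBImage::writeImage(ov, path, type = "png")
  invisible(path)
}

#' Read an optimisation task configuration file
#'
#' YAML with: `search_space` (list of `{name, kind, min, max, interval}`),
#' `target_qs`, `max_iterations`, `bootstrap_count`, `seed`, `evaluator`
#' (`auto`, `manual` or `composite`), optional `weights`
#' (`{automated, manual}`), optional `criteria` (<= 4 entries of
#' `{object, measurement, min, max}`), optional `xi`, `candidate_count`
#' and `gp_bounds` (`{sigma_n, sigma_f, sigma_l}` ranges).
#'
#' @param path YAML file path.
#' @return List with `space` ([SearchSpace-class]), `settings`
#'   ([boSettings()]), `evaluator` (mode string), `criteria` (an
#'   [automatedCriteria()] or NULL) and `weights`.
#' @export
readTaskConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$search_space))
    stop("config must declare a search_space")
  specs <- lapply(cfg$search_space, function(s)
    parameterSpec(s$name, s$kind %||% "float", s$min, s$max, s$interval))
  space <- searchSpace(specs)
  gb <- defaultGPBounds()
  for (nm in names(cfg$gp_bounds %||% list()))
    gb[[nm]] <- as.numeric(cfg$gp_bounds[[nm]])
  settings <- boSettings(
    targetQS = cfg$target_qs %||% 9,
    maxIterations = cfg$max_iterations %||% 30,
    bootstrapCount = cfg$bootstrap_count %||% 2,
    xi = cfg$xi %||% 0.5,
    candidateCount = cfg$candidate_count %||% 2048,
    gpBounds = gb,
    seed = cfg$seed %||% 1L)
  criteria <- NULL
  if (!is.null(cfg$criteria)) {
    crits <- lapply(cfg$criteria, function(cr)
      measurementCriterion(cr$measurement,
                           lower = cr$min %||% -Inf,
                           upper = cr$max %||% Inf))
    criteria <- automatedCriteria(crits,
      targetObject = cfg$criteria[[1]]$object %||% "primary")
  }
  weights <- unlist(cfg$weights %||% c(automated = 0.5, manual = 0.5))
  list(space = space, settings = settings,
       evaluator = cfg$evaluator %||% "manual", criteria = criteria,
       weights = weights)
}
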