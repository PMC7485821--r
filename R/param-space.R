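#' Declare a tunable pipeline setting
#'
#' @param name Setting name (must be unique within a search space).
#' @param kind `"integer"` or `"float"`.
#' @param minimum,maximum Range bounds, `minimum < maximum`.
#' @param interval Positive step laying out the value grid; at most
#'   `maximum - minimum`.
#' @return A validated [ParameterSpec-class].
#' @examples
#' parameterSpec("Threshold correction factor I", "float", 0.6, 1.5, 0.1)
#' @export
parameterSpec <- function(name, kind = c("float", "integer"), minimum,
                          maximum, interval) {
  kind <- match.arg(kind)
  new("ParameterSpec", name = as.character(name), kind = kind,
      minimum = as.numeric(minimum), maximum = as.numeric(maximum),
      interval = as.numeric(interval))
}

#' Assemble and validate a search space
#'
#' @param ... [ParameterSpec-class] objects, or a single list of them.
#' @return A validated [SearchSpace-class].
#' @examples
#' searchSpace(parameterSpec("window", "integer", 3, 11, 2))
#' @export
searchSpace <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) && !is(specs[[1]], "ParameterSpec"))
    specs <- specs[[1]]
  new("SearchSpace", specs = specs)
}

#' Validate a search space
#'
#' Returns the space unchanged when every setting satisfies its invariants;
#' otherwise signals an error naming the offending setting. Validation also
#' runs automatically whenever a [SearchSpace-class] is constructed.
#'
#' @param space A [SearchSpace-class].
#' @return `space`, invisibly unchanged.
#' @export
validateSearchSpace <- function(space) {
  validObject(space)
  space
}

#' Grid of admissible values of one setting
#'
#' Values `minimum, minimum + interval, ...` up to the largest grid point
#' not exceeding `maximum`; `maximum` itself is appended when the last
#' step falls short of it by more than 1e-9, so both bounds are always
#' reachable.
#'
#' @param spec A [ParameterSpec-class].
#' @return Numeric vector of grid values (whole-valued for integer kinds).
#' @examples
#' gridValues(parameterSpec("f", "float", 0.6, 1.5, 0.4))  # 0.6 1.0 1.4 1.5
#' @export
gridValues <- function(spec) {
  stopifnot(is(spec, "ParameterSpec"))
  k <- 0:floor((spec@maximum - spec@minimum) / spec@interval + 1e-9)
  g <- spec@minimum + k * spec@interval
  if (spec@maximum - g[length(g)] > 1e-9) g <- c(g, spec@maximum)
  if (spec@kind == "integer") g <- round(g)
  g
}

checkConfiguration <- function(config, space) {
  nms <- specNames(space)
  if (is.null(names(config)) || !all(nzchar(names(config))))
    stop("configuration values must be named")
  missing <- setdiff(nms, names(config))
  if (length(missing))
    stop("configuration is missing setting(s): ",
         paste(sQuote(missing), collapse = ", "))
  unknown <- setdiff(names(config), nms)
  if (length(unknown))
    stop("unknown setting(s): ", paste(sQuote(unknown), collapse = ", "),
         "; expected: ", paste(sQuote(nms), collapse = ", "))
  invisible(config[nms])
}

#' Encode a configuration into the unit hypercube
#'
#' Component i is `(value_i - min_i) / (max_i - min_i)` in the order of the
#' space's settings, so heterogeneous settings (a window of hundreds of
#' pixels, a correction factor near 1) contribute comparably to kernel
#' distances.
#'
#' @param config Named numeric configuration (one value per setting).
#' @param space A [SearchSpace-class].
#' @return Numeric vector in `[0,1]^d`, named by setting.
#' @seealso [decodeConfiguration()]
#' @export
encodeConfiguration <- function(config, space) {
  config <- checkConfiguration(config, space)
  p <- vapply(seq_along(space@specs), function(i) {
    s <- space@specs[[i]]
    (config[[i]] - s@minimum) / (s@maximum - s@minimum)
  }, numeric(1))
  names(p) <- specNames(space)
  p
}

#' Decode a unit-hypercube point into a configuration
#'
#' De-normalises each coordinate into its setting's range and, by default,
#' snaps to the nearest grid value (midpoint ties break toward the lower
#' value; integer kinds are whole). `snap = FALSE` returns the raw
#' continuous values, used to log the optimiser's continuous proposals.
#'
#' @param point Numeric vector in `[0,1]^d`.
#' @param space A [SearchSpace-class].
#' @param snap Snap to the interval grid (default TRUE).
#' @return Named numeric configuration.
#' @export
decodeConfiguration <- function(point, space, snap = TRUE) {
  d <- spaceDim(space)
  if (length(point) != d)
    stop("point has length ", length(point), ", expected ", d)
  if (any(point < -1e-12 | point > 1 + 1e-12))
    stop("coordinates must lie in [0, 1]")
  point <- pmin(pmax(point, 0), 1)
  v <- vapply(seq_len(d), function(i) {
    s <- space@specs[[i]]
    raw <- s@minimum + point[i] * (s@maximum - s@minimum)
    if (!snap) return(raw)
    g <- gridValues(s)
    g[which.min(abs(g - raw))]   # first minimum = lower value on ties
  }, numeric(1))
  names(v) <- specNames(space)
  v
}

#' Draw random configurations uniformly from the grid
#'
#' Each setting is drawn independently and uniformly from its
#' [gridValues()] grid. Used for the optimiser's bootstrap phase and for
#' the random-search baseline.
#'
#' @param space A [SearchSpace-class].
#' @param n Number of configurations (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   sequence (NULL draws from the current RNG stream).
#' @return List of `n` named numeric configurations.
#' @export
sampleConfigurations <- function(space, n, seed = NULL) {
  validObject(space)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be >= 1")
  n <- as.integer(n)
  grids <- lapply(space@specs, gridValues)
  nms <- specNames(space)
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      v <- vapply(grids, function(g) g[sample.int(length(g), 1L)], numeric(1))
      names(v) <- nms
      v
    })
  })
}

# All grid configurations one step away (per coordinate) from `config`,
# encoded; feeds the acquisition candidate set so EI can refine locally.
gridNeighbours <- function(config, space) {
  config <- checkConfiguration(config, space)
  out <- list()
  for (i in seq_along(space@specs)) {
    g <- gridValues(space@specs[[i]])
    j <- which.min(abs(g - config[[i]]))
    for (k in c(j - 1L, j + 1L)) {
      if (k >= 1L && k <= length(g)) {
        nb <- config
        nb[[i]] <- g[k]
        out[[length(out) + 1L]] <- encodeConfiguration(nb, space)
      }
    }
  }
  out
}
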