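# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Round half away from zero (round() rounds half to even).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

isWhole <- function(x, tol = 1e-9) abs(x - round(x)) <= tol

# Coerce EBImage returns (Image or plain array) back to a base matrix.
asMatrix <- function(x) {
  m <- if (methods::is(x, "Image")) EBImage::imageData(x) else x
  dim(m) <- dim(m)[1:2]
  m
}
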