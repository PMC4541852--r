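#' @importFrom stats pf rnorm runif sd var prcomp plogis dnorm
#' @importFrom utils read.csv write.csv
NULL

# round-half-up on non-negative values (base round() is round-half-even)
.roundHalfUp <- function(x) floor(x + 0.5)

.clip255 <- function(x) pmin(pmax(x, 0), 255)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All package randomness flows through this helper.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# derive k child seeds from one parent seed, all < 2^31
.childSeeds <- function(seed, k) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

.assertRgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop("expected an H x W x 3 RGB array, got dimensions [",
         paste(dim(img), collapse = " x "), "]")
  if (dim(img)[1L] < 2L || dim(img)[2L] < 2L)
    stop("image must be at least 2 x 2 pixels")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("channel values must lie in [0, 255]")
  invisible(img)
}

.assertGray <- function(gray) {
  if (!is.matrix(gray))
    stop("expected an H x W grayscale matrix")
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 255)
    stop("gray values must lie in [0, 255]")
  invisible(gray)
}
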