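# Independent oracles and small fixture builders, shared across test files.

# Brute-force Roberts gradient: explicit double loop applying both 2x2
# masks with edge-replicate padding (independent of the vectorized path).
robertsOracle <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  at <- function(i, j) gray[min(i, h), min(j, w)]
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gx <- at(i, j) - at(i + 1L, j + 1L)
    gy <- at(i, j + 1L) - at(i + 1L, j)
    out[i, j] <- as.integer(min(255, floor(sqrt(gx^2 + gy^2) + 0.5)))
  }
  out
}

# Per-column one-way ANOVA F through R's linear-model machinery
anovaOracleF <- function(x, g) {
  g <- factor(g)
  apply(x, 2L, function(col) {
    tab <- stats::anova(stats::lm(col ~ g))
    tab$`F value`[1L]
  })
}

# flat single-color RGB image
flatRgb <- function(r, g, b, h = 2L, w = 2L) {
  img <- array(0L, dim = c(h, w, 3L))
  img[, , 1L] <- r; img[, , 2L] <- g; img[, , 3L] <- b
  img
}

# small-canvas generator settings: keeps unit tests fast while exercising
# the same rendering code as the full-size defaults
smallParams <- function(preset = "default", ...) {
  generatorParams(preset = preset, imageSize = c(100L, 150L),
                  nOlives = c(6L, 10L), oliveAxes = c(8, 13), ...)
}

# one small default-preset labeled dataset, built once per test run
.fixtureCache <- new.env(parent = emptyenv())
smallDataset <- function() {
  if (is.null(.fixtureCache$fs)) {
    p <- smallParams()
    imgs <- c(lapply(1:10, function(i) generateBatch("tree", p, 300 + i)),
              lapply(1:10, function(i) generateBatch("soil", p, 600 + i)))
    .fixtureCache$fs <- extractFeatures(
      imgs, labels = rep(c("tree", "soil"), each = 10L))
  }
  .fixtureCache$fs
}
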