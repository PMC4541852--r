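#' Construct synthetic-generator parameters
#'
#' The generator emulates the statistical structure of olive-batch
#' photographs: 15-25 smooth-shaded ellipses on a white tray. Tree-picked
#' batches keep the green/purple/black palette and smooth skin;
#' ground-collected batches additionally get (i) a brown shift of the red
#' channel (oxidation), (ii) band-limited multiplicative skin-wrinkle
#' noise that raises Roberts-gradient energy, and (iii) small dark debris
#' spots. The three effects are orthogonal knobs; with all three at zero
#' the two class distributions coincide exactly (the null preset).
#'
#' @param preset \code{"default"} (wrinkle 40, brown shift 50, debris 8),
#'   \code{"null"} (all zero), \code{"texture-only"} (wrinkle 40 only) or
#'   \code{"color-only"} (brown shift 50 only).
#' @param imageSize height and width in pixels (default 240 x 360).
#' @param nOlives inclusive range of olives per batch (default 15-25).
#' @param oliveAxes ellipse semi-axis range in pixels (default 14-24).
#' @param palette 3 x k matrix of RGB base colors; defaults to a green, a
#'   purple and a near-black olive tone.
#' @param wrinkleAmplitude,brownShift,debrisCount explicit effect sizes
#'   overriding the preset (gray levels, gray levels, count).
#' @return a \linkS4class{GeneratorParams}.
#' @export
generatorParams <- function(preset = c("default", "null", "texture-only",
                                       "color-only"),
                            imageSize = c(240L, 360L),
                            nOlives = c(15L, 25L),
                            oliveAxes = c(14, 24),
                            palette = NULL,
                            wrinkleAmplitude = NULL,
                            brownShift = NULL,
                            debrisCount = NULL) {
  preset <- match.arg(preset)
  eff <- switch(preset,
                "default"      = c(40, 50, 8),
                "null"         = c(0, 0, 0),
                "texture-only" = c(40, 0, 0),
                "color-only"   = c(0, 50, 0))
  if (is.null(wrinkleAmplitude)) wrinkleAmplitude <- eff[1L]
  if (is.null(brownShift)) brownShift <- eff[2L]
  if (is.null(debrisCount)) debrisCount <- eff[3L]
  if (is.null(palette))
    palette <- cbind(green = c(85, 120, 50),
                     purple = c(75, 40, 70),
                     black = c(38, 34, 40))
  new("GeneratorParams",
      imageSize = as.integer(imageSize), nOlives = as.integer(nOlives),
      oliveAxes = as.numeric(oliveAxes), palette = palette,
      wrinkleAmplitude = as.numeric(wrinkleAmplitude),
      brownShift = as.numeric(brownShift),
      debrisCount = as.integer(debrisCount))
}

# 3x3 box blur with edge replication; keeps pixel-scale structure while
# removing the roughest white-noise component (band-limited texture)
.boxBlur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- rbind(m[1L, ], m, m[h, ])
  p <- cbind(p[, 1L], p, p[, w])
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[dr + seq_len(h), dc + seq_len(w)]
  acc / 9
}

# rejection-sampled ellipse layout: centers kept inside a margin, pairwise
# bounding-circle separation of at least 75% of the summed radii (allows
# slight overlap, like loosely packed fruit); placement gives up after 150
# attempts and accepts the candidate to guarantee termination
.placeEllipses <- function(n, h, w, axes) {
  margin <- axes[2L] + 2
  out <- matrix(NA_real_, n, 5L,
                dimnames = list(NULL, c("cx", "cy", "a", "b", "phi")))
  for (i in seq_len(n)) {
    for (attempt in 1:150) {
      cx <- stats::runif(1, margin, h - margin)
      cy <- stats::runif(1, margin, w - margin)
      a <- stats::runif(1, axes[1L], axes[2L])
      b <- stats::runif(1, axes[1L], a)        # b <= a: olive-like
      ok <- TRUE
      if (i > 1L) {
        r <- pmax(out[seq_len(i - 1L), "a"], out[seq_len(i - 1L), "b"])
        dd <- sqrt((out[seq_len(i - 1L), "cx"] - cx)^2 +
                   (out[seq_len(i - 1L), "cy"] - cy)^2)
        ok <- all(dd >= 0.75 * (r + max(a, b)))
      }
      if (ok) break
    }
    out[i, ] <- c(cx, cy, a, b, stats::runif(1, 0, pi))
  }
  out
}

#' Generate one synthetic batch image
#'
#' Renders a white-tray batch photograph for the requested class. Both
#' classes share the layout and shading machinery; the ground class then
#' applies the brown shift, the wrinkle texture and the debris spots as
#' configured. Deterministic given (class, params, seed).
#'
#' @param cls \code{"tree"} or \code{"soil"}.
#' @param params a \linkS4class{GeneratorParams}.
#' @param seed integer RNG seed.
#' @return an H x W x 3 integer array in [0, 255].
#' @export
generateBatch <- function(cls = c("tree", "soil"), params = generatorParams(),
                          seed = 1L) {
  cls <- match.arg(cls)
  stopifnot(is(params, "GeneratorParams"))
  validObject(params)
  .withSeed(seed, {
    h <- params@imageSize[1L]; w <- params@imageSize[2L]
    chan <- list(matrix(255, h, w), matrix(255, h, w), matrix(255, h, w))
    mask <- matrix(FALSE, h, w)
    n <- if (params@nOlives[1L] == params@nOlives[2L]) params@nOlives[1L]
         else sample(params@nOlives[1L]:params@nOlives[2L], 1L)
    ell <- .placeEllipses(n, h, w, params@oliveAxes)
    for (i in seq_len(n)) {
      base <- params@palette[, sample.int(ncol(params@palette), 1L)] *
        stats::runif(1, 0.85, 1.15)
      cx <- ell[i, "cx"]; cy <- ell[i, "cy"]
      a <- ell[i, "a"]; b <- ell[i, "b"]; phi <- ell[i, "phi"]
      rmax <- max(a, b)
      rows <- max(1L, floor(cx - rmax)):min(h, ceiling(cx + rmax))
      cols <- max(1L, floor(cy - rmax)):min(w, ceiling(cy + rmax))
      dx <- outer(rows - cx, rep(1, length(cols)))
      dy <- outer(rep(1, length(rows)), cols - cy)
      u <- (dx * cos(phi) + dy * sin(phi)) / a
      v <- (-dx * sin(phi) + dy * cos(phi)) / b
      q <- u^2 + v^2
      inside <- q <= 1
      shade <- 0.72 + 0.48 * (1 - q)   # smooth radial highlight
      for (c3 in 1:3) {
        blk <- chan[[c3]][rows, cols]
        blk[inside] <- (base[c3] * shade)[inside]
        chan[[c3]][rows, cols] <- blk
      }
      mblk <- mask[rows, cols]
      mblk[inside] <- TRUE
      mask[rows, cols] <- mblk
    }
    if (cls == "soil") {
      if (params@brownShift > 0)
        chan[[1L]][mask] <- chan[[1L]][mask] + params@brownShift
      if (params@wrinkleAmplitude > 0) {
        noise <- .boxBlur3(matrix(stats::rnorm(h * w), h, w))
        noise <- noise / stats::sd(noise)
        fac <- 1 + params@wrinkleAmplitude * noise / 255
        for (c3 in 1:3)
          chan[[c3]][mask] <- chan[[c3]][mask] * fac[mask]
      }
      if (params@debrisCount > 0L) {
        for (k in seq_len(params@debrisCount)) {
          r <- stats::runif(1, 2, 5)
          cx <- stats::runif(1, r + 1, h - r - 1)
          cy <- stats::runif(1, r + 1, w - r - 1)
          col <- c(70, 55, 45) * stats::runif(1, 0.7, 1.1)
          rows <- max(1L, floor(cx - r)):min(h, ceiling(cx + r))
          cols <- max(1L, floor(cy - r)):min(w, ceiling(cy + r))
          d2 <- outer((rows - cx)^2, rep(1, length(cols))) +
                outer(rep(1, length(rows)), (cols - cy)^2)
          inside <- d2 <= r^2
          for (c3 in 1:3) {
            blk <- chan[[c3]][rows, cols]
            blk[inside] <- col[c3]
            chan[[c3]][rows, cols] <- blk
          }
        }
      }
    }
    img <- array(0L, dim = c(h, w, 3L))
    for (c3 in 1:3)
      img[, , c3] <- as.integer(.clip255(.roundHalfUp(chan[[c3]])))
    img
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes \code{2 * nPerClass} 8-bit PNG batch images (balanced classes)
#' and a \code{path,label} manifest CSV into \code{outDir}. Per-image
#' seeds are derived from \code{seed}, so two runs with the same arguments
#' produce pixel-identical images and identical manifests.
#'
#' @param nPerClass images per class (at least 2).
#' @param params a \linkS4class{GeneratorParams}.
#' @param seed integer RNG seed.
#' @param outDir output directory, created if missing.
#' @return invisibly, the manifest data.frame (with paths relative to
#'   \code{outDir}); the manifest file is \code{file.path(outDir,
#'   "manifest.csv")}.
#' @export
generateDataset <- function(nPerClass, params = generatorParams(),
                            seed = 1L, outDir) {
  nPerClass <- as.integer(nPerClass)
  if (nPerClass < 2L) stop("nPerClass must be at least 2")
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  seeds <- .childSeeds(seed, 2L * nPerClass)
  cls <- rep(c("tree", "soil"), each = nPerClass)
  fname <- sprintf("%s_%03d.png", cls, c(seq_len(nPerClass),
                                         seq_len(nPerClass)))
  for (i in seq_along(fname)) {
    img <- generateBatch(cls[i], params, seeds[i])
    png::writePNG(img / 255, target = file.path(outDir, fname[i]))
  }
  manifest <- data.frame(path = fname,
                         label = ifelse(cls == "tree", "tree", "soil"))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
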