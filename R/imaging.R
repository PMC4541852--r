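#' Convert an RGB batch image to grayscale
#'
#' Luma conversion with ITU-R BT.601 weights:
#' \eqn{0.299 R + 0.587 G + 0.114 B}, rounded half-up and clipped to
#' [0, 255].
#'
#' @param img an H x W x 3 array of channel intensities in [0, 255].
#' @return an H x W integer matrix of gray levels.
#' @examples
#' img <- array(c(200, 120, 80), dim = c(1, 1, 3))
#' # 2 x 2 copy of the same pixel
#' img <- array(rep(c(200, 120, 80), each = 4), dim = c(2, 2, 3))
#' toGrayscale(img)
#' @export
toGrayscale <- function(img) {
  .assertRgb(img)
  g <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  matrix(as.integer(.clip255(.roundHalfUp(g))), nrow = dim(img)[1L])
}

#' Roberts-operator gradient magnitude image
#'
#' Applies the two 2 x 2 Roberts cross masks to a grayscale image and
#' returns the per-pixel gradient magnitude
#' \eqn{\sqrt{G_x^2 + G_y^2}} with
#' \eqn{G_x(x,y) = I(x,y) - I(x+1,y+1)} and
#' \eqn{G_y(x,y) = I(x,y+1) - I(x+1,y)} (x = row, y = column, origin
#' top-left). The last row and column are computed with edge-replicate
#' padding so the output matches the input size; magnitudes are rounded
#' half-up and clipped at 255. Wrinkled olive skin produces high gradient
#' energy; smooth skin and constant background produce zero.
#'
#' @param gray an H x W matrix of gray levels in [0, 255], H, W >= 2.
#' @return an H x W integer matrix of gradient magnitudes in [0, 255].
#' @examples
#' robertsGradient(matrix(c(5, 0, 0, 0), 2, 2, byrow = TRUE))
#' @export
robertsGradient <- function(gray) {
  .assertGray(gray)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 2L || w < 2L)
    stop("Roberts masks need a 2 x 2 neighborhood; image is ",
         h, " x ", w)
  pad <- rbind(gray, gray[h, ])
  pad <- cbind(pad, pad[, w])
  gx <- pad[1:h, 1:w] - pad[2:(h + 1L), 2:(w + 1L)]
  gy <- pad[1:h, 2:(w + 1L)] - pad[2:(h + 1L), 1:w]
  g <- .roundHalfUp(sqrt(gx^2 + gy^2))
  matrix(as.integer(pmin(g, 255)), nrow = h)
}

#' Channel-difference image
#'
#' Per-pixel difference between the red channel and the green
#' (\code{pair = "rg"}) or blue (\code{pair = "rb"}) channel, with negative
#' values clipped to 0. Large positive differences mark the brownish tones
#' of oxidized, ground-collected fruit.
#'
#' @param img an H x W x 3 array of channel intensities in [0, 255].
#' @param pair \code{"rg"} for red minus green, \code{"rb"} for red minus
#'   blue.
#' @return an H x W integer matrix in [0, 255].
#' @examples
#' px <- array(rep(c(200, 120, 80), each = 4), dim = c(2, 2, 3))
#' channelDifference(px, "rg")[1, 1]  # 80
#' channelDifference(px, "rb")[1, 1]  # 120
#' @export
channelDifference <- function(img, pair = c("rg", "rb")) {
  .assertRgb(img)
  pair <- match.arg(pair)
  other <- if (pair == "rg") 2L else 3L
  d <- img[, , 1L] - img[, , other]
  matrix(as.integer(pmax(d, 0)), nrow = dim(img)[1L])
}

#' Derive the three analysis images of one batch photograph
#'
#' Computes the Roberts texture gradient of the grayscale conversion and
#' the two channel-difference images from a single RGB batch image.
#'
#' @param img an H x W x 3 array of channel intensities in [0, 255].
#' @return a \linkS4class{ProcessedTriple}.
#' @examples
#' img <- array(255, dim = c(4, 4, 3))  # blank white tray
#' processSample(img)
#' @export
processSample <- function(img) {
  .assertRgb(img)
  new("ProcessedTriple",
      gradient = robertsGradient(toGrayscale(img)),
      crg = channelDifference(img, "rg"),
      crb = channelDifference(img, "rb"))
}
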