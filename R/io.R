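#' Read a batch photograph from disk
#'
#' Decodes a PNG, TIFF or JPEG image into the H x W x 3 integer array the
#' pipeline works on. An alpha channel, if present, is dropped; grayscale
#' images are replicated across the three channels; 16-bit inputs are
#' rejected.
#'
#' @param path path to a \code{.png}, \code{.tif(f)}, \code{.jpg} or
#'   \code{.jpeg} file.
#' @return an H x W x 3 array of integers in [0, 255].
#' @export
readBatchImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8L)
      stop("16-bit PNG images are not supported: ", path)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (!is.null(bits) && any(bits > 8L))
      stop("16-bit TIFF images are not supported: ", path)
  } else if (ext %in% c("jpg", "jpeg")) {
    raw <- jpeg::readJPEG(path)
  } else {
    stop("unsupported image format '.", ext, "': ", path)
  }
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  nc <- dim(raw)[3L]
  if (nc == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  else if (nc == 2L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]  # gray+alpha
  else if (nc >= 4L) raw <- raw[, , 1:3, drop = FALSE]            # drop alpha
  img <- .roundHalfUp(raw[, , 1:3, drop = FALSE] * 255)
  storage.mode(img) <- "integer"
  .assertRgb(img)
  img
}

#' Read and validate a dataset manifest
#'
#' A manifest is a CSV file with header \code{path,label} mapping one image
#' file per row to its class, \code{tree} or \code{soil}. Relative image
#' paths are resolved against the manifest's directory.
#'
#' @param path path to the manifest CSV.
#' @return a data.frame with columns \code{path} (absolute) and
#'   \code{label} (factor soil/tree).
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df)))
    stop("manifest must have columns 'path' and 'label': ", path)
  bad <- which(!df$label %in% c("tree", "soil"))
  if (length(bad))
    stop("manifest row ", bad[1L] + 1L, " has unknown label '",
         df$label[bad[1L]], "'; allowed labels are 'tree' and 'soil'")
  rel <- !file.exists(df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  missing <- which(!file.exists(df$path))
  if (length(missing))
    stop("manifest row ", missing[1L] + 1L, " points to a missing image: ",
         df$path[missing[1L]])
  df$label <- factor(df$label, levels = c("soil", "tree"))
  df
}
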