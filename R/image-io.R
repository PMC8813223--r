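# Images are plain numeric arrays [height, width, channels] with values in
# [0, 1]; single-channel images may also arrive as bare [H, W] matrices.

#' Read an image file into an [H, W, C] array
#'
#' PNG files are read natively; other raster formats (JPEG, TIFF) go through
#' EBImage. Pixel values are rescaled to `[0, 1]` doubles; palette/alpha
#' channels are not supported.
#'
#' @param path Image file path.
#' @return Numeric array `[H, W, C]` with `C` 1 or 3.
#' @export
read_ortho_image <- function(path) {
  if (!file.exists(path)) {
    abort_fmt("orthoarc_io_error", paste0("image not found: ", path))
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    eb <- EBImage::readImage(path)
    d <- dim(eb)
    img <- if (length(d) == 2) t(EBImage::imageData(eb)) else aperm(EBImage::imageData(eb), c(2, 1, 3))
  }
  as_image_array(img)
}

#' Write an [H, W, C] array as PNG
#'
#' @param img Image array (values clipped to `[0, 1]`).
#' @param path Output path (created directories permitting).
#' @return `path`, invisibly.
#' @export
write_ortho_image <- function(img, path) {
  img <- as_image_array(img)
  img[img < 0] <- 0
  img[img > 1] <- 1
  if (dim(img)[3] == 1) img <- img[, , 1]
  png::writePNG(img, path)
  invisible(path)
}

#' Coerce to a canonical [H, W, C] image array
#' @keywords internal
as_image_array <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  if (length(d) != 3 || !(d[3] %in% c(1L, 3L))) {
    if (length(d) == 3 && d[3] == 4) { # drop alpha
      img <- img[, , 1:3, drop = FALSE]
    } else {
      abort_fmt("orthoarc_format_error",
                paste0("expected 1 or 3 channels, got dims ", paste(d, collapse = "x")))
    }
  }
  storage.mode(img) <- "double"
  img
}

#' @keywords internal
image_height <- function(img) dim(as_image_array(img))[1]

#' @keywords internal
image_width <- function(img) dim(as_image_array(img))[2]

#' Resize an image array with bilinear filtering
#' @keywords internal
resize_image <- function(img, width, height) {
  img <- as_image_array(img)
  if (image_width(img) == width && image_height(img) == height) return(img)
  eb <- EBImage::Image(aperm(img, c(2, 1, 3)),
                       colormode = if (dim(img)[3] == 3) "Color" else "Grayscale")
  out <- EBImage::resize(eb, w = width, h = height)
  res <- aperm(EBImage::imageData(out), c(2, 1, 3))
  res[res < 0] <- 0
  res[res > 1] <- 1
  res
}
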