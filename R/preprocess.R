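# Preprocessing stage: grayscale tagging, the radiograph aspect-ratio rule,
# standardised resizing/orientation, and pluggable face detection. Grayscale
# images bypass the network entirely; colour photographs are standardised,
# optionally face-cropped, and handed to the classifier.

#' Is an image grayscale?
#'
#' Radiographs are stored single-channel, which is what routes them to the
#' aspect-ratio rule instead of the network. Three-channel images whose
#' channels are identical at every pixel also count as grayscale, because
#' real exports often save radiographs as RGB.
#'
#' @param img Image array (`[H, W]`, `[H, W, 1]` or `[H, W, 3]`).
#' @return `TRUE` iff the image carries no colour information.
#' @export
tag_grayscale <- function(img) {
  img <- as_image_array(img)
  ch <- dim(img)[3]
  if (ch == 1) return(TRUE)
  identical(img[, , 1], img[, , 2]) && identical(img[, , 2], img[, , 3])
}

#' Aspect-ratio rule for radiograph classification
#'
#' Lateral cephalograms print at roughly 1.2:1 (width:height) and panoramic
#' radiographs at roughly 2:1. The decision boundary defaults to the midpoint
#' 1.6; ratios at or above it classify as panoramic.
#'
#' @param lateral_ratio,panoramic_ratio Prototype ratios.
#' @param threshold Decision boundary; must sit strictly between the two
#'   prototypes.
#' @return An `aspect_rule` list.
#' @export
aspect_rule <- function(lateral_ratio = 1.2, panoramic_ratio = 2.0,
                        threshold = (lateral_ratio + panoramic_ratio) / 2) {
  if (!(lateral_ratio < threshold && threshold < panoramic_ratio)) {
    abort_fmt("orthoarc_validation_error",
              "aspect rule needs lateral_ratio < threshold < panoramic_ratio")
  }
  structure(list(lateral_ratio = lateral_ratio, panoramic_ratio = panoramic_ratio,
                 threshold = threshold), class = "aspect_rule")
}

#' Classify a grayscale image as lateral cephalogram or panoramic radiograph
#'
#' @param width,height Pixel dimensions (vectors allowed).
#' @param rule An [aspect_rule()].
#' @return Character vector of radiograph category labels. Portrait inputs
#'   (ratio below 1) raise a warning and are assigned the nearest prototype.
#' @export
#' @examples
#' classify_radiograph(360, 300) # lateral_cephalogram
#' classify_radiograph(600, 300) # panoramic_radiograph
classify_radiograph <- function(width, height, rule = aspect_rule()) {
  stopifnot(all(width > 0), all(height > 0))
  ratio <- width / height
  if (any(ratio < 1)) {
    warning("portrait grayscale image(s) (width < height); classified by nearest prototype ratio",
            call. = FALSE)
  }
  out <- ifelse(ratio < rule$threshold, "lateral_cephalogram", "panoramic_radiograph")
  # portrait inputs: nearest prototype (always the lateral one for ratio < 1,
  # kept explicit for clarity)
  portrait <- ratio < 1
  if (any(portrait)) {
    nearer_lat <- abs(ratio - rule$lateral_ratio) <= abs(ratio - rule$panoramic_ratio)
    out[portrait] <- ifelse(nearer_lat[portrait], "lateral_cephalogram", "panoramic_radiograph")
  }
  out
}

#' Standardise a photograph to 450x300 or 300x450
#'
#' Landscape images (width >= height, squares counted as landscape) are
#' resized to 450x300 pixels, portrait ones to 300x450, by direct bilinear
#' resize without padding. With `force_landscape = TRUE` a portrait image is
#' first rotated 90 degrees — the orientation normalisation applied to
#' intraoral photographs that were captured or scanned sideways.
#' The operation is idempotent: an image already at its target size is
#' returned unchanged.
#'
#' @param img Image array.
#' @param force_landscape Rotate portrait input to landscape first.
#' @return Standardised image array.
#' @export
standardize_image <- function(img, force_landscape = FALSE) {
  img <- as_image_array(img)
  if (force_landscape && image_height(img) > image_width(img)) {
    img <- rotate90(img)
  }
  landscape <- image_width(img) >= image_height(img)
  if (landscape) resize_image(img, 450, 300) else resize_image(img, 300, 450)
}

#' @keywords internal
rotate90 <- function(img) {
  img <- as_image_array(img)
  # clockwise: new[h', w'] = old[H - w', h']
  aperm(img[rev(seq_len(dim(img)[1])), , , drop = FALSE], c(2, 1, 3))
}

#' Built-in bright-blob face detector
#'
#' Detector contract: a detector is a function taking an image array and
#' returning a tibble with columns `x`, `y`, `w`, `h`, `confidence`
#' (0-based top-left origin, half-open boxes). This default implementation
#' thresholds luminance halfway between the image extremes and returns the
#' bounding box of the largest bright connected component — adequate for the
#' synthetic fixtures, where the face (or tooth row) is the dominant bright
#' region. Production deployments are expected to plug in a trained
#' single-shot detector behind the same contract.
#'
#' @param min_area_frac Components smaller than this fraction of the image
#'   are ignored.
#' @param min_range Minimum luminance range below which the image is treated
#'   as blank (no detection).
#' @return A detector function.
#' @export
detector_brightblob <- function(min_area_frac = 0.01, min_range = 0.1) {
  function(img) {
    img <- as_image_array(img)
    lum <- if (dim(img)[3] == 3) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img[, , 1]
    rng <- range(lum)
    empty <- tibble::tibble(x = integer(), y = integer(), w = integer(), h = integer(),
                            confidence = numeric())
    if (diff(rng) < min_range) return(empty)
    mask <- lum > mean(rng)
    labels <- EBImage::bwlabel(EBImage::Image(t(mask)))
    lab <- EBImage::imageData(labels)
    if (max(lab) == 0) return(empty)
    areas <- tabulate(lab[lab > 0])
    big <- which.max(areas)
    if (areas[big] < min_area_frac * length(lum)) return(empty)
    hit <- which(t(lab) == big, arr.ind = TRUE) # rows = image rows
    y0 <- min(hit[, 1]) - 1L
    x0 <- min(hit[, 2]) - 1L
    tibble::tibble(
      x = x0, y = y0,
      w = max(hit[, 2]) - x0, h = max(hit[, 1]) - y0,
      confidence = areas[big] / length(lum)
    )
  }
}

#' Passthrough detector returning precomputed boxes
#'
#' Wraps externally supplied detections (e.g. from an offline face detector)
#' in the detector contract.
#'
#' @param x,y,w,h,confidence Box parameters (0-based top-left origin).
#' @return A detector function that ignores its image argument.
#' @export
detector_fixed <- function(x, y, w, h, confidence = 1) {
  box <- tibble::tibble(x = x, y = y, w = w, h = h, confidence = confidence)
  function(img) box
}

#' Detect the face region of a photograph
#'
#' Runs the detector and returns its highest-confidence box, clipped to the
#' image bounds. When the detector reports nothing the photograph bypasses
#' the face crop and the full standardised image goes to classification.
#'
#' @param img RGB image array.
#' @param detector A detector function (see [detector_brightblob()]).
#' @return A `face_box` list (`x`, `y`, `w`, `h`, `confidence`) or `NULL`.
#' @export
detect_face_region <- function(img, detector = detector_brightblob()) {
  img <- as_image_array(img)
  boxes <- tryCatch(detector(img), error = function(e) {
    abort_fmt("orthoarc_detection_error", paste0("face detector failed: ", conditionMessage(e)))
  })
  if (is.null(boxes) || nrow(boxes) == 0) return(NULL)
  b <- boxes[which.max(boxes$confidence), ]
  H <- image_height(img); W <- image_width(img)
  x <- max(0L, as.integer(b$x)); y <- max(0L, as.integer(b$y))
  w <- min(as.integer(b$w), W - x); h <- min(as.integer(b$h), H - y)
  if (w <= 0 || h <= 0) return(NULL)
  structure(list(x = x, y = y, w = w, h = h, confidence = b$confidence),
            class = "face_box")
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes as lists with `x`, `y`, `w`, `h` (half-open).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  if (union <= 0) 0 else inter / union
}

#' Crop an image to a face box
#' @param img Image array.
#' @param box A `face_box` (or any list with `x`, `y`, `w`, `h`).
#' @return Cropped image array.
#' @export
crop_box <- function(img, box) {
  img <- as_image_array(img)
  img[(box$y + 1):(box$y + box$h), (box$x + 1):(box$x + box$w), , drop = FALSE]
}

#' Standardise, face-crop and resize a photograph for the network
#'
#' The full preprocessing path for one RGB photograph: standardise to
#' 450x300/300x450, detect the face region, crop it when found, and resize to
#' the square network input.
#'
#' @param img RGB image array.
#' @param input_size Side length of the network input (pixels).
#' @param detector Face detector (see [detector_brightblob()]).
#' @param force_landscape Passed to [standardize_image()].
#' @return `[input_size, input_size, 3]` array.
#' @export
prepare_for_net <- function(img, input_size = 150,
                            detector = detector_brightblob(),
                            force_landscape = FALSE) {
  std <- standardize_image(img, force_landscape = force_landscape)
  box <- detect_face_region(std, detector)
  if (!is.null(box)) std <- crop_box(std, box)
  resize_image(std, input_size, input_size)
}
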