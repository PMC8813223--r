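#' The 14 orthodontic image categories
#'
#' Every patient record in routine orthodontic practice comprises fourteen
#' images: six extraoral photographs (frontal, oblique and profile views, each
#' at rest and smiling), six intraoral photographs (right, front and left
#' views, the two mirror-captured occlusal views, and an overjet close-up),
#' and two radiographs (lateral cephalogram and panoramic radiograph). The
#' order returned here is fixed and is used for category indices, array
#' layouts and tie-breaking throughout the package: `frontal_rest` has index
#' 1 and `panoramic_radiograph` index 14.
#'
#' @param which `"all"` (default), `"rgb"` for the 12 photograph classes, or
#'   `"radiograph"` for the two grayscale classes.
#' @return Character vector of category labels in canonical order.
#' @export
#' @examples
#' ortho_categories("radiograph")
ortho_categories <- function(which = c("all", "rgb", "radiograph")) {
  which <- match.arg(which)
  switch(which,
    all = .CATEGORIES,
    rgb = .CATEGORIES[1:12],
    radiograph = .CATEGORIES[13:14]
  )
}

.CATEGORIES <- c(
  "frontal_rest", "frontal_smile",
  "oblique_rest", "oblique_smile",
  "profile_rest", "profile_smile",
  "intraoral_right", "intraoral_front", "intraoral_left",
  "maxillary_occlusal", "mandibular_occlusal",
  "overjet",
  "lateral_cephalogram", "panoramic_radiograph"
)

.OCCLUSAL <- c("maxillary_occlusal", "mandibular_occlusal")

#' Canonical index of a category label
#'
#' @param category Character vector of category labels (or `"unknown"`).
#' @return Integer vector: 1-based position in [ortho_categories()]; `NA` for
#'   `"unknown"`.
#' @export
category_index <- function(category) {
  bad <- !(category %in% c(.CATEGORIES, "unknown", NA_character_))
  if (any(bad)) {
    rlang::abort(
      paste0("unknown category label(s): ", paste(unique(category[bad]), collapse = ", ")),
      class = "orthoarc_validation_error"
    )
  }
  match(category, .CATEGORIES)
}

#' @keywords internal
is_occlusal <- function(category) category %in% .OCCLUSAL
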