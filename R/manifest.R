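#' @importFrom rlang .data
#' @import tibble
NULL

abort_fmt <- function(class, msg) rlang::abort(msg, class = class)

#' Build a cohort manifest tibble
#'
#' A manifest is an ordinary tibble (one row per image) carrying the columns
#' `patient_id`, `path`, `category`, `qc_flags`, plus lazily filled
#' `width`, `height`, `channels` and `predicted_category`. `qc_flags` is a
#' semicolon-separated string drawn from `"blurred"` and `"nonconforming"`
#' (empty string = passed review). All manifest-consuming functions accept any
#' data frame with these columns, so manifests compose with dplyr verbs.
#'
#' @param patient_id,path Character vectors (paths must be unique).
#' @param category Category labels or `"unknown"`.
#' @param qc_flags Semicolon-separated flag strings, `""` for clean records.
#' @param cohort_name Optional cohort tag stored in the `cohort` column.
#' @return A manifest tibble.
#' @export
manifest <- function(patient_id, path, category = "unknown", qc_flags = "",
                     cohort_name = NA_character_) {
  m <- tibble::tibble(
    patient_id = as.character(patient_id),
    path = as.character(path),
    category = as.character(category),
    qc_flags = as.character(qc_flags),
    width = NA_integer_,
    height = NA_integer_,
    channels = NA_integer_,
    predicted_category = NA_character_,
    cohort = cohort_name
  )
  validate_manifest(m)
}

#' Validate manifest invariants
#'
#' Checks that every record has a nonempty patient id, that file paths are
#' unique within the manifest, and that every category is one of the 14
#' labels or `"unknown"`.
#'
#' @param m A manifest data frame.
#' @return `m` as a tibble, invisibly validated.
#' @export
validate_manifest <- function(m) {
  m <- tibble::as_tibble(m)
  if (nrow(m) == 0) return(m)
  if (any(is.na(m$patient_id) | m$patient_id == "")) {
    abort_fmt("orthoarc_validation_error", "every record needs a nonempty patient_id")
  }
  dup <- m$path[duplicated(m$path)]
  if (length(dup) > 0) {
    abort_fmt(
      "orthoarc_validation_error",
      paste0("duplicate path(s) in manifest: ", paste(utils::head(unique(dup), 3), collapse = ", "))
    )
  }
  category_index(m$category) # errors on unknown labels
  m
}

#' Read a manifest CSV
#'
#' The on-disk format is UTF-8 CSV with a header and columns `patient_id`,
#' `path`, and optionally `category` and `qc_flags` (semicolon-separated).
#' Missing optional columns are filled with `"unknown"` / `""`.
#'
#' @param csv_path Path to the manifest CSV.
#' @param cohort_name Optional cohort tag.
#' @return A manifest tibble.
#' @export
load_manifest <- function(csv_path, cohort_name = NA_character_) {
  if (!file.exists(csv_path)) {
    abort_fmt("orthoarc_io_error", paste0("manifest not found: ", csv_path))
  }
  raw <- readr::read_csv(csv_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("patient_id", "path")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort_fmt(
      "orthoarc_format_error",
      paste0("manifest CSV lacks required column(s): ", paste(missing, collapse = ", "))
    )
  }
  manifest(
    patient_id = raw$patient_id,
    path = raw$path,
    category = if ("category" %in% names(raw)) dplyr::coalesce(raw$category, "unknown") else "unknown",
    qc_flags = if ("qc_flags" %in% names(raw)) dplyr::coalesce(raw$qc_flags, "") else "",
    cohort_name = cohort_name
  )
}

#' Write a manifest CSV
#'
#' @param m Manifest tibble.
#' @param csv_path Output path.
#' @return `csv_path`, invisibly.
#' @export
write_manifest <- function(m, csv_path) {
  readr::write_csv(m[, c("patient_id", "path", "category", "qc_flags")], csv_path,
                   progress = FALSE)
  invisible(csv_path)
}

#' Partition a manifest by quality-control flags
#'
#' QC review in the source workflow is manual, so flags are taken from the
#' manifest as given, never computed from pixels. A record is kept iff its
#' `qc_flags` field is empty.
#'
#' @param m Manifest tibble.
#' @return Named list with manifest tibbles `kept` and `excluded`;
#'   `nrow(kept) + nrow(excluded) == nrow(m)` always.
#' @export
#' @examples
#' m <- manifest(c("p1", "p2"), c("a.png", "b.png"), qc_flags = c("", "blurred"))
#' qc_filter(m)$excluded$path
qc_filter <- function(m) {
  m <- tibble::as_tibble(m)
  flagged <- !is.na(m$qc_flags) & m$qc_flags != ""
  list(kept = m[!flagged, , drop = FALSE], excluded = m[flagged, , drop = FALSE])
}

#' Stratified per-category holdout split
#'
#' Draws exactly `n_per_category` records of every category present in `m`
#' into a validation manifest, uniformly without replacement, and returns the
#' remainder as training. To make the split reproducible across platforms the
#' records of each category are ordered by path before shuffling and a single
#' seed drives all draws.
#'
#' @param m Manifest tibble with known categories.
#' @param n_per_category Validation images per category.
#' @param seed Integer seed.
#' @return List with manifest tibbles `train` and `validation` (disjoint by
#'   path, union equal to `m`).
#' @export
stratified_holdout <- function(m, n_per_category, seed) {
  m <- tibble::as_tibble(m)
  cats <- unique(m$category)
  cats <- cats[cats != "unknown" & !is.na(cats)]
  cats <- cats[order(category_index(cats))]
  counts <- table(factor(m$category, levels = cats))
  short <- names(counts)[counts < n_per_category]
  if (length(short) > 0) {
    abort_fmt(
      "orthoarc_insufficient_data_error",
      paste0(
        "category(ies) with fewer than ", n_per_category, " records: ",
        paste(short, collapse = ", ")
      )
    )
  }
  val_paths <- withr::with_seed(seed, {
    unlist(lapply(cats, function(ct) {
      p <- sort(m$path[m$category == ct])
      sample(p, n_per_category)
    }), use.names = FALSE)
  })
  in_val <- m$path %in% val_paths
  list(train = m[!in_val, , drop = FALSE], validation = m[in_val, , drop = FALSE])
}

#' Patient-level holdout split
#'
#' Alternative split that holds out whole patients rather than images, for
#' workflows where the validation unit is the case. Patients are ordered by
#' id before the seeded draw.
#'
#' @param m Manifest tibble.
#' @param n_patients Number of patients to hold out.
#' @param seed Integer seed.
#' @return List with manifest tibbles `train` and `validation`.
#' @export
patient_holdout <- function(m, n_patients, seed) {
  m <- tibble::as_tibble(m)
  ids <- sort(unique(m$patient_id))
  if (length(ids) < n_patients) {
    abort_fmt("orthoarc_insufficient_data_error",
              paste0("only ", length(ids), " patients available, need ", n_patients))
  }
  val_ids <- withr::with_seed(seed, sample(ids, n_patients))
  in_val <- m$patient_id %in% val_ids
  list(train = m[!in_val, , drop = FALSE], validation = m[in_val, , drop = FALSE])
}
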