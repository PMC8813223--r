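# Postprocessing stage: mirror-flip of occlusal photographs, per-patient
# integrity audit (duplicate / missing category slots), and the archiving
# table handed to human reviewers.

#' Horizontally mirror an image
#'
#' Occlusal photographs are taken through an intraoral mirror and arrive
#' left-right reversed; the pipeline applies this flip to every image whose
#' predicted label is maxillary or mandibular occlusal. The operation is an
#' involution and preserves dimensions and channel count.
#'
#' @param img Image array (`[H, W]` matrices allowed).
#' @return Image with column order reversed, same shape as the input.
#' @export
#' @examples
#' mirror_flip(matrix(1:6, 2, byrow = TRUE))
mirror_flip <- function(img) {
  if (is.matrix(img)) return(img[, rev(seq_len(ncol(img))), drop = FALSE])
  img <- as_image_array(img)
  img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
}

#' Group classified records into per-patient case archives
#'
#' @param classified Data frame with columns `patient_id`, `path` and a label
#'   column (`predicted_category` by default, falling back to `category`).
#' @param label_col Which column holds the category assignment.
#' @return List of `case_archive` objects, one per patient (sorted by id),
#'   each mapping every one of the 14 category slots to its (possibly empty)
#'   list of paths.
#' @export
case_archives <- function(classified, label_col = NULL) {
  df <- tibble::as_tibble(classified)
  if (is.null(label_col)) {
    label_col <- if ("predicted_category" %in% names(df) &&
                     !all(is.na(df$predicted_category))) "predicted_category" else "category"
  }
  labs <- df[[label_col]]
  if (any(is.na(labs) | !(labs %in% .CATEGORIES))) {
    abort_fmt("orthoarc_validation_error",
              "every record needs an assigned category before archiving")
  }
  lapply(split(df, df$patient_id)[sort(unique(df$patient_id))], function(p) {
    slots <- lapply(.CATEGORIES, function(ct) p$path[p[[label_col]] == ct])
    names(slots) <- .CATEGORIES
    structure(list(patient_id = p$patient_id[1], slots = slots), class = "case_archive")
  })
}

#' Per-patient and cohort integrity report
#'
#' A complete case holds exactly one image in each of the 14 category slots.
#' Surplus images in a slot are duplicates, empty slots are missing. Cohort
#' totals always satisfy `images = 14 * patients + duplicates - missing`.
#'
#' @param archives List of `case_archive` objects (see [case_archives()]), or
#'   a classified data frame which is grouped first.
#' @param label_col Passed to [case_archives()] when `archives` is a data
#'   frame.
#' @return An `integrity_report`: list with `per_patient` (tibble: patient_id,
#'   n_images, duplicates, missing, missing_categories, duplicate_categories,
#'   complete) and `totals` (patients, images, duplicates, missing,
#'   complete_cases).
#' @export
integrity_check <- function(archives, label_col = NULL) {
  if (is.data.frame(archives)) archives <- case_archives(archives, label_col)
  per <- purrr::map_dfr(archives, function(a) {
    counts <- vapply(a$slots, length, integer(1))
    dup <- pmax(counts - 1L, 0L)
    mis <- counts == 0L
    tibble::tibble(
      patient_id = a$patient_id,
      n_images = sum(counts),
      duplicates = sum(dup),
      missing = sum(mis),
      missing_categories = paste(names(counts)[mis], collapse = ";"),
      duplicate_categories = paste(
        sprintf("%s(%d)", names(counts)[dup > 0], counts[dup > 0]), collapse = ";"),
      complete = sum(dup) == 0L && !any(mis)
    )
  })
  if (nrow(per) == 0) {
    per <- tibble::tibble(patient_id = character(), n_images = integer(),
                          duplicates = integer(), missing = integer(),
                          missing_categories = character(),
                          duplicate_categories = character(), complete = logical())
  }
  totals <- list(
    patients = nrow(per),
    images = sum(per$n_images),
    duplicates = sum(per$duplicates),
    missing = sum(per$missing),
    complete_cases = sum(per$complete)
  )
  structure(list(per_patient = per, totals = totals), class = "integrity_report")
}

#' @export
print.integrity_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<integrity_report> %d patients, %d images | duplicates %d, missing %d, complete cases %d\n",
    t$patients, t$images, t$duplicates, t$missing, t$complete_cases))
  invisible(x)
}

#' Tidy an integrity report
#'
#' @param x An `integrity_report`.
#' @param ... Unused.
#' @return The per-patient findings tibble.
#' @export
tidy.integrity_report <- function(x, ...) x$per_patient

#' One-row cohort summary of an integrity report
#'
#' @param x An `integrity_report`.
#' @param ... Unused.
#' @return Tibble of cohort totals.
#' @export
glance.integrity_report <- function(x, ...) tibble::as_tibble(x$totals)

#' Build the archiving table
#'
#' One row per image, ordered by patient then canonical category index, each
#' carrying the predicted label, its verification score, a hyperlink
#' (path relative to the archive root) and a duplicate flag; every patient's
#' rows are followed by a summary row naming that patient's missing
#' categories. The `corrected_label` column is left blank for human review.
#'
#' @param classified Data frame with `patient_id`, `path`,
#'   `predicted_category` and optionally `confidence`.
#' @param report Optional [integrity_check()] result (recomputed otherwise).
#' @param root Archive root for relative hyperlinks; with `NULL` the raw
#'   paths are used verbatim.
#' @return Tibble with columns patient_id, category, predicted_label,
#'   confidence, hyperlink, duplicate_flag, corrected_label, row_type.
#' @export
build_archive_table <- function(classified, report = NULL, root = NULL) {
  df <- tibble::as_tibble(classified)
  cols <- c("patient_id", "category", "predicted_label", "confidence",
            "hyperlink", "duplicate_flag", "corrected_label", "row_type")
  empty <- tibble::tibble(
    patient_id = character(), category = character(), predicted_label = character(),
    confidence = numeric(), hyperlink = character(), duplicate_flag = logical(),
    corrected_label = character(), row_type = character()
  )
  if (nrow(df) == 0) return(empty)
  if (is.null(report)) report <- integrity_check(df)
  if (!"confidence" %in% names(df)) df$confidence <- NA_real_

  if (is.null(root)) {
    df$hyperlink <- df$path
  } else {
    df$hyperlink <- relative_to(df$path, root)
    unresolved <- !startsWith(normalizePath(df$path, mustWork = FALSE),
                              paste0(normalizePath(root, mustWork = FALSE),
                                     .Platform$file.sep))
    if (any(unresolved)) {
      warning(sum(unresolved), " hyperlink(s) resolve outside the archive root",
              call. = FALSE)
    }
  }
  df <- df |>
    dplyr::group_by(.data$patient_id, .data$predicted_category) |>
    dplyr::mutate(duplicate_flag = dplyr::n() > 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$patient_id, match(.data$predicted_category, .CATEGORIES), .data$path)

  image_rows <- tibble::tibble(
    patient_id = df$patient_id,
    category = df$predicted_category,
    predicted_label = df$predicted_category,
    confidence = df$confidence,
    hyperlink = df$hyperlink,
    duplicate_flag = df$duplicate_flag,
    corrected_label = "",
    row_type = "image"
  )
  per <- report$per_patient
  summary_rows <- tibble::tibble(
    patient_id = per$patient_id,
    category = "summary",
    predicted_label = ifelse(
      per$complete, "complete case",
      paste0(
        ifelse(per$missing > 0, paste0("missing: ", per$missing_categories), ""),
        ifelse(per$missing > 0 & per$duplicates > 0, " | ", ""),
        ifelse(per$duplicates > 0, paste0("duplicates: ", per$duplicate_categories), "")
      )),
    confidence = NA_real_,
    hyperlink = "",
    duplicate_flag = FALSE,
    corrected_label = "",
    row_type = "summary"
  )
  dplyr::bind_rows(image_rows, summary_rows) |>
    dplyr::arrange(.data$patient_id, .data$row_type == "summary",
                   match(.data$category, .CATEGORIES), .data$hyperlink) |>
    dplyr::select(dplyr::all_of(cols))
}

#' Write the archiving table as CSV
#'
#' @param table A [build_archive_table()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_archive_csv <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

relative_to <- function(paths, root) {
  root_n <- normalizePath(root, mustWork = FALSE)
  p_n <- normalizePath(paths, mustWork = FALSE)
  pre <- paste0(root_n, .Platform$file.sep)
  ifelse(startsWith(p_n, pre), substring(p_n, nchar(pre) + 1), paths)
}
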