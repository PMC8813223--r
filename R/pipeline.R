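# End-to-end wiring: preprocess -> classify -> postprocess, plus training.
#
# Routing is strict: a grayscale (single-channel or channel-equal) image is
# classified by the aspect-ratio rule and can only receive a radiograph
# label; an RGB image goes through face detection, the network and the joint
# Bayesian gallery and can only receive one of the 12 photograph labels.

#' Pipeline configuration
#'
#' @param input_size Network input side (pixels).
#' @param aspect An [aspect_rule()].
#' @param detector Face detector function.
#' @param train A [train_config()].
#' @param n_val_per_class Stratified holdout size used for model selection.
#' @param force_landscape Rotate portrait photographs before resizing.
#' @param apply_mirror_flip Flip occlusal photographs in the output archive.
#' @param seed Master seed, propagated to every stochastic component.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_size = 150L, aspect = aspect_rule(),
                            detector = detector_brightblob(),
                            train = NULL, n_val_per_class = 8L,
                            force_landscape = FALSE, apply_mirror_flip = TRUE,
                            seed = 1L) {
  if (is.null(train)) train <- train_config(seed = seed)
  structure(list(input_size = as.integer(input_size), aspect = aspect,
                 detector = detector, train = train,
                 n_val_per_class = as.integer(n_val_per_class),
                 force_landscape = force_landscape,
                 apply_mirror_flip = apply_mirror_flip, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Read, standardise, face-crop and resize a set of records into a 4-d batch.
load_net_inputs <- function(paths, config) {
  n <- length(paths)
  s <- config$input_size
  x <- array(0, c(s, s, 3, n))
  for (i in seq_len(n)) {
    img <- read_ortho_image(paths[i])
    x[, , , i] <- prepare_for_net(img, s, config$detector, config$force_landscape)
  }
  x
}

#' Train the full pipeline on a labelled manifest
#'
#' Runs QC filtering, a stratified holdout for model selection, image
#' preprocessing, network training, DeepID extraction on the training images,
#' joint Bayesian fitting and gallery construction, then evaluates the
#' holdout through the fitted verifier (per-class, macro and micro
#' one-vs-rest AUC on the joint-Bayes scores, plus accuracy).
#'
#' @param m Manifest with ground-truth categories (paths must exist).
#' @param config A [pipeline_config()].
#' @return An `ortho_pipeline` object: network, joint-Bayes model, gallery,
#'   training history, validation metrics and the configuration.
#' @export
train_pipeline <- function(m, config = pipeline_config()) {
  kept <- qc_filter(m)$kept
  rgb <- kept[kept$category %in% ortho_categories("rgb"), , drop = FALSE]
  if (nrow(rgb) == 0) {
    abort_fmt("orthoarc_training_error", "no RGB photograph records to train on")
  }
  split <- stratified_holdout(rgb, config$n_val_per_class, config$seed)

  x_train <- load_net_inputs(split$train$path, config)
  y_train <- category_index(split$train$category)
  x_val <- load_net_inputs(split$validation$path, config)
  y_val <- category_index(split$validation$category)

  fit <- train_network(x_train, y_train, x_val, y_val, config$train)

  feats <- extract_deepid(fit$network, x_train)
  jb <- fit_joint_bayesian(feats, split$train$category)
  gallery <- build_gallery(feats, split$train$category, jb)

  val_feats <- extract_deepid(fit$network, x_val)
  cls <- classify_rgb(jb, gallery, val_feats)
  metrics <- score_metrics(split$validation$category, cls$label, cls$scores)

  structure(list(network = fit$network, joint_bayes = jb, gallery = gallery,
                 history = fit$history, metrics = metrics, config = config),
            class = "ortho_pipeline")
}

#' Classify a cohort end to end
#'
#' Stage order per image: grayscale tag, then either the aspect-ratio rule
#' (grayscale) or standardise + face detection + network + joint Bayes (RGB);
#' afterwards the occlusal mirror flip, the integrity check and the archiving
#' table. Unreadable images are excluded and reported, and the run continues.
#'
#' @param pipeline A fitted `ortho_pipeline`.
#' @param m Manifest of images to classify.
#' @param out_dir Optional archive directory: every image is copied under
#'   `out_dir/<patient>/`, occlusal photographs mirror-flipped (when the
#'   config enables the flip), and hyperlinks point into it. With `NULL`
#'   nothing is written and hyperlinks point at the inputs.
#' @param chunk_size Images per network batch.
#' @return An `ortho_classification`: `results` (per-image tibble with route,
#'   predicted_category, confidence, scores), `integrity`, `archive` table,
#'   `metrics` (when ground truth is present), `failures`.
#' @export
classify_cohort <- function(pipeline, m, out_dir = NULL, chunk_size = 100L) {
  config <- pipeline$config
  res <- tibble::as_tibble(m)
  n <- nrow(res)
  res$route <- NA_character_
  res$predicted_category <- NA_character_
  res$confidence <- NA_real_
  res$width <- NA_integer_
  res$height <- NA_integer_
  scores_all <- matrix(NA_real_, n, 12,
                       dimnames = list(NULL, ortho_categories("rgb")))
  failures <- character()
  s <- config$input_size
  # images are streamed chunk-wise, never all held in memory at once
  prepared <- vector("list", n)

  for (i in seq_len(n)) {
    img <- tryCatch(read_ortho_image(res$path[i]), error = function(e) NULL)
    if (is.null(img)) {
      failures <- c(failures, res$path[i])
      next
    }
    res$width[i] <- image_width(img)
    res$height[i] <- image_height(img)
    if (tag_grayscale(img)) {
      res$route[i] <- "ratio_rule"
      res$predicted_category[i] <-
        classify_radiograph(res$width[i], res$height[i], config$aspect)
    } else {
      res$route[i] <- "network"
      prepared[[i]] <- prepare_for_net(img, s, config$detector,
                                       config$force_landscape)
    }
  }

  rgb_idx <- which(res$route == "network")
  for (start in seq_len(ceiling(length(rgb_idx) / chunk_size))) {
    ix <- rgb_idx[((start - 1) * chunk_size + 1):min(start * chunk_size, length(rgb_idx))]
    x <- array(0, c(s, s, 3, length(ix)))
    for (k in seq_along(ix)) x[, , , k] <- prepared[[ix[k]]]
    prepared[ix] <- list(NULL)
    feats <- extract_deepid(pipeline$network, x)
    cls <- classify_rgb(pipeline$joint_bayes, pipeline$gallery, feats)
    res$predicted_category[ix] <- cls$label
    res$confidence[ix] <- cls$scores[cbind(seq_along(ix), max.col(cls$scores, "first"))]
    scores_all[ix, ] <- cls$scores
  }

  ok <- !res$path %in% failures
  res <- res[ok, , drop = FALSE]
  scores_all <- scores_all[ok, , drop = FALSE]

  if (!is.null(out_dir) && nrow(res) > 0) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    new_paths <- file.path(out_dir, res$patient_id, basename(res$path))
    for (p in unique(res$patient_id)) {
      dir.create(file.path(out_dir, p), showWarnings = FALSE)
    }
    for (i in seq_len(nrow(res))) {
      img <- read_ortho_image(res$path[i])
      if (config$apply_mirror_flip && is_occlusal(res$predicted_category[i])) {
        img <- mirror_flip(img)
      }
      write_ortho_image(img, new_paths[i])
    }
    res$archived_path <- new_paths
  }

  link_col <- if (!is.null(out_dir)) "archived_path" else "path"
  archive_df <- res
  archive_df$path <- archive_df[[link_col]]
  integrity <- integrity_check(res, label_col = "predicted_category")
  archive <- build_archive_table(archive_df,
                                 report = integrity,
                                 root = out_dir)

  metrics <- NULL
  has_truth <- all(res$category %in% .CATEGORIES) && nrow(res) > 0
  if (has_truth) {
    metrics <- score_metrics(res$category, res$predicted_category, scores_all)
  }

  structure(list(results = res, scores = scores_all, integrity = integrity,
                 archive = archive, metrics = metrics, failures = failures),
            class = "ortho_classification")
}

# Accuracy plus one-vs-rest AUCs on the joint-Bayes score columns. Accuracy
# spans every record (rule-classified radiographs included); AUCs cover the
# 12 photograph classes, whose scores exist.
score_metrics <- function(truth, predicted, scores) {
  acc <- mean(predicted == truth)
  rgb_mask <- truth %in% ortho_categories("rgb") & !is.na(scores[, 1])
  per_class <- tibble::tibble(category = colnames(scores), auc = NA_real_,
                              n = NA_integer_, accuracy = NA_real_)
  macro <- micro <- NA_real_
  if (any(rgb_mask)) {
    tr <- truth[rgb_mask]
    sc <- scores[rgb_mask, , drop = FALSE]
    aucs <- vapply(colnames(sc), function(ct) {
      resp <- tr == ct
      if (length(unique(resp)) < 2) return(NA_real_)
      as.numeric(pROC::auc(resp, sc[, ct], quiet = TRUE,
                           direction = "<", levels = c(FALSE, TRUE)))
    }, numeric(1))
    per_class$auc <- aucs
    per_class$n <- vapply(colnames(sc), function(ct) sum(tr == ct), integer(1))
    per_class$accuracy <- vapply(colnames(sc), function(ct) {
      if (sum(tr == ct) == 0) return(NA_real_)
      mean(predicted[rgb_mask][tr == ct] == ct)
    }, numeric(1))
    macro <- mean(aucs, na.rm = TRUE)
    onehot <- as.vector(outer(tr, colnames(sc), "=="))
    micro <- as.numeric(pROC::auc(onehot, as.vector(sc), quiet = TRUE,
                                  direction = "<", levels = c(FALSE, TRUE)))
  }
  rad_mask <- truth %in% ortho_categories("radiograph")
  list(
    accuracy = acc,
    accuracy_rgb = if (any(rgb_mask)) mean(predicted[rgb_mask] == truth[rgb_mask]) else NA_real_,
    accuracy_radiograph = if (any(rad_mask)) mean(predicted[rad_mask] == truth[rad_mask]) else NA_real_,
    macro_auc = macro, micro_auc = micro,
    per_class = per_class, n = length(truth)
  )
}

#' Save / load a fitted pipeline
#'
#' One archive holding the network checkpoint, the joint-Bayes covariances,
#' the gallery and the configuration (the detector function is replaced by
#' the default on load if it does not serialise).
#'
#' @param pipeline An `ortho_pipeline`.
#' @param path File path.
#' @return `path` (save) or the restored pipeline (load).
#' @export
save_pipeline <- function(pipeline, path) {
  saveRDS(pipeline, path)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) readRDS(path)

#' @export
print.ortho_pipeline <- function(x, ...) {
  cat("<ortho_pipeline>\n")
  print(x$network)
  cat(sprintf("  validation: accuracy %.3f | macro-AUC %.3f | micro-AUC %.3f\n",
              x$metrics$accuracy, x$metrics$macro_auc, x$metrics$micro_auc))
  invisible(x)
}

#' @export
print.ortho_classification <- function(x, ...) {
  cat(sprintf("<ortho_classification> %d images (%d via ratio rule, %d via network)\n",
              nrow(x$results), sum(x$results$route == "ratio_rule"),
              sum(x$results$route == "network")))
  if (!is.null(x$metrics)) {
    cat(sprintf("  accuracy %.3f | macro-AUC %.3f\n",
                x$metrics$accuracy, x$metrics$macro_auc))
  }
  print(x$integrity)
  invisible(x)
}

#' Per-class validation metrics of a fitted pipeline
#'
#' @param x An `ortho_pipeline`.
#' @param ... Unused.
#' @return Tibble with per-class AUC and accuracy on the model-selection
#'   holdout.
#' @export
tidy.ortho_pipeline <- function(x, ...) x$metrics$per_class

#' One-row summary of a fitted pipeline
#'
#' @param x An `ortho_pipeline`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs trained, and holdout metrics.
#' @export
glance.ortho_pipeline <- function(x, ...) {
  tibble::tibble(
    n_parameters = param_count(x$network),
    epochs_trained = nrow(x$history),
    best_val_acc = if (nrow(x$history)) max(x$history$val_acc) else NA_real_,
    holdout_accuracy = x$metrics$accuracy,
    holdout_macro_auc = x$metrics$macro_auc,
    holdout_micro_auc = x$metrics$micro_auc
  )
}

#' Per-image classification results
#'
#' @param x An `ortho_classification`.
#' @param ... Unused.
#' @return The per-image results tibble.
#' @export
tidy.ortho_classification <- function(x, ...) x$results

#' One-row summary of a classification run
#'
#' @param x An `ortho_classification`.
#' @param ... Unused.
#' @return Tibble with image counts, routing totals, accuracy and AUC (when
#'   ground truth was present) and integrity totals.
#' @export
glance.ortho_classification <- function(x, ...) {
  tibble::tibble(
    n_images = nrow(x$results),
    n_ratio_rule = sum(x$results$route == "ratio_rule"),
    n_network = sum(x$results$route == "network"),
    accuracy = if (!is.null(x$metrics)) x$metrics$accuracy else NA_real_,
    macro_auc = if (!is.null(x$metrics)) x$metrics$macro_auc else NA_real_,
    micro_auc = if (!is.null(x$metrics)) x$metrics$micro_auc else NA_real_,
    duplicates = x$integrity$totals$duplicates,
    missing = x$integrity$totals$missing,
    complete_cases = x$integrity$totals$complete_cases
  )
}
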