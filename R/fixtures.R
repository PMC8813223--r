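# Seeded synthetic cohort generator.
#
# Archetypes are abstract geometric motifs, not photorealistic faces or
# dentitions: every operator downstream (channel check, aspect-ratio rule,
# bright-blob detector, ConvNet, joint Bayes) is agnostic to realism, and
# synthetic motifs keep the repository free of patient-like imagery. Each of
# the 12 photograph classes has a distinct combination of silhouette, local
# texture orientation/scale and colour statistics, so the classes are
# separable by translation-invariant (globally pooled) convolutional
# features. Occlusal motifs carry an asymmetric marker and are horizontally
# mirrored at generation time, emulating capture through an intraoral
# mirror. Radiograph fixtures are single-channel with the canonical 1.2:1 /
# 2:1 aspect ratios (small jitter), so preprocessing always routes them
# through the ratio rule.

SKIN <- c(0.92, 0.76, 0.64)
HAIR <- c(0.15, 0.12, 0.10)
EXTRA_BG <- c(0.32, 0.38, 0.45)
ORAL_BG <- c(0.25, 0.09, 0.09)
GUM <- c(0.85, 0.48, 0.52)
TOOTH <- c(0.96, 0.95, 0.90)

coords <- function(H, W) {
  list(x = matrix(rep(seq_len(W), each = H), H, W),
       y = matrix(rep(seq_len(H), W), H, W))
}

blank_rgb <- function(H, W, color) {
  array(rep(color, each = H * W), c(H, W, 3))
}

paint <- function(img, mask, color) {
  for (ch in seq_len(dim(img)[3])) {
    plane <- img[, , ch]
    plane[mask] <- color[min(ch, length(color))]
    img[, , ch] <- plane
  }
  img
}

emask <- function(cw, cx, cy, rx, ry) {
  ((cw$x - cx) / rx)^2 + ((cw$y - cy) / ry)^2 <= 1
}

stripes <- function(cw, theta, period, phase = 0) {
  u <- cw$x * cos(theta) + cw$y * sin(theta) + phase
  (u %% period) < period / 2
}

jit <- function(on, lo, hi) if (on) stats::runif(1, lo, hi) else (lo + hi) / 2

mask_bbox <- function(mask) {
  hit <- which(mask, arr.ind = TRUE)
  x0 <- min(hit[, 2]) - 1L; y0 <- min(hit[, 1]) - 1L
  list(x = x0, y = y0, w = max(hit[, 2]) - x0, h = max(hit[, 1]) - y0)
}

draw_extraoral <- function(category, H, W, jitter) {
  cw <- coords(H, W)
  s <- H / 300 # motif scale
  pose <- sub("_(rest|smile)$", "", category)
  smiling <- grepl("_smile$", category)

  bg <- EXTRA_BG + if (jitter) stats::rnorm(3, 0, 0.03) else 0
  img <- blank_rgb(H, W, pmin(pmax(bg, 0), 1))

  cx <- W / 2 + jit(jitter, -10, 10) * s
  cy <- H * 0.5 + jit(jitter, -8, 8) * s
  scale <- jit(jitter, 0.92, 1.08)
  ryf <- if (smiling) 1.18 else 1.0 # open jaw lengthens the face

  face <- switch(pose,
    frontal = emask(cw, cx, cy, 70 * s * scale, 105 * s * scale * ryf),
    oblique = emask(cw, cx - 8 * s, cy, 56 * s * scale, 105 * s * scale * ryf) |
      emask(cw, cx + 48 * s * scale, cy + 8 * s, 18 * s * scale, 22 * s * scale),
    profile = (emask(cw, cx - 10 * s, cy, 78 * s * scale, 105 * s * scale * ryf) &
                 cw$x >= cx - 28 * s * scale) |
      emask(cw, cx + 62 * s * scale, cy + 16 * s, 18 * s * scale, 13 * s * scale)
  )
  skin <- pmin(pmax(SKIN + if (jitter) stats::rnorm(3, 0, 0.02) else 0, 0), 1)
  img <- paint(img, face, skin)

  # hair: top cap of the head, striped at a pose-specific orientation
  hair_theta <- switch(pose, frontal = 0, oblique = pi / 4, profile = pi / 2)
  cap <- switch(pose,
    frontal = emask(cw, cx, cy - 10 * s, 76 * s * scale, 108 * s * scale),
    oblique = emask(cw, cx - 8 * s, cy - 10 * s, 62 * s * scale, 108 * s * scale),
    profile = emask(cw, cx - 10 * s, cy - 10 * s, 84 * s * scale, 108 * s * scale)
  )
  hair <- cap & (cw$y < cy - 55 * s) & stripes(cw, hair_theta, 9 * s)
  img <- paint(img, hair, HAIR)

  # eyes
  eye <- switch(pose,
    frontal = emask(cw, cx - 28 * s, cy - 22 * s, 7 * s, 5 * s) |
      emask(cw, cx + 28 * s, cy - 22 * s, 7 * s, 5 * s),
    oblique = emask(cw, cx - 26 * s, cy - 22 * s, 6 * s, 5 * s) |
      emask(cw, cx + 14 * s, cy - 22 * s, 7 * s, 5 * s),
    profile = emask(cw, cx + 30 * s, cy - 24 * s, 7 * s, 5 * s)
  )
  img <- paint(img, eye & face, c(0.12, 0.10, 0.12))

  # mouth state: thin dark line at rest; a broad bright tooth crescent with
  # lip outline and cheek creases when smiling (the motif's "mouth state")
  mx <- cx + if (pose == "profile") 30 * s else 0
  my <- cy + 58 * s
  mw <- if (pose == "oblique") 0.75 else 1 # mouth narrows with the face
  if (smiling) {
    img <- paint(img, emask(cw, mx, my, 52 * s * mw, 27 * s) & face, c(0.55, 0.30, 0.28))
    img <- paint(img, emask(cw, mx, my, 46 * s * mw, 20 * s) & face, c(0.45, 0.16, 0.18))
    img <- paint(img, emask(cw, mx, my, 40 * s * mw, 13 * s) & face, c(0.98, 0.98, 0.95))
    crease <- (emask(cw, mx, my - 16 * s, 70 * s * mw, 50 * s) &
                 !emask(cw, mx, my - 16 * s, 60 * s * mw, 40 * s)) &
      face & cw$y < my & cw$y > my - 58 * s
    img <- paint(img, crease, skin * 0.8)
  } else {
    img <- paint(img, emask(cw, mx, my, 24 * s * mw, 2.5 * s), c(0.42, 0.20, 0.20))
  }

  list(img = img, face_mask = face)
}

draw_intraoral <- function(category, H, W, jitter) {
  cw <- coords(H, W)
  s <- H / 300
  bg <- pmin(pmax(ORAL_BG + if (jitter) stats::rnorm(3, 0, 0.02) else 0, 0), 1)
  img <- blank_rgb(H, W, bg)
  cx <- W / 2 + jit(jitter, -8, 8) * s
  cy <- H / 2 + jit(jitter, -6, 6) * s
  mirrored <- FALSE

  if (category %in% c("intraoral_front", "intraoral_right", "intraoral_left")) {
    slope <- switch(category, intraoral_front = 0, intraoral_right = 0.3, intraoral_left = -0.3)
    theta <- switch(category, intraoral_front = 0, intraoral_right = pi / 6, intraoral_left = -pi / 6)
    yline <- cy + slope * (cw$x - cx)
    half_w <- 125 * s
    inband <- abs(cw$x - cx) <= half_w
    gums <- inband & abs(cw$y - yline) <= 58 * s
    teeth <- inband & abs(cw$y - yline) <= 34 * s
    seps <- stripes(cw, pi / 2 + theta, 26 * s) # tooth separators, view-tilted
    img <- paint(img, gums, GUM)
    img <- paint(img, teeth & seps, TOOTH)
    img <- paint(img, teeth & !seps, TOOTH * 0.82)
    img <- paint(img, inband & abs(cw$y - yline) <= 3 * s, c(0.2, 0.08, 0.08))
    # distal shadow wedge on the far side of lateral views
    if (category == "intraoral_right") img <- paint(img, cw$x < cx - 100 * s, bg * 0.5)
    if (category == "intraoral_left") img <- paint(img, cw$x > cx + 100 * s, bg * 0.5)
  } else if (category %in% c("maxillary_occlusal", "mandibular_occlusal")) {
    up <- category == "maxillary_occlusal"
    ay <- cy + (if (up) 45 else -45) * s
    rr <- sqrt((cw$x - cx)^2 + (cw$y - ay)^2)
    half <- if (up) cw$y <= ay else cw$y >= ay
    arch <- half & rr >= 68 * s & rr <= 108 * s
    inner <- half & rr < 68 * s
    # palate is pale pink; tongue dome is darker red
    img <- paint(img, inner, if (up) c(0.82, 0.55, 0.50) else c(0.62, 0.28, 0.32))
    img <- paint(img, arch, GUM)
    ang <- atan2(cw$y - ay, cw$x - cx)
    tooth_seg <- ((ang * 9 / pi) %% 1) < 0.62
    img <- paint(img, arch & rr >= 76 * s & tooth_seg, TOOTH)
    # asymmetric molar marker; the mirror capture flips it across the midline
    img <- paint(img, emask(cw, cx - 88 * s, ay + (if (up) -20 else 20) * s, 9 * s, 9 * s),
                 c(0.2, 0.35, 0.75))
    mirrored <- TRUE
  } else { # overjet: macro close-up of offset incisal edges
    upper <- cw$y >= cy - 78 * s & cw$y <= cy - 8 * s & cw$x >= cx - 30 * s & cw$x <= cx + 150 * s
    lower <- cw$y >= cy + 8 * s & cw$y <= cy + 70 * s & cw$x >= cx - 150 * s & cw$x <= cx + 30 * s
    img <- paint(img, upper | lower, TOOTH)
    img <- paint(img, upper & cw$y <= cy - 62 * s, GUM)
    img <- paint(img, lower & cw$y >= cy + 54 * s, GUM)
    img <- paint(img, (upper | lower) & stripes(cw, 0, 60 * s), TOOTH * 0.88)
  }
  list(img = img, mirrored = mirrored)
}

draw_radiograph <- function(category, H, W, jitter) {
  cw <- coords(H, W)
  s <- H / 300
  img <- matrix(0.10, H, W)
  if (category == "lateral_cephalogram") {
    skull <- emask(cw, W * 0.55, H * 0.42, 95 * s, 110 * s)
    jaw <- emask(cw, W * 0.42, H * 0.72, 70 * s, 34 * s)
    img[skull] <- 0.55
    img[jaw] <- pmax(img[jaw], 0.7)
    img[emask(cw, W * 0.55, H * 0.42, 60 * s, 75 * s)] <- 0.35
  } else {
    ay <- H * 0.25
    rr <- sqrt((cw$x - W / 2)^2 + (cw$y - ay)^2)
    band <- cw$y >= ay & rr >= 90 * s & rr <= 150 * s
    img[band] <- 0.65
    ang <- atan2(cw$y - ay, cw$x - W / 2)
    img[band & (((ang * 14 / pi) %% 1) < 0.6)] <- 0.85
  }
  array(img, c(H, W, 1))
}

#' Generate one synthetic image of a category
#'
#' Deterministic under `(category, seed, base_size)`. Photograph categories
#' return 3-channel landscape arrays (4:3); radiograph categories return
#' single-channel arrays at the canonical 1.2:1 or 2:1 aspect ratio with a
#' small jitter. Extraoral categories also record the ground-truth face box;
#' occlusal categories are generated mirrored (as captured through an
#' intraoral mirror) and say so.
#'
#' @param category One of [ortho_categories()].
#' @param seed Integer seed.
#' @param base_size Shorter image side in pixels.
#' @param jitter Randomise pose, colour and noise (`FALSE` gives the
#'   noiseless class template).
#' @return List with `img`, `category`, `face_box` (or `NULL`) and `mirrored`.
#' @export
generate_category_image <- function(category, seed = 1L, base_size = 300L,
                                    jitter = TRUE) {
  stopifnot(category %in% .CATEGORIES)
  withr::with_seed(seed, {
    H <- as.integer(base_size)
    if (category %in% ortho_categories("radiograph")) {
      ratio <- switch(category, lateral_cephalogram = 1.2, panoramic_radiograph = 2.0) +
        jit(jitter, -0.04, 0.04)
      W <- as.integer(round(H * ratio))
      img <- draw_radiograph(category, H, W, jitter)
      if (jitter) img <- img + array(stats::rnorm(length(img), 0, 0.03), dim(img))
      out <- list(img = pmin(pmax(img, 0), 1), category = category,
                  face_box = NULL, mirrored = FALSE)
    } else {
      W <- as.integer(round(H * 4 / 3))
      if (category %in% .CATEGORIES[1:6]) {
        dr <- draw_extraoral(category, H, W, jitter)
        img <- dr$img
        box <- mask_bbox(dr$face_mask)
        mirrored <- FALSE
      } else {
        dr <- draw_intraoral(category, H, W, jitter)
        img <- dr$img
        box <- NULL
        mirrored <- dr$mirrored
      }
      gain <- jit(jitter, 0.92, 1.08)
      img <- img * gain
      if (jitter) img <- img + array(stats::rnorm(length(img), 0, 0.02), dim(img))
      img <- pmin(pmax(img, 0), 1)
      if (mirrored) {
        img <- mirror_flip(img)
      }
      out <- list(img = img, category = category, face_box = box, mirrored = mirrored)
    }
    out
  })
}

#' Specify a synthetic cohort
#'
#' Either give explicit per-category image totals (`counts`, named by
#' category; surpluses over one-per-patient become duplicates and deficits
#' become missing slots, both distributed deterministically from the seed),
#' or a defect model (`defect_rate` = fraction of patients with defects,
#' `defects_per_patient` each, split evenly between an extra duplicate image
#' and a dropped one). The two modes are mutually exclusive; with neither,
#' every patient has one image per category.
#'
#' @param patients Number of patients.
#' @param counts Optional named integer vector of per-category totals.
#' @param defect_rate,defects_per_patient Defect model parameters.
#' @param seed Master seed; per-image seeds are split from it.
#' @param base_size Shorter image side (pixels).
#' @param categories Categories present in the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(patients, counts = NULL, defect_rate = 0,
                        defects_per_patient = 2L, seed = 1L, base_size = 300L,
                        categories = ortho_categories()) {
  if (!is.null(counts) && defect_rate > 0) {
    abort_fmt("orthoarc_spec_error", "explicit counts and a defect model are mutually exclusive")
  }
  if (!is.null(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% .CATEGORIES)) {
      abort_fmt("orthoarc_spec_error", "counts must be named by category")
    }
    if (any(counts < 0)) abort_fmt("orthoarc_spec_error", "counts must be non-negative")
    categories <- names(counts)
  }
  structure(list(patients = as.integer(patients), counts = counts,
                 defect_rate = defect_rate,
                 defects_per_patient = as.integer(defects_per_patient),
                 seed = as.integer(seed), base_size = as.integer(base_size),
                 categories = categories),
            class = "cohort_spec")
}

# Decide how many images of each category every patient receives.
allocate_counts <- function(spec) {
  P <- spec$patients
  alloc <- matrix(1L, P, length(spec$categories),
                  dimnames = list(NULL, spec$categories))
  if (!is.null(spec$counts)) {
    for (ct in spec$categories) {
      delta <- spec$counts[[ct]] - P
      if (delta > 0) {
        who <- sample.int(P, min(delta, P))
        if (delta > P) who <- c(who, sample.int(P, delta - P, replace = TRUE))
        for (w in who) alloc[w, ct] <- alloc[w, ct] + 1L
      } else if (delta < 0) {
        who <- sample.int(P, -delta)
        alloc[who, ct] <- 0L
      }
    }
  } else if (spec$defect_rate > 0) {
    n_def <- round(spec$defect_rate * P)
    defective <- sample.int(P, n_def)
    for (w in defective) {
      for (k in seq_len(spec$defects_per_patient)) {
        ct <- sample(spec$categories, 1)
        if (stats::runif(1) < 0.5) {
          alloc[w, ct] <- alloc[w, ct] + 1L
        } else {
          present <- spec$categories[alloc[w, ] > 0]
          if (length(present) > 0) {
            drop_ct <- if (length(present) == 1) present else sample(present, 1)
            alloc[w, drop_ct] <- alloc[w, drop_ct] - 1L
          }
        }
      }
    }
  }
  alloc
}

#' Generate a synthetic cohort on disk
#'
#' Writes one PNG per image under `dir/<patient>/`, plus `manifest.csv` (the
#' package's manifest format) and `ground_truth.csv` (path, true category,
#' face box, mirror flag). Identical spec and seed give identical manifests
#' and image bytes. With `write_images = FALSE` only the tables are produced
#' (paths are still listed), which is enough for split and integrity
#' arithmetic at full cohort scale.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created).
#' @param write_images Render and write PNGs.
#' @param cohort_name Cohort tag for the manifest.
#' @return List with `manifest` (tibble), `ground_truth` (tibble), `dir`.
#' @export
generate_cohort <- function(spec, dir = tempfile("cohort"), write_images = TRUE,
                            cohort_name = "synthetic") {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- withr::with_seed(spec$seed, {
    alloc <- allocate_counts(spec)
    pid <- sprintf("P%04d", seq_len(spec$patients))
    rows <- list()
    for (i in seq_len(spec$patients)) {
      for (ct in spec$categories) {
        k <- alloc[i, ct]
        if (k == 0) next
        for (j in seq_len(k)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            patient_id = pid[i], category = ct, copy = j)
        }
      }
    }
    rows <- dplyr::bind_rows(rows)
    rows$img_seed <- sample.int(.Machine$integer.max - 1L, nrow(rows))
    rows
  })
  rows$path <- file.path(dir, rows$patient_id,
                         sprintf("%s_%s_%d.png", rows$patient_id, rows$category, rows$copy))

  gt <- tibble::tibble(
    path = rows$path, true_category = rows$category,
    box_x = NA_integer_, box_y = NA_integer_, box_w = NA_integer_, box_h = NA_integer_,
    mirrored = FALSE
  )
  if (write_images) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in unique(rows$patient_id)) {
      dir.create(file.path(dir, p), showWarnings = FALSE)
    }
    for (r in seq_len(nrow(rows))) {
      g <- generate_category_image(rows$category[r], rows$img_seed[r], spec$base_size)
      write_ortho_image(g$img, rows$path[r])
      if (!is.null(g$face_box)) {
        gt$box_x[r] <- g$face_box$x; gt$box_y[r] <- g$face_box$y
        gt$box_w[r] <- g$face_box$w; gt$box_h[r] <- g$face_box$h
      }
      gt$mirrored[r] <- g$mirrored
    }
  }
  m <- manifest(rows$patient_id, rows$path, rows$category, "", cohort_name)
  if (write_images) {
    write_manifest(m, file.path(dir, "manifest.csv"))
    readr::write_csv(gt, file.path(dir, "ground_truth.csv"), progress = FALSE)
  }
  list(manifest = m, ground_truth = gt, dir = dir)
}

#' Per-category image totals of the reference cohorts
#'
#' The per-category counts of the clinical cohorts the synthetic generator
#' reproduces: the internal training set (12,999 images), the internal
#' validation set (100 per category, 1,400), their union (14,399), and the
#' 100-patient external set (1,420 images, whose surpluses and deficits
#' relative to one-per-patient encode its duplicate/missing structure).
#'
#' @param which One of `"internal_train"`, `"internal_validation"`,
#'   `"internal"`, `"external"`.
#' @return Named integer vector over the 14 categories.
#' @export
reference_counts <- function(which = c("internal_train", "internal_validation",
                                       "internal", "external")) {
  which <- match.arg(which)
  train <- c(950L, 1012L, 896L, 906L, 1002L, 935L, 976L, 899L, 1009L, 828L,
             932L, 854L, 900L, 900L)
  val <- rep(100L, 14L)
  external <- c(110L, 99L, 109L, 123L, 87L, 90L, 102L, 109L, 107L, 98L, 97L,
                89L, 100L, 100L)
  out <- switch(which,
    internal_train = train,
    internal_validation = val,
    internal = train + val,
    external = external
  )
  stats::setNames(out, .CATEGORIES)
}
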