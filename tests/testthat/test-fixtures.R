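test_that("category images are deterministic and structurally correct", {
  g1 <- generate_category_image("frontal_smile", 11, base_size = 96)
  g2 <- generate_category_image("frontal_smile", 11, base_size = 96)
  expect_identical(g1$img, g2$img)

  for (ct in ortho_categories()) {
    g <- generate_category_image(ct, 5, base_size = 96)
    is_rad <- ct %in% ortho_categories("radiograph")
    expect_equal(dim(g$img)[3], if (is_rad) 1L else 3L)
    expect_equal(tag_grayscale(g$img), is_rad)
    expect_equal(!is.null(g$face_box), ct %in% ortho_categories()[1:6])
    expect_equal(g$mirrored,
                 ct %in% c("maxillary_occlusal", "mandibular_occlusal"))
  }

  lat <- generate_category_image("lateral_cephalogram", 7, base_size = 300)
  ratio <- dim(lat$img)[2] / dim(lat$img)[1]
  expect_gte(ratio, 1.15); expect_lte(ratio, 1.25)
  pan <- generate_category_image("panoramic_radiograph", 7, base_size = 300)
  rpan <- dim(pan$img)[2] / dim(pan$img)[1]
  expect_gte(rpan, 1.95); expect_lte(rpan, 2.05)
})

test_that("the 14 archetype templates are mutually distinct and recoverable", {
  to_gray_vec <- function(img) {
    g <- if (dim(img)[3] == 3) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img[, , 1]
    as.vector(orthoarc:::resize_image(array(g, c(dim(g), 1)), 128, 96)[, , 1])
  }
  cats <- ortho_categories()
  templates <- vapply(cats, function(ct) {
    to_gray_vec(generate_category_image(ct, 1, base_size = 96, jitter = FALSE)$img)
  }, numeric(128 * 96))

  # pairwise: noiseless templates differ in at least 5% of pixels
  for (i in 1:13) for (j in (i + 1):14) {
    expect_gte(mean(abs(templates[, i] - templates[, j]) > 0.05), 0.05)
  }

  # nearest-template assignment by correlation recovers jittered instances
  for (ct in cats) {
    v <- to_gray_vec(generate_category_image(ct, 900 + match(ct, cats),
                                             base_size = 96)$img)
    cors <- apply(templates, 2, stats::cor, y = v)
    expect_equal(cats[which.max(cors)], ct)
  }
})

test_that("cohort generation honours explicit counts and round-trips", {
  dir <- withr::local_tempdir()
  counts <- stats::setNames(c(3L, 2L, 4L, 3L, 3L, 3L, 3L, 3L, 3L, 2L, 3L, 3L, 3L, 3L),
                            ortho_categories())
  out <- generate_cohort(cohort_spec(patients = 3, counts = counts, seed = 9,
                                     base_size = 96), dir = dir)
  expect_equal(nrow(out$manifest), sum(counts))
  expect_equal(as.integer(table(factor(out$manifest$category,
                                       ortho_categories()))), unname(counts))
  expect_true(all(file.exists(out$manifest$path)))

  # round trip: the on-disk manifest reproduces the in-memory one
  back <- load_manifest(file.path(dir, "manifest.csv"), cohort_name = "synthetic")
  expect_equal(back, out$manifest)

  # determinism, including image bytes
  dir2 <- withr::local_tempdir()
  out2 <- generate_cohort(cohort_spec(patients = 3, counts = counts, seed = 9,
                                      base_size = 96), dir = dir2)
  expect_equal(out2$manifest[c("patient_id", "category")],
               out$manifest[c("patient_id", "category")])
  expect_identical(readBin(out$manifest$path[1], "raw", 1e6),
                   readBin(out2$manifest$path[1], "raw", 1e6))
})

test_that("a defect-free cohort is complete and fully clean", {
  out <- generate_cohort(cohort_spec(patients = 10, seed = 2), write_images = FALSE)
  expect_equal(nrow(out$manifest), 140)
  rep <- integrity_check(out$manifest, label_col = "category")
  expect_equal(rep$totals$complete_cases, 10)
  expect_equal(rep$totals$duplicates + rep$totals$missing, 0)
})

test_that("cohort specs validate their arguments", {
  expect_error(cohort_spec(5, counts = c(frontal_rest = -1L)),
               class = "orthoarc_spec_error")
  expect_error(cohort_spec(5, counts = c(nonsense = 3L)),
               class = "orthoarc_spec_error")
  expect_error(cohort_spec(5, counts = c(frontal_rest = 3L), defect_rate = 0.5),
               class = "orthoarc_spec_error")
})

test_that("reference cohort counts reproduce the published totals", {
  expect_equal(sum(reference_counts("internal_train")), 12999)
  expect_equal(sum(reference_counts("internal_validation")), 1400)
  expect_equal(sum(reference_counts("internal")), 14399)
  expect_equal(sum(reference_counts("external")), 1420)
  ext <- generate_cohort(cohort_spec(patients = 100,
                                     counts = reference_counts("external"),
                                     seed = 3), write_images = FALSE)
  expect_equal(nrow(ext$manifest), 1420)
})
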