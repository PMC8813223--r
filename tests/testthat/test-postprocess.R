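test_that("mirror flip is an involution that preserves shape", {
  expect_equal(mirror_flip(matrix(1:6, 2, byrow = TRUE)),
               matrix(c(3, 2, 1, 6, 5, 4), 2, byrow = TRUE))
  for (seed in 1:5) {
    withr::with_seed(seed, {
      h <- sample(2:40, 1); w <- sample(2:40, 1); ch <- sample(c(1, 3), 1)
      img <- array(runif(h * w * ch), c(h, w, ch))
      expect_identical(mirror_flip(mirror_flip(img)), img)
      expect_equal(dim(mirror_flip(img)), dim(img))
    })
  }
})

test_that("integrity findings match hand-constructed cases", {
  complete <- manifest("p1", sprintf("c%02d.png", 1:14),
                       category = ortho_categories())
  rep1 <- integrity_check(complete, label_col = "category")
  expect_equal(rep1$totals$duplicates, 0)
  expect_equal(rep1$totals$missing, 0)
  expect_equal(rep1$totals$complete_cases, 1)

  # duplicate frontal smile, no overjet
  cats <- c(ortho_categories()[ortho_categories() != "overjet"], "frontal_smile")
  m <- manifest("p1", sprintf("d%02d.png", seq_along(cats)), category = cats)
  rep2 <- integrity_check(m, label_col = "category")
  expect_equal(rep2$totals$duplicates, 1)
  expect_equal(rep2$totals$missing, 1)
  expect_match(rep2$per_patient$missing_categories, "overjet")
  expect_match(rep2$per_patient$duplicate_categories, "frontal_smile\\(2\\)")
})

test_that("cohort totals satisfy images = 14*patients + duplicates - missing", {
  for (seed in 1:6) {
    spec <- cohort_spec(patients = 12, defect_rate = 0.5,
                        defects_per_patient = 2, seed = 700 + seed)
    cohort <- generate_cohort(spec, write_images = FALSE)
    rep <- integrity_check(cohort$manifest, label_col = "category")
    t <- rep$totals
    expect_equal(t$images, nrow(cohort$manifest))
    expect_equal(t$images, 14 * t$patients + t$duplicates - t$missing)
    # brute-force recount oracle, independent of the report's bookkeeping
    counts <- table(factor(cohort$manifest$category, ortho_categories()),
                    cohort$manifest$patient_id)
    expect_equal(t$duplicates, sum(pmax(counts - 1, 0)))
    expect_equal(t$missing, sum(counts == 0))
    expect_equal(t$complete_cases, sum(colSums(counts != 1) == 0))
  }
})

test_that("the reference external cohort shows 60 duplicates and 40 missing", {
  cohort <- generate_cohort(
    cohort_spec(patients = 100, counts = reference_counts("external"), seed = 31),
    write_images = FALSE)
  expect_equal(nrow(cohort$manifest), 1420)
  rep <- integrity_check(cohort$manifest, label_col = "category")
  expect_equal(rep$totals$images, 1420)
  expect_equal(rep$totals$duplicates, 60)
  expect_equal(rep$totals$missing, 40)
})

test_that("archive table lists every image plus one summary row per patient", {
  m <- manifest("p1", sprintf("/data/p1/c%02d.png", 1:14),
                category = ortho_categories())
  m$predicted_category <- m$category
  m$confidence <- seq(0.5, 1.8, length.out = 14)
  tab <- build_archive_table(m)
  expect_equal(nrow(tab), 15)
  expect_equal(sum(tab$row_type == "image"), 14)
  expect_equal(tab$predicted_label[tab$row_type == "summary"], "complete case")
  expect_false(any(tab$duplicate_flag))
  # canonical ordering by category index
  expect_equal(tab$category[1:14], ortho_categories())

  # duplicates flag both rows and the summary names the category
  m2 <- manifest("p2", c("/d/a.png", "/d/b.png", "/d/c.png"),
                 category = c("overjet", "overjet", "frontal_rest"))
  m2$predicted_category <- m2$category
  tab2 <- build_archive_table(m2)
  expect_equal(sum(tab2$duplicate_flag), 2)
  expect_match(tab2$predicted_label[tab2$row_type == "summary"], "overjet\\(2\\)")
  expect_match(tab2$predicted_label[tab2$row_type == "summary"], "missing")

  # empty input: header-only table
  tab0 <- build_archive_table(manifest(character(), character()))
  expect_equal(nrow(tab0), 0)
  expect_true(all(c("patient_id", "category", "predicted_label", "confidence",
                    "hyperlink", "duplicate_flag", "corrected_label") %in% names(tab0)))

  # row-count property on generated cohorts
  cohort <- generate_cohort(cohort_spec(patients = 9, defect_rate = 0.4, seed = 55),
                            write_images = FALSE)
  cm <- cohort$manifest
  cm$predicted_category <- cm$category
  tabc <- build_archive_table(cm)
  expect_equal(nrow(tabc), nrow(cm) + 9)

  # relative hyperlinks under a root
  tabr <- build_archive_table(m, root = "/data")
  expect_equal(tabr$hyperlink[tabr$row_type == "image"][1], "p1/c01.png")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_archive_csv(tabr, csv)
  expect_equal(nrow(readr::read_csv(csv, show_col_types = FALSE)), 15)
})
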