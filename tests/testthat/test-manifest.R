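test_that("manifest CSV round-trips and validates its invariants", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,path,category,qc_flags",
    "p1,a.png,frontal_rest,",
    "p2,b.png,overjet,blurred",
    "p3,c.png,unknown,"
  ), csv)
  m <- load_manifest(csv)
  expect_equal(nrow(m), 3)
  expect_equal(m$category, c("frontal_rest", "overjet", "unknown"))
  expect_equal(m$qc_flags, c("", "blurred", ""))

  # duplicate paths violate a manifest invariant
  writeLines(c("patient_id,path", "p1,a.png", "p2,a.png"), csv)
  expect_error(load_manifest(csv), class = "orthoarc_validation_error")

  # required columns
  writeLines(c("patient,file", "p1,a.png"), csv)
  expect_error(load_manifest(csv), class = "orthoarc_format_error")

  expect_error(manifest("p1", "a.png", category = "sideways"),
               class = "orthoarc_validation_error")
  expect_error(manifest("", "a.png"), class = "orthoarc_validation_error")
})

test_that("qc_filter partitions any manifest by flags", {
  # the reference arithmetic: 106 blurred + 296 nonconforming leave 15,819
  flags <- rep("", 16221)
  flags[1:106] <- "blurred"
  flags[107:402] <- "nonconforming"
  m <- manifest(paste0("p", seq_len(16221) %% 1200),
                sprintf("img%05d.png", seq_len(16221)), qc_flags = flags)
  out <- qc_filter(m)
  expect_equal(nrow(out$kept), 15819)
  expect_equal(nrow(out$excluded), 402)

  # partition property on random flaggings
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(0:200, 1)
      fl <- sample(c("", "blurred", "nonconforming", "blurred;nonconforming"),
                   n, replace = TRUE)
      mm <- manifest(rep("p", n), sprintf("s%d_%d.png", seed, seq_len(n)),
                     qc_flags = fl)
      oo <- qc_filter(mm)
      expect_equal(nrow(oo$kept) + nrow(oo$excluded), n)
      expect_true(all(oo$kept$qc_flags == ""))
    })
  }

  empty <- qc_filter(manifest(character(), character()))
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$excluded), 0)

  allbad <- qc_filter(manifest(c("a", "b"), c("x.png", "y.png"),
                               qc_flags = "blurred"))
  expect_equal(nrow(allbad$kept), 0)
})

test_that("stratified holdout draws exact per-category counts, reproducibly", {
  cats <- ortho_categories()
  m <- manifest(
    patient_id = rep("p", 14 * 30),
    path = sprintf("%s_%02d.png", rep(cats, each = 30), rep(1:30, 14)),
    category = rep(cats, each = 30)
  )
  s1 <- stratified_holdout(m, 10, seed = 5)
  s2 <- stratified_holdout(m, 10, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$validation), 140)
  expect_equal(nrow(s1$train), 14 * 20)
  expect_equal(as.integer(table(s1$validation$category)[cats]), rep(10L, 14))
  # disjoint, union = input
  expect_length(intersect(s1$train$path, s1$validation$path), 0)
  expect_setequal(c(s1$train$path, s1$validation$path), m$path)
  # a different seed draws a different validation set
  s3 <- stratified_holdout(m, 10, seed = 6)
  expect_false(setequal(s1$validation$path, s3$validation$path))

  # exhaustive holdout empties the training set
  m100 <- m[rep(1:30, 14) <= 10, ]
  sx <- stratified_holdout(m100, 10, seed = 1)
  expect_equal(nrow(sx$train), 0)

  # insufficient records name the category
  expect_error(stratified_holdout(m, 31, seed = 1),
               regexp = "frontal_rest",
               class = "orthoarc_insufficient_data_error")
})

test_that("patient-level holdout splits whole cases", {
  m <- manifest(rep(sprintf("p%02d", 1:10), each = 3),
                sprintf("i%02d.png", 1:30))
  s <- patient_holdout(m, 4, seed = 2)
  expect_length(unique(s$validation$patient_id), 4)
  expect_length(intersect(s$train$patient_id, s$validation$patient_id), 0)
  expect_error(patient_holdout(m, 11, seed = 1),
               class = "orthoarc_insufficient_data_error")
})
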