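# Shared fixtures, built lazily once per test run.
#
# The "mini" pipeline is a fast, fully real end-to-end fit: a 14-patient
# complete synthetic cohort rendered at 96 px, trained at 96 px inputs.
# It exists so routing, mirror-flip, archiving and determinism contracts can
# be exercised against genuine trained components without the cost of the
# desk-scale run.

.fixture_env <- new.env(parent = emptyenv())

mini_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(
      cohort_spec(patients = 14, seed = 401L, base_size = 96),
      dir = file.path(tempdir(), "orthoarc-mini-internal")
    )
  }
  .fixture_env$cohort
}

mini_external <- function() {
  if (is.null(.fixture_env$external)) {
    counts <- stats::setNames(
      c(4L, 3L, 4L, 5L, 2L, 3L, 4L, 4L, 4L, 3L, 3L, 2L, 3L, 3L),
      ortho_categories()
    )
    .fixture_env$external <- generate_cohort(
      cohort_spec(patients = 3, counts = counts, seed = 402L, base_size = 96),
      dir = file.path(tempdir(), "orthoarc-mini-external")
    )
  }
  .fixture_env$external
}

mini_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    cfg <- pipeline_config(
      input_size = 96L, seed = 7L, n_val_per_class = 3L,
      train = train_config(max_epochs = 25L, seed = 7L)
    )
    .fixture_env$pipe <- train_pipeline(mini_cohort()$manifest, cfg)
  }
  .fixture_env$pipe
}

# simulate features from the joint Bayesian generative model
simulate_jb <- function(n_classes, n_per_class, d, sd_mu, sd_eps, seed) {
  withr::with_seed(seed, {
    mu <- matrix(stats::rnorm(n_classes * d, 0, sd_mu), n_classes, d)
    X <- mu[rep(seq_len(n_classes), each = n_per_class), , drop = FALSE] +
      matrix(stats::rnorm(n_classes * n_per_class * d, 0, sd_eps),
             n_classes * n_per_class, d)
    list(X = X, labels = rep(seq_len(n_classes), each = n_per_class), mu = mu)
  })
}
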