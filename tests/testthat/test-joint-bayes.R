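test_that("scalar verification ratio matches the Gaussian log-density oracle", {
  s_mu <- 1.7; s_eps <- 0.6; sig2 <- s_mu + s_eps
  model <- joint_bayes_model(matrix(s_mu), matrix(s_eps))
  # brute-force oracle: joint normal density under shared identity vs
  # independent identities
  ldnorm <- function(x, S) {
    -0.5 * (length(x) * log(2 * pi) +
              as.numeric(determinant(S)$modulus) +
              as.numeric(t(x) %*% solve(S) %*% x))
  }
  oracle <- function(x1, x2) {
    ldnorm(c(x1, x2), matrix(c(sig2, s_mu, s_mu, sig2), 2)) -
      ldnorm(x1, matrix(sig2)) - ldnorm(x2, matrix(sig2))
  }
  withr::with_seed(4, {
    for (i in 1:25) {
      x1 <- rnorm(1, 0, 2); x2 <- rnorm(1, 0, 2)
      expect_lt(abs(verification_ratio(model, x1, x2) - oracle(x1, x2)), 1e-10)
    }
  })
})

test_that("verification ratio is symmetric and vanishes without identity variance", {
  model <- joint_bayes_model(diag(2, 5), diag(0.7, 5) + 0.1)
  withr::with_seed(8, {
    for (i in 1:20) {
      x1 <- rnorm(5); x2 <- rnorm(5)
      expect_equal(verification_ratio(model, x1, x2),
                   verification_ratio(model, x2, x1), tolerance = 1e-12)
    }
  })

  m0 <- joint_bayes_model(matrix(0, 4, 4), diag(1.3, 4))
  expect_equal(max(abs(m0$A)), 0, tolerance = 1e-12)
  expect_equal(max(abs(m0$G)), 0, tolerance = 1e-12)
  withr::with_seed(9, {
    for (i in 1:10) {
      expect_equal(verification_ratio(m0, rnorm(4), rnorm(4)), 0,
                   tolerance = 1e-10)
    }
  })

  expect_error(verification_ratio(model, rnorm(3), rnorm(5)),
               class = "orthoarc_input_error")
})

test_that("EM recovers the generative covariances from 2,000 features", {
  # 200 identities x 10 samples, d = 8, identity sd 2, noise sd 1.
  sim <- simulate_jb(200, 10, 8, sd_mu = 2, sd_eps = 1, seed = 10)
  fit <- fit_joint_bayesian(sim$X, sim$labels)
  expect_true(fit$converged)

  # S_mu is compared against the realized covariance of the simulated
  # identity vectors: with 200 identities the nominal diag(4) itself has
  # ~21% sampling deviation, so the realized covariance is what the EM can
  # at best recover.
  mu_c <- sweep(sim$mu, 2, colMeans(sim$mu))
  realized <- crossprod(mu_c) / nrow(mu_c)
  rel <- function(a, b) norm(a - b, "F") / norm(b, "F")
  expect_lte(rel(fit$S_mu, realized), 0.15)
  expect_lte(rel(fit$S_eps, diag(1, 8)), 0.15)

  # block-inverse identity at convergence (A = Sigma^-1 - (F+G))
  Sigma <- fit$S_mu + fit$S_eps
  FG <- solve(Sigma) - fit$A
  big <- rbind(cbind(Sigma, fit$S_mu), cbind(fit$S_mu, Sigma))
  inv <- rbind(cbind(FG, fit$G), cbind(fit$G, FG))
  expect_lt(max(abs(big %*% inv - diag(16))), 1e-8)
})

test_that("EM log-likelihood is non-decreasing and degenerate identity shrinks S_mu", {
  sim <- simulate_jb(40, 5, 4, sd_mu = 1.5, sd_eps = 1, seed = 3)
  ll <- vapply(1:8, function(it) {
    fit_joint_bayesian(sim$X, sim$labels, max_iter = it, tol = 0)$loglik
  }, numeric(1))
  expect_true(all(diff(ll) > -1e-6))

  # all classes share one mean: fitted S_mu collapses
  flat <- simulate_jb(30, 10, 6, sd_mu = 0, sd_eps = 1, seed = 5)
  fit0 <- fit_joint_bayesian(flat$X, flat$labels)
  expect_lte(norm(fit0$S_mu, "F"), 0.05 * norm(fit0$S_eps, "F"))
})

test_that("fitting rejects unidentifiable or invalid inputs", {
  expect_error(fit_joint_bayesian(matrix(rnorm(8), 2, 4), c(1, 1)),
               class = "orthoarc_fitting_error")
  expect_error(fit_joint_bayesian(matrix(rnorm(12), 3, 4), c(1, 2, 3)),
               class = "orthoarc_fitting_error")
  X <- matrix(rnorm(16), 4, 4); X[2, 2] <- NA
  expect_error(fit_joint_bayesian(X, c(1, 1, 2, 2)),
               class = "orthoarc_input_error")
})

test_that("gallery classification picks the matching mean and breaks ties low", {
  cats <- ortho_categories("rgb")
  sim <- simulate_jb(12, 20, 16, sd_mu = 6, sd_eps = 1, seed = 6)
  labels <- cats[sim$labels]
  fit <- fit_joint_bayesian(sim$X, labels)
  gal <- build_gallery(sim$X, labels, fit, cats)

  # queries at the true class means are recovered exactly
  cls <- classify_rgb(fit, gal, sweep(gal$class_means, 2, -fit$mean))
  expect_equal(cls$label, cats)
  expect_equal(ncol(cls$scores), 12)
  expect_equal(cls$label,
               cats[apply(cls$scores, 1, which.max)])

  # two identical gallery means: the lower category index wins
  gal2 <- gal
  gal2$class_means[5, ] <- gal2$class_means[2, ]
  q <- gal2$class_means[5, ] + fit$mean
  cls2 <- classify_rgb(fit, gal2, q)
  expect_equal(cls2$label, cats[2])

  expect_error(build_gallery(sim$X[sim$labels < 12, ], labels[sim$labels < 12], fit),
               class = "orthoarc_config_error")
})

test_that("classification accuracy degrades monotonely with within-class noise", {
  cats <- ortho_categories("rgb")
  accs <- vapply(c(0.5, 2, 4, 8, 16), function(sd_eps) {
    sim <- simulate_jb(12, 30, 8, sd_mu = 3, sd_eps = sd_eps, seed = 21)
    labels <- cats[sim$labels]
    fit <- fit_joint_bayesian(sim$X, labels)
    gal <- build_gallery(sim$X, labels, fit, cats)
    test <- simulate_jb(12, 30, 8, sd_mu = 3, sd_eps = sd_eps, seed = 22)
    # score queries drawn around the same identities via fresh draws
    q <- sim$mu[rep(1:12, each = 20), ] +
      matrix(withr::with_seed(23, rnorm(12 * 20 * 8, 0, sd_eps)), 240, 8)
    mean(classify_rgb(fit, gal, q)$label == cats[rep(1:12, each = 20)])
  }, numeric(1))
  expect_equal(accs[1], 1)
  expect_true(all(diff(accs) <= 0.02))
})

test_that("models round-trip through the archive with A and G recomputed", {
  sim <- simulate_jb(10, 8, 6, sd_mu = 2, sd_eps = 1, seed = 12)
  fit <- fit_joint_bayesian(sim$X, sim$labels)
  path <- withr::local_tempfile(fileext = ".rds")
  save_joint_bayes(fit, path)
  back <- load_joint_bayes(path)
  expect_equal(back$A, fit$A, tolerance = 1e-12)
  expect_equal(back$G, fit$G, tolerance = 1e-12)
  expect_equal(verification_ratio(back, sim$X[1, ], sim$X[2, ]),
               verification_ratio(fit, sim$X[1, ], sim$X[2, ]))
})
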