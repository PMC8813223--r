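test_that("parameter ledger matches the closed-form architecture sum", {
  net <- build_network(seed = 1)
  expect_equal(param_count(net), 170988L)
  expect_equal(spec_param_count(network_spec()), 170988L)
  expect_equal(param_count(net, with_head = FALSE), 169824L)
  expect_equal(param_count(list()), 0L)

  ledger <- tidy(net)
  expect_equal(sum(ledger$parameters), param_count(net))
  # the 7x7 input layer alone: 7*7*3*16 weights + 16 biases
  expect_equal(sum(ledger$parameters[ledger$layer %in% c("conv1_w", "conv1_b")]),
               2368L)
  expect_equal(glance(net)$n_parameters_m, 0.17)

  # doubling every width breaks the pinned budget
  fat <- network_spec(conv1_out = 32, unit_widths = c(64, 96, 128, 160),
                      conv6_out = 128, conv7_out = 64)
  expect_error(build_network(fat), class = "orthoarc_spec_error")
})

test_that("feature extraction is a pure 96-vector for any admissible input", {
  net <- build_network(seed = 2)
  x1 <- withr::with_seed(1, array(runif(96 * 96 * 3), c(96, 96, 3)))
  f1 <- extract_deepid(net, x1)
  expect_equal(dim(f1), c(1L, 96L))
  expect_true(all(is.finite(f1)))
  # determinism / purity: same input, same network, same features
  expect_identical(extract_deepid(net, x1), f1)

  # input-size independence of the feature dimension
  x2 <- withr::with_seed(2, array(runif(64 * 150 * 3), c(64, 150, 3)))
  expect_equal(dim(extract_deepid(net, x2)), c(1L, 96L))

  expect_error(extract_deepid(net, array(0.5, c(50, 100, 3))),
               class = "orthoarc_size_error")
})

test_that("analytic gradients match numerical differentiation", {
  net <- build_network(seed = 3)
  x <- withr::with_seed(4, array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2)))
  y <- c(1L, 5L)
  fw <- orthoarc:::net_forward(net, x, keep = TRUE)
  sx <- orthoarc:::softmax_xent(fw$logits, y)
  g <- orthoarc:::net_backward(net, fw, sx$dlogits)
  loss_of <- function(n) {
    orthoarc:::softmax_xent(orthoarc:::net_forward(n, x)$logits, y)$loss
  }
  eps <- 1e-5
  withr::with_seed(5, {
    for (nm in c("conv1_w", "u3_w", "u4_pw", "conv6_w", "conv7_b", "head_w")) {
      for (i in sample(length(net$params[[nm]]), 2)) {
        n2 <- net
        n2$params[[nm]][i] <- net$params[[nm]][i] + eps
        up <- loss_of(n2)
        n2$params[[nm]][i] <- net$params[[nm]][i] - eps
        dn <- loss_of(n2)
        num <- (up - dn) / (2 * eps)
        expect_lt(abs(g[[nm]][i] - num), 1e-6 + 1e-4 * abs(num))
      }
    }
  })
})

test_that("an untrained network scores a balanced batch at ~ln(12) cross-entropy", {
  net <- build_network(seed = 6)
  x <- withr::with_seed(7, array(runif(96 * 96 * 3 * 12), c(96, 96, 3, 12)))
  fw <- orthoarc:::net_forward(net, x)
  loss <- orthoarc:::softmax_xent(fw$logits, 1:12)$loss
  expect_lt(abs(loss - log(12)), 0.3)
})

test_that("training reduces loss, selects the best checkpoint, and seeds cleanly", {
  # small separable 2-class problem: bright-left vs bright-right images
  make_xy <- function(n, seed) {
    withr::with_seed(seed, {
      x <- array(runif(64 * 64 * 3 * n, 0, 0.3), c(64, 64, 3, n))
      y <- rep(1:2, length.out = n)
      for (i in seq_len(n)) {
        if (y[i] == 1) x[, 1:32, , i] <- x[, 1:32, , i] + 0.6
        else x[33:64, , , i] <- x[33:64, , , i] + 0.6
      }
      list(x = x, y = y)
    })
  }
  tr <- make_xy(16, 1)
  va <- make_xy(8, 2)
  cfg <- train_config(max_epochs = 5, batch_size = 8, seed = 11,
                      stop_at_val_acc = 2) # run all epochs
  fit <- train_network(tr$x, tr$y, va$x, va$y, cfg)
  expect_equal(nrow(fit$history), 5)
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  expect_gte(max(fit$history$val_acc), 0.75)

  # determinism: same seed, same history
  fit2 <- train_network(tr$x, tr$y, va$x, va$y, cfg)
  expect_identical(fit$history, fit2$history)

  # zero-epoch call returns the initialised network untouched
  fit0 <- train_network(tr$x, tr$y, va$x, va$y,
                        train_config(max_epochs = 0, seed = 11))
  expect_equal(nrow(fit0$history), 0)
  expect_identical(fit0$network$params, build_network(seed = 11)$params)

  expect_error(train_network(tr$x, rep(1L, 16), va$x, va$y, cfg),
               class = "orthoarc_training_error")
})

test_that("checkpoints round-trip through the archive file", {
  net <- build_network(seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_network(net, path)
  back <- load_network(path)
  x <- withr::with_seed(1, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_identical(extract_deepid(back, x), extract_deepid(net, x))
})
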