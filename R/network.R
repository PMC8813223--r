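# The compact residual ConvNet that produces DeepID features.
#
# Pinned architecture (channel widths 16/32/48/64/80/64/32):
#   conv1: 7x7, stride 2, pad 3, 3 -> 16, ReLU
#   pool -> unit2(16->32) -> pool -> unit3(32->48) -> pool -> unit4(48->64)
#        -> pool -> unit5(64->80)
#   conv6: 3x3, 80 -> 64, ReLU;  conv7: 3x3, 64 -> 32, ReLU
#   DeepID feature = [GAP(conv6), GAP(conv7)]  (64 + 32 = 96 values)
#   training head: linear 96 -> 12
# Residual units are a single 3x3 convolution plus a 1x1 projection shortcut
# (identity when widths match), ReLU after the sum. No batch normalisation:
# plain biases keep the parameter ledger exact. Global average pooling makes
# the feature dimension independent of input size (any RGB input with both
# sides >= 64).

#' Network architecture description
#'
#' The default values pin the reference architecture, whose trainable
#' parameter count (including the 12-way training head and all biases) is
#' 170,988 — i.e. 0.17 M. [build_network()] refuses a spec whose closed-form
#' count falls outside \[165,000, 175,000\].
#'
#' @param conv1_out Width of the 7x7 input layer.
#' @param unit_widths Output widths of residual units 2–5.
#' @param conv6_out,conv7_out Widths of the two feature layers.
#' @param n_classes Classes of the training head.
#' @param input_channels Input channels (RGB photographs: 3).
#' @return A `network_spec` list.
#' @export
network_spec <- function(conv1_out = 16L, unit_widths = c(32L, 48L, 64L, 80L),
                         conv6_out = 64L, conv7_out = 32L, n_classes = 12L,
                         input_channels = 3L) {
  stopifnot(length(unit_widths) == 4)
  structure(list(
    input_channels = as.integer(input_channels),
    conv1_out = as.integer(conv1_out),
    conv1_kernel = 7L, conv1_stride = 2L, conv1_pad = 3L,
    unit_widths = as.integer(unit_widths),
    conv6_out = as.integer(conv6_out),
    conv7_out = as.integer(conv7_out),
    feature_dim = as.integer(conv6_out + conv7_out),
    n_classes = as.integer(n_classes)
  ), class = "network_spec")
}

#' Closed-form trainable parameter count of a spec
#'
#' Sums kernel, projection, bias and head scalars layer by layer; used both
#' to validate specs and as the independent check that the instantiated
#' network carries exactly the parameters the architecture promises.
#'
#' @param spec A [network_spec()].
#' @param with_head Include the linear training head.
#' @return Integer parameter count.
#' @export
spec_param_count <- function(spec, with_head = TRUE) {
  k <- spec$conv1_kernel
  n <- k * k * spec$input_channels * spec$conv1_out + spec$conv1_out
  cin <- spec$conv1_out
  for (cout in spec$unit_widths) {
    n <- n + 3 * 3 * cin * cout + cout          # 3x3 conv
    if (cin != cout) n <- n + cin * cout + cout # 1x1 projection
    cin <- cout
  }
  n <- n + 3 * 3 * cin * spec$conv6_out + spec$conv6_out
  n <- n + 3 * 3 * spec$conv6_out * spec$conv7_out + spec$conv7_out
  if (with_head) n <- n + spec$feature_dim * spec$n_classes + spec$n_classes
  as.integer(n)
}

.PARAM_BUDGET <- c(165000L, 175000L)

#' Instantiate the network with seeded He-normal weights
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed driving weight initialisation.
#' @return A `deepid_net` object (list of weight arrays plus the spec).
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  n <- spec_param_count(spec)
  if (n < .PARAM_BUDGET[1] || n > .PARAM_BUDGET[2]) {
    abort_fmt("orthoarc_spec_error",
              sprintf("spec counts %d parameters, outside the pinned budget [%d, %d]",
                      n, .PARAM_BUDGET[1], .PARAM_BUDGET[2]))
  }
  he <- function(kh, kw, cin, cout) {
    sd <- sqrt(2 / (kh * kw * cin))
    array(stats::rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
  }
  params <- withr::with_seed(seed, {
    p <- list(
      conv1_w = he(spec$conv1_kernel, spec$conv1_kernel, spec$input_channels, spec$conv1_out),
      conv1_b = numeric(spec$conv1_out)
    )
    cin <- spec$conv1_out
    for (i in seq_along(spec$unit_widths)) {
      cout <- spec$unit_widths[i]
      u <- paste0("u", i + 1)
      p[[paste0(u, "_w")]] <- he(3, 3, cin, cout)
      p[[paste0(u, "_b")]] <- numeric(cout)
      if (cin != cout) {
        p[[paste0(u, "_pw")]] <- he(1, 1, cin, cout)
        p[[paste0(u, "_pb")]] <- numeric(cout)
      }
      cin <- cout
    }
    p$conv6_w <- he(3, 3, cin, spec$conv6_out)
    p$conv6_b <- numeric(spec$conv6_out)
    p$conv7_w <- he(3, 3, spec$conv6_out, spec$conv7_out)
    p$conv7_b <- numeric(spec$conv7_out)
    # near-zero head so an untrained network scores all classes evenly
    p$head_w <- matrix(stats::rnorm(spec$feature_dim * spec$n_classes, sd = 0.01),
                       spec$feature_dim, spec$n_classes)
    p$head_b <- numeric(spec$n_classes)
    p
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "deepid_net")
}

#' Count trainable parameters of a network
#'
#' @param network A `deepid_net`, or a bare list of numeric arrays.
#' @param with_head Include the training head (ignored for bare lists).
#' @return Integer count of trainable scalars.
#' @export
param_count <- function(network, with_head = TRUE) {
  params <- if (inherits(network, "deepid_net")) network$params else network
  if (!with_head) params <- params[!names(params) %in% c("head_w", "head_b")]
  sum(vapply(params, length, integer(1))) |> as.integer()
}

relu <- function(a) { a[a < 0] <- 0; a }

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  x
}

gap_pool <- function(a) {
  d <- dim(a) # [h, w, c, n]
  m <- matrix(a, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4]) # c x n
}

gap_unpool <- function(dfeat_cn, h, w, n) {
  # dfeat_cn: c x n gradient of the pooled means
  c <- nrow(dfeat_cn)
  array(rep(as.vector(dfeat_cn) / (h * w), each = h * w), c(h, w, c, n))
}

# Forward pass. Returns list(feat = N x 96, logits = N x K or NULL,
# cache = activations for the backward pass when keep = TRUE).
net_forward <- function(net, x, with_head = TRUE, keep = FALSE) {
  p <- net$params
  x <- as_batch(x) - 0.5 # centre pixels
  d <- dim(x)
  if (d[1] < 64 || d[2] < 64) {
    abort_fmt("orthoarc_size_error",
              sprintf("network input must have both sides >= 64, got %dx%d", d[1], d[2]))
  }
  cache <- if (keep) list(x = x) else NULL

  a <- relu(conv2d_fwd(x, p$conv1_w, p$conv1_b, 2L, 3L))
  if (keep) cache$a1 <- a
  pl <- maxpool2_fwd(a)
  if (keep) { cache$idx1 <- pl$idx; cache$dim1 <- dim(a) }
  a <- pl$y

  for (i in 1:4) {
    u <- paste0("u", i + 1)
    if (keep) cache[[paste0(u, "_in")]] <- a
    z <- conv2d_fwd(a, p[[paste0(u, "_w")]], p[[paste0(u, "_b")]], 1L, 1L)
    pw <- p[[paste0(u, "_pw")]]
    z <- z + if (is.null(pw)) a else conv2d_fwd(a, pw, p[[paste0(u, "_pb")]], 1L, 0L)
    a <- relu(z)
    if (keep) cache[[paste0(u, "_out")]] <- a
    if (i < 4) {
      pl <- maxpool2_fwd(a)
      if (keep) { cache[[paste0("idx", i + 1)]] <- pl$idx; cache[[paste0("dim", i + 1)]] <- dim(a) }
      a <- pl$y
    }
  }

  c6 <- relu(conv2d_fwd(a, p$conv6_w, p$conv6_b, 1L, 1L))
  c7 <- relu(conv2d_fwd(c6, p$conv7_w, p$conv7_b, 1L, 1L))
  if (keep) { cache$u5a <- a; cache$c6 <- c6; cache$c7 <- c7 }

  feat <- t(rbind(gap_pool(c6), gap_pool(c7))) # N x 96
  logits <- if (with_head) sweep(feat %*% p$head_w, 2, p$head_b, "+") else NULL
  list(feat = feat, logits = logits, cache = cache)
}

# Backward pass from dlogits (N x K); returns gradients named like params.
net_backward <- function(net, fwd, dlogits) {
  p <- net$params
  cc <- fwd$cache
  g <- list()

  g$head_w <- t(fwd$feat) %*% dlogits
  g$head_b <- colSums(dlogits)
  dfeat <- dlogits %*% t(p$head_w) # N x 96

  d6 <- dim(cc$c6); d7 <- dim(cc$c7)
  n6 <- net$spec$conv6_out
  dc7 <- gap_unpool(t(dfeat[, (n6 + 1):ncol(dfeat), drop = FALSE]), d7[1], d7[2], d7[4])
  dc7 <- dc7 * (cc$c7 > 0)
  b7 <- conv2d_bwd(cc$c6, p$conv7_w, dc7, 1L, 1L, TRUE)
  g$conv7_w <- b7$dw; g$conv7_b <- b7$db

  dc6 <- gap_unpool(t(dfeat[, 1:n6, drop = FALSE]), d6[1], d6[2], d6[4]) + b7$dx
  dc6 <- dc6 * (cc$c6 > 0)
  b6 <- conv2d_bwd(cc$u5a, p$conv6_w, dc6, 1L, 1L, TRUE)
  g$conv6_w <- b6$dw; g$conv6_b <- b6$db

  da <- b6$dx
  for (i in 4:1) {
    u <- paste0("u", i + 1)
    if (i < 4) da <- maxpool2_bwd(da, cc[[paste0("idx", i + 1)]], dim(cc[[paste0(u, "_out")]]))
    dz <- da * (cc[[paste0(u, "_out")]] > 0)
    ain <- cc[[paste0(u, "_in")]]
    bm <- conv2d_bwd(ain, p[[paste0(u, "_w")]], dz, 1L, 1L, TRUE)
    g[[paste0(u, "_w")]] <- bm$dw; g[[paste0(u, "_b")]] <- bm$db
    pw <- p[[paste0(u, "_pw")]]
    if (is.null(pw)) {
      da <- bm$dx + dz
    } else {
      bp <- conv2d_bwd(ain, pw, dz, 1L, 0L, TRUE)
      g[[paste0(u, "_pw")]] <- bp$dw; g[[paste0(u, "_pb")]] <- bp$db
      da <- bm$dx + bp$dx
    }
  }

  da <- maxpool2_bwd(da, cc$idx1, cc$dim1)
  dz <- da * (cc$a1 > 0)
  b1 <- conv2d_bwd(cc$x, p$conv1_w, dz, 2L, 3L, FALSE)
  g$conv1_w <- b1$dw; g$conv1_b <- b1$db
  g[names(net$params)]
}

softmax_xent <- function(logits, y) {
  # y: integer class ids 1..K
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  prob <- e / rowSums(e)
  n <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(prob[cbind(seq_len(n), y)] + eps))
  dlogits <- prob
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n, prob = prob)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with learning rate 0.001,
#' batches of 50, cross-entropy loss. The reference run trains 100 epochs;
#' desk-scale runs on separable synthetic cohorts converge far sooner, so
#' `max_epochs` defaults to 30 and training may stop early once validation
#' accuracy reaches `stop_at_val_acc` (the best-epoch checkpoint is returned
#' either way).
#'
#' @param learning_rate,batch_size,max_epochs,seed Scalars.
#' @param stop_at_val_acc Stop when validation accuracy reaches this value;
#'   set above 1 to disable.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 50L, max_epochs = 30L,
                         seed = 1L, stop_at_val_acc = 1.0) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 0)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 stop_at_val_acc = stop_at_val_acc),
            class = "train_config")
}

predict_batched <- function(net, x, batch_size = 50L, with_head = TRUE) {
  x <- as_batch(x)
  n <- dim(x)[4]
  feats <- NULL; logits <- NULL
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    fw <- net_forward(net, x[, , , ix, drop = FALSE], with_head = with_head, keep = FALSE)
    feats <- rbind(feats, fw$feat)
    if (with_head) logits <- rbind(logits, fw$logits)
  }
  list(feat = feats, logits = logits)
}

#' Train the network with Adam and cross-entropy
#'
#' Runs seeded minibatch SGD (Adam) and returns the checkpoint with the best
#' validation accuracy across epochs, together with a per-epoch history.
#' With `cfg$max_epochs = 0` the initialised network is returned untouched
#' with an empty history.
#'
#' @param x Training images, `[H, W, 3, N]` array (pixel values in `[0, 1]`).
#' @param y Integer class ids `1..K` (the 12 photograph categories).
#' @param x_val,y_val Validation set in the same format.
#' @param cfg A [train_config()].
#' @param net Optional pre-built `deepid_net`; built from `cfg$seed` otherwise.
#' @return List with `network` (best checkpoint) and `history` (tibble with
#'   epoch, train_loss, train_acc, val_acc).
#' @export
train_network <- function(x, y, x_val, y_val, cfg = train_config(), net = NULL) {
  y <- as.integer(y); y_val <- as.integer(y_val)
  if (length(unique(y)) < 2) {
    abort_fmt("orthoarc_training_error", "training needs at least 2 classes")
  }
  if (is.null(net)) net <- build_network(seed = cfg$seed)
  x <- as_batch(x); x_val <- as_batch(x_val)
  n <- dim(x)[4]
  history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                            train_acc = numeric(), val_acc = numeric())
  if (cfg$max_epochs == 0) {
    return(list(network = net, history = history))
  }
  state <- adam_init(net$params)
  best <- list(acc = -Inf, params = net$params)
  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        ix <- ord[start:min(start + cfg$batch_size - 1, n)]
        xb <- x[, , , ix, drop = FALSE]
        fw <- net_forward(net, xb, with_head = TRUE, keep = TRUE)
        sx <- softmax_xent(fw$logits, y[ix])
        tot_loss <- tot_loss + sx$loss * length(ix)
        tot_correct <- tot_correct + sum(max.col(sx$prob, ties.method = "first") == y[ix])
        grads <- net_backward(net, fw, sx$dlogits)
        upd <- adam_step(net$params, grads, state, cfg$learning_rate)
        net$params <- upd$params
        state <- upd$state
      }
      val_pred <- predict_batched(net, x_val, cfg$batch_size)$logits
      val_acc <- mean(max.col(val_pred, ties.method = "first") == y_val)
      history <- tibble::add_row(history, epoch = epoch,
                                 train_loss = tot_loss / n,
                                 train_acc = tot_correct / n,
                                 val_acc = val_acc)
      if (val_acc > best$acc) best <- list(acc = val_acc, params = net$params)
      if (val_acc >= cfg$stop_at_val_acc) break
    }
  })
  net$params <- best$params
  list(network = net, history = history)
}

#' Extract 96-dimensional DeepID features
#'
#' Concatenates the globally average-pooled outputs of the conv6 (64) and
#' conv7 (32) layers. Deterministic for fixed weights and inputs; no state is
#' mutated.
#'
#' @param network A `deepid_net`.
#' @param x One image `[H, W, 3]` or a batch `[H, W, 3, N]`, both sides >= 64.
#' @param batch_size Internal forward batch size.
#' @return `N x 96` matrix of features.
#' @export
extract_deepid <- function(network, x, batch_size = 50L) {
  predict_batched(network, x, batch_size, with_head = FALSE)$feat
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single archive holding the weight arrays keyed by
#' layer name together with the spec and seed.
#'
#' @param network A `deepid_net`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `deepid_net` (load).
#' @export
save_network <- function(network, path) {
  saveRDS(unclass(network), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  structure(obj, class = "deepid_net")
}

#' @export
print.deepid_net <- function(x, ...) {
  cat("<deepid_net> ", param_count(x), " trainable parameters (",
      sprintf("%.2f", param_count(x) / 1e6), " M), feature dim ",
      x$spec$feature_dim, "\n", sep = "")
  invisible(x)
}

#' Tidy the per-layer parameter ledger of a network
#'
#' @param x A `deepid_net`.
#' @param ... Unused.
#' @return Tibble with one row per weight array: layer, shape, parameters.
#' @export
tidy.deepid_net <- function(x, ...) {
  tibble::tibble(
    layer = names(x$params),
    shape = vapply(x$params, function(p) paste(dim(p) %||% length(p), collapse = "x"),
                   character(1)),
    parameters = vapply(x$params, length, integer(1))
  )
}

#' One-row summary of a network
#'
#' @param x A `deepid_net`.
#' @param ... Unused.
#' @return Tibble with parameter counts and feature dimension.
#' @export
glance.deepid_net <- function(x, ...) {
  tibble::tibble(
    n_parameters = param_count(x),
    n_parameters_m = round(param_count(x) / 1e6, 2),
    n_parameters_no_head = param_count(x, with_head = FALSE),
    feature_dim = x$spec$feature_dim,
    n_classes = x$spec$n_classes
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
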