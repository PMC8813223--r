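# Joint Bayesian identity model over DeepID features.
#
# Generative model: a centred feature decomposes as x = mu + eps with
# mu ~ N(0, S_mu) (identity, shared within a class) and eps ~ N(0, S_eps)
# (within-class variation), independent. Verification compares the
# likelihood of two features under the same-identity hypothesis
# (shared mu) against the different-identity hypothesis (independent mu):
# with Sigma = S_mu + S_eps the joint covariances are
#   same:      [[Sigma, S_mu], [S_mu, Sigma]]
#   different: [[Sigma, 0   ], [0,    Sigma]]
# Writing [[Sigma, S_mu],[S_mu, Sigma]]^-1 = [[F+G, G],[G, F+G]] and
# A = Sigma^-1 - (F+G), the log-likelihood ratio is
#   r(x1, x2) = 1/2 (x1' A x1 + x2' A x2) - x1' G x2 + c,
# where c = -1/2 [logdet(S_eps + 2 S_mu) + logdet(S_eps) - 2 logdet(Sigma)]
# collects the determinant terms (c = 0 when S_mu = 0). The constant is the
# same for every pair, so classification by argmax is unaffected by it, but
# including it makes r the exact log-likelihood ratio.

sym <- function(m) (m + t(m)) / 2

logdet_pd <- function(m) 2 * sum(log(diag(chol(m))))

jb_derived <- function(S_mu, S_eps) {
  Sigma <- S_mu + S_eps
  Sigma_inv <- solve(Sigma)
  FG <- solve(Sigma - S_mu %*% Sigma_inv %*% S_mu) # F + G block
  G <- -FG %*% S_mu %*% Sigma_inv
  A <- Sigma_inv - FG
  const <- -0.5 * (logdet_pd(S_eps + 2 * S_mu) + logdet_pd(S_eps) - 2 * logdet_pd(Sigma))
  list(A = sym(A), G = sym(G), const = const)
}

#' Construct a joint Bayesian model from known covariances
#'
#' Mainly useful for testing and for closed-form scenarios; fitted models
#' come from [fit_joint_bayesian()].
#'
#' @param S_mu Between-class (identity) covariance, d x d.
#' @param S_eps Within-class covariance, d x d positive definite.
#' @param mean Global feature mean (subtracted before modelling).
#' @return A `joint_bayes` model with derived verification matrices `A`, `G`.
#' @export
joint_bayes_model <- function(S_mu, S_eps, mean = rep(0, nrow(as.matrix(S_eps)))) {
  S_mu <- sym(as.matrix(S_mu)); S_eps <- sym(as.matrix(S_eps))
  drv <- jb_derived(S_mu, S_eps)
  structure(list(S_mu = S_mu, S_eps = S_eps, mean = as.numeric(mean),
                 A = drv$A, G = drv$G, const = drv$const,
                 d = nrow(S_eps), n_iter = NA_integer_, converged = NA,
                 loglik = NA_real_),
            class = "joint_bayes")
}

#' Fit the joint Bayesian model by EM
#'
#' Alternates an E-step computing, per class, the posterior of the shared
#' identity component given the current covariances with an M-step that
#' re-estimates `S_mu` (across classes) and `S_eps` (across residuals,
#' including posterior uncertainty). A ridge proportional to the mean
#' within-class variance is added to `S_eps` every iteration for positive
#' definiteness. The global feature mean is estimated once and subtracted
#' everywhere.
#'
#' @param features n x d numeric matrix.
#' @param labels Class ids, length n (any atomic type; >= 2 distinct classes,
#'   at least one class with >= 2 samples).
#' @param max_iter,tol EM stopping rule: stop when the largest absolute entry
#'   change of both covariances falls below `tol`.
#' @param ridge Ridge coefficient; default `1e-6 * trace(S_eps)/d` each
#'   iteration.
#' @return A fitted `joint_bayes` model.
#' @export
fit_joint_bayesian <- function(features, labels, max_iter = 100L, tol = 1e-6,
                               ridge = NULL) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) {
    abort_fmt("orthoarc_input_error", "features contain non-finite values")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) {
    abort_fmt("orthoarc_input_error", "labels length must match feature rows")
  }
  classes <- unique(labels)
  if (length(classes) < 2) {
    abort_fmt("orthoarc_fitting_error", "need at least 2 classes to fit the identity model")
  }
  sizes <- table(labels)
  if (all(sizes < 2)) {
    abort_fmt("orthoarc_fitting_error",
              "within-class covariance unidentifiable: every class is a singleton")
  }
  d <- ncol(X)
  mu_hat <- colMeans(X)
  Xc <- sweep(X, 2, mu_hat)

  idx <- split(seq_len(nrow(Xc)), labels)
  class_means <- t(vapply(idx, function(i) colMeans(Xc[i, , drop = FALSE]), numeric(d)))

  # moment initialisation: between = cov of class means, within = pooled residual cov
  S_mu <- sym(crossprod(class_means) / nrow(class_means))
  resid <- Xc - class_means[match(labels, names(idx)), , drop = FALSE]
  S_eps <- sym(crossprod(resid) / nrow(resid))
  base_ridge <- if (is.null(ridge)) 1e-6 * sum(diag(S_eps)) / d else ridge
  S_eps <- S_eps + diag(base_ridge + 1e-10, d)

  n_iter <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    S_mu_acc <- matrix(0, d, d)
    S_eps_acc <- matrix(0, d, d)
    n_total <- 0L
    for (k in seq_along(idx)) {
      i <- idx[[k]]
      m <- length(i)
      Xi <- Xc[i, , drop = FALSE]
      # posterior of the identity component, in a form that never inverts
      # S_mu (stable as S_mu -> 0): cov = S_mu (m S_mu + S_eps)^-1 S_eps
      W <- solve(m * S_mu + S_eps)
      post_cov <- sym(S_mu %*% W %*% S_eps)
      mu_post <- as.numeric(m * (S_mu %*% (W %*% colMeans(Xi))))
      S_mu_acc <- S_mu_acc + post_cov + tcrossprod(mu_post)
      R <- sweep(Xi, 2, mu_post)
      S_eps_acc <- S_eps_acc + crossprod(R) + m * post_cov
      n_total <- n_total + m
    }
    S_mu_new <- sym(S_mu_acc / length(idx))
    S_eps_new <- sym(S_eps_acc / n_total) + diag(base_ridge, d)
    delta <- max(max(abs(S_mu_new - S_mu)), max(abs(S_eps_new - S_eps)))
    S_mu <- S_mu_new
    S_eps <- S_eps_new
    if (delta < tol) { converged <- TRUE; break }
  }

  model <- joint_bayes_model(S_mu, S_eps, mean = mu_hat)
  model$n_iter <- n_iter
  model$converged <- converged
  model$loglik <- jb_loglik(model, X, labels)
  model
}

#' Marginal log-likelihood of labelled features under the model
#'
#' Uses the block-eigenstructure of the class covariance
#' `I (x) S_eps + J (x) S_mu`: the scaled class mean `sqrt(m) xbar` has
#' covariance `S_eps + m S_mu` and the m-1 orthonormal within-class contrasts
#' are i.i.d. `N(0, S_eps)`.
#'
#' @param model A `joint_bayes` model.
#' @param features n x d matrix (uncentred; the model mean is subtracted).
#' @param labels Class ids, length n.
#' @return Scalar log-likelihood.
#' @export
jb_loglik <- function(model, features, labels) {
  X <- sweep(as.matrix(features), 2, model$mean)
  d <- ncol(X)
  Se_inv <- solve(model$S_eps)
  ld_eps <- logdet_pd(model$S_eps)
  ll <- 0
  for (i in split(seq_len(nrow(X)), as.character(labels))) {
    m <- length(i)
    Xi <- X[i, , drop = FALSE]
    xbar <- colMeans(Xi)
    Tm <- model$S_eps + m * model$S_mu
    q_bar <- m * as.numeric(t(xbar) %*% solve(Tm, xbar))
    q_all <- sum((Xi %*% Se_inv) * Xi)
    q_within <- q_all - m * as.numeric(t(xbar) %*% Se_inv %*% xbar)
    ll <- ll - 0.5 * (m * d * log(2 * pi) + logdet_pd(Tm) + (m - 1) * ld_eps +
                        q_bar + q_within)
  }
  ll
}

#' Verification log-likelihood ratio of two features
#'
#' Larger values mean the two features are more likely to share an identity
#' (category). Symmetric in its arguments; identically zero when `S_mu = 0`.
#'
#' @param model A `joint_bayes` model.
#' @param x1,x2 Feature vectors of dimension `model$d` (uncentred).
#' @return Scalar log-likelihood ratio.
#' @export
verification_ratio <- function(model, x1, x2) {
  if (length(x1) != model$d || length(x2) != model$d) {
    abort_fmt("orthoarc_input_error",
              sprintf("features must have dimension %d", model$d))
  }
  x1 <- as.numeric(x1) - model$mean
  x2 <- as.numeric(x2) - model$mean
  0.5 * (sum(x1 * (model$A %*% x1)) + sum(x2 * (model$A %*% x2))) -
    sum(x1 * (model$G %*% x2)) + model$const
}

#' Build a gallery of per-category mean features
#'
#' @param features n x d matrix of training features (uncentred).
#' @param labels Category labels, length n.
#' @param model Fitted `joint_bayes` model (supplies the global mean).
#' @param categories Required category order; defaults to the 12 photograph
#'   classes.
#' @return A `gallery` object: `class_means` is a `length(categories) x d`
#'   matrix of centred per-category means.
#' @export
build_gallery <- function(features, labels, model,
                          categories = ortho_categories("rgb")) {
  X <- sweep(as.matrix(features), 2, model$mean)
  labels <- as.character(labels)
  missing <- setdiff(categories, unique(labels))
  if (length(missing) > 0) {
    abort_fmt("orthoarc_config_error",
              paste0("gallery is missing categories: ", paste(missing, collapse = ", ")))
  }
  cm <- t(vapply(categories, function(ct) colMeans(X[labels == ct, , drop = FALSE]),
                 numeric(ncol(X))))
  structure(list(class_means = cm, categories = categories, d = ncol(X)),
            class = "gallery")
}

#' Classify features against the gallery by verification ratio
#'
#' Scores each query against every gallery mean with [verification_ratio()]
#' and returns the argmax label; ties break to the lowest category index.
#' The score matrix doubles as the per-class ROC input.
#'
#' @param model Fitted `joint_bayes` model.
#' @param gallery A [build_gallery()] result.
#' @param x Feature vector or n x d matrix (uncentred).
#' @return List with `label` (character vector) and `scores`
#'   (n x n_categories matrix, columns named by category).
#' @export
classify_rgb <- function(model, gallery, x) {
  if (!inherits(gallery, "gallery") || nrow(gallery$class_means) == 0) {
    abort_fmt("orthoarc_config_error", "complete gallery required")
  }
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != model$d) {
    abort_fmt("orthoarc_input_error",
              sprintf("features must have dimension %d", model$d))
  }
  Xc <- sweep(X, 2, model$mean)
  M <- gallery$class_means # centred already
  qx <- 0.5 * rowSums((Xc %*% model$A) * Xc)           # n
  qm <- 0.5 * rowSums((M %*% model$A) * M)             # K
  cross <- Xc %*% model$G %*% t(M)                     # n x K
  scores <- outer(qx, qm, "+") - cross + model$const
  colnames(scores) <- gallery$categories
  label <- gallery$categories[apply(scores, 1, which.max)] # which.max: first max
  list(label = label, scores = scores)
}

#' Save / load a joint Bayesian model
#'
#' The archive holds the mean and the two covariances; the derived
#' verification matrices are recomputed on load.
#'
#' @param model A `joint_bayes` model.
#' @param path File path.
#' @return `path` (save) or the restored model (load).
#' @export
save_joint_bayes <- function(model, path) {
  saveRDS(list(S_mu = model$S_mu, S_eps = model$S_eps, mean = model$mean,
               n_iter = model$n_iter, converged = model$converged,
               loglik = model$loglik), path)
  invisible(path)
}

#' @rdname save_joint_bayes
#' @export
load_joint_bayes <- function(path) {
  obj <- readRDS(path)
  model <- joint_bayes_model(obj$S_mu, obj$S_eps, obj$mean)
  model$n_iter <- obj$n_iter
  model$converged <- obj$converged
  model$loglik <- obj$loglik
  model
}

#' @export
print.joint_bayes <- function(x, ...) {
  cat("<joint_bayes> d =", x$d,
      "| EM iterations:", x$n_iter,
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' One-row summary of a fitted joint Bayesian model
#'
#' @param x A `joint_bayes` model.
#' @param ... Unused.
#' @return Tibble with dimension, iterations, convergence flag, log-likelihood
#'   and the traces of the two covariances.
#' @export
glance.joint_bayes <- function(x, ...) {
  tibble::tibble(
    d = x$d, n_iter = x$n_iter, converged = x$converged, loglik = x$loglik,
    trace_s_mu = sum(diag(x$S_mu)), trace_s_eps = sum(diag(x$S_eps))
  )
}
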