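# Single fully connected layer classifier over encoder features, with two
# similarity modes: the plain inner product ||w|| ||z|| cos(theta) for
# large training sets, and the t-vMF pseudo inner product
# ||w|| ||z|| phi(cos(theta); tau) for small ones, where
# phi(c; tau) = (1 + c) / (1 + tau (1 - c)) - 1 compresses the similarity
# of poorly aligned directions and tightens class clusters.

#' t-vMF similarity
#'
#' The concentration-parameterised squashing of cosine similarity,
#' `phi(c; tau) = (1 + c) / (1 + tau * (1 - c)) - 1`. For `tau = 0` it is
#' the identity (plain cosine similarity); for growing `tau` it pushes all
#' but well-aligned directions towards -1. Maps `[-1, 1]` onto `[-1, 1]`,
#' strictly increasing in `cos_theta`.
#'
#' @param cos_theta Numeric vector of cosines, in `[-1, 1]` (values within
#'   1e-9 outside are clamped).
#' @param tau Non-negative concentration parameter.
#' @return Numeric vector of similarities in `[-1, 1]`.
#' @export
tvmf_similarity <- function(cos_theta, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("invalid parameter: tau must be a single non-negative number",
         call. = FALSE)
  if (any(abs(cos_theta) > 1 + 1e-9))
    stop("invalid input: |cos_theta| exceeds 1", call. = FALSE)
  ct <- pmin(pmax(cos_theta, -1), 1)
  (1 + ct) / (1 + tau * (1 - ct)) - 1
}

# derivative of phi w.r.t. cos_theta: (1 + 2 tau) / (1 + tau (1 - c))^2
tvmf_similarity_grad <- function(cos_theta, tau) {
  ct <- pmin(pmax(cos_theta, -1), 1)
  (1 + 2 * tau) / (1 + tau * (1 - ct))^2
}

#' Create classifier weights
#'
#' @param d Feature dimension.
#' @param C Number of in-distribution classes.
#' @param mode `"cosine"` or `"tvmf"`.
#' @param tau t-vMF concentration (ignored for cosine mode; default 64).
#' @param normalize_features Scale every feature vector to unit length
#'   before the similarity (the common variant in the t-vMF literature);
#'   default `FALSE`, i.e. magnitudes retained.
#' @param seed Seed for the Gaussian initialisation.
#' @return List of class `"classifier_weights"` with the `C x d` weight
#'   matrix `W`, `mode`, `tau` and `normalize_features`.
#' @export
init_classifier <- function(d, C, mode = c("cosine", "tvmf"), tau = 64,
                            normalize_features = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (tau < 0) stop("invalid parameter: tau must be >= 0", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  structure(list(W = matrix(stats::rnorm(C * d, sd = 1 / sqrt(d)), C, d),
                 mode = mode, tau = tau,
                 normalize_features = isTRUE(normalize_features),
                 C = as.integer(C), d = as.integer(d)),
            class = "classifier_weights")
}

as_feature_matrix <- function(z, d) {
  if (is.null(dim(z))) z <- matrix(z, 1L)
  if (ncol(z) != d)
    stop("invalid input: feature dimension ", ncol(z), " != ", d, call. = FALSE)
  z
}

#' Classifier logits
#'
#' Cosine mode returns the ordinary inner products `z . w_c`
#' (`= ||w_c|| ||z|| cos(theta_c)`); t-vMF mode returns
#' `||w_c|| ||z|| phi(cos(theta_c); tau)`. Magnitudes are retained (no
#' feature normalisation).
#'
#' @param z Feature vector of length `d` or an `N x d` matrix.
#' @param weights A `"classifier_weights"` object.
#' @return `N x C` matrix of logits.
#' @export
classifier_logits <- function(z, weights) {
  z <- as_feature_matrix(z, weights$d)
  if (!all(is.finite(z))) stop("invalid input: non-finite features", call. = FALSE)
  zn <- sqrt(rowSums(z^2))
  wn <- sqrt(rowSums(weights$W^2))
  if (any(zn == 0) || any(wn == 0))
    stop("degenerate vector: zero-norm feature or weight (cosine undefined)",
         call. = FALSE)
  if (isTRUE(weights$normalize_features)) {
    z <- z / zn
    zn <- rep(1, length(zn))
  }
  ip <- tcrossprod(z, weights$W)  # N x C
  if (weights$mode == "cosine") return(ip)
  cs <- ip / outer(zn, wn)
  outer(zn, wn) * tvmf_similarity(cs, weights$tau)
}

#' Softmax class probabilities
#'
#' Max-shifted softmax over logits, numerically safe for large values.
#'
#' @param logits Numeric vector or `N x C` matrix.
#' @return Matrix of probabilities with rows summing to one.
#' @export
predict_proba <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1L)
  if (!all(is.finite(logits)))
    stop("invalid input: non-finite logits", call. = FALSE)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Predict class labels
#'
#' Argmax of the softmax probabilities; exact ties resolve to the lowest
#' class index.
#'
#' @inheritParams classifier_logits
#' @return Integer vector of predicted labels in `1..C`.
#' @export
predict_class <- function(z, weights) {
  p <- predict_proba(classifier_logits(z, weights))
  apply(p, 1L, which.max)
}

#' Mean cross-entropy loss
#'
#' `-(1/N) sum_i log P(y = y_i | x_i)`, with probabilities floored at
#' 1e-12 before the logarithm.
#'
#' @param probs `N x C` matrix of class probabilities.
#' @param labels Integer labels in `1..C`.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1L)
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > ncol(probs)))
    stop("invalid label: labels must lie in 1..C", call. = FALSE)
  if (length(labels) != nrow(probs))
    stop("invalid input: one label per probability row required", call. = FALSE)
  p <- probs[cbind(seq_len(nrow(probs)), labels)]
  -mean(log(pmax(p, 1e-12)))
}

#' Choose the similarity mode from the training-set size
#'
#' Large training sets use the plain cosine classifier; small ones the
#' t-vMF classifier. The boundary counts as large.
#'
#' @param n_train Number of training samples.
#' @param threshold Size at and above which cosine mode is used (default
#'   5000).
#' @return `"cosine"` or `"tvmf"`.
#' @export
select_mode <- function(n_train, threshold = 5000L) {
  stopifnot(n_train >= 1)
  if (n_train >= threshold) "cosine" else "tvmf"
}

# logits with zero-norm clamping (inference path: a degenerate feature
# scores like an unaligned one rather than aborting the batch)
classifier_logits_safe <- function(z, weights) {
  z <- as_feature_matrix(z, weights$d)
  zn <- pmax(sqrt(rowSums(z^2)), 1e-12)
  wn <- pmax(sqrt(rowSums(weights$W^2)), 1e-12)
  if (isTRUE(weights$normalize_features)) {
    z <- z / zn
    zn <- rep(1, length(zn))
  }
  ip <- tcrossprod(z, weights$W)
  if (weights$mode == "cosine") return(ip)
  cs <- pmin(pmax(ip / outer(zn, wn), -1), 1)
  outer(zn, wn) * tvmf_similarity(cs, weights$tau)
}

# loss + gradients w.r.t. W and z for a batch (used by the training loop).
# Returns list(loss, probs, dW (C x d), dZ (N x d)).
classifier_grad <- function(z, weights, labels) {
  z <- as_feature_matrix(z, weights$d)
  N <- nrow(z); C <- weights$C
  # norms clamped away from zero: a dead (all-zero) feature vector gets a
  # well-defined zero-similarity gradient instead of an error mid-training
  zn0 <- pmax(sqrt(rowSums(z^2)), 1e-12)
  normed <- isTRUE(weights$normalize_features)
  if (normed) z <- z / zn0
  zn <- if (normed) rep(1, nrow(z)) else zn0
  wn <- pmax(sqrt(rowSums(weights$W^2)), 1e-12)
  ip <- tcrossprod(z, weights$W)
  nz <- outer(zn, wn)
  cs <- pmin(pmax(ip / nz, -1), 1)
  if (weights$mode == "cosine") {
    logits <- ip
  } else {
    logits <- nz * tvmf_similarity(cs, weights$tau)
  }
  P <- predict_proba(logits)
  loss <- cross_entropy_loss(P, labels)
  Y <- matrix(0, N, C); Y[cbind(seq_len(N), labels)] <- 1
  G <- (P - Y) / N            # dLoss/dlogits
  if (weights$mode == "cosine") {
    dW <- crossprod(G, z)     # C x d
    dZ <- G %*% weights$W
  } else {
    phi <- tvmf_similarity(cs, weights$tau)
    dphi <- tvmf_similarity_grad(cs, weights$tau)
    Zh <- z / zn; Wh <- weights$W / wn
    # logit = ||w|| ||z|| phi(c), c = <zh, wh>
    # d/dw = ||z|| (phi - dphi * c) wh + ||z|| dphi * zh
    A <- G * matrix(zn, N, C) * (phi - dphi * cs)
    B <- G * matrix(zn, N, C) * dphi
    dW <- colSums(A) * Wh + crossprod(B, Zh)
    # d/dz = ||w|| (phi - dphi * c) zh + ||w|| dphi * wh
    A2 <- G * matrix(wn, N, C, byrow = TRUE) * (phi - dphi * cs)
    B2 <- G * matrix(wn, N, C, byrow = TRUE) * dphi
    dZ <- rowSums(A2) * Zh + B2 %*% Wh
  }
  if (normed) {
    # chain rule through z -> z / ||z||: project out the radial component
    dZ <- (dZ - rowSums(dZ * z) * z) / zn0
  }
  list(loss = loss, probs = P, dW = dW, dZ = dZ)
}
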