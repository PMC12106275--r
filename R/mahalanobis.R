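# Class-conditional Gaussian model over encoder features: one prototype
# (mean) per class and a single tied covariance pooled over all classes,
# normalised by the total sample count N. The confidence score of a
# feature z is the negated squared Mahalanobis distance to the nearest
# prototype; features scoring below a calibrated threshold lambda are
# declared out-of-distribution.

#' Fit class-conditional Gaussians with a tied covariance
#'
#' Computes per-class mean prototypes and the pooled within-class
#' covariance `(1/N) * sum_c sum_{i in c} (z_i - mu_c)(z_i - mu_c)^T`.
#' The precision matrix is computed from `Sigma + ridge * (tr(Sigma)/d) * I`
#' (plain `ridge * I` when the covariance is zero), which guarantees
#' invertibility when `N <= d`.
#'
#' @param features `N x d` numeric matrix of encoder features.
#' @param labels Integer class labels in `1..C`; every class needs at
#'   least 2 samples.
#' @param ridge Relative ridge coefficient (default 1e-3).
#' @return List of class `"gaussian_class_model"` with `prototypes`
#'   (`C x d`), `covariance`, `precision`, `ridge_used`, `counts`,
#'   `n_total`.
#' @export
fit_class_gaussians <- function(features, labels, ridge = 1e-3) {
  features <- as.matrix(features)
  if (!all(is.finite(features)))
    stop("invalid input: non-finite features", call. = FALSE)
  labels <- as.integer(labels)
  C <- max(labels)
  if (any(labels < 1L)) stop("invalid label: labels must be in 1..C", call. = FALSE)
  counts <- tabulate(labels, C)
  if (any(counts < 2L))
    stop("insufficient data: every class needs >= 2 samples (class ",
         paste(which(counts < 2L), collapse = ","), " has fewer)", call. = FALSE)
  N <- nrow(features); d <- ncol(features)
  mu <- matrix(0, C, d)
  Xc <- features
  for (c in seq_len(C)) {
    idx <- labels == c
    mu[c, ] <- colMeans(features[idx, , drop = FALSE])
    Xc[idx, ] <- sweep(features[idx, , drop = FALSE], 2L, mu[c, ])
  }
  Sigma <- crossprod(Xc) / N
  lam <- ridge * sum(diag(Sigma)) / d
  if (lam <= 0) lam <- ridge
  prec <- chol2inv(chol(Sigma + diag(lam, d)))
  structure(list(prototypes = mu, covariance = Sigma, precision = prec,
                 ridge = ridge, ridge_used = lam, counts = counts,
                 n_total = N, d = d, C = C),
            class = "gaussian_class_model")
}

#' Mahalanobis distance to a class prototype
#'
#' `sqrt((z - mu_c)^T Sigma^{-1} (z - mu_c))` using the model's tied
#' (ridge-regularised) precision.
#'
#' @param z Feature vector of length `d` or `N x d` matrix.
#' @param model A fitted [fit_class_gaussians()] model.
#' @param c Class index in `1..C`.
#' @return Non-negative distance(s).
#' @export
mahalanobis_distance <- function(z, model, c) {
  stopifnot(inherits(model, "gaussian_class_model"))
  if (c < 1L || c > model$C) stop("invalid input: class index out of range",
                                  call. = FALSE)
  z <- as_feature_matrix(z, model$d)
  dlt <- sweep(z, 2L, model$prototypes[c, ])
  sqrt(pmax(rowSums((dlt %*% model$precision) * dlt), 0))
}

#' Confidence score for OOD detection
#'
#' `S(z) = max_c -d_M(z, G_c)^2`: zero when `z` sits on a prototype,
#' increasingly negative as `z` moves away from every class Gaussian.
#'
#' @inheritParams mahalanobis_distance
#' @return Numeric score(s) `<= 0`.
#' @export
confidence_score <- function(z, model) {
  stopifnot(inherits(model, "gaussian_class_model"))
  z <- as_feature_matrix(z, model$d)
  d2 <- sapply(seq_len(model$C), function(c) {
    dlt <- sweep(z, 2L, model$prototypes[c, ])
    rowSums((dlt %*% model$precision) * dlt)
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = nrow(z))
  -apply(d2, 1L, min)
}

#' Calibrate the ID-acceptance threshold
#'
#' Picks the largest `lambda` such that at least `target_tpr` of the
#' calibration scores satisfy `S >= lambda` (the empirical
#' `(1 - target_tpr)`-quantile with lower interpolation), so the achieved
#' true-positive rate on the calibration set is at least the target.
#'
#' @param id_scores Confidence scores of held-out in-distribution samples
#'   (at least 20).
#' @param target_tpr Required ID acceptance rate, default 0.95.
#' @return The threshold `lambda`.
#' @export
calibrate_threshold <- function(id_scores, target_tpr = 0.95) {
  if (length(id_scores) < 20L)
    stop("insufficient data: need >= 20 calibration scores", call. = FALSE)
  stopifnot(target_tpr > 0, target_tpr <= 1)
  s <- sort(id_scores, decreasing = TRUE)
  s[ceiling(target_tpr * length(s))]
}

#' Decide ID vs OOD for a feature
#'
#' A feature is in-distribution iff its confidence score is at least
#' `lambda` (ties accept).
#'
#' @inheritParams confidence_score
#' @param lambda Decision threshold from [calibrate_threshold()].
#' @return A data.frame with columns `score` and `label` (`"ID"` /
#'   `"OOD"`).
#' @export
detect <- function(z, model, lambda) {
  stopifnot(is.finite(lambda))
  s <- confidence_score(z, model)
  data.frame(score = s, label = ifelse(s >= lambda, "ID", "OOD"))
}
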