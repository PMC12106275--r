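# Training and inference orchestration. cryowave() is the fitting
# function: it optimises the DWT encoder and the adaptive classifier with
# SGD on the cross-entropy loss (random right-angle rotation
# augmentation), then fits the class-conditional Gaussian OOD model on
# augmentation-free evaluation-mode features and calibrates the
# ID-acceptance threshold on a held-out validation split. predict() runs
# the full inference path: encode -> detect -> classify-or-discard.

#' Training configuration
#'
#' Defaults follow the standard SGD recipe used for the method: 100
#' epochs, batch size 64, learning rate 0.1, momentum 0.9, weight decay
#' 1e-4, random rotation augmentation.
#'
#' @param epochs,batch_size,learning_rate,momentum,weight_decay SGD
#'   hyper-parameters; all positive (weight decay non-negative).
#' @param augment Apply a random right-angle rotation to every training
#'   volume each epoch.
#' @param val_fraction Stratified fraction of training data held out for
#'   threshold calibration.
#' @param target_tpr ID true-positive rate the threshold is calibrated
#'   to.
#' @param seed Integer seed controlling all randomness of the fit.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         learning_rate = 0.1, momentum = 0.9,
                         weight_decay = 1e-4, augment = TRUE,
                         val_fraction = 0.1, target_tpr = 0.95, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            momentum >= 0, momentum < 1, weight_decay >= 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, augment = isTRUE(augment),
                 val_fraction = val_fraction, target_tpr = target_tpr,
                 seed = as.integer(seed)), class = "train_config")
}

# one SGD update with momentum; buffers live in the environment `opt`
opt_update <- function(opt, name, param, grad, lr, momentum, decay) {
  g <- grad + decay * param
  buf <- opt[[name]]
  if (is.null(buf)) buf <- 0 * g
  buf <- momentum * buf + g
  opt[[name]] <- buf
  param - lr * buf
}

apply_gradients <- function(state, weights, genc, dW, cfg, opt) {
  lr <- cfg$learning_rate; mo <- cfg$momentum; wd <- cfg$weight_decay
  state$stem$W <- opt_update(opt, "stem.W", state$stem$W, genc$stem$W, lr, mo, wd)
  state$stem$bn$gamma <- opt_update(opt, "stem.g", state$stem$bn$gamma,
                                    genc$stem$bn$gamma, lr, mo, 0)
  state$stem$bn$beta <- opt_update(opt, "stem.b", state$stem$bn$beta,
                                   genc$stem$bn$beta, lr, mo, 0)
  for (i in seq_along(state$blocks)) {
    b <- state$blocks[[i]]; g <- genc$blocks[[i]]; p <- paste0("b", i, ".")
    b$W1 <- opt_update(opt, paste0(p, "W1"), b$W1, g$W1, lr, mo, wd)
    b$bn1$gamma <- opt_update(opt, paste0(p, "g1"), b$bn1$gamma, g$bn1$gamma, lr, mo, 0)
    b$bn1$beta <- opt_update(opt, paste0(p, "b1"), b$bn1$beta, g$bn1$beta, lr, mo, 0)
    b$W2 <- opt_update(opt, paste0(p, "W2"), b$W2, g$W2, lr, mo, wd)
    b$bn2$gamma <- opt_update(opt, paste0(p, "g2"), b$bn2$gamma, g$bn2$gamma, lr, mo, 0)
    b$bn2$beta <- opt_update(opt, paste0(p, "b2"), b$bn2$beta, g$bn2$beta, lr, mo, 0)
    if (!is.null(b$Wp)) {
      b$Wp <- opt_update(opt, paste0(p, "Wp"), b$Wp, g$Wp, lr, mo, wd)
      b$bnp$gamma <- opt_update(opt, paste0(p, "gp"), b$bnp$gamma, g$bnp$gamma, lr, mo, 0)
      b$bnp$beta <- opt_update(opt, paste0(p, "bp"), b$bnp$beta, g$bnp$beta, lr, mo, 0)
    }
    state$blocks[[i]] <- b
  }
  weights$W <- opt_update(opt, "clf.W", weights$W, dW, lr, mo, wd)
  list(state = state, weights = weights)
}

#' Fit the subtomogram classification pipeline
#'
#' Trains the DWT encoder and the adaptive similarity classifier jointly
#' by SGD on the cross-entropy loss, then fits the Gaussian OOD reference
#' (per-class prototypes, tied covariance) on evaluation-mode,
#' augmentation-free training features, and calibrates the ID-acceptance
#' threshold `lambda` on a stratified held-out validation split (falling
#' back to training features when the split is too small).
#'
#' The classifier mode is chosen from the training-set size
#' ([select_mode()]): cosine similarity for large sets, t-vMF similarity
#' (concentration `tau`) for small ones.
#'
#' @param x Training volumes: list of 3D arrays or a 4D array (samples
#'   last).
#' @param y Integer class labels in `1..C`; every class needs at least 2
#'   samples.
#' @param encoder An [encoder_config()]; default is the `"tiny"` preset.
#' @param config A [train_config()].
#' @param mode `"auto"` (default), `"cosine"` or `"tvmf"`.
#' @param tau t-vMF concentration, default 64.
#' @param normalize_features Unit-normalise features inside the
#'   classifier (see [init_classifier()]).
#' @param mode_threshold Training-set size at which `"auto"` switches to
#'   cosine mode.
#' @param ridge Ridge coefficient of the OOD covariance.
#' @param verbose Print the per-epoch loss.
#' @return An object of class `"cryowave"`: the trained encoder state,
#'   classifier weights, Gaussian model, threshold `lambda`, per-epoch
#'   `loss` and configuration. Use [predict.cryowave()] to run
#'   inference.
#' @export
cryowave <- function(x, y, encoder = encoder_config("tiny"),
                     config = train_config(), mode = "auto", tau = 64,
                     normalize_features = FALSE, mode_threshold = 5000L,
                     ridge = 1e-3, verbose = FALSE) {
  stopifnot(inherits(encoder, "encoder_config"),
            inherits(config, "train_config"))
  if (is.array(x) && length(dim(x)) == 4L)
    x <- lapply(seq_len(dim(x)[4L]), function(i) x[, , , i])
  if (is.array(x) && length(dim(x)) == 3L) x <- list(x)
  y <- as.integer(y)
  n <- length(x)
  if (length(y) != n) stop("invalid input: one label per volume required",
                           call. = FALSE)
  C <- max(y)
  if (any(y < 1L)) stop("invalid label: labels must be in 1..C", call. = FALSE)
  if (any(tabulate(y, C) < 2L))
    stop("insufficient data: every class in 1..", C,
         " needs at least 2 samples", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  if (mode == "auto") mode <- select_mode(n, mode_threshold)
  state <- init_encoder(encoder)
  weights <- init_classifier(encoder$feature_dim, C, mode = mode, tau = tau,
                             normalize_features = normalize_features,
                             seed = config$seed + 1L)

  # stratified validation split for threshold calibration
  val_idx <- integer(0)
  if (config$val_fraction > 0) {
    for (c in seq_len(C)) {
      idx <- which(y == c)
      k <- floor(config$val_fraction * length(idx))
      if (k > 0) val_idx <- c(val_idx, sample(idx, k))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  # standardise once; right-angle rotations commute with standardisation
  xs <- lapply(x, function(v) {
    s <- stats::sd(v); if (s > 0) (v - mean(v)) / s else v - mean(v)
  })

  v <- prod(encoder$input_shape)
  losses <- numeric(config$epochs)
  opt <- new.env(parent = emptyenv())
  for (ep in seq_len(config$epochs)) {
    perm <- sample(tr_idx)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(perm), by = config$batch_size)) {
      bi <- perm[start:min(start + config$batch_size - 1L, length(perm))]
      B <- length(bi)
      X <- array(0, c(v, B, 1L))
      for (j in seq_len(B)) {
        xv <- xs[[bi[j]]]
        if (config$augment) xv <- random_rotation_augment(xv)
        X[, j, 1L] <- xv
      }
      fw <- encoder_forward(state, X, training = TRUE)
      state <- fw$state
      cg <- classifier_grad(fw$z, weights, y[bi])
      genc <- encoder_backward(state, fw$caches, cg$dZ)
      up <- apply_gradients(state, weights, genc, cg$dW, config, opt)
      state <- up$state; weights <- up$weights
      ep_loss <- ep_loss + cg$loss; nb <- nb + 1L
    }
    losses[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, losses[ep]))
  }

  # OOD reference: evaluation-mode features, no augmentation
  feats <- encode_in_batches(xs[tr_idx], state, config$batch_size)
  gm <- fit_class_gaussians(feats, y[tr_idx], ridge = ridge)
  cal_feats <- if (length(val_idx) >= 20L)
    encode_in_batches(xs[val_idx], state, config$batch_size) else feats
  lambda <- calibrate_threshold(confidence_score(cal_feats, gm),
                                config$target_tpr)

  structure(list(encoder = state, classifier = weights, gaussian = gm,
                 lambda = lambda, loss = losses, n_classes = C,
                 n_train = length(tr_idx), n_val = length(val_idx),
                 config = config, encoder_config = encoder,
                 calibrated_on = if (length(val_idx) >= 20L) "validation"
                                 else "training"),
            class = "cryowave")
}

# encode standardised volumes in manageable batches (evaluation mode)
encode_in_batches <- function(xs, state, batch_size = 64L) {
  v <- prod(state$cfg$input_shape)
  out <- matrix(0, length(xs), state$cfg$feature_dim)
  for (start in seq(1L, length(xs), by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, length(xs))
    X <- array(0, c(v, length(bi), 1L))
    for (j in seq_along(bi)) X[, j, 1L] <- xs[[bi[j]]]
    out[bi, ] <- encoder_forward(state, X, training = FALSE)$z
  }
  out
}

#' Inference on new volumes
#'
#' Encodes each volume, scores it against the Gaussian OOD reference and
#' either discards it (decision `"OOD"`, no class probabilities) or
#' classifies it with the trained similarity classifier.
#'
#' @param object A fitted `"cryowave"` pipeline.
#' @param newdata Volumes: list of 3D arrays or a 4D array.
#' @param sample_ids Optional identifiers (default `sample_1 ...`).
#' @param ... Unused.
#' @return data.frame with columns `sample_id`, `score`, `decision`,
#'   `predicted_label` (NA when discarded) and `prob.<c>` per class (NA
#'   when discarded).
#' @export
predict.cryowave <- function(object, newdata, sample_ids = NULL, ...) {
  if (is.null(object$lambda))
    stop("uncalibrated pipeline: no threshold lambda", call. = FALSE)
  if (is.array(newdata) && length(dim(newdata)) == 4L)
    newdata <- lapply(seq_len(dim(newdata)[4L]), function(i) newdata[, , , i])
  if (is.array(newdata) && length(dim(newdata)) == 3L) newdata <- list(newdata)
  xs <- lapply(newdata, function(v) {
    s <- stats::sd(v); if (s > 0) (v - mean(v)) / s else v - mean(v)
  })
  z <- encode_in_batches(xs, object$encoder, object$config$batch_size)
  dec <- detect(z, object$gaussian, object$lambda)
  C <- object$n_classes
  probs <- matrix(NA_real_, nrow(z), C)
  label <- rep(NA_integer_, nrow(z))
  id <- dec$label == "ID"
  if (any(id)) {
    p <- predict_proba(classifier_logits_safe(z[id, , drop = FALSE],
                                              object$classifier))
    probs[id, ] <- p
    label[id] <- apply(p, 1L, which.max)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(z)))
  out <- data.frame(sample_id = sample_ids, score = dec$score,
                    decision = dec$label, predicted_label = label,
                    stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob.", seq_len(C))
  cbind(out, probs)
}

#' Classify-or-discard inference (functional form)
#'
#' @param volumes Volumes to score and classify.
#' @param state A fitted `"cryowave"` pipeline.
#' @return See [predict.cryowave()].
#' @export
infer <- function(volumes, state) {
  stopifnot(inherits(state, "cryowave"))
  predict(state, volumes)
}

#' @export
print.cryowave <- function(x, ...) {
  cat("Subtomogram classification pipeline (cryowave)\n")
  cat("  classes:           ", x$n_classes, "\n")
  cat("  classifier mode:   ", x$classifier$mode,
      if (x$classifier$mode == "tvmf") sprintf("(tau = %g)", x$classifier$tau),
      "\n")
  cat("  feature dimension: ", x$encoder_config$feature_dim, "\n")
  cat("  wavelet bank:      ", x$encoder_config$bank_name, "\n")
  cat(sprintf("  OOD threshold:      %.4f (%.0f%% TPR, %s set)\n",
              x$lambda, 100 * x$config$target_tpr, x$calibrated_on))
  cat(sprintf("  final train loss:   %.4f (%d epochs)\n",
              x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

#' @export
summary.cryowave <- function(object, ...) {
  print(object)
  cat("\nTraining loss by epoch:\n")
  print(round(object$loss, 4))
  cat("\nPer-class training sample counts:\n")
  print(object$gaussian$counts)
  invisible(object)
}

#' @export
coef.cryowave <- function(object, ...) object$classifier$W

#' @export
plot.cryowave <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "b", pch = 19,
                 xlab = "epoch", ylab = "mean cross-entropy loss",
                 main = "Training loss", ...)
  invisible(x)
}

#' Persist / restore a fitted pipeline
#'
#' Single-file archive (RDS) of encoder state, classifier weights,
#' Gaussian model, threshold and configuration, with a format version.
#'
#' @param object Fitted `"cryowave"` pipeline.
#' @param path File path.
#' @return `save_pipeline`: invisibly, `path`; `load_pipeline`: the
#'   pipeline.
#' @export
save_pipeline <- function(object, path) {
  stopifnot(inherits(object, "cryowave"))
  saveRDS(list(format_version = 1L, pipeline = object), path)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version) ||
      !inherits(obj$pipeline, "cryowave"))
    stop("format error: not a cryowave pipeline archive", call. = FALSE)
  obj$pipeline
}
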