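# Open-set evaluation: AUROC and FPR@TPR over ID/OOD confidence scores,
# mixed-set accuracy (an OOD sample counts correct iff it is discarded),
# and score-distribution / embedding diagnostics.

#' Area under the ROC curve for ID-vs-OOD separation
#'
#' Computed as the pairwise probability `P(S_id > S_ood) + 0.5 P(tie)`
#' via midranks (equivalent to the Mann-Whitney statistic).
#'
#' @param id_scores,ood_scores Non-empty numeric score vectors; higher
#'   means more in-distribution.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(id_scores, ood_scores) {
  if (length(id_scores) == 0L || length(ood_scores) == 0L)
    stop("invalid input: empty score vector", call. = FALSE)
  r <- rank(c(id_scores, ood_scores))
  n1 <- length(id_scores); n2 <- length(ood_scores)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' False-positive rate at a fixed ID true-positive rate
#'
#' Sets the threshold to the largest value accepting at least
#' `target_tpr` of the ID scores, then reports the fraction of OOD scores
#' at or above it (ties count as false positives). `target_tpr = 0.95`
#' gives the usual FPR95.
#'
#' @inheritParams auroc
#' @param target_tpr Required ID acceptance rate.
#' @return FPR in `[0, 1]`.
#' @export
fpr_at_tpr <- function(id_scores, ood_scores, target_tpr = 0.95) {
  if (length(id_scores) == 0L || length(ood_scores) == 0L)
    stop("invalid input: empty score vector", call. = FALSE)
  s <- sort(id_scores, decreasing = TRUE)
  lambda <- s[ceiling(target_tpr * length(s))]
  mean(ood_scores >= lambda)
}

#' Mixed-set accuracy with an OOD rejection branch
#'
#' An ID sample is correct iff it was detected as ID and its predicted
#' label matches the truth; an OOD sample is correct iff it was discarded.
#'
#' @param predictions A data.frame with columns `decision` (`"ID"` /
#'   `"OOD"`) and `predicted_label` (integer or NA), one row per sample,
#'   e.g. from [infer()].
#' @param truth Integer vector of true labels, with `NA` marking OOD
#'   samples.
#' @return Fraction of correct samples.
#' @export
mixed_accuracy <- function(predictions, truth) {
  if (nrow(predictions) != length(truth))
    stop("invalid input: one prediction per truth record required",
         call. = FALSE)
  is_ood <- is.na(truth)
  ok_ood <- is_ood & predictions$decision == "OOD"
  ok_id <- !is_ood & predictions$decision == "ID" &
    !is.na(predictions$predicted_label) & predictions$predicted_label == truth
  mean(ok_ood | ok_id)
}

#' Evaluate a fitted pipeline on labelled ID and OOD volumes
#'
#' @param object A fitted `"cryowave"` pipeline.
#' @param id_volumes,ood_volumes Lists of volumes (or 4D arrays).
#' @param id_labels True class labels of `id_volumes`.
#' @param target_tpr TPR at which the reported FPR is measured.
#' @return List of class `"cryowave_eval"`: `fpr_at_tpr`, `auroc`, `acc`,
#'   `n_id`, `n_ood`, `threshold`, `target_tpr`.
#' @export
evaluate_pipeline <- function(object, id_volumes, id_labels, ood_volumes,
                              target_tpr = 0.95) {
  stopifnot(inherits(object, "cryowave"))
  pid <- predict(object, id_volumes)
  pood <- predict(object, ood_volumes)
  preds <- rbind(pid, pood)
  truth <- c(as.integer(id_labels), rep(NA_integer_, nrow(pood)))
  structure(list(
    fpr_at_tpr = fpr_at_tpr(pid$score, pood$score, target_tpr),
    auroc = auroc(pid$score, pood$score),
    acc = mixed_accuracy(preds, truth),
    id_accuracy = mean(pid$predicted_label == as.integer(id_labels),
                       na.rm = TRUE),
    n_id = nrow(pid), n_ood = nrow(pood),
    threshold = object$lambda, target_tpr = target_tpr
  ), class = "cryowave_eval")
}

#' @export
print.cryowave_eval <- function(x, ...) {
  cat("Open-set evaluation (", x$n_id, " ID / ", x$n_ood, " OOD samples)\n",
      sep = "")
  cat(sprintf("  AUROC          %.4f\n", x$auroc))
  cat(sprintf("  FPR@%.0f%%TPR     %.4f\n", 100 * x$target_tpr, x$fpr_at_tpr))
  cat(sprintf("  mixed accuracy %.4f\n", x$acc))
  cat(sprintf("  deployed lambda %.4f\n", x$threshold))
  invisible(x)
}

#' Export score-distribution and embedding diagnostics
#'
#' Writes a 2D principal-component embedding of the features (ID vs OOD
#' coloured) and overlaid score histograms, as both plots (PNG) and plain
#' tables (CSV), under `out_dir`.
#'
#' @param features `N x d` feature matrix.
#' @param scores Confidence scores, length `N`.
#' @param decisions Character vector (`"ID"` / `"OOD"`), length `N`.
#' @param out_dir Output directory (created if missing).
#' @param seed Seed for reproducibility of the embedding.
#' @param bins Number of histogram bins.
#' @return Invisibly, the paths written.
#' @export
export_diagnostics <- function(features, scores, decisions, out_dir,
                               seed = 1L, bins = 30L) {
  stopifnot(length(scores) == nrow(features),
            length(decisions) == nrow(features))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", out_dir, call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pc <- stats::prcomp(features, rank. = 2L)
  emb <- data.frame(dim1 = pc$x[, 1L],
                    dim2 = if (ncol(pc$x) > 1L) pc$x[, 2L] else 0,
                    decision = decisions, score = scores)
  emb_path <- file.path(out_dir, "embedding.csv")
  utils::write.csv(emb, emb_path, row.names = FALSE)
  brk <- seq(min(scores), max(scores), length.out = bins + 1L)
  if (length(unique(brk)) == 1L) brk <- c(brk[1L] - 0.5, brk[1L] + 0.5)
  hid <- graphics::hist(scores[decisions == "ID"], breaks = brk, plot = FALSE)
  hood <- graphics::hist(scores[decisions == "OOD"], breaks = brk, plot = FALSE)
  hist_path <- file.path(out_dir, "score_histogram.csv")
  utils::write.csv(data.frame(bin_left = brk[-length(brk)],
                              bin_right = brk[-1L],
                              count_id = hid$counts, count_ood = hood$counts),
                   hist_path, row.names = FALSE)
  png_emb <- file.path(out_dir, "embedding.png")
  grDevices::png(png_emb, width = 640, height = 640)
  graphics::plot(emb$dim1, emb$dim2,
                 col = ifelse(decisions == "ID", "#2166ac", "#b2182b"),
                 pch = 19, cex = 0.6, xlab = "PC1", ylab = "PC2",
                 main = "Feature embedding (blue ID / red OOD)")
  grDevices::dev.off()
  png_hist <- file.path(out_dir, "score_histogram.png")
  grDevices::png(png_hist, width = 640, height = 480)
  graphics::plot(hid, col = grDevices::adjustcolor("#2166ac", 0.5),
                 xlim = range(brk), main = "Confidence scores",
                 xlab = "S(z)")
  graphics::plot(hood, col = grDevices::adjustcolor("#b2182b", 0.5),
                 add = TRUE)
  grDevices::dev.off()
  invisible(c(emb_path, hist_path, png_emb, png_hist))
}
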