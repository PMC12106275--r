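# Desk-scale synthetic benchmark: 3 in-distribution phantom families
# (sphere, dumbbell, torus) vs 2 out-of-distribution families (ellipsoid,
# cross); 250 samples per family split 0.8/0.1/0.1, i.e. 200 training
# volumes per ID class; tiny DWT encoder; 20 epochs of the standard SGD
# recipe; cosine-similarity classifier. Result summaries are memoised so
# several tests can share one run; volumes are regenerated per call to
# keep memory bounded.

.benchmark_cache <- new.env(parent = emptyenv())

benchmark_dataset <- function(seed, snr) {
  make_dataset(c("sphere", "dumbbell", "torus"), c("ellipsoid", "cross"),
               n_per_class = 250L, snr = snr, seed = seed)
}

benchmark_fit_eval <- function(ds, seed, op) {
  m <- ds$manifest
  tr <- which(m$split %in% c("train", "val"))
  te <- which(m$split == "test_id")
  oo <- which(m$split == "test_ood")
  fit <- cryowave(ds$volumes[tr], m$label[tr],
                  encoder = encoder_config("tiny", downsample_op = op,
                                           seed = seed),
                  config = train_config(epochs = 20L, seed = seed),
                  mode = "cosine")
  ev <- evaluate_pipeline(fit, ds$volumes[te], m$label[te], ds$volumes[oo])
  # classification accuracy of the classifier head alone on the ID test set
  xs <- lapply(ds$volumes[te], function(v) (v - mean(v)) / sd(v))
  z <- cryowave:::encode_in_batches(xs, fit$encoder)
  lg <- cryowave:::classifier_logits_safe(z, fit$classifier)
  list(id_accuracy = mean(apply(lg, 1, which.max) == m$label[te]),
       auroc = ev$auroc, fpr95 = ev$fpr_at_tpr, mixed = ev$acc,
       loss = fit$loss)
}

# one seed of the benchmark; ops = "dwt" or c("dwt", "conv") (shared data)
run_benchmark <- function(seed, snr, ops = "dwt") {
  key <- paste(seed, snr, paste(ops, collapse = "+"), sep = "_")
  hit <- .benchmark_cache[[key]]
  if (!is.null(hit)) return(hit)
  ds <- benchmark_dataset(seed, snr)
  res <- lapply(ops, function(op) benchmark_fit_eval(ds, seed, op))
  names(res) <- ops
  .benchmark_cache[[key]] <- res
  res
}

benchmark_seeds <- c(101L, 102L, 103L)
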