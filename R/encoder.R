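# The 3D DWT-downsampled residual encoder E(.). Each wavelet block runs
# DWT -> conv -> BatchNorm -> ReLU -> [DWT ->] conv -> BatchNorm on its main
# branch (the number of DWT applications is the block's downsample_steps),
# adds a shape-matched residual branch (DWT low-pass + 1x1x1 projection +
# BatchNorm when shape or channel count changes) and applies a final ReLU.
# A strided-convolution control mode replaces every DWT halving with stride
# on the following convolution, keeping everything else identical.

#' Encoder configuration
#'
#' Describes the DWT-based residual encoder: the filter bank, the stem, the
#' per-stage channel widths and downsampling steps, and the feature
#' dimension `d` (the channel count of the last stage, global-average
#' pooled). The `"default"` preset mirrors a depth-18 residual layout
#' (widths 64/128/256/512, one DWT halving per stage, two blocks per
#' stage); the `"tiny"` preset is a desk-scale network small enough to
#' train on a single CPU.
#'
#' @param preset `"default"` or `"tiny"`; explicit arguments override the
#'   preset values.
#' @param bank_name Wavelet bank used by every DWT step (default
#'   `"ch3.3"`).
#' @param input_shape Integer vector of 3 spatial extents (default 32^3).
#' @param stem_channels Channels produced by the stem convolution.
#' @param stem_downsample DWT halvings applied before the stem convolution
#'   (0--2).
#' @param stage_widths Channel width per stage.
#' @param stage_downsample DWT halvings of the first block of each stage
#'   (each 0--2).
#' @param blocks_per_stage Number of residual blocks per stage; blocks
#'   after the first keep resolution and width.
#' @param feature_dim Length of the output feature vector `z`; must equal
#'   the last stage width.
#' @param downsample_op `"dwt"` for wavelet downsampling, `"conv"` for the
#'   strided-convolution control.
#' @param seed Integer seed for parameter initialisation.
#' @return A list of class `"encoder_config"`.
#' @export
encoder_config <- function(preset = c("default", "tiny"), bank_name = "ch3.3",
                           input_shape = c(32L, 32L, 32L),
                           stem_channels = NULL, stem_downsample = NULL,
                           stage_widths = NULL, stage_downsample = NULL,
                           blocks_per_stage = NULL, feature_dim = NULL,
                           downsample_op = c("dwt", "conv"), seed = 1L) {
  preset <- match.arg(preset)
  downsample_op <- match.arg(downsample_op)
  p <- if (preset == "default") {
    list(stem_channels = 64L, stem_downsample = 0L,
         stage_widths = c(64L, 128L, 256L, 512L),
         stage_downsample = c(1L, 1L, 1L, 1L),
         blocks_per_stage = c(2L, 2L, 2L, 2L), feature_dim = 512L)
  } else {
    list(stem_channels = 8L, stem_downsample = 2L,
         stage_widths = c(16L, 32L), stage_downsample = c(1L, 1L),
         blocks_per_stage = c(1L, 1L), feature_dim = 32L)
  }
  if (!is.null(stem_channels)) p$stem_channels <- as.integer(stem_channels)
  if (!is.null(stem_downsample)) p$stem_downsample <- as.integer(stem_downsample)
  if (!is.null(stage_widths)) p$stage_widths <- as.integer(stage_widths)
  if (!is.null(stage_downsample)) p$stage_downsample <- as.integer(stage_downsample)
  if (!is.null(blocks_per_stage)) p$blocks_per_stage <- as.integer(blocks_per_stage)
  if (!is.null(feature_dim)) p$feature_dim <- as.integer(feature_dim)
  cfg <- c(list(bank_name = bank_name, input_shape = as.integer(input_shape),
                downsample_op = downsample_op, seed = as.integer(seed)), p)
  get_filter_bank(bank_name)
  if (length(cfg$stage_widths) != length(cfg$stage_downsample) ||
      length(cfg$stage_widths) != length(cfg$blocks_per_stage))
    stop("invalid config: stage_widths, stage_downsample and blocks_per_stage lengths differ",
         call. = FALSE)
  if (!all(c(cfg$stem_downsample, cfg$stage_downsample) %in% 0:2))
    stop("invalid config: downsample steps must be 0, 1 or 2", call. = FALSE)
  total <- 2^(cfg$stem_downsample + sum(cfg$stage_downsample))
  if (total > min(cfg$input_shape))
    stop("invalid config: cumulative downsampling factor ", total,
         " exceeds the smallest input extent ", min(cfg$input_shape),
         call. = FALSE)
  if (cfg$feature_dim != cfg$stage_widths[length(cfg$stage_widths)])
    stop("invalid config: feature_dim must equal the last stage width",
         call. = FALSE)
  class(cfg) <- "encoder_config"
  cfg
}

block_init <- function(cin, cout, ds) {
  blk <- list(cin = cin, cout = cout, ds = ds,
              W1 = conv3_init(cin, cout), bn1 = bn_init(cout),
              W2 = conv3_init(cout, cout), bn2 = bn_init(cout))
  if (ds > 0L || cin != cout) {
    blk$Wp <- conv1_init(cin, cout)
    blk$bnp <- bn_init(cout)
  }
  blk
}

#' Initialise an encoder
#'
#' Draws all convolution weights (Kaiming fan-out) and batch-normalisation
#' parameters deterministically from `config$seed`. Two calls with the same
#' configuration produce identical states.
#'
#' @param config An [encoder_config()].
#' @return A list of class `"encoder_state"` with elements `cfg`, `stem`
#'   and `blocks`.
#' @export
init_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  state <- list(cfg = config,
                stem = list(W = conv3_init(1L, config$stem_channels),
                            bn = bn_init(config$stem_channels)))
  blocks <- list()
  cin <- config$stem_channels
  for (s in seq_along(config$stage_widths)) {
    cout <- config$stage_widths[s]
    for (b in seq_len(config$blocks_per_stage[s])) {
      ds <- if (b == 1L) config$stage_downsample[s] else 0L
      blocks[[length(blocks) + 1L]] <- block_init(cin, cout, ds)
      cin <- cout
    }
  }
  state$blocks <- blocks
  class(state) <- "encoder_state"
  state
}

# strided spatial subsampling of (v, N, C) activations (control-mode
# residual path); returns out + the index used (for the backward scatter)
subsample_forward <- function(x, d3, s) {
  dd <- dim(x)
  X <- array(x, c(d3, dd[2L] * dd[3L]))
  si <- seq(1L, d3[1L], by = s); sj <- seq(1L, d3[2L], by = s)
  sl <- seq(1L, d3[3L], by = s)
  Y <- X[si, sj, sl, , drop = FALSE]
  d3o <- c(length(si), length(sj), length(sl))
  dim(Y) <- c(prod(d3o), dd[2L], dd[3L])
  list(out = Y, d3 = d3o)
}

subsample_backward <- function(grad_out, d3_in, d3_out, s) {
  dd <- dim(grad_out)
  G <- array(0, c(d3_in, dd[2L] * dd[3L]))
  G[seq(1L, d3_in[1L], by = s), seq(1L, d3_in[2L], by = s),
    seq(1L, d3_in[3L], by = s), ] <- grad_out
  dim(G) <- c(prod(d3_in), dd[2L], dd[3L])
  G
}

# one residual wavelet block; x is (v, N, C_in)
block_forward <- function(x, d3, blk, bank, op, training) {
  cache <- list(d3_in = d3)
  a <- x; d3a <- d3
  s1 <- 1L; s2 <- 1L
  if (op == "dwt") {
    if (blk$ds >= 1L) { r1 <- nn_dwt_low(a, d3a, bank); a <- r1$out; d3a <- r1$d3 }
  } else {
    if (blk$ds >= 1L) s1 <- 2L
    if (blk$ds == 2L) s2 <- 2L
  }
  cache$d3_c1 <- d3a
  c1 <- conv3_forward(a, d3a, blk$W1, stride = s1, keep_cache = training)
  b1 <- bn_forward(c1$out, blk$bn1, training)
  blk$bn1 <- b1$bn
  r1a <- relu_forward(b1$out)
  a <- r1a$out; d3a <- c1$d3
  if (op == "dwt" && blk$ds == 2L) {
    cache$d3_dwt2 <- d3a
    r2 <- nn_dwt_low(a, d3a, bank); a <- r2$out; d3a <- r2$d3
  }
  cache$d3_c2 <- d3a
  c2 <- conv3_forward(a, d3a, blk$W2, stride = s2, keep_cache = training)
  b2 <- bn_forward(c2$out, blk$bn2, training)
  blk$bn2 <- b2$bn
  main <- b2$out; d3o <- c2$d3
  # residual branch
  if (is.null(blk$Wp)) {
    res <- x
  } else {
    r <- x; d3r <- d3
    if (blk$ds > 0L) {
      if (op == "dwt") {
        for (i in seq_len(blk$ds)) {
          cache$d3_res <- c(cache$d3_res, list(d3r))
          rr <- nn_dwt_low(r, d3r, bank); r <- rr$out; d3r <- rr$d3
        }
      } else {
        ss <- subsample_forward(r, d3r, 2L^blk$ds)
        cache$sub_in <- d3r; cache$sub_out <- ss$d3
        r <- ss$out; d3r <- ss$d3
      }
    }
    cache$res_pre_proj <- r
    rp <- conv1_forward(r, blk$Wp)
    bp <- bn_forward(rp, blk$bnp, training)
    blk$bnp <- bp$bn
    res <- bp$out
    cache$bnp_cache <- bp$cache
  }
  out <- relu_forward(main + res)
  cache$mask_out <- out$mask
  cache$mask1 <- r1a$mask
  cache$c1 <- c1$cache; cache$c2 <- c2$cache
  cache$bn1_cache <- b1$cache; cache$bn2_cache <- b2$cache
  cache$s1 <- s1; cache$s2 <- s2
  list(out = out$out, d3 = d3o, blk = blk, cache = cache)
}

block_backward <- function(blk, cache, bank, op, grad_out) {
  g <- grad_out * cache$mask_out
  # main branch
  gb2 <- bn_backward(blk$bn2, cache$bn2_cache, g)
  gc2 <- conv3_backward(cache$c2, gb2$gx)
  gm <- gc2$gx
  if (op == "dwt" && blk$ds == 2L)
    gm <- nn_dwt_low_backward(gm, cache$d3_dwt2, bank)
  gm <- gm * cache$mask1
  gb1 <- bn_backward(blk$bn1, cache$bn1_cache, gm)
  gc1 <- conv3_backward(cache$c1, gb1$gx)
  gx_main <- gc1$gx
  if (op == "dwt" && blk$ds >= 1L)
    gx_main <- nn_dwt_low_backward(gx_main, cache$d3_in, bank)
  grads <- list(W1 = gc1$gW, bn1 = list(gamma = gb1$dgamma, beta = gb1$dbeta),
                W2 = gc2$gW, bn2 = list(gamma = gb2$dgamma, beta = gb2$dbeta))
  # residual branch
  if (is.null(blk$Wp)) {
    gx_res <- g
  } else {
    gbp <- bn_backward(blk$bnp, cache$bnp_cache, g)
    gpp <- conv1_backward(cache$res_pre_proj, blk$Wp, gbp$gx)
    grads$Wp <- gpp$gW
    grads$bnp <- list(gamma = gbp$dgamma, beta = gbp$dbeta)
    gr <- gpp$gx
    if (blk$ds > 0L) {
      if (op == "dwt") {
        for (d3r in rev(cache$d3_res)) gr <- nn_dwt_low_backward(gr, d3r, bank)
      } else {
        gr <- subsample_backward(gr, cache$sub_in, cache$sub_out, 2L^blk$ds)
      }
    }
    gx_res <- gr
  }
  list(grads = grads, gx = gx_main + gx_res)
}

#' Run one wavelet block
#'
#' Applies a single residual wavelet block to a multi-channel feature
#' volume. Exposed mainly for inspection and testing; [encode()] runs the
#' full encoder.
#'
#' @param x Array of dim `(voxels, batch, channels)`.
#' @param d3 Integer vector of 3: the spatial grid of `x`.
#' @param params A block parameter list as produced inside
#'   [init_encoder()] (fields `W1`, `bn1`, `W2`, `bn2`, optional `Wp`,
#'   `bnp`, plus `cin`, `cout`, `ds`).
#' @param bank_name Wavelet bank name.
#' @param downsample_op `"dwt"` or `"conv"`.
#' @param training Logical; batch statistics vs running statistics.
#' @return List with `out` (the block output) and `d3` (its grid).
#' @export
wavelet_block_forward <- function(x, d3, params, bank_name = "ch3.3",
                                  downsample_op = "dwt", training = FALSE) {
  if (downsample_op == "dwt" && params$ds > 0L && any(d3 %% 2L != 0L))
    stop("invalid shape: odd spatial extent at a DWT step", call. = FALSE)
  r <- block_forward(x, as.integer(d3), params, bank_name, downsample_op, training)
  list(out = r$out, d3 = r$d3)
}

# full forward pass; X is (v, N, 1); returns features plus caches
encoder_forward <- function(state, X, training = FALSE) {
  cfg <- state$cfg
  d3 <- cfg$input_shape
  caches <- list()
  a <- X
  stem_stride <- 1L
  if (cfg$stem_downsample > 0L) {
    if (cfg$downsample_op == "dwt") {
      caches$stem_d3 <- list()
      for (i in seq_len(cfg$stem_downsample)) {
        caches$stem_d3 <- c(caches$stem_d3, list(d3))
        r <- nn_dwt_low(a, d3, cfg$bank_name); a <- r$out; d3 <- r$d3
      }
    } else {
      stem_stride <- 2L^cfg$stem_downsample
    }
  }
  c0 <- conv3_forward(a, d3, state$stem$W, stride = stem_stride,
                      keep_cache = training)
  b0 <- bn_forward(c0$out, state$stem$bn, training)
  state$stem$bn <- b0$bn
  r0 <- relu_forward(b0$out)
  a <- r0$out; d3 <- c0$d3
  caches$stem <- list(conv = c0$cache, bn = b0$cache, mask = r0$mask)
  caches$blocks <- vector("list", length(state$blocks))
  for (i in seq_along(state$blocks)) {
    r <- block_forward(a, d3, state$blocks[[i]], cfg$bank_name,
                       cfg$downsample_op, training)
    state$blocks[[i]] <- r$blk
    caches$blocks[[i]] <- r$cache
    a <- r$out; d3 <- r$d3
  }
  caches$final_v <- prod(d3)
  z <- gap_forward(a)
  list(z = z, caches = caches, state = state)
}

encoder_backward <- function(state, caches, dz) {
  cfg <- state$cfg
  g <- gap_backward(dz, caches$final_v)
  grads <- list(blocks = vector("list", length(state$blocks)))
  for (i in rev(seq_along(state$blocks))) {
    bb <- block_backward(state$blocks[[i]], caches$blocks[[i]],
                         cfg$bank_name, cfg$downsample_op, g)
    grads$blocks[[i]] <- bb$grads
    g <- bb$gx
  }
  g <- g * caches$stem$mask
  gb0 <- bn_backward(state$stem$bn, caches$stem$bn, g)
  gc0 <- conv3_backward(caches$stem$conv, gb0$gx)
  grads$stem <- list(W = gc0$gW,
                     bn = list(gamma = gb0$dgamma, beta = gb0$dbeta))
  grads
}

# stack a list of 3D volumes (or a single volume / 4D array) into the
# (v, N, 1) activation layout, standardising each volume to zero mean and
# unit variance (the input normalisation applied before encoding)
volumes_to_batch <- function(x, input_shape, standardize = TRUE) {
  if (is.array(x) && length(dim(x)) == 3L) x <- list(x)
  if (is.array(x) && length(dim(x)) == 4L) {
    x <- lapply(seq_len(dim(x)[4L]), function(i) x[, , , i])
  }
  v <- prod(input_shape)
  N <- length(x)
  X <- array(0, c(v, N, 1L))
  for (i in seq_len(N)) {
    xi <- x[[i]]
    if (!is.array(xi) || !identical(dim(xi), as.integer(input_shape)))
      stop("invalid shape: volume ", i, " is not ",
           paste(input_shape, collapse = "x"), call. = FALSE)
    if (standardize) {
      s <- stats::sd(xi)
      xi <- if (s > 0) (xi - mean(xi)) / s else xi - mean(xi)
    }
    X[, i, 1L] <- xi
  }
  X
}

#' Encode volumes into feature vectors
#'
#' Runs the encoder in evaluation mode (fixed normalisation statistics) on
#' one volume or a batch, returning one length-`d` feature vector per
#' sample. Volumes are standardised to zero mean / unit variance first.
#'
#' @param x A 3D array, a list of 3D arrays, or a 4D array with samples in
#'   the fourth dimension.
#' @param state An `"encoder_state"` from [init_encoder()] (trained or
#'   not).
#' @return Numeric matrix, one row per sample, `d` columns.
#' @export
encode <- function(x, state) {
  stopifnot(inherits(state, "encoder_state"))
  X <- volumes_to_batch(x, state$cfg$input_shape)
  encoder_forward(state, X, training = FALSE)$z
}
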