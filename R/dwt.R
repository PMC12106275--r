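# Single-level discrete wavelet transform in matrix and convolution form.
# The matrix form writes the transform as y_low = L x, y_high = H x where L
# and H are floor(m/2) x m banded matrices whose row j carries the filter
# taps at columns 2j + k (periodic wrap by default). Internal volume axis
# order is (height, width, depth); dwt3d transforms width first, then
# height, then depth.

dwt_check_length <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 2)
    stop("invalid signal length: need m >= 2", call. = FALSE)
}

extend_signal <- function(x, pad, boundary) {
  # returns the index map used to read x periodically / symmetrically
  m <- length(x)
  switch(boundary,
    periodic = x[((seq_len(m + 2 * pad) - pad - 1) %% m) + 1L],
    symmetric = {
      idx <- seq_len(m + 2 * pad) - pad  # 1-pad .. m+pad
      refl <- function(i) {
        # half-sample symmetric reflection onto 1..m
        p <- (i - 1) %% (2 * m)
        ifelse(p < m, p + 1, 2 * m - p)
      }
      x[refl(idx)]
    },
    stop("unknown boundary mode '", boundary, "'", call. = FALSE)
  )
}

#' Build explicit single-level DWT filter matrices
#'
#' Constructs the `floor(m/2) x m` low-pass matrix `L` and high-pass matrix
#' `H` such that `L %*% x` and `H %*% x` perform one level of the DWT of a
#' length-`m` signal. Row `j` (0-based) of `L` holds the low-pass taps
#' `l_k` at columns `2j + k` with periodic (circular) column wrap.
#'
#' @param bank A `filter_bank` or a bank name accepted by
#'   [get_filter_bank()].
#' @param m Signal length; must be an even integer `>= 2`.
#' @return A list of class `"dwt_matrices"` with elements `L`, `H`, `m`,
#'   `bank`.
#' @examples
#' build_dwt_matrices("haar", 4)$L  # (1/sqrt(2)) * [[1,1,0,0],[0,0,1,1]]
#' @export
build_dwt_matrices <- function(bank, m) {
  bank <- get_filter_bank(bank)
  dwt_check_length(m)
  if (m %% 2 != 0) stop("invalid signal length: m must be even", call. = FALSE)
  m <- as.integer(m)
  rows <- m %/% 2L
  fill <- function(taps, offset) {
    M <- matrix(0, rows, m)
    for (t in seq_along(taps)) {
      k <- offset + t - 1L
      cols <- ((2L * (seq_len(rows) - 1L) + k) %% m) + 1L
      M[cbind(seq_len(rows), cols)] <- M[cbind(seq_len(rows), cols)] + taps[t]
    }
    M
  }
  structure(list(L = fill(bank$lowpass, bank$offset_low),
                 H = fill(bank$highpass, bank$offset_high),
                 m = m, bank = bank),
            class = "dwt_matrices")
}

dwt1d_conv <- function(x, taps, offset, boundary) {
  m <- length(x)
  half <- m %/% 2L
  pad <- length(taps) + abs(offset) + 2L
  xe <- extend_signal(x, pad, boundary)
  out <- numeric(half)
  for (t in seq_along(taps)) {
    k <- offset + t - 1L
    out <- out + taps[t] * xe[pad + 2L * (seq_len(half) - 1L) + k + 1L]
  }
  out
}

#' Single-level 1D discrete wavelet transform
#'
#' Splits a signal into its low-pass (approximation) and high-pass (detail)
#' halves, computed either by explicit filter-matrix multiplication or by
#' direct subsampled convolution; both paths agree to machine precision.
#' Odd-length inputs are padded by one periodically repeated sample and the
#' result carries attribute `padded = TRUE`.
#'
#' @param x Numeric vector, length `>= 2`.
#' @param bank Filter bank or name, see [get_filter_bank()].
#' @param via `"matrix"` or `"convolution"`.
#' @param boundary `"periodic"` (default; keeps Haar orthonormal) or
#'   `"symmetric"` (convolution path only).
#' @return A list with numeric vectors `low` and `high`, each of length
#'   `floor(m/2)` of the (possibly padded) length.
#' @export
dwt1d <- function(x, bank, via = c("matrix", "convolution"),
                  boundary = c("periodic", "symmetric")) {
  via <- match.arg(via)
  boundary <- match.arg(boundary)
  bank <- get_filter_bank(bank)
  dwt_check_length(length(x))
  padded <- FALSE
  if (length(x) %% 2L != 0L) {
    x <- c(x, x[1L])  # periodic single-sample pad
    padded <- TRUE
  }
  if (via == "matrix") {
    if (boundary != "periodic")
      stop("matrix form supports only periodic boundaries", call. = FALSE)
    mats <- build_dwt_matrices(bank, length(x))
    out <- list(low = drop(mats$L %*% x), high = drop(mats$H %*% x))
  } else {
    out <- list(low = dwt1d_conv(x, bank$lowpass, bank$offset_low, boundary),
                high = dwt1d_conv(x, bank$highpass, bank$offset_high, boundary))
  }
  if (padded) attr(out, "padded") <- TRUE
  out
}

# Apply the low- or high-pass DWT matrix along one axis of a 3D array.
# mode: which = "L" or "H"; axis in 1:3 of an (h, w, d) array.
dwt_apply_axis <- function(x, mat, axis) {
  d <- dim(x)
  if (axis == 1L) {
    y <- mat %*% matrix(x, d[1L], d[2L] * d[3L])
    dim(y) <- c(nrow(mat), d[2L], d[3L])
  } else if (axis == 2L) {
    xp <- aperm(x, c(2L, 1L, 3L))
    y <- mat %*% matrix(xp, d[2L], d[1L] * d[3L])
    dim(y) <- c(nrow(mat), d[1L], d[3L])
    y <- aperm(y, c(2L, 1L, 3L))
  } else {
    xp <- aperm(x, c(3L, 1L, 2L))
    y <- mat %*% matrix(xp, d[3L], d[1L] * d[2L])
    dim(y) <- c(nrow(mat), d[1L], d[2L])
    y <- aperm(y, c(2L, 3L, 1L))
  }
  y
}

dwt3d_check <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("invalid shape: expected a 3D array", call. = FALSE)
  if (any(dim(x) < 2L))
    stop("invalid shape: every dimension must be >= 2", call. = FALSE)
  if (any(dim(x) %% 2L != 0L))
    stop("invalid shape: dimensions must be even (pad upstream)", call. = FALSE)
}

#' Single-level 3D discrete wavelet transform
#'
#' Applies the 1D DWT separably: along the width (second axis) first, then
#' the height (first axis), then the depth (third axis), yielding eight
#' subbands each of half the input extent per axis. Subband names `lll` ...
#' `hhh` give the filter (`l`ow / `h`igh) applied along (height, width,
#' depth) in that letter order.
#'
#' @param x 3D numeric array indexed `[height, width, depth]`, all even
#'   extents `>= 2`.
#' @param bank Filter bank or name.
#' @return A list of class `"dwt_subbands"` holding the eight half-size
#'   arrays `lll`, `llh`, `lhl`, `lhh`, `hll`, `hlh`, `hhl`, `hhh`.
#' @export
dwt3d <- function(x, bank) {
  bank <- get_filter_bank(bank)
  dwt3d_check(x)
  d <- dim(x)
  mW <- build_dwt_matrices(bank, d[2L]); mH <- build_dwt_matrices(bank, d[1L])
  mD <- build_dwt_matrices(bank, d[3L])
  # width first, then height, then depth
  w <- list(l = dwt_apply_axis(x, mW$L, 2L), h = dwt_apply_axis(x, mW$H, 2L))
  hw <- list()
  for (wn in names(w)) {
    hw[[paste0("l", wn)]] <- dwt_apply_axis(w[[wn]], mH$L, 1L)
    hw[[paste0("h", wn)]] <- dwt_apply_axis(w[[wn]], mH$H, 1L)
  }
  out <- list()
  for (hwn in names(hw)) {
    out[[paste0(hwn, "l")]] <- dwt_apply_axis(hw[[hwn]], mD$L, 3L)
    out[[paste0(hwn, "h")]] <- dwt_apply_axis(hw[[hwn]], mD$H, 3L)
  }
  out <- out[c("lll", "llh", "lhl", "lhh", "hll", "hlh", "hhl", "hhh")]
  class(out) <- "dwt_subbands"
  out
}

#' Low-frequency 3D DWT downsampling
#'
#' Returns only the `lll` subband of [dwt3d()]: the input smoothed and
#' halved (floor) along every axis. A constant volume of value `c` maps to a
#' constant `2 * sqrt(2) * c` (the DC gain of three low-pass applications).
#'
#' @inheritParams dwt3d
#' @return 3D array of shape `floor(dim(x) / 2)`.
#' @export
dwt3d_lowpass <- function(x, bank) {
  bank <- get_filter_bank(bank)
  dwt3d_check(x)
  d <- dim(x)
  y <- dwt_apply_axis(x, build_dwt_matrices(bank, d[2L])$L, 2L)
  y <- dwt_apply_axis(y, build_dwt_matrices(bank, d[1L])$L, 1L)
  dwt_apply_axis(y, build_dwt_matrices(bank, d[3L])$L, 3L)
}
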