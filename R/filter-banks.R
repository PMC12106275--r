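# Decomposition (analysis) filter banks. Coefficients are the canonical
# Haar and Cohen-Daubechies-Feauveau (CDF) biorthogonal values at full double
# precision, normalised so every low-pass sums to sqrt(2). Offsets give the
# tap index k of the first stored coefficient in the correlation
#   y_j = sum_k f_k x_{2j + k}  (indices periodic modulo the signal length),
# fixed so that matrix and convolution paths reproduce the standard
# periodised single-level transform. High-pass signs for the antisymmetric
# filters (haar, ch3.3) follow h_k = (-1)^k l_{1-k}.

.cryowave_banks <- local({
  s2 <- sqrt(2) / 2
  list(
    haar = list(
      lowpass  = c(s2, s2),           offset_low  = 0L,
      highpass = c(s2, -s2),          offset_high = 0L
    ),
    ch2.2 = list(
      lowpass = c(-0.1767766952966369, 0.3535533905932738, 1.0606601717798212,
                  0.3535533905932738, -0.1767766952966369),
      offset_low = -2L,
      highpass = c(0.3535533905932738, -0.7071067811865476, 0.3535533905932738),
      offset_high = 0L
    ),
    ch3.3 = list(
      lowpass = c(0.06629126073623882, -0.1988737822087165, -0.15467960838455727,
                  0.9943689110435825, 0.9943689110435825, -0.15467960838455727,
                  -0.1988737822087165, 0.06629126073623882),
      offset_low = -3L,
      highpass = c(0.1767766952966369, -0.5303300858899106, 0.5303300858899106,
                   -0.1767766952966369),
      offset_high = -1L
    ),
    ch4.4 = list(
      lowpass = c(0.03782845550726404, -0.023849465019556843, -0.11062440441843718,
                  0.37740285561283066, 0.8526986790088938, 0.37740285561283066,
                  -0.11062440441843718, -0.023849465019556843, 0.03782845550726404),
      offset_low = -4L,
      highpass = c(-0.06453888262869706, 0.04068941760916406, 0.41809227322161724,
                   -0.7884856164055829, 0.41809227322161724, 0.04068941760916406,
                   -0.06453888262869706),
      offset_high = -2L
    ),
    ch5.5 = list(
      lowpass = c(0.03968708834740544, 0.007948108637240322, -0.05446378846823691,
                  0.34560528195603346, 0.7366601814282105, 0.34560528195603346,
                  -0.05446378846823691, 0.007948108637240322, 0.03968708834740544),
      offset_low = -4L,
      highpass = c(-0.013456709459118716, -0.002694966880111507, 0.13670658466432914,
                   -0.09350469740093886, -0.47680326579848425, 0.8995061097486484,
                   -0.47680326579848425, -0.09350469740093886, 0.13670658466432914,
                   -0.002694966880111507, -0.013456709459118716),
      offset_high = -4L
    )
  )
})

#' Retrieve a wavelet decomposition filter bank
#'
#' Returns the analysis low-pass/high-pass filter pair used by the DWT
#' downsampling layers. Supported banks are the Haar wavelet (`"haar"`) and
#' the CDF biorthogonal family of orders 2--5 (`"ch2.2"`, `"ch3.3"`,
#' `"ch4.4"`, `"ch5.5"`). Low-pass coefficients sum to `sqrt(2)` (so the
#' retained low-frequency subband has a DC gain of `sqrt(2)` per axis);
#' high-pass coefficients sum to zero.
#'
#' @param name One of `"haar"`, `"ch2.2"`, `"ch3.3"`, `"ch4.4"`, `"ch5.5"`.
#' @return An object of class `"filter_bank"`: a list with elements `name`,
#'   `lowpass`, `highpass` (numeric coefficient vectors) and `offset_low`,
#'   `offset_high` (integer index of the leading tap).
#' @examples
#' fb <- get_filter_bank("haar")
#' sum(fb$lowpass)  # sqrt(2)
#' @export
get_filter_bank <- function(name) {
  if (inherits(name, "filter_bank")) return(name)
  if (!is.character(name) || length(name) != 1L || !name %in% names(.cryowave_banks)) {
    stop("unsupported wavelet '", paste(name, collapse = ","),
         "'; supported banks: ", paste(names(.cryowave_banks), collapse = ", "),
         call. = FALSE)
  }
  bank <- c(list(name = name), .cryowave_banks[[name]])
  class(bank) <- "filter_bank"
  bank
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank>", x$name, "\n")
  cat("  lowpass  (", length(x$lowpass), " taps, first index ", x$offset_low,
      "): ", paste(signif(x$lowpass, 5), collapse = " "), "\n", sep = "")
  cat("  highpass (", length(x$highpass), " taps, first index ", x$offset_high,
      "): ", paste(signif(x$highpass, 5), collapse = " "), "\n", sep = "")
  invisible(x)
}
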