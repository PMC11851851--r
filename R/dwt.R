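# Multilevel discrete wavelet transform (Daubechies family, symmetric padding).
#
# Conventions match the common "symmetric" (half-sample reflection) boundary
# mode: a level-1 transform of a length-n signal yields floor((n + fl - 1)/2)
# coefficients per branch, where fl is the filter length. Coefficient lengths
# therefore depend on the boundary mode; reconstruction trims each inverse
# step back to the recorded length, so decompose -> reconstruct is exact to
# floating-point rounding.

# Daubechies scaling (low-pass decomposition) filters.
.dwt_filters <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.83651630373746899, 0.48296291314469025),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651)
)

.dwt_bank <- function(wavelet) {
  dec_lo <- .dwt_filters[[wavelet]]
  if (is.null(dec_lo)) {
    abort(sprintf("unsupported wavelet '%s' (available: %s)",
                  wavelet, paste(names(.dwt_filters), collapse = ", ")),
          class = "painsense_parameter_error")
  }
  fl <- length(dec_lo)
  dec_hi <- rev(dec_lo) * rep(c(-1, 1), length.out = fl)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), fl = fl)
}

# Full linear convolution, filter b short: O(n * length(b)) at C speed.
.conv_full <- function(a, b) {
  fb <- length(b)
  ap <- c(rep(0, fb - 1), a, rep(0, fb - 1))
  out <- stats::filter(ap, b, method = "convolution", sides = 1)
  as.numeric(out)[fb:(2 * fb - 2 + length(a))]
}

# One analysis step: symmetric extension, convolve, keep every second sample.
.dwt_step <- function(x, bank) {
  n <- length(x)
  m <- bank$fl - 1
  ext <- c(rev(head(x, m)), x, rev(tail(x, m)))
  nout <- floor((n + bank$fl - 1) / 2)
  idx <- seq(bank$fl + 1, by = 2, length.out = nout)
  list(a = .conv_full(ext, bank$dec_lo)[idx],
       d = .conv_full(ext, bank$dec_hi)[idx])
}

# One synthesis step; target_len undoes the boundary growth of the matching
# analysis step.
.idwt_step <- function(a, d, bank, target_len) {
  up <- function(co) {
    u <- numeric(2 * length(co))
    u[seq(1, by = 2, length.out = length(co))] <- co
    u
  }
  s <- .conv_full(up(a), bank$rec_lo) + .conv_full(up(d), bank$rec_hi)
  s[(bank$fl - 2) + seq_len(target_len)]
}

#' Minimum signal length for a multilevel wavelet decomposition
#'
#' @param wavelet Wavelet name (`"db4"`, `"db2"` or `"haar"`).
#' @param level Decomposition depth.
#' @return Minimum number of samples accepted by [dwt_decompose()].
#' @export
dwt_min_length <- function(wavelet = "db4", level = 5L) {
  bank <- .dwt_bank(wavelet)
  (bank$fl - 1L) * 2L^level
}

#' Multilevel discrete wavelet decomposition of a single channel
#'
#' Decomposes a signal into `level + 1` coefficient bands: the final
#' approximation (e.g. A5) followed by details from coarsest to finest
#' (D5 ... D1). At a 500 Hz sampling rate and level 5 the bands cover
#' approximately A5 0-7.8 Hz, D5 7.8-15.6 Hz, D4 15.6-31 Hz, D3 31-62.5 Hz,
#' D2 62.5-125 Hz, D1 125-250 Hz, so A5/D5/D4 carry the classical
#' delta-theta/alpha/beta oscillations of interest for pain-related activity.
#'
#' @param x Numeric vector, one channel of (preprocessed) signal.
#' @param wavelet Wavelet name; default `"db4"`.
#' @param level Decomposition depth; default 5.
#' @return An object of class `wavelet_bands`: list with `bands` (named list
#'   of coefficient vectors, approximation first), `lengths` (input length at
#'   each analysis step, used for exact reconstruction), `wavelet`, `level`.
#' @seealso [dwt_reconstruct()], [band_statistics()]
#' @export
#' @examples
#' wb <- dwt_decompose(sin(seq_len(1024) / 20))
#' names(wb$bands)
#' max(abs(dwt_reconstruct(wb) - sin(seq_len(1024) / 20)))
dwt_decompose <- function(x, wavelet = "db4", level = 5L) {
  x <- as.numeric(x)
  level <- as.integer(level)
  bank <- .dwt_bank(wavelet)
  min_len <- dwt_min_length(wavelet, level)
  if (length(x) < min_len) {
    abort(sprintf(
      "signal too short for a level-%d %s decomposition: %d samples given, minimum is %d",
      level, wavelet, length(x), min_len), class = "painsense_length_error")
  }
  details <- vector("list", level)
  lengths <- integer(level)
  a <- x
  for (j in seq_len(level)) {
    lengths[j] <- length(a)
    step <- .dwt_step(a, bank)
    details[[j]] <- step$d
    a <- step$a
  }
  bands <- c(list(a), rev(details))
  names(bands) <- c(paste0("A", level), paste0("D", level:1))
  structure(
    list(bands = bands, lengths = lengths, wavelet = wavelet, level = level),
    class = "wavelet_bands")
}

#' Inverse multilevel wavelet transform
#'
#' Reconstructs the original signal from a [dwt_decompose()] result. The
#' round trip is exact to floating-point rounding (relative error well below
#' 1e-8).
#'
#' @param wb A `wavelet_bands` object.
#' @return Numeric vector of the original length.
#' @export
dwt_reconstruct <- function(wb) {
  stopifnot(inherits(wb, "wavelet_bands"))
  bank <- .dwt_bank(wb$wavelet)
  a <- wb$bands[[1]]
  for (j in wb$level:1) {
    d <- wb$bands[[paste0("D", j)]]
    a <- .idwt_step(a, d, bank, wb$lengths[j])
  }
  a
}

#' @export
print.wavelet_bands <- function(x, ...) {
  cat(sprintf("<wavelet_bands> %s level %d; band lengths: %s\n",
              x$wavelet, x$level,
              paste(sprintf("%s=%d", names(x$bands), lengths(x$bands)),
                    collapse = ", ")))
  invisible(x)
}
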