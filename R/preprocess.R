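# Signal cleaning: zero-phase high-pass and notch filtering, anti-aliased
# downsampling, and extended-Infomax ICA with artifact-component rejection.
# Pipeline order is fixed: high-pass -> notch -> downsample -> ICA.

.check_nyquist <- function(freq, fs, what) {
  if (freq >= fs / 2) {
    abort(sprintf("%s (%g Hz) must be below the Nyquist frequency (%g Hz)",
                  what, freq, fs / 2), class = "painsense_parameter_error")
  }
}

.filtfilt_rows <- function(rec, b, a, demean = FALSE) {
  out <- rec$data
  flt <- signal::Arma(b = b, a = a)
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    if (demean) x <- x - mean(x)
    out[ch, ] <- signal::filtfilt(flt, x)
  }
  eeg_recording(out, rec$fs, rec$channel_names, rec$montage)
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (`filtfilt`), per channel, removing DC and sub-cutoff drift without phase
#' distortion.
#'
#' @param recording An `eeg_recording`.
#' @param cutoff Cutoff frequency in Hz (default 1).
#' @return Filtered `eeg_recording`.
#' @export
eeg_highpass <- function(recording, cutoff = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  .check_nyquist(cutoff, recording$fs, "high-pass cutoff")
  bt <- signal::butter(4, cutoff / (recording$fs / 2), type = "high")
  # demean per channel first: removes the DC step the IIR edge transient
  # would otherwise smear across the record
  .filtfilt_rows(recording, bt$b, bt$a, demean = TRUE)
}

#' Zero-phase notch filter
#'
#' Biquad band-stop at `freq` with quality factor `q` (default 30, ~1.7 Hz
#' -3 dB width at 50 Hz), applied forward and backward per channel. Removes
#' power-line interference while leaving tones a few Hz away essentially
#' untouched.
#'
#' @param recording An `eeg_recording`.
#' @param freq Notch frequency in Hz (default 50).
#' @param q Quality factor (centre frequency / bandwidth).
#' @return Filtered `eeg_recording`.
#' @export
eeg_notch <- function(recording, freq = 50, q = 30) {
  stopifnot(inherits(recording, "eeg_recording"))
  .check_nyquist(freq, recording$fs, "notch frequency")
  w0 <- 2 * pi * freq / recording$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  .filtfilt_rows(recording, b, a)
}

#' Anti-aliased downsampling
#'
#' Integer decimation (low-pass then keep every q-th sample) when
#' `fs / target_fs` is a whole number, polyphase resampling otherwise. The
#' output has `floor(n * target_fs / fs)` samples and updated `fs`/`dt`.
#'
#' @param recording An `eeg_recording`.
#' @param target_fs Target sampling rate in Hz (default 500); upsampling is
#'   refused.
#' @return Downsampled `eeg_recording`.
#' @export
eeg_downsample <- function(recording, target_fs = 500) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (target_fs > fs) {
    abort("target_fs exceeds the recording's sampling rate (no upsampling)",
          class = "painsense_parameter_error")
  }
  if (target_fs == fs) return(recording)
  n_out <- floor(ncol(recording$data) * target_fs / fs)
  ratio <- fs / target_fs
  out <- matrix(0, nrow(recording$data), n_out)
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- as.integer(round(ratio))
    # linear-phase FIR anti-alias (cutoff 0.8 of the new Nyquist) applied
    # centred, i.e. zero phase; then keep every q-th sample
    h <- as.numeric(signal::fir1(64, 0.8 / q))
    m <- (length(h) - 1L) %/% 2L
    n_in <- ncol(recording$data)
    for (ch in seq_len(nrow(out))) {
      x <- recording$data[ch, ]
      ext <- c(rev(x[2:(m + 1)]), x, rev(x[(n_in - m):(n_in - 1)]))
      y <- stats::filter(ext, h, sides = 2)[(m + 1):(m + n_in)]
      out[ch, ] <- y[seq(1, by = q, length.out = n_out)]
    }
  } else {
    # rational approximation for polyphase resampling
    fr <- .rat_approx(target_fs / fs)
    for (ch in seq_len(nrow(out))) {
      y <- signal::resample(recording$data[ch, ], fr[1], fr[2])
      out[ch, ] <- y[seq_len(n_out)]
    }
  }
  eeg_recording(out, target_fs, recording$channel_names, recording$montage)
}

.rat_approx <- function(x, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (den in 1:max_den) {
    num <- round(x * den)
    if (num >= 1 && abs(num / den - x) < err) {
      err <- abs(num / den - x); best <- c(as.integer(num), den)
      if (err < 1e-12) break
    }
  }
  best
}

#' Fit an extended-Infomax ICA decomposition
#'
#' PCA-whitens the (centred) channel data and runs the extended Infomax
#' natural-gradient rule, which handles both super- and sub-Gaussian sources
#' via a per-component sign estimated from a kurtosis statistic. Fitting is
#' deterministic under a fixed seed (the seed drives the block shuffling).
#'
#' @param recording An `eeg_recording` (high-pass it first: Infomax assumes
#'   roughly zero-mean, drift-free channels).
#' @param n_components Number of components (default: channel count).
#' @param max_iter Maximum training passes (default 200).
#' @param tol Stop when the update norm falls below this (default 1e-6).
#' @param lrate Initial learning rate (default 0.01 / log(n_components)).
#' @param max_samples Fit the unmixing on at most this many evenly spaced
#'   samples (default 1e5); sources are then computed for all samples.
#' @param seed Integer seed.
#' @return An object of class `ica_decomposition`: `unmixing` (components x
#'   channels), `mixing` (channels x components), `sources` (components x
#'   samples), `means`, `fs`, `rejected` (initially empty).
#' @export
fit_ica <- function(recording, n_components = NULL, max_iter = 200L,
                    tol = 1e-6, lrate = NULL, max_samples = 1e5, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  X <- recording$data
  nch <- nrow(X)
  if (is.null(n_components)) n_components <- nch
  if (n_components > nch) {
    abort("n_components cannot exceed the channel count",
          class = "painsense_parameter_error")
  }
  means <- rowMeans(X)
  Xc <- X - means
  # PCA whitening
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[n_components] < 1e-12 * eg$values[1]) {
    abort(paste0("data are rank deficient at ", n_components,
                 " components; reduce n_components"),
          class = "painsense_rank_error")
  }
  sphere <- diag(1 / sqrt(eg$values[seq_len(n_components)]),
                 n_components) %*% t(eg$vectors[, seq_len(n_components)])
  if (ncol(Xc) > max_samples) {
    sel <- unique(as.integer(round(seq(1, ncol(Xc), length.out = max_samples))))
  } else {
    sel <- seq_len(ncol(Xc))
  }
  Xw <- sphere %*% Xc[, sel, drop = FALSE]
  n <- ncol(Xw)
  k <- n_components
  if (is.null(lrate)) lrate <- 0.01 / log(k + 1)
  block <- as.integer(min(max(64, floor(sqrt(n / 3))), n))
  W <- diag(k)
  I_b <- diag(k)
  signs <- rep(1, k)   # +1 super-Gaussian, -1 sub-Gaussian
  with_local_seed(seed, {
    for (iter in seq_len(max_iter)) {
      W_old <- W
      perm <- sample.int(n)
      # refresh source-sign estimates from the current sources
      U_all <- W %*% Xw
      m2 <- rowMeans(U_all^2)
      signs <- sign(rowMeans(1 / cosh(U_all)^2) * m2 -
                      rowMeans(tanh(U_all) * U_all))
      signs[signs == 0] <- 1
      K <- diag(signs, k)
      for (b0 in seq(1, n - block + 1, by = block)) {
        U <- W %*% Xw[, perm[b0:(b0 + block - 1)], drop = FALSE]
        Y <- tanh(U)
        dW <- (I_b - (K %*% Y %*% t(U) + U %*% t(U)) / block) %*% W
        if (max(abs(dW)) > 1e8) {   # blow-up: restart with a smaller rate
          lrate <- lrate / 2
          W <- diag(k)
          break
        }
        W <- W + lrate * dW
      }
      delta <- max(abs(W - W_old))
      if (delta < tol) break
      if (iter %% 20 == 0) lrate <- lrate * 0.9
    }
  })
  unmixing <- W %*% sphere                       # components x channels
  mixing <- .pinv(unmixing)                  # channels x components
  sources <- unmixing %*% Xc
  structure(list(unmixing = unmixing, mixing = mixing, sources = sources,
                 means = means, fs = recording$fs,
                 channel_names = recording$channel_names,
                 montage = recording$montage, rejected = integer(0)),
            class = "ica_decomposition")
}

# Moore-Penrose pseudoinverse via SVD (square full-rank case reduces to
# solve()).
.pinv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components x %d channels; %d rejected\n",
              nrow(x$unmixing), ncol(x$unmixing), length(x$rejected)))
  invisible(x)
}

#' Default artifact-component criterion
#'
#' Flags a component as artifactual when its kurtosis z-score across
#' components exceeds `kurt_z` (spiky, blink-like activity) or when it
#' correlates above `drift_cor` with its own <1 Hz low-passed version
#' (drift-dominated activity).
#'
#' @param sources Components x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param kurt_z Kurtosis z-score threshold (default 3).
#' @param drift_cor Drift-correlation threshold (default 0.8).
#' @return Integer vector of component indices to reject.
#' @export
ica_default_rule <- function(sources, fs, kurt_z = 3, drift_cor = 0.8) {
  kurt <- apply(sources, 1, function(s) {
    s <- s - mean(s)
    mean(s^4) / mean(s^2)^2 - 3
  })
  kz <- (kurt - mean(kurt)) / (sd(kurt) + 1e-12)
  bt <- signal::butter(2, min(1 / (fs / 2), 0.99), type = "low")
  driftish <- apply(sources, 1, function(s) {
    lp <- signal::filtfilt(bt, s)
    if (sd(lp) < 1e-12) return(0)
    abs(cor(s, lp))
  })
  which(kz > kurt_z | driftish > drift_cor)
}

#' Reject artifact components and reconstruct the cleaned recording
#'
#' Reconstructs the channel data from the retained independent components
#' only. With an empty rejection set this is the identity to float tolerance.
#'
#' @param ica An `ica_decomposition`.
#' @param rule Either an integer vector of component indices to reject, or a
#'   function `(sources, fs) -> indices` (default [ica_default_rule()]).
#' @return An `eeg_recording` rebuilt from the retained components, with the
#'   rejected set attached as attribute `rejected`.
#' @export
reject_components <- function(ica, rule = ica_default_rule) {
  stopifnot(inherits(ica, "ica_decomposition"))
  rejected <- if (is.function(rule)) rule(ica$sources, ica$fs)
              else as.integer(rule)
  k <- nrow(ica$sources)
  rejected <- intersect(rejected, seq_len(k))
  if (length(rejected) >= k) {
    abort("artifact rule rejected every component; refusing to return an empty signal",
          class = "painsense_parameter_error")
  }
  if (length(rejected) > 0) {
    inform(paste0("rejecting ICA component(s): ",
                  paste(rejected, collapse = ", ")))
  }
  keep <- setdiff(seq_len(k), rejected)
  Xr <- ica$mixing[, keep, drop = FALSE] %*%
    ica$sources[keep, , drop = FALSE] + ica$means
  rec <- eeg_recording(Xr, ica$fs, ica$channel_names, ica$montage)
  attr(rec, "rejected") <- rejected
  rec
}

#' Preprocessing configuration
#'
#' @param hp_cutoff High-pass cutoff in Hz (default 1).
#' @param notch_freq Notch frequency in Hz (default 50).
#' @param target_fs Downsampling target in Hz (default 500).
#' @param ica Logical, run ICA artifact removal (default TRUE).
#' @param ica_n_components Component count (default: channel count).
#' @param ica_rule Artifact criterion passed to [reject_components()].
#' @param ica_max_samples Sample budget for ICA fitting.
#' @param seed Integer seed for the ICA fit.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(hp_cutoff = 1, notch_freq = 50, target_fs = 500,
                              ica = TRUE, ica_n_components = NULL,
                              ica_rule = ica_default_rule,
                              ica_max_samples = 1e5, seed = 1L) {
  if (!(hp_cutoff > 0 && hp_cutoff < notch_freq)) {
    abort("need 0 < hp_cutoff < notch_freq", class = "painsense_config_error")
  }
  structure(list(hp_cutoff = hp_cutoff, notch_freq = notch_freq,
                 target_fs = target_fs, ica = ica,
                 ica_n_components = ica_n_components, ica_rule = ica_rule,
                 ica_max_samples = ica_max_samples, seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Run the full preprocessing chain
#'
#' Fixed order: high-pass, notch, downsample, then (optionally) ICA artifact
#' rejection.
#'
#' @param recording An `eeg_recording`.
#' @param config A [preprocess_config()].
#' @return Cleaned `eeg_recording`.
#' @export
preprocess <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  rec <- eeg_highpass(recording, config$hp_cutoff)
  rec <- eeg_notch(rec, config$notch_freq)
  rec <- eeg_downsample(rec, config$target_fs)
  if (isTRUE(config$ica)) {
    ica <- fit_ica(rec, n_components = config$ica_n_components,
                   max_samples = config$ica_max_samples, seed = config$seed)
    rec <- reject_components(ica, rule = config$ica_rule)
  }
  rec
}
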