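# Shared test helpers: small signal builders and spectral oracles.

rms <- function(x) sqrt(mean(x^2))

# single-channel recording from a vector
rec1 <- function(x, fs = 1000) eeg_recording(matrix(x, 1), fs)

tone <- function(freq, fs = 1000, secs = 10, phase = 0) {
  sin(2 * pi * freq * seq(0, secs, by = 1 / fs) + phase)
}

# FFT-peak oracle: dominant frequency of a real signal in Hz
fft_peak <- function(x, fs) {
  n <- length(x)
  spec <- Mod(fft(x))[seq_len(floor(n / 2))]
  (which.max(spec) - 1) * fs / n
}

# Welch-style band power oracle (mean periodogram power in [lo, hi] Hz)
band_power <- function(x, fs, lo, hi, seg = 1024) {
  starts <- seq(1, length(x) - seg + 1, by = seg %/% 2)
  pows <- vapply(starts, function(s) {
    w <- x[s:(s + seg - 1)] * signal::hanning(seg)
    p <- Mod(fft(w))^2
    f <- (seq_len(seg) - 1) * fs / seg
    mean(p[f >= lo & f <= hi])
  }, 0)
  mean(pows)
}

# small epoch set built directly from matrices
epochs_from <- function(signals, ratings, fs = 500, channel_names = NULL) {
  if (is.null(channel_names)) {
    channel_names <- sprintf("EEG%02d", seq_len(nrow(signals[[1]])))
  }
  structure(list(signals = signals, ratings = as.integer(ratings),
                 durations = vapply(signals, ncol, 0L) / fs, fs = fs,
                 channel_names = channel_names),
            class = "eeg_epochs")
}

# brute-force confusion-matrix metrics used as the independent oracle
oracle_metrics <- function(truth, estimate, positive = NULL) {
  lv <- levels(truth)
  per_class <- lapply(lv, function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f)
  })
  names(per_class) <- lv
  acc <- mean(truth == estimate)
  if (length(lv) == 2) {
    if (is.null(positive)) positive <- if ("pain" %in% lv) "pain" else lv[2]
    pc <- per_class[[positive]]
    list(accuracy = acc, precision = pc["p"], recall = pc["r"], f1 = pc["f"])
  } else {
    list(accuracy = acc,
         precision = mean(vapply(per_class, `[`, 0, "p")),
         recall = mean(vapply(per_class, `[`, 0, "r")),
         f1 = mean(vapply(per_class, `[`, 0, "f")))
  }
}
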