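# Synthetic EEG generator.
#
# The generator produces recordings with the statistical structure the
# downstream pipeline assumes: ~1000 Hz multichannel signal, event markers
# encoding 1-10 pain ratings as 10000 + rating, variable 8-12 s epochs
# separated by 1 s inter-trial gaps, class-conditional alpha/beta oscillatory
# amplitude, 50 Hz line interference, slow drift and pink-ish background
# noise. Each nuisance component is a designed target for one preprocessing
# stage (drift -> high-pass, line -> notch, drift/blink-like spatial pattern
# -> ICA rejection).

#' Simulation configuration for the synthetic EEG generator
#'
#' @param n_channels Number of EEG channels (default 62, the analysis montage).
#' @param fs Sampling rate in Hz (default 1000).
#' @param n_events Number of pain trials (epochs) to generate.
#' @param rating_distribution Probability weights over ratings 1..10; must sum
#'   to 1. Default uniform.
#' @param epoch_duration_range Two ascending positive numbers, epoch duration
#'   bounds in seconds (default `c(8, 12)`).
#' @param band_effect List with numeric vectors `alpha` and `beta` of length
#'   10: multiplicative amplitude gain of the 10 Hz (alpha) and 20 Hz (beta)
#'   oscillations for each rating 1..10. Default: gain rising linearly from 1
#'   to 2 across the rating scale for both bands, so higher-rated trials carry
#'   more alpha/beta power.
#' @param alpha_amp,beta_amp Baseline oscillation amplitudes in microvolts.
#' @param line_noise_amp Amplitude of the 50 Hz line component (microvolts).
#' @param drift_amp Amplitude of the <0.5 Hz drift component (microvolts).
#' @param noise_sd Standard deviation of the pink-ish background noise.
#' @param gap Inter-epoch silence in seconds (default 1), so epoching from
#'   markers is unambiguous.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 62L, fs = 1000, n_events = 20L,
                       rating_distribution = rep(0.1, 10),
                       epoch_duration_range = c(8, 12),
                       band_effect = default_band_effect(),
                       alpha_amp = 4, beta_amp = 2,
                       line_noise_amp = 2, drift_amp = 20,
                       noise_sd = 5, gap = 1, seed = 1L) {
  .assert_scalar_num(n_channels, "n_channels", lower = 1)
  .assert_scalar_num(fs, "fs", lower = 1)
  .assert_scalar_num(n_events, "n_events", lower = 1)
  if (!is.numeric(rating_distribution) || length(rating_distribution) != 10 ||
      any(rating_distribution < 0) ||
      abs(sum(rating_distribution) - 1) > 1e-8) {
    abort("invalid 'rating_distribution': must be 10 non-negative weights summing to 1",
          class = "painsense_config_error")
  }
  if (!is.numeric(epoch_duration_range) || length(epoch_duration_range) != 2 ||
      any(epoch_duration_range <= 0) ||
      epoch_duration_range[1] > epoch_duration_range[2]) {
    abort("invalid 'epoch_duration_range': need 0 < low <= high",
          class = "painsense_config_error")
  }
  if (!is.list(band_effect) || !all(c("alpha", "beta") %in% names(band_effect)) ||
      length(band_effect$alpha) != 10 || length(band_effect$beta) != 10) {
    abort("invalid 'band_effect': need list(alpha=, beta=) with 10 gains each",
          class = "painsense_config_error")
  }
  # injected oscillations: alpha 10 Hz, beta 20 Hz, line 50 Hz
  if (fs <= 2 * 50) {
    abort("invalid 'fs': must exceed twice the highest injected frequency (50 Hz)",
          class = "painsense_config_error")
  }
  for (nm in c("alpha_amp", "beta_amp", "line_noise_amp", "drift_amp",
               "noise_sd", "gap")) {
    .assert_scalar_num(get(nm), nm, lower = 0)
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs,
    n_events = as.integer(n_events),
    rating_distribution = rating_distribution,
    epoch_duration_range = epoch_duration_range,
    band_effect = band_effect, alpha_amp = alpha_amp, beta_amp = beta_amp,
    line_noise_amp = line_noise_amp, drift_amp = drift_amp,
    noise_sd = noise_sd, gap = gap, seed = as.integer(seed)),
    class = "sim_config")
}

#' Default class-conditional band-amplitude gains
#'
#' Gain of the alpha (10 Hz) and beta (20 Hz) oscillation amplitude per pain
#' rating 1..10; linear from 1 to `max_gain`.
#'
#' @param max_gain Gain at rating 10 (default 2).
#' @export
default_band_effect <- function(max_gain = 2) {
  g <- seq(1, max_gain, length.out = 10)
  list(alpha = g, beta = g)
}

#' Generate a synthetic EEG recording with pain-rating event markers
#'
#' Builds a continuous recording of `n_events` epochs separated by `gap`
#' seconds of oscillation-free background. Each epoch's alpha/beta amplitude
#' is scaled by `band_effect` at its drawn rating; line noise, drift and
#' background noise run through the whole recording. One event marker with id
#' `10000 + rating` is placed at each epoch onset.
#'
#' @param config A [sim_config()].
#' @return List with `recording` (an `eeg_recording`) and `events` (tibble
#'   with 0-based `sample_index`, `event_id`, `rating`, `duration` in
#'   seconds).
#' @export
#' @examples
#' sim <- generate_recording(sim_config(n_channels = 4, n_events = 3, seed = 7))
#' sim$events
generate_recording <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("config must be a sim_config object", class = "painsense_config_error")
  }
  with_local_seed(config$seed, {
    fs <- config$fs
    n_ev <- config$n_events
    ratings <- sample.int(10L, n_ev, replace = TRUE,
                          prob = config$rating_distribution)
    durations <- runif(n_ev, config$epoch_duration_range[1],
                       config$epoch_duration_range[2])
    epoch_samps <- as.integer(round(durations * fs))
    gap_samps <- as.integer(round(config$gap * fs))
    starts <- gap_samps + cumsum(c(0L, head(epoch_samps + gap_samps, -1L)))
    n_total <- starts[n_ev] + epoch_samps[n_ev] + gap_samps
    tt <- seq(0, by = 1 / fs, length.out = n_total)

    nch <- config$n_channels
    X <- matrix(0, nrow = nch, ncol = n_total)
    # shared components: line noise (common phase), per-channel drift
    line <- config$line_noise_amp * sin(2 * pi * 50 * tt)
    drift_freqs <- runif(nch, 0.05, 0.3)
    drift_phases <- runif(nch, 0, 2 * pi)
    for (ch in seq_len(nch)) {
      bg <- as.numeric(
        stats::filter(rnorm(n_total), 0.9, method = "recursive"))
      bg <- bg * config$noise_sd / stats::sd(bg)
      X[ch, ] <- bg + line +
        config$drift_amp * sin(2 * pi * drift_freqs[ch] * tt + drift_phases[ch])
    }
    # class-conditional oscillations, per epoch / channel random phase
    for (ev in seq_len(n_ev)) {
      idx <- starts[ev] + seq_len(epoch_samps[ev])
      te <- tt[idx]
      ga <- config$band_effect$alpha[ratings[ev]] * config$alpha_amp
      gb <- config$band_effect$beta[ratings[ev]] * config$beta_amp
      pha <- runif(nch, 0, 2 * pi)
      phb <- runif(nch, 0, 2 * pi)
      for (ch in seq_len(nch)) {
        X[ch, idx] <- X[ch, idx] +
          ga * sin(2 * pi * 10 * te + pha[ch]) +
          gb * sin(2 * pi * 20 * te + phb[ch])
      }
    }
    rec <- eeg_recording(X, fs,
                         channel_names = sprintf("EEG%02d", seq_len(nch)))
    events <- tibble(
      sample_index = starts,            # 0-based sample of epoch onset
      event_id = PAIN_ID_BASE + ratings,
      rating = ratings,
      duration = epoch_samps / fs)
    list(recording = rec, events = events)
  })
}

#' Generate a labelled synthetic feature table
#'
#' Draws `sum(class_sizes)` rows of `n_features` Gaussian features; class k's
#' mean sits at `(k - 1) * effect_size` along one random unit direction, so
#' `effect_size = 0` gives exchangeable classes and large values give
#' linearly separable ones.
#'
#' @param class_sizes Named or unnamed positive integer vector of per-class
#'   row counts.
#' @param n_features Number of feature columns (default 10).
#' @param effect_size Between-class mean separation scale (default 1).
#' @param seed Integer seed.
#' @return A tibble with a `label` factor column followed by feature columns
#'   `f1..fn`.
#' @export
#' @examples
#' tab <- generate_feature_table(c(pain = 30, no_pain = 10), seed = 2)
#' dplyr::count(tab, label)
generate_feature_table <- function(class_sizes, n_features = 10L,
                                   effect_size = 1, seed = 1L) {
  if (!is.numeric(class_sizes) || length(class_sizes) < 1 ||
      any(class_sizes < 1)) {
    abort("invalid 'class_sizes': every class must have at least 1 sample",
          class = "painsense_config_error")
  }
  .assert_scalar_num(n_features, "n_features", lower = 1)
  labels <- names(class_sizes)
  class_sizes <- as.integer(class_sizes)
  if (is.null(labels)) labels <- paste0("class", seq_along(class_sizes))
  with_local_seed(seed, {
    u <- rnorm(n_features)
    u <- u / sqrt(sum(u^2))
    rows <- purrr::map2(seq_along(class_sizes), class_sizes, function(k, nk) {
      mu <- (k - 1) * effect_size * u
      matrix(rnorm(nk * n_features), nk, n_features) +
        matrix(mu, nk, n_features, byrow = TRUE)
    })
    X <- do.call(rbind, rows)
    colnames(X) <- paste0("f", seq_len(n_features))
    dplyr::bind_cols(
      tibble(label = factor(rep(labels, class_sizes), levels = labels)),
      as_tibble(X))
  })
}
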