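# Training-data augmentation: multiplicative scaling, bounded uniform noise
# injection, Hilbert-transform frequency shifting, and SMOTE class
# balancing. All of it applies to training partitions only; data flagged as
# a test partition is refused (leakage guard).

#' Augmentation configuration
#'
#' @param c_mult Multiplication constant; each sample yields variants scaled
#'   by `1 + c_mult` and `1 - c_mult` (default 0.05).
#' @param c_noise Noise constant (default 0.02). Under `noise_mode =
#'   "target_sd"` the injected uniform noise is rescaled so its realised
#'   standard deviation equals `c_noise * sigma(data)`; under
#'   `"formula_literal"` the noise is `rand * sigma * c_noise` with `rand`
#'   uniform on `rand_range`.
#' @param noise_mode `"target_sd"` (default) or `"formula_literal"`.
#' @param c_freq Frequency-shift magnitude in Hz (default 0.2); each sample
#'   yields a `-c_freq` and a `+c_freq` shifted variant.
#' @param rand_range Support of the uniform noise, symmetric about 0
#'   (default `c(-0.5, 0.5)`).
#' @param sigma_scope `"partition"` (default: one sigma for the whole
#'   training set) or `"sample"` (per-row sigma) for the noise operator.
#' @param operators Which transform operators to apply in
#'   [transform_training_set()].
#' @param smote_k SMOTE neighbour count (default 5).
#' @param seed Integer seed for one generator per augmentation run.
#' @return An `augment_config` list.
#' @export
augment_config <- function(c_mult = 0.05, c_noise = 0.02,
                           noise_mode = c("target_sd", "formula_literal"),
                           c_freq = 0.2, rand_range = c(-0.5, 0.5),
                           sigma_scope = c("partition", "sample"),
                           operators = c("multiply", "noise", "freq_shift"),
                           smote_k = 5L, seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  sigma_scope <- match.arg(sigma_scope)
  if (c_mult < 0 || c_mult >= 1) {
    abort("c_mult must lie in [0, 1)", class = "painsense_config_error")
  }
  if (c_freq < 0) abort("c_freq must be >= 0", class = "painsense_config_error")
  if (length(rand_range) != 2 || abs(rand_range[1] + rand_range[2]) > 1e-12) {
    abort("rand_range must be symmetric about 0",
          class = "painsense_config_error")
  }
  if (smote_k < 1) abort("smote_k must be >= 1", class = "painsense_config_error")
  structure(list(c_mult = c_mult, c_noise = c_noise, noise_mode = noise_mode,
                 c_freq = c_freq, rand_range = rand_range,
                 sigma_scope = sigma_scope, operators = operators,
                 smote_k = as.integer(smote_k), seed = as.integer(seed)),
            class = "augment_config")
}

#' Multiplicative augmentation variants
#'
#' @param sample Numeric vector (signal or feature row).
#' @param c_mult Multiplication constant.
#' @return List with `plus` (`sample * (1 + c_mult)`) and `minus`
#'   (`sample * (1 - c_mult)`).
#' @export
#' @examples
#' augment_multiply(c(1, 2), 0.05)
augment_multiply <- function(sample, c_mult = 0.05) {
  list(plus = sample * (1 + c_mult), minus = sample * (1 - c_mult))
}

#' Uniform-noise augmentation variant
#'
#' Adds bounded uniform noise scaled by the data's standard deviation. Under
#' the default `target_sd` mode the uniform draws are rescaled so the
#' realised noise standard deviation converges to `c_noise * sigma` (a
#' uniform on `[-0.5, 0.5]` has sd `1/sqrt(12)`, so the scale is
#' `c_noise * sigma * sqrt(12)`).
#'
#' @param sample Numeric vector.
#' @param config An [augment_config()].
#' @param sigma Standard deviation to scale by; defaults to `sd(sample)`
#'   (pass the training-partition sd for partition-scoped noise).
#' @param seed Optional seed (defaults to the config's).
#' @return Numeric vector, `sample + noise`.
#' @export
augment_noise <- function(sample, config = augment_config(), sigma = NULL,
                          seed = config$seed) {
  if (is.null(sigma)) sigma <- sd(sample)
  if (!is.finite(sigma)) {
    abort("sample standard deviation is not finite",
          class = "painsense_value_error")
  }
  if (sigma < 1e-300) {
    inform("zero-variance sample: noise scale is 0, returning input unchanged")
    return(sample)
  }
  u_sd <- diff(config$rand_range) / sqrt(12)
  scale <- switch(config$noise_mode,
    target_sd = config$c_noise * sigma / u_sd,
    formula_literal = sigma * config$c_noise)
  with_local_seed(seed, {
    sample + runif(length(sample), config$rand_range[1],
                   config$rand_range[2]) * scale
  })
}

#' Hilbert-transform frequency-shift variants
#'
#' Forms the analytic signal (Fourier transform with doubled positive
#' frequencies), multiplies by `exp(+-2i * pi * c_freq * t)` and returns the
#' real parts. A zero shift reproduces the input exactly.
#'
#' @param signal Numeric vector, length >= 4.
#' @param c_freq Shift magnitude in Hz.
#' @param dt Seconds per sample (`1/fs`).
#' @return List with `minus` and `plus` shifted variants.
#' @export
#' @examples
#' x <- cos(2 * pi * 8 * seq(0, 1, by = 1 / 500))
#' shifted <- freq_shift(x, c_freq = 2, dt = 1 / 500)
freq_shift <- function(signal, c_freq = 0.2, dt = 1) {
  n <- length(signal)
  if (n < 4) abort("signal too short for frequency shifting (need >= 4 samples)",
                   class = "painsense_parameter_error")
  if (c_freq >= 1 / (2 * dt)) {
    abort(sprintf("c_freq (%g Hz) must be below the Nyquist frequency (%g Hz)",
                  c_freq, 1 / (2 * dt)), class = "painsense_parameter_error")
  }
  h <- numeric(n)                      # 2 * unit step in the frequency domain
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- fft(fft(signal) * h, inverse = TRUE) / n
  t <- (seq_len(n) - 1) * dt
  list(minus = Re(analytic * exp(-2i * pi * c_freq * t)),
       plus = Re(analytic * exp(2i * pi * c_freq * t)))
}

.check_not_test <- function(data, what) {
  if (identical(attr(data, "painsense_partition"), "test")) {
    abort(paste0(what, " must only be applied to training data; ",
                 "this table is flagged as a test partition"),
          class = "painsense_leakage_error")
  }
}

#' Flag a table as a train or test partition
#'
#' The augmentation and balancing stages refuse tables flagged `"test"`.
#'
#' @param data A data frame.
#' @param partition `"train"` or `"test"`.
#' @return `data` with the partition attribute set.
#' @export
flag_partition <- function(data, partition = c("train", "test")) {
  attr(data, "painsense_partition") <- match.arg(partition)
  data
}

#' Expand a training table with the three transform operators
#'
#' Each input row yields six rows: the original, two multiplicative variants
#' (`1 +- c_mult`), one noise-injected variant, and two frequency-shifted
#' variants (`+-c_freq`); labels are replicated and a `variant` column
#' records provenance. Operators can be disabled via `config$operators`.
#' Rows are treated as series with spacing `dt` for the frequency-shift
#' operator (use the epoch sampling interval for signal rows; for feature
#' rows the operator acts on the ordered feature vector with `dt = 1`).
#'
#' @param data Tibble: label/metadata columns plus numeric feature columns
#'   (everything except `epoch`, `rating`, `label`, `variant`).
#' @param config An [augment_config()].
#' @param dt Sample spacing for the frequency-shift operator (default 1).
#' @return Tibble with the augmented rows and a `variant` column in
#'   `c("original", "mult_plus", "mult_minus", "noise", "freq_minus",
#'   "freq_plus")`.
#' @export
transform_training_set <- function(data, config = augment_config(), dt = 1) {
  .check_not_test(data, "transform_training_set()")
  fm <- feature_matrix(data)
  X <- fm$x
  n <- nrow(X)
  sigma_part <- sd(as.vector(X))
  pieces <- list(dplyr::mutate(data, variant = "original"))
  remake <- function(newX, tag) {
    out <- fm$meta
    out$variant <- tag
    dplyr::bind_cols(out, as_tibble(newX))
  }
  if ("multiply" %in% config$operators) {
    pieces <- c(pieces, list(
      remake(X * (1 + config$c_mult), "mult_plus"),
      remake(X * (1 - config$c_mult), "mult_minus")))
  }
  if ("noise" %in% config$operators) {
    noisy <- with_local_seed(config$seed, {
      t(apply(X, 1, function(row) {
        s <- if (config$sigma_scope == "partition") sigma_part else sd(row)
        augment_noise(row, config, sigma = s, seed = NULL)
      }))
    })
    colnames(noisy) <- colnames(X)
    pieces <- c(pieces, list(remake(noisy, "noise")))
  }
  if ("freq_shift" %in% config$operators) {
    minus <- plus <- X
    for (i in seq_len(n)) {
      fsft <- freq_shift(X[i, ], config$c_freq, dt)
      minus[i, ] <- fsft$minus
      plus[i, ] <- fsft$plus
    }
    pieces <- c(pieces, list(remake(minus, "freq_minus"),
                             remake(plus, "freq_plus")))
  }
  out <- dplyr::bind_rows(pieces)
  if (ncol(fm$meta) > 0) {
    dplyr::relocate(out, "variant",
                    .after = names(fm$meta)[ncol(fm$meta)])
  } else {
    dplyr::relocate(out, "variant")
  }
}

#' Balance classes with SMOTE
#'
#' For every minority class, synthesises points by interpolating between a
#' random class member `x` and one of its `k` nearest same-class neighbours
#' `x_nbr` (Euclidean): `x + u * (x_nbr - x)`, `u ~ U(0, 1)`, until every
#' class matches the majority count. Originals are preserved verbatim.
#'
#' @param data Tibble with a label column plus numeric feature columns.
#' @param k Neighbour count (default 5; capped at class size minus 1 with a
#'   warning).
#' @param label_col Name of the label column (default `"label"`).
#' @param seed Integer seed.
#' @return Tibble of originals followed by synthetic rows; per-class counts
#'   are exactly equal afterwards.
#' @export
#' @examples
#' tab <- generate_feature_table(c(a = 30, b = 10), n_features = 3, seed = 1)
#' dplyr::count(smote_balance(tab, seed = 1), label)
smote_balance <- function(data, k = 5L, label_col = "label", seed = 1L) {
  .check_not_test(data, "smote_balance()")
  if (!label_col %in% names(data)) {
    abort(paste0("label column '", label_col, "' not found"),
          class = "painsense_config_error")
  }
  y <- data[[label_col]]
  counts <- table(y)
  n_maj <- max(counts)
  feat_cols <- setdiff(names(data),
                       intersect(c("epoch", "rating", "label", "variant",
                                   label_col), names(data)))
  X <- as.matrix(data[feat_cols])
  synth_pieces <- list()
  with_local_seed(seed, {
    for (cls in names(counts)) {
      n_new <- n_maj - counts[[cls]]
      if (n_new == 0) next
      idx <- which(y == cls)
      if (length(idx) < 2) {
        abort(sprintf(
          "minority class '%s' has a single sample; no neighbour to interpolate",
          cls), class = "painsense_config_error")
      }
      k_use <- min(k, length(idx) - 1L)
      if (k_use < k) {
        warn(sprintf("class '%s': neighbour count reduced to %d (class size %d)",
                     cls, k_use, length(idx)))
      }
      Xc <- X[idx, , drop = FALSE]
      d2 <- as.matrix(stats::dist(Xc))^2
      diag(d2) <- Inf
      nbrs <- t(apply(d2, 1, function(r) order(r)[seq_len(k_use)]))
      base <- sample.int(length(idx), n_new, replace = TRUE)
      pick <- nbrs[cbind(base, sample.int(k_use, n_new, replace = TRUE))]
      u <- runif(n_new)
      Xs <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      piece <- as_tibble(Xs)
      piece[[label_col]] <- y[idx[1]][rep(1, n_new)]  # preserves factor levels
      synth_pieces <- c(synth_pieces, list(piece))
    }
  })
  if (length(synth_pieces) == 0) return(data)
  synth <- dplyr::bind_rows(synth_pieces)
  dplyr::bind_rows(data, synth[names(synth)])
}
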