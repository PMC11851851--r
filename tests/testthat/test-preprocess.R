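# Filtering, downsampling and ICA: attenuation oracles on pure tones,
# blind-source recovery, artifact rejection algebra.

test_that("high-pass removes DC and drift but passes alpha-band tones", {
  fs <- 1000
  x_const <- rep(7.3, 10 * fs)
  out <- eeg_highpass(rec1(x_const, fs), 1)
  expect_lt(max(abs(out$data)), 1e-3 * 7.3)
  slow <- tone(0.1, fs)
  out_slow <- eeg_highpass(rec1(slow, fs), 1)
  expect_lt(20 * log10(rms(out_slow$data) / rms(slow)), -20)
  fast <- tone(10, fs)
  out_fast <- eeg_highpass(rec1(fast, fs), 1)
  expect_lt(abs(20 * log10(rms(out_fast$data) / rms(fast))), 1)
  expect_equal(eeg_highpass(rec1(numeric(5000), fs), 1)$data,
               matrix(0, 1, 5000))
  expect_error(eeg_highpass(rec1(fast, fs), 600),
               class = "painsense_parameter_error")
})

test_that("notch kills 50 Hz but leaves tones 5 Hz away almost untouched", {
  fs <- 1000
  line <- tone(50, fs)
  out <- eeg_notch(rec1(line, fs), 50)
  expect_lt(20 * log10(rms(out$data) / rms(line)), -20)
  for (f in c(10, 45, 55)) {
    x <- tone(f, fs)
    out_f <- eeg_notch(rec1(x, fs), 50)
    expect_lt(abs(20 * log10(rms(out_f$data) / rms(x))), 1)
  }
  expect_equal(eeg_notch(rec1(numeric(4000), fs))$data, matrix(0, 1, 4000))
  expect_error(eeg_notch(rec1(line, fs), 500),
               class = "painsense_parameter_error")
})

test_that("filtering is linear within tolerance", {
  fs <- 1000
  x <- tone(7, fs, 4)
  y <- tone(23, fs, 4)
  fx <- eeg_highpass(rec1(x, fs))$data
  fy <- eeg_highpass(rec1(y, fs))$data
  fxy <- eeg_highpass(rec1(2 * x - 3 * y, fs))$data
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))) / max(abs(fxy)), 1e-6)
})

test_that("downsampling halves the sample count and preserves tone location", {
  fs <- 1000
  x <- tone(10, fs)[1:10000]
  ds <- eeg_downsample(rec1(x, fs), 500)
  expect_equal(ncol(ds$data), 5000)
  expect_equal(ds$fs, 500)
  expect_equal(ds$dt, 1 / 500)
  expect_equal(fft_peak(ds$data[1, ], 500), 10, tolerance = 0.1)
  # identity at equal rates, refusal to upsample
  same <- eeg_downsample(rec1(x, fs), fs)
  expect_identical(same$data[1, ], x)
  expect_error(eeg_downsample(rec1(x, fs), 2000),
               class = "painsense_parameter_error")
})

test_that("extended Infomax unmixes a sine/sawtooth mixture (|r| >= 0.95)", {
  n <- 20000
  s1 <- sin(2 * pi * 7 * (1:n) / 1000)
  s2 <- 2 * (((1:n) / 83) %% 1) - 1
  S <- rbind(s1, s2)
  A <- matrix(c(0.8, 0.3, -0.4, 0.9), 2, 2)
  ica <- fit_ica(eeg_recording(A %*% S, 1000), seed = 3)
  cc <- abs(cor(t(ica$sources), t(S)))
  expect_gt(max(cc[, 1]), 0.95)
  expect_gt(max(cc[, 2]), 0.95)
  # permutation structure: one dominant match per source
  expect_equal(sort(unname(apply(cc, 2, which.max))), c(1, 2))
})

test_that("ICA is deterministic under a fixed seed and returns n components", {
  rec <- eeg_recording(matrix(rnorm(4 * 6000), 4), 500)
  a <- fit_ica(rec, seed = 5, max_iter = 40)
  b <- fit_ica(rec, seed = 5, max_iter = 40)
  expect_identical(a$unmixing, b$unmixing)
  expect_equal(nrow(a$sources), 4)
  expect_equal(dim(a$unmixing), c(4, 4))
  c3 <- fit_ica(rec, n_components = 3, seed = 1, max_iter = 40)
  expect_equal(nrow(c3$sources), 3)
})

test_that("already-independent sources give a near-permutation unmixing", {
  set.seed(8)
  n <- 12000
  S <- rbind(runif(n, -sqrt(3), sqrt(3)),          # sub-Gaussian
             sin(2 * pi * 11 * (1:n) / 500))       # sub-Gaussian
  ica <- fit_ica(eeg_recording(S, 500), seed = 2)
  cc <- abs(cor(t(ica$sources), t(S)))
  expect_true(all(apply(cc, 2, max) > 0.95))
})

test_that("rank-deficient data are refused with advice", {
  X <- matrix(rnorm(2 * 4000), 2, 4000)
  X3 <- rbind(X, X[1, ] + X[2, ])
  expect_error(fit_ica(eeg_recording(X3, 500)), "reduce",
               class = "painsense_rank_error")
})

test_that("reconstruction with no rejected components is the identity", {
  rec <- eeg_recording(matrix(rnorm(3 * 5000), 3), 500)
  ica <- fit_ica(rec, seed = 1, max_iter = 40)
  clean <- reject_components(ica, rule = integer(0))
  expect_lt(max(abs(clean$data - rec$data)), 1e-8)
})

test_that("an injected blink/drift-like component is flagged and removed", {
  set.seed(4)
  n <- 30000
  fs <- 500
  t <- (1:n) / fs
  brain1 <- sin(2 * pi * 10 * t) + 0.3 * rnorm(n)
  brain2 <- sin(2 * pi * 21 * t + 1) + 0.3 * rnorm(n)
  # slow drifting artifact, spread across all channels
  artifact <- 8 * sin(2 * pi * 0.08 * t)
  A <- matrix(c(1, 0.2, 0.4,
                0.1, 1, 0.3,
                0.9, 0.8, 1), 3, 3)
  X <- A %*% rbind(brain1, brain2, artifact)
  rec <- eeg_recording(X, fs)
  ica <- fit_ica(rec, seed = 6)
  clean <- reject_components(ica)
  expect_gte(length(attr(clean, "rejected")), 1)
  # residual artifact variance down by at least half on every channel
  drift_var <- function(M) {
    vapply(seq_len(nrow(M)), function(ch) {
      var(M[ch, ]) * cor(M[ch, ], artifact)^2
    }, 0)
  }
  expect_true(all(drift_var(clean$data) < 0.5 * drift_var(rec$data)))
})

test_that("rejecting a component orthogonal to a channel leaves it unchanged", {
  # hand-built decomposition: component 2 has zero loading on channel 1
  set.seed(2)
  S <- matrix(rnorm(2 * 2000), 2, 2000)
  A <- matrix(c(1.0, 0.0,
                0.5, 1.2), 2, 2, byrow = TRUE)   # A[1, 2] = 0
  ica <- structure(list(
    unmixing = solve(A), mixing = A, sources = S,
    means = c(0, 0), fs = 500, channel_names = c("c1", "c2"),
    montage = NULL, rejected = integer(0)), class = "ica_decomposition")
  X <- A %*% S
  clean <- suppressMessages(reject_components(ica, rule = 2L))
  expect_lt(max(abs(clean$data[1, ] - X[1, ])), 1e-10)
  expect_gt(max(abs(clean$data[2, ] - X[2, ])), 0.1)
  expect_error(reject_components(ica, rule = c(1L, 2L)),
               class = "painsense_parameter_error")
})

test_that("the preprocessing chain runs in fixed order and cleans a tiny recording", {
  cfg <- sim_config(n_channels = 3, n_events = 3, seed = 12)
  sim <- generate_recording(cfg)
  clean <- suppressMessages(
    preprocess(sim$recording,
               preprocess_config(ica_max_samples = 2e4, seed = 1)))
  expect_equal(clean$fs, 500)
  expect_equal(nrow(clean$data), 3)
  expect_equal(ncol(clean$data), ncol(sim$recording$data) %/% 2)
  # line noise and drift strongly attenuated relative to the raw signal
  raw_line <- band_power(sim$recording$data[1, ], 1000, 49, 51)
  out_line <- band_power(clean$data[1, ], 500, 49, 51)
  expect_lt(out_line, 0.05 * raw_line)
})
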