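# Shared internal helpers.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# All randomised operations in the package take explicit seeds and go through
# this helper, so nothing depends on (or disturbs) the global RNG stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("invalid value for '%s': must be a number in [%s, %s]",
                  name, format(lower), format(upper)),
          class = "painsense_config_error")
  }
  invisible(x)
}

#' Construct an EEG recording container
#'
#' Lightweight container for continuous multichannel EEG: a channels x samples
#' matrix in microvolts plus sampling metadata. `dt` (seconds per sample) is
#' derived as `1/fs`.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param montage Optional data frame of per-channel X, Y, Z positions.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, montage = NULL) {
  data <- as.matrix(data)
  .assert_scalar_num(fs, "fs", lower = 1e-9)
  if (is.null(channel_names)) {
    channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    abort("channel_names length must equal the number of data rows",
          class = "painsense_config_error")
  }
  if (anyNA(data)) {
    abort("recording data contains NA values", class = "painsense_io_error")
  }
  # channel names live in their own field; naming the (potentially huge)
  # matrix would force a full copy
  structure(list(data = data, fs = fs, dt = 1 / fs,
                 channel_names = channel_names, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)
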