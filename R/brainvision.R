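# BrainVision-style triplet I/O and epoching.
#
# Dialect covered: INI header (.vhdr) with BINARY / MULTIPLEXED /
# IEEE_FLOAT_32 data, data file (.eeg) of 32-bit floats in sample-major
# (multiplexed) order, marker file (.vmrk) with
# "Mk<n>=<type>,<description>,<position>[,...]" lines. Marker positions are
# 1-based data points on disk (BrainVision convention); in memory the package
# uses 0-based sample indices and half-open [start, end) epoch windows.
# Anything else (VECTORIZED orientation, INT_16 data, segmented files) raises
# an explicit unsupported-dialect error rather than misparsing silently.

#' Decode a pain rating from an event id
#'
#' Event ids encode the 1-10 rating as `10000 + rating` (id 10005 means a
#' rating of 5).
#'
#' @param event_id Integer vector of marker ids.
#' @return Integer vector of ratings in 1..10.
#' @export
#' @examples
#' decode_event(c(10010, 10005))
decode_event <- function(event_id) {
  rating <- as.integer(event_id) - PAIN_ID_BASE
  bad <- is.na(rating) | rating < 1L | rating > 10L
  if (any(bad)) {
    abort(sprintf("event id(s) %s do not encode a pain rating in 1..10",
                  paste(event_id[bad], collapse = ", ")),
          class = "painsense_decode_error")
  }
  rating
}

#' Map pain ratings to pain/no-pain labels
#'
#' Ratings of 5 or below are `no_pain`; ratings above 5 are `pain`.
#'
#' @param rating Integer vector of ratings in 1..10.
#' @return Factor with levels `no_pain`, `pain`.
#' @export
#' @examples
#' label_binary(c(5, 6, 10))
label_binary <- function(rating) {
  .check_rating(rating)
  factor(ifelse(rating <= 5, "no_pain", "pain"),
         levels = c("no_pain", "pain"))
}

#' Map pain ratings to low/moderate/high severity labels
#'
#' Ratings of 3 or below are `low`, 4-6 are `moderate`, above 6 are `high`.
#'
#' @inheritParams label_binary
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
#' @examples
#' label_ternary(c(3, 6, 7))
label_ternary <- function(rating) {
  .check_rating(rating)
  factor(ifelse(rating <= 3, "low", ifelse(rating <= 6, "moderate", "high")),
         levels = c("low", "moderate", "high"))
}

.check_rating <- function(rating) {
  if (any(is.na(rating)) || any(rating < 1) || any(rating > 10) ||
      any(rating != round(rating))) {
    abort("ratings must be integers in 1..10", class = "painsense_domain_error")
  }
  invisible(rating)
}

#' Write a recording as a BrainVision triplet
#'
#' Serialises an `eeg_recording` plus event table to `<prefix>.vhdr`,
#' `<prefix>.eeg` (IEEE float-32, multiplexed) and `<prefix>.vmrk`
#' (`Mk<n>=Comment,<id>,<position>` with 1-based positions).
#'
#' @param recording An `eeg_recording`.
#' @param events Tibble with `sample_index` (0-based) and `event_id`.
#' @param prefix Output path prefix (without extension).
#' @return Invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(recording, events, prefix) {
  stopifnot(inherits(recording, "eeg_recording"))
  base <- basename(prefix)
  vhdr <- paste0(prefix, ".vhdr")
  nch <- nrow(recording$data)
  header <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    sprintf("SamplingInterval=%.6g", 1e6 / recording$fs),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), recording$channel_names))
  writeLines(header, vhdr, useBytes = TRUE)
  con <- file(paste0(prefix, ".eeg"), "wb")
  on.exit(close(con), add = TRUE)
  # multiplexed: all channels of sample 1, then sample 2, ... = column-major
  writeBin(as.numeric(recording$data), con, size = 4L, endian = "little")
  markers <- c(
    "Brain Vision Data Exchange Marker File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    sprintf("Mk%d=Comment,%d,%d,1,0", seq_len(nrow(events)),
            events$event_id, events$sample_index + 1L))
  writeLines(markers, paste0(prefix, ".vmrk"), useBytes = TRUE)
  invisible(vhdr)
}

.parse_ini <- function(lines) {
  out <- list()
  section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && section != "") {
      key <- sub("=.*$", "", ln)
      out[[section]][[key]] <- sub("^[^=]*=", "", ln)
    }
  }
  out
}

#' Read a BrainVision triplet
#'
#' Parses the header, loads the binary data scaled to microvolts, and decodes
#' pain-event markers (`Comment` markers whose description is `10000 +
#' rating`). Other marker types/ids are ignored with a message stating how
#' many were skipped. Channels not in `include_channels` (when given) are
#' dropped with a message listing them, mirroring the 68-recorded /
#' 62-analysed montage situation.
#'
#' @param header_path Path to the `.vhdr` file.
#' @param include_channels Optional character vector of channel names to keep.
#' @return List with `recording` (an `eeg_recording`) and `events` (tibble
#'   with 0-based `sample_index`, `event_id`, `rating`).
#' @export
read_brainvision <- function(header_path, include_channels = NULL) {
  if (!file.exists(header_path)) {
    abort(paste0("header file not found: ", header_path),
          class = "painsense_io_error")
  }
  ini <- .parse_ini(readLines(header_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci$DataFile) || is.null(ci$MarkerFile)) {
    abort("header does not reference DataFile/MarkerFile",
          class = "painsense_io_error")
  }
  if (!identical(ci$DataFormat, "BINARY") ||
      !identical(ci$DataOrientation, "MULTIPLEXED") ||
      !identical(bi$BinaryFormat, "IEEE_FLOAT_32")) {
    abort(sprintf(
      "unsupported BrainVision dialect (DataFormat=%s, DataOrientation=%s, BinaryFormat=%s); only BINARY/MULTIPLEXED/IEEE_FLOAT_32 is read",
      ci$DataFormat, ci$DataOrientation, bi$BinaryFormat),
      class = "painsense_unsupported_error")
  }
  dir <- dirname(header_path)
  data_path <- file.path(dir, ci$DataFile)
  marker_path <- file.path(dir, ci$MarkerFile)
  for (p in c(data_path, marker_path)) {
    if (!file.exists(p)) {
      abort(paste0("companion file not found: ", p),
            class = "painsense_io_error")
    }
  }
  nch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  chinfo <- ini[["Channel Infos"]]
  ch_fields <- lapply(unname(unlist(chinfo)), function(v) strsplit(v, ",")[[1]])
  ch_names <- vapply(ch_fields, `[`, "", 1L)
  resolution <- vapply(ch_fields, function(f) {
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r)) 1 else r
  }, 0)

  n_bytes <- file.size(data_path)
  n_vals <- n_bytes %/% 4L
  if (n_bytes %% 4L != 0L || n_vals %% nch != 0L) {
    abort(sprintf(
      "data file %s has %d bytes, not a whole number of %d-channel float-32 samples",
      data_path, n_bytes, nch), class = "painsense_io_error")
  }
  con <- file(data_path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = n_vals, size = 4L, endian = "little")
  X <- matrix(vals, nrow = nch) * resolution   # multiplexed -> channels x samples

  mk <- .parse_ini(readLines(marker_path, warn = FALSE))[["Marker Infos"]]
  mk_fields <- lapply(unname(unlist(mk)), function(v) strsplit(v, ",")[[1]])
  types <- vapply(mk_fields, `[`, "", 1L)
  descs <- vapply(mk_fields, `[`, "", 2L)
  pos <- vapply(mk_fields, function(f) suppressWarnings(as.integer(f[3])), 0L)
  ids <- suppressWarnings(as.integer(descs))
  is_pain <- types == "Comment" & !is.na(ids) &
    ids > PAIN_ID_BASE & ids <= PAIN_ID_BASE + 10L
  n_skip <- sum(!is_pain)
  if (n_skip > 0) {
    inform(sprintf("ignored %d non-pain marker(s)", n_skip))
  }
  events <- tibble(
    sample_index = pos[is_pain] - 1L,   # disk positions are 1-based
    event_id = ids[is_pain],
    rating = decode_event(ids[is_pain]))

  if (!is.null(include_channels)) {
    drop <- setdiff(ch_names, include_channels)
    if (length(drop) > 0) {
      inform(paste0("dropping channel(s) not in analysis montage: ",
                    paste(drop, collapse = ", ")))
    }
    keep <- ch_names %in% include_channels
    X <- X[keep, , drop = FALSE]
    ch_names <- ch_names[keep]
  }
  list(recording = eeg_recording(X, fs, channel_names = ch_names),
       events = events)
}

#' Cut epochs from a continuous recording at its event markers
#'
#' Each epoch starts at its event's sample index and ends at the next event,
#' `max_duration`, or the end of the recording, whichever comes first
#' (half-open window). Epochs shorter than `min_duration` are kept with a
#' warning.
#'
#' @param recording An `eeg_recording`.
#' @param events Tibble with 0-based `sample_index` and `rating` (or
#'   `event_id` to decode).
#' @param max_duration,min_duration Duration bounds in seconds (defaults 12
#'   and 8).
#' @return An object of class `eeg_epochs`: list with `signals` (list of
#'   channels x time matrices), `ratings`, `durations`, `fs`,
#'   `channel_names`.
#' @export
epoch_recording <- function(recording, events, max_duration = 12,
                            min_duration = 8) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- ncol(recording$data)
  fs <- recording$fs
  if (!"rating" %in% names(events)) {
    events$rating <- decode_event(events$event_id)
  }
  starts <- as.integer(events$sample_index)
  if (any(starts < 0L) || any(starts >= n)) {
    abort("event beyond the end of the recording",
          class = "painsense_bounds_error")
  }
  next_start <- c(starts[-1L], n)
  ends <- pmin(next_start, starts + as.integer(round(max_duration * fs)), n)
  durations <- (ends - starts) / fs
  if (any(durations < min_duration)) {
    warn(sprintf("%d epoch(s) shorter than %g s", sum(durations < min_duration),
                 min_duration))
  }
  signals <- purrr::map2(starts, ends, function(s, e) {
    recording$data[, (s + 1L):e, drop = FALSE]   # [start, end), 0-based
  })
  structure(list(signals = signals, ratings = as.integer(events$rating),
                 durations = durations, fs = fs,
                 channel_names = recording$channel_names),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels @ %g Hz; durations %.1f-%.1f s\n",
              length(x$signals), nrow(x$signals[[1]]), x$fs,
              min(x$durations), max(x$durations)))
  invisible(x)
}

#' @export
length.eeg_epochs <- function(x) length(x$signals)
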