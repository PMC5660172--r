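#' Multichannel EEG recording container
#'
#' An `eeg_recording` holds a channels-by-samples matrix in microvolts together
#' with its sampling rate, ordered channel labels and a start-time offset.
#' It is the common input of the filtering, spectral, coherence, coupling and
#' evoked-potential stages.
#'
#' @param data numeric matrix, channels x samples, in microvolts. Row names,
#'   if present, are used as default labels.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of unique channel names, one per row of
#'   `data`. Conventional montage labels are `PFC_L`, `PFC_R`, `CA1_L`,
#'   `CA1_R`, `CA3_L`, `CA3_R`.
#' @param start_time offset of the first sample in seconds (default 0).
#'
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `labels`, `start_time`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 2), fs = 1000,
#'                  labels = c("PFC_L", "PFC_R"))
#' duration(rec)
#' @export
recording <- function(data, fs, labels = rownames(data), start_time = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop_param("`data` must be a numeric channels x samples matrix")
  if (!all(is.finite(data)))
    stop_param("recording samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_param("`fs` must be a single positive number (Hz)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop_param("need one label per channel (", nrow(data), " channels, ",
               length(labels), " labels)")
  if (anyDuplicated(labels))
    stop_param("channel labels must be unique")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, duration(x)))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an [recording()] object.
#' @return length of the recording in seconds.
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$data) / rec$fs
}

# fetch one channel as a numeric vector, with a lookup error on unknown labels
channel_data <- function(rec, channel) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!channel %in% rec$labels)
    stop_param("unknown channel label '", channel, "'; recording has: ",
               paste(rec$labels, collapse = ", "))
  rec$data[channel, ]
}

#' Stimulus/event table
#'
#' Onset times (seconds from recording start) with an event code per onset.
#' Codes are free strings; the oddball analyses use `"standard"` and
#' `"deviant"`, and `"artifact"` marks events to be skipped.
#'
#' @param onsets numeric vector of onset times in seconds, non-decreasing.
#' @param codes character vector of event codes, recycled if length 1.
#' @return An object of class `event_list` (a data.frame with columns
#'   `onset_s`, `code`).
#' @export
event_list <- function(onsets, codes) {
  if (length(codes) == 1L) codes <- rep(codes, length(onsets))
  if (length(onsets) != length(codes))
    stop_param("`onsets` and `codes` must have equal length")
  if (length(onsets) && (any(!is.finite(onsets)) || any(onsets < 0)))
    stop_param("onsets must be finite and >= 0")
  if (is.unsorted(onsets))
    stop_param("onsets must be non-decreasing")
  structure(
    data.frame(onset_s = as.numeric(onsets), code = as.character(codes),
               stringsAsFactors = FALSE),
    class = c("event_list", "data.frame")
  )
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d events\n", nrow(x)))
  if (nrow(x)) print(table(x$code))
  invisible(x)
}
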