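#' Epoch container
#'
#' Fixed-length signal segments (epochs x channels x samples, microvolts) with
#' per-epoch metadata: vigilance-state label, condition label, artifact flag
#' and the onset of the epoch in the source recording. ERP epochs additionally
#' carry `tmin`, the time of the first sample relative to stimulus onset.
#'
#' @param data numeric array epochs x channels x samples.
#' @param fs sampling rate in Hz.
#' @param epoch_length epoch length in seconds.
#' @param meta data.frame with one row per epoch; columns `state`,
#'   `condition`, `artifact`, `onset` are filled with defaults when missing.
#' @param labels channel labels.
#' @param tmin time of the first sample relative to the epoch anchor
#'   (seconds; 0 for sleep/connectivity epochs, negative for ERP epochs).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, epoch_length, meta = NULL, labels = NULL,
                      tmin = 0) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n_ep <- dim(data)[1]
  n_sp <- dim(data)[3]
  if (n_ep > 0 && n_sp != round(epoch_length * fs))
    stop_param("samples per epoch (", n_sp, ") must equal round(epoch_length * fs) = ",
               round(epoch_length * fs))
  if (is.null(labels)) labels <- dimnames(data)[[2]] %||% paste0("ch", seq_len(dim(data)[2]))
  if (is.null(meta)) {
    meta <- data.frame(state = character(0), condition = character(0),
                       artifact = logical(0), onset = numeric(0))
    if (n_ep > 0)
      meta <- data.frame(state = rep("unknown", n_ep),
                         condition = rep(NA_character_, n_ep),
                         artifact = rep(FALSE, n_ep),
                         onset = rep(NA_real_, n_ep),
                         stringsAsFactors = FALSE)
  }
  if (nrow(meta) != n_ep)
    stop_param("meta must have one row per epoch")
  for (col in c("state", "condition", "artifact", "onset")) {
    if (is.null(meta[[col]])) {
      meta[[col]] <- switch(col,
        state = rep("unknown", n_ep), condition = rep(NA_character_, n_ep),
        artifact = rep(FALSE, n_ep), onset = rep(NA_real_, n_ep))
    }
  }
  dimnames(data) <- list(NULL, labels, NULL)
  structure(
    list(data = data, fs = fs, epoch_length = epoch_length, meta = meta,
         labels = labels, tmin = tmin),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epoch(s) x %d channel(s) x %d samples @ %g Hz (%g s epochs)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$epoch_length))
  if (nrow(x$meta))
    cat(sprintf("  artifact-flagged: %d; conditions: %s\n",
                sum(x$meta$artifact),
                paste(unique(stats::na.omit(x$meta$condition)), collapse = ", ")))
  invisible(x)
}

#' Number of epochs
#' @param epochs an [epoch_set()].
#' @return integer epoch count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

#' Segment a recording into consecutive fixed-length epochs
#'
#' Cuts the recording into consecutive, non-overlapping epochs on half-open
#' boundaries `[t, t + epoch_length)`; a trailing partial epoch is discarded.
#' An epoch is flagged as artifact when any sample on any channel exceeds
#' `artifact_threshold` in absolute value, or when any channel is flat
#' (variance below `flat_variance`, a dead-electrode guard).
#'
#' @param rec an [recording()].
#' @param epoch_length epoch length in seconds (default 4, the conventional
#'   scoring epoch for rodent EEG).
#' @param artifact_threshold absolute-amplitude rejection threshold in
#'   microvolts (default 1000).
#' @param state_labels optional character vector of per-epoch vigilance-state
#'   labels (`waking`/`NREM`/`REM`/`unknown`), recycled if length 1.
#' @param flat_variance per-epoch, per-channel variance (µV²) below which a
#'   channel counts as flat-lined (default 1e-3).
#' @return An [epoch_set()]; empty (zero epochs) when the recording is shorter
#'   than one epoch.
#' @export
segment_epochs <- function(rec, epoch_length = 4, artifact_threshold = 1000,
                           state_labels = NULL, flat_variance = 1e-3) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_per <- round(epoch_length * rec$fs)
  if (n_per < 2)
    stop_param("epoch_length x fs must be at least 2 samples")
  n_ep <- ncol(rec$data) %/% n_per
  n_ch <- nrow(rec$data)
  data <- array(0, dim = c(n_ep, n_ch, n_per))
  artifact <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * n_per + 1L):(e * n_per)
    seg <- rec$data[, idx, drop = FALSE]
    data[e, , ] <- seg
    v <- apply(seg, 1, stats::var)
    artifact[e] <- any(abs(seg) > artifact_threshold) || any(v < flat_variance)
  }
  state <- rep("unknown", n_ep)
  if (!is.null(state_labels)) {
    if (length(state_labels) == 1L) state_labels <- rep(state_labels, n_ep)
    if (length(state_labels) != n_ep)
      stop_param("state_labels must have one entry per epoch (", n_ep, ")")
    state <- as.character(state_labels)
  }
  meta <- data.frame(state = state, condition = rep(NA_character_, n_ep),
                     artifact = artifact,
                     onset = rec$start_time + (seq_len(n_ep) - 1L) * epoch_length,
                     stringsAsFactors = FALSE)
  if (n_ep == 0)
    meta <- data.frame(state = character(0), condition = character(0),
                       artifact = logical(0), onset = numeric(0))
  epoch_set(data, rec$fs, epoch_length, meta, labels = rec$labels)
}

# epochs surviving artifact rejection (and optionally a state/condition filter)
usable_epochs <- function(epochs, state = NULL, condition = NULL) {
  keep <- !epochs$meta$artifact
  if (!is.null(state)) keep <- keep & epochs$meta$state %in% state
  if (!is.null(condition)) keep <- keep & !is.na(epochs$meta$condition) &
      epochs$meta$condition %in% condition
  which(keep)
}
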