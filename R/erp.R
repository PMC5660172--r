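# Passive-oddball evoked-potential analysis: stimulus-locked epoching,
# baseline-corrected averaging, P1/N1/P2/N2 component extraction with the
# N1-P1 / N1-P2 peak-to-peak complex amplitudes, and Morlet evoked-
# oscillation power. Polarity convention: positive is upward; N components
# are detected as minima.

#' Extract stimulus-locked epochs
#'
#' One epoch per non-artifact event, spanning `window[1]` to `window[2]`
#' seconds around each onset (default -50 ms to +450 ms). Events whose
#' window exceeds the recording bounds are skipped; the skipped count is
#' attached as attribute `n_skipped`.
#'
#' @param rec an [recording()].
#' @param events an [event_list()]; events coded `"artifact"` are ignored.
#' @param window `c(start, end)` in seconds relative to stimulus onset
#'   (default `c(-0.05, 0.45)`).
#' @return An [epoch_set()] with `tmin = window[1]` and per-epoch condition
#'   labels copied from the event codes.
#' @export
extract_erp_epochs <- function(rec, events, window = c(-0.05, 0.45)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(events, "event_list"))
  if (window[1] >= window[2])
    stop_param("window must satisfy start < end")
  n_sp <- round((window[2] - window[1]) * rec$fs)
  keep <- events$code != "artifact"
  onsets <- events$onset_s[keep]
  codes <- events$code[keep]
  n_total <- ncol(rec$data)
  first <- round((onsets - rec$start_time + window[1]) * rec$fs) + 1L
  ok <- first >= 1L & (first + n_sp - 1L) <= n_total
  n_skipped <- sum(!ok)
  if (!any(ok))
    stop_param("no extractable events: all ", length(onsets),
               " event windows fall outside the recording")
  first <- first[ok]
  codes <- codes[ok]
  n_ep <- length(first)
  data <- array(0, dim = c(n_ep, nrow(rec$data), n_sp))
  for (e in seq_len(n_ep))
    data[e, , ] <- rec$data[, first[e]:(first[e] + n_sp - 1L), drop = FALSE]
  meta <- data.frame(state = rep("unknown", n_ep), condition = codes,
                     artifact = rep(FALSE, n_ep),
                     onset = onsets[ok], stringsAsFactors = FALSE)
  out <- epoch_set(data, rec$fs, n_sp / rec$fs, meta, labels = rec$labels,
                   tmin = window[1])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Condition-averaged evoked potential
#'
#' Per epoch and channel, subtracts the mean of the pre-stimulus baseline
#' interval `[tmin, 0)` and averages the corrected epochs of the requested
#' condition. The baseline mean of the result is zero by construction.
#'
#' @param epochs an [epoch_set()] from [extract_erp_epochs()] (`tmin < 0`).
#' @param condition condition label to average (e.g. `"standard"`).
#' @return An `erp_average` object: `times` (ms relative to onset),
#'   `waveform` (channels x samples, µV), `condition`, `n_trials`.
#' @export
average_erp <- function(epochs, condition) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$tmin >= 0)
    stop_param("epochs carry no pre-stimulus baseline (tmin = ", epochs$tmin, ")")
  use <- usable_epochs(epochs, condition = condition)
  if (!length(use))
    stop_param("no usable epochs of condition '", condition, "'")
  n_sp <- dim(epochs$data)[3]
  times <- (epochs$tmin + (seq_len(n_sp) - 1L) / epochs$fs) * 1000
  bl <- which(times < 0)
  n_ch <- dim(epochs$data)[2]
  wav <- matrix(0, n_ch, n_sp, dimnames = list(epochs$labels, NULL))
  for (e in use) {
    seg <- epochs$data[e, , , drop = TRUE]
    if (n_ch == 1L) seg <- matrix(seg, nrow = 1)
    seg <- seg - rowMeans(seg[, bl, drop = FALSE])
    wav <- wav + seg
  }
  wav <- wav / length(use)
  structure(
    list(times = times, waveform = wav, condition = condition,
         n_trials = length(use), fs = epochs$fs),
    class = "erp_average"
  )
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf("<erp_average> '%s', %d channel(s), %g..%g ms, %d trial(s)\n",
              x$condition, nrow(x$waveform), min(x$times), max(x$times),
              x$n_trials))
  invisible(x)
}

#' @export
as.data.frame.erp_average <- function(x, ...) {
  data.frame(
    condition = x$condition,
    channel = rep(rownames(x$waveform), times = length(x$times)),
    time_ms = rep(x$times, each = nrow(x$waveform)),
    amplitude = as.vector(x$waveform), stringsAsFactors = FALSE)
}

#' Grand average across animals
#'
#' Unweighted mean of per-animal [average_erp()] waveforms sharing the same
#' time grid and condition.
#'
#' @param erps list of `erp_average` objects.
#' @return An `erp_average`; `n_trials` is the number of animals averaged.
#' @export
grand_average <- function(erps) {
  if (!is.list(erps) || !length(erps))
    stop_param("need a non-empty list of erp_average objects")
  ref <- erps[[1]]
  wav <- ref$waveform * 0
  for (e in erps) {
    stopifnot(inherits(e, "erp_average"))
    if (!isTRUE(all.equal(e$times, ref$times)) ||
        !identical(e$condition, ref$condition))
      stop_param("all ERPs must share the same time grid and condition")
    wav <- wav + e$waveform
  }
  ref$waveform <- wav / length(erps)
  ref$n_trials <- length(erps)
  ref
}

# earliest strict local extremum of the requested polarity inside [lo, hi) ms;
# returns c(amp, lat) or NULL when the segment is monotone there
find_peak <- function(times, x, lo, hi, polarity) {
  sel <- which(times >= lo & times < hi)
  if (length(sel) < 1) return(NULL)
  y <- if (polarity > 0) x else -x
  n <- length(x)
  is_lmax <- vapply(sel, function(i) {
    l <- if (i > 1L) y[i - 1L] else -Inf
    r <- if (i < n) y[i + 1L] else -Inf
    y[i] >= l && y[i] >= r && (y[i] > l || y[i] > r)
  }, logical(1))
  cand <- sel[is_lmax]
  if (!length(cand)) return(NULL)
  best <- cand[which.max(y[cand])]               # which.max returns earliest tie
  c(amp = x[best], lat = times[best])
}

#' P1/N1/P2/N2 component table
#'
#' Peak amplitudes and latencies of the four auditory components within
#' per-component latency windows, plus the N1-P1 and N1-P2 peak-to-peak
#' complex amplitudes (P peak minus N peak, both non-negative for canonical
#' polarity). P components are maxima, N components minima; ties are broken
#' towards the earlier latency. A window containing no local extremum of the
#' expected polarity (a monotone segment) yields `NA` for that component and
#' for any complex involving it.
#'
#' @param erp an [average_erp()] result.
#' @param windows named list of `c(lo, hi)` latency windows in ms, ordered
#'   P1 < N1 < P2 < N2. Defaults: P1 `[10, 30)`, N1 `[30, 50)`, P2
#'   `[50, 100)`, N2 `[100, 200)`.
#' @return A `component_table` data.frame, one row per channel, with columns
#'   `<comp>_amp` (µV), `<comp>_lat` (ms), `N1P1`, `N1P2`.
#' @export
detect_components <- function(erp,
                              windows = list(P1 = c(10, 30), N1 = c(30, 50),
                                             P2 = c(50, 100), N2 = c(100, 200))) {
  stopifnot(inherits(erp, "erp_average"))
  los <- vapply(windows, `[`, numeric(1), 1)
  if (is.unsorted(los, strictly = TRUE))
    stop_param("component windows must be ordered by increasing latency")
  for (w in windows)
    if (w[1] < min(erp$times) || w[2] > max(erp$times) + 1e-9)
      stop_param("component window [", w[1], ", ", w[2],
                 ") ms exceeds the epoch time range")
  rows <- lapply(rownames(erp$waveform), function(ch) {
    x <- erp$waveform[ch, ]
    row <- list(channel = ch, condition = erp$condition)
    for (nm in names(windows)) {
      pol <- if (startsWith(nm, "P")) 1 else -1
      pk <- find_peak(erp$times, x, windows[[nm]][1], windows[[nm]][2], pol)
      row[[paste0(nm, "_amp")]] <- if (is.null(pk)) NA_real_ else unname(pk["amp"])
      row[[paste0(nm, "_lat")]] <- if (is.null(pk)) NA_real_ else unname(pk["lat"])
    }
    row$N1P1 <- row$P1_amp - row$N1_amp
    row$N1P2 <- row$P2_amp - row$N1_amp
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("component_table", "data.frame")
  out
}

#' Morlet wavelet spectrogram of event-related oscillations
#'
#' Complex Morlet transform (fixed number of cycles at every frequency,
#' analytic Gaussian kernel applied in the frequency domain), with power
#' averaged across the epochs of a condition. This is total power
#' (transform-then-average), i.e. evoked plus induced activity.
#'
#' @param epochs an [epoch_set()] (typically from [extract_erp_epochs()]).
#' @param condition optional condition filter; `NULL` uses all usable epochs.
#' @param freqs analysis frequencies in Hz (default 1-100, 1 Hz step); all
#'   must lie below Nyquist.
#' @param n_cycles wavelet width in cycles (default 6).
#' @return A `tf_map` object: `power` array (freqs x times x channels, µV²;
#'   a pure sinusoid of amplitude A maps to power ~A²), `times` (ms),
#'   `freqs`, `n_epochs`.
#' @export
morlet_spectrogram <- function(epochs, condition = NULL, freqs = 1:100,
                               n_cycles = 6) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (max(freqs) >= epochs$fs / 2)
    stop_param("wavelet frequencies must lie below Nyquist fs/2 = ",
               epochs$fs / 2)
  use <- usable_epochs(epochs, condition = condition)
  if (!length(use))
    stop_param("no usable epochs",
               if (!is.null(condition)) paste0(" of condition '", condition, "'") else "")
  n_sp <- dim(epochs$data)[3]
  n_ch <- dim(epochs$data)[2]
  times <- (epochs$tmin + (seq_len(n_sp) - 1L) / epochs$fs) * 1000
  nf <- next_fft_n(2L * n_sp)                 # pad against wrap-around
  fgrid <- c(0, seq_len(nf - 1)) * epochs$fs / nf
  power <- array(0, dim = c(length(freqs), n_sp, n_ch),
                 dimnames = list(freqs, NULL, epochs$labels))
  # analytic Morlet response: Gaussian of sd 1/(2*pi*sigma_t) around +f only
  masks <- lapply(freqs, function(f) {
    sigma_t <- n_cycles / (2 * pi * f)
    h <- 2 * exp(-2 * pi^2 * sigma_t^2 * (fgrid - f)^2)
    h[fgrid > epochs$fs / 2] <- 0             # negative-frequency half
    h
  })
  for (ch in seq_len(n_ch)) {
    for (e in use) {
      X <- stats::fft(c(epochs$data[e, ch, ], numeric(nf - n_sp)))
      for (k in seq_along(freqs)) {
        w <- stats::fft(X * masks[[k]], inverse = TRUE)[seq_len(n_sp)] / nf
        power[k, , ch] <- power[k, , ch] + Mod(w)^2
      }
    }
  }
  structure(
    list(power = power / length(use), times = times, freqs = freqs,
         n_epochs = length(use), condition = condition, fs = epochs$fs),
    class = "tf_map"
  )
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d freq(s) x %d time point(s) x %d channel(s), %d epoch(s)\n",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3], x$n_epochs))
  invisible(x)
}

#' Evoked band power
#'
#' Mean time-frequency power over a frequency band and time window
#' (defaults: the evoked-gamma 40-80 Hz band).
#'
#' @param tf a [morlet_spectrogram()] result.
#' @param band `c(lo, hi)` in Hz, half-open (default `c(40, 80)`).
#' @param window `c(lo, hi)` in ms, half-open.
#' @param channels optional channel subset (labels); default all.
#' @return Scalar mean power (µV²).
#' @export
evoked_band_power <- function(tf, band = c(40, 80), window, channels = NULL) {
  stopifnot(inherits(tf, "tf_map"))
  fsel <- which(tf$freqs >= band[1] & tf$freqs < band[2])
  tsel <- which(tf$times >= window[1] & tf$times < window[2])
  csel <- if (is.null(channels)) seq_len(dim(tf$power)[3]) else
    match(channels, dimnames(tf$power)[[3]])
  if (!length(fsel) || !length(tsel) || !length(csel) || anyNA(csel))
    stop_param("band/window/channel selection is empty or outside the map")
  mean(tf$power[fsel, tsel, csel])
}
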