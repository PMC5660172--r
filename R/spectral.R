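# Welch-type spectral estimation: Hann-tapered FFT over 4-s windows with 50%
# overlap, averaged across windows and epochs, native bins aggregated to the
# 1 Hz grid the band summaries and coherence spectra share.

# tapered, demeaned FFTs of all windows of one channel across usable epochs;
# returns complex matrix [n_native_bins x n_windows] for positive freqs
welch_fft_windows <- function(epochs, ch_idx, window_sec, overlap, use) {
  n_sp <- dim(epochs$data)[3]
  w <- min(round(window_sec * epochs$fs), n_sp)
  step <- max(1L, round(w * (1 - overlap)))
  taper <- hann_window(w)
  starts <- seq(1L, n_sp - w + 1L, by = step)
  kmax <- w %/% 2L
  out <- vector("list", length(use) * length(starts))
  j <- 0L
  for (e in use) {
    x <- epochs$data[e, ch_idx, ]
    for (s in starts) {
      seg <- x[s:(s + w - 1L)]
      seg <- (seg - mean(seg)) * taper
      X <- stats::fft(seg)
      j <- j + 1L
      out[[j]] <- X[2L:(kmax + 1L)]
    }
  }
  list(X = matrix(unlist(out), nrow = kmax),
       freqs = (1:kmax) * epochs$fs / w,
       scale = 2 / (epochs$fs * sum(taper^2)),   # |X|^2 -> one-sided PSD
       df = epochs$fs / w)
}

# map native-resolution values onto integer-centred 1 Hz bins [f-0.5, f+0.5)
aggregate_1hz <- function(freqs_native, values, centers, fun = sum) {
  bin <- floor(freqs_native + 0.5)
  vapply(centers, function(f) {
    idx <- which(bin == f)
    if (!length(idx)) return(NA_real_)
    fun(values[idx])
  }, numeric(1))
}

#' Relative and absolute power spectrum
#'
#' Hann-tapered FFT over `window_sec` windows with 50% overlap, averaged over
#' windows and epochs, aggregated to 1 Hz bins (native bins summed within
#' `[f - 0.5, f + 0.5)` and labelled by the centre `f`). Per channel, relative
#' power is each bin's fraction of the total over `[fmin, fmax]`.
#'
#' @param epochs an [epoch_set()]; artifact-flagged epochs are excluded.
#' @param fmin,fmax analysis range in Hz (defaults 1 and 100); `fmax` must be
#'   below the Nyquist frequency.
#' @param window_sec analysis window length in seconds (default 4); clipped
#'   to the epoch length for shorter epochs.
#' @param overlap fractional window overlap (default 0.5).
#' @param state optional vigilance-state filter (e.g. `"waking"`).
#' @return A `power_spectrum` object: `freqs` (1 Hz bin centres), `abs_power`
#'   and `rel_power` (channels x bins, µV² per bin and dimensionless),
#'   `n_epochs` used.
#' @export
power_spectrum <- function(epochs, fmin = 1, fmax = 100, window_sec = 4,
                           overlap = 0.5, state = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (fmax >= epochs$fs / 2)
    stop_param("fmax must be below the Nyquist frequency fs/2 = ", epochs$fs / 2)
  if (fmin <= 0 || fmin >= fmax)
    stop_param("need 0 < fmin < fmax")
  use <- usable_epochs(epochs, state = state)
  if (!length(use))
    stop_param("no usable (artifact-free) epochs to estimate a spectrum from")
  centers <- seq(ceiling(fmin), floor(fmax))
  n_ch <- dim(epochs$data)[2]
  abs_power <- matrix(0, n_ch, length(centers),
                      dimnames = list(epochs$labels, centers))
  for (ch in seq_len(n_ch)) {
    wf <- welch_fft_windows(epochs, ch, window_sec, overlap, use)
    psd <- rowMeans(Mod(wf$X)^2) * wf$scale
    abs_power[ch, ] <- aggregate_1hz(wf$freqs, psd * wf$df, centers)
  }
  rel_power <- abs_power / rowSums(abs_power)
  structure(
    list(freqs = centers, abs_power = abs_power, rel_power = rel_power,
         n_epochs = length(use), fs = epochs$fs, window_sec = window_sec),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d channel(s), %d-%d Hz (1 Hz bins), %d epoch(s)\n",
              nrow(x$abs_power), min(x$freqs), max(x$freqs), x$n_epochs))
  invisible(x)
}

#' @export
as.data.frame.power_spectrum <- function(x, ...) {
  data.frame(
    channel = rep(rownames(x$abs_power), times = length(x$freqs)),
    freq = rep(x$freqs, each = nrow(x$abs_power)),
    abs_power = as.vector(x$abs_power),
    rel_power = as.vector(x$rel_power),
    stringsAsFactors = FALSE
  )
}

#' Band-summed relative power
#'
#' Sums relative power over the bins whose centres fall in the half-open
#' interval `[lo, hi)` of each named band.
#'
#' @param spec a [power_spectrum()].
#' @param bands named list of `c(lo, hi)` intervals in Hz. Defaults are the
#'   conventional rodent delta (1-4), theta (4-12) and gamma (25-100) bands.
#' @return A channels x bands matrix of class `band_power_table`.
#' @export
band_power <- function(spec, bands = list(delta = c(1, 4), theta = c(4, 12),
                                          gamma = c(25, 100))) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (is.null(names(bands)) || any(names(bands) == ""))
    stop_param("bands must be a named list of c(lo, hi) intervals")
  out <- matrix(0, nrow(spec$rel_power), length(bands),
                dimnames = list(rownames(spec$rel_power), names(bands)))
  for (b in seq_along(bands)) {
    iv <- bands[[b]]
    if (length(iv) != 2 || !(iv[1] < iv[2]))
      stop_param("band '", names(bands)[b], "' must be c(lo, hi) with lo < hi")
    if (iv[1] < min(spec$freqs) - 0.5 || iv[2] > max(spec$freqs) + 1)
      stop_param("band '", names(bands)[b], "' [", iv[1], ", ", iv[2],
                 ") lies outside the spectrum range")
    sel <- spec$freqs >= iv[1] & spec$freqs < iv[2]
    if (!any(sel))
      stop_param("band '", names(bands)[b], "' selects no frequency bins")
    out[, b] <- rowSums(spec$rel_power[, sel, drop = FALSE])
  }
  class(out) <- c("band_power_table", class(out))
  out
}

#' Longitudinal session-power ratios
#'
#' Per session, channel and frequency bin: the ratio of absolute spectral
#' power to the corresponding power in the first (reference) session.
#' The first session's ratios are identically 1. Reference bins with zero
#' power yield `NA` (flagged, not silent infinities).
#'
#' @param sessions ordered list of [power_spectrum()] objects on identical
#'   bin grids and channel sets.
#' @return A `longitudinal_ratio` object with array `ratio`
#'   (sessions x channels x bins) and the count of undefined cells.
#' @export
longitudinal_ratio <- function(sessions) {
  if (!is.list(sessions) || length(sessions) < 2)
    stop_param("need an ordered list of at least 2 power spectra")
  ref <- sessions[[1]]
  for (s in sessions) {
    stopifnot(inherits(s, "power_spectrum"))
    if (!identical(s$freqs, ref$freqs) ||
        !identical(rownames(s$abs_power), rownames(ref$abs_power)))
      stop_param("all sessions must share the same frequency grid and channels")
  }
  n_s <- length(sessions)
  ratio <- array(NA_real_, dim = c(n_s, nrow(ref$abs_power), length(ref$freqs)),
                 dimnames = list(paste0("session", seq_len(n_s)),
                                 rownames(ref$abs_power), ref$freqs))
  zero_ref <- ref$abs_power == 0
  for (i in seq_len(n_s)) {
    r <- sessions[[i]]$abs_power / ref$abs_power
    r[zero_ref] <- NA_real_
    ratio[i, , ] <- r
  }
  structure(
    list(ratio = ratio, freqs = ref$freqs, labels = rownames(ref$abs_power),
         n_undefined = sum(zero_ref) * n_s),
    class = "longitudinal_ratio"
  )
}

#' @export
as.data.frame.longitudinal_ratio <- function(x, ...) {
  d <- dim(x$ratio)
  data.frame(
    session = rep(dimnames(x$ratio)[[1]], times = d[2] * d[3]),
    channel = rep(rep(x$labels, each = d[1]), times = d[3]),
    freq = rep(x$freqs, each = d[1] * d[2]),
    ratio = as.vector(x$ratio),
    stringsAsFactors = FALSE
  )
}

#' @export
print.band_power_table <- function(x, digits = 3, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}
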