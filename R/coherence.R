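# Magnitude-squared coherence between electrode sites:
# Coh(f) = |S_AB(f)|^2 / (S_AA(f) S_BB(f)), with the cross- and auto-spectra
# averaged over Hann-tapered windows *before* the quotient (the coherence of
# a single window is identically 1). No small-sample bias correction is
# applied: with M independent windows the expected coherence of unrelated
# signals is ~1/M, which is documented and covered by tests.

#' Magnitude-squared coherence spectrum
#'
#' Welch estimator of the magnitude-squared coherence between two channels:
#' auto- and cross-spectral densities are averaged over Hann-tapered
#' `window_sec` windows (50% overlap) across all usable epochs; the quotient
#' `|S_AB|^2 / (S_AA S_BB)` is formed at native frequency resolution and then
#' averaged into 1 Hz bins.
#'
#' @param epochs an [epoch_set()]; artifact-flagged epochs are excluded.
#' @param pair character vector of two channel labels `c(A, B)`.
#' @param fmin,fmax frequency range in Hz (defaults 1 and 100).
#' @param window_sec window length in seconds (default 4).
#' @param overlap fractional window overlap (default 0.5).
#' @param state optional vigilance-state filter.
#' @return A `coherence_spectrum` object: `pair`, `freqs` (1 Hz centres),
#'   `coh` in `[0, 1]` per bin, and `n_segments`, the number of windows
#'   averaged.
#' @export
msc_coherence <- function(epochs, pair, fmin = 1, fmax = 100,
                          window_sec = 4, overlap = 0.5, state = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(pair) != 2)
    stop_param("`pair` must name exactly two channels")
  for (p in pair)
    if (!p %in% epochs$labels)
      stop_param("unknown channel label '", p, "'; epochs have: ",
                 paste(epochs$labels, collapse = ", "))
  if (fmax >= epochs$fs / 2)
    stop_param("fmax must be below the Nyquist frequency")
  use <- usable_epochs(epochs, state = state)
  ia <- match(pair[1], epochs$labels)
  ib <- match(pair[2], epochs$labels)
  wa <- welch_fft_windows(epochs, ia, window_sec, overlap, use)
  wb <- welch_fft_windows(epochs, ib, window_sec, overlap, use)
  m <- ncol(wa$X)
  if (m < 2)
    stop_param("coherence needs at least 2 windows (got ", m,
               "); it is identically 1 from a single segment")
  saa <- rowMeans(Mod(wa$X)^2)
  sbb <- rowMeans(Mod(wb$X)^2)
  sab <- rowMeans(wa$X * Conj(wb$X))
  coh_native <- Mod(sab)^2 / (saa * sbb)
  centers <- seq(ceiling(fmin), floor(fmax))
  coh <- aggregate_1hz(wa$freqs, coh_native, centers, fun = mean)
  structure(
    list(pair = pair, freqs = centers, coh = coh, n_segments = m),
    class = "coherence_spectrum"
  )
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %s - %s, %d-%d Hz, %d segment(s)\n",
              x$pair[1], x$pair[2], min(x$freqs), max(x$freqs), x$n_segments))
  invisible(x)
}

#' @export
as.data.frame.coherence_spectrum <- function(x, ...) {
  data.frame(pair = paste(x$pair, collapse = "-"), freq = x$freqs,
             coherence = x$coh, stringsAsFactors = FALSE)
}

#' Band-averaged coherence
#'
#' Arithmetic mean of the coherence over bins whose centres lie in the
#' half-open band `[lo, hi)`.
#'
#' @param cs a [msc_coherence()] result.
#' @param band `c(lo, hi)` in Hz; default is the theta band `c(4, 12)`.
#' @return A scalar coherence value.
#' @export
band_coherence <- function(cs, band = c(4, 12)) {
  stopifnot(inherits(cs, "coherence_spectrum"))
  if (length(band) != 2 || !(band[1] < band[2]))
    stop_param("band must be c(lo, hi) with lo < hi")
  sel <- cs$freqs >= band[1] & cs$freqs < band[2]
  if (!any(sel))
    stop_param("band [", band[1], ", ", band[2],
               ") selects no bins of the coherence spectrum")
  mean(cs$coh[sel])
}

#' Two-group comparison of per-animal scalars
#'
#' Two-sided independent-samples Student t-test with pooled variance, plus
#' the confidence interval of the mean difference at level `1 - alpha`.
#'
#' @param values_a,values_b per-animal scalar summaries (e.g. theta band
#'   coherence) for the two groups; each group needs `n >= 2`.
#' @param alpha significance level (default 0.05).
#' @return A list with `t`, `df`, `p`, `ci` (length-2), `mean_diff`, and
#'   per-group `n`.
#' @export
group_compare <- function(values_a, values_b, alpha = 0.05) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_param("each group needs at least 2 finite values")
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE,
                      conf.level = 1 - alpha)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = unname(tt$conf.int),
       mean_diff = mean(values_a) - mean(values_b),
       n = c(a = length(values_a), b = length(values_b)))
}
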