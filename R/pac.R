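# Theta-gamma phase-amplitude cross-frequency coupling.
#
# The modulation index (MI) is the modulus of the time average of the
# composite signal z(t) = A_H(t) * exp(i * phi_L(t)), where A_H is the
# analytic amplitude of the narrow-band signal around the "amplitude"
# frequency f_H and phi_L the analytic phase around the "phase" frequency
# f_L. MI carries the units of A_H (µV) and vanishes when amplitude and
# phase are unrelated. Comodulograms evaluate MI on the grid
# f_L in {2,4,...,12} Hz x f_H in {10,15,...,200} Hz; significance is
# assessed against circular-shift surrogates (z-score plus Rayleigh-tail
# surrogate p-value), Bonferroni-corrected over the grid.

#' Narrow-band analytic decomposition
#'
#' Zero-phase FIR band-pass around `f_center` followed by the analytic-signal
#' (Hilbert) construction. The returned envelope and phase are valid away
#' from the edges: one filter length at each end is marked for exclusion.
#'
#' @param rec an [recording()].
#' @param channel channel label.
#' @param f_center band centre frequency, Hz.
#' @param bandwidth full bandwidth, Hz; the pass band is
#'   `f_center +/- bandwidth/2` (clipped above 0 at the low end).
#' @return An `analytic_band` object: `amplitude` (µV envelope), `phase`
#'   (radians in (-pi, pi]), `valid` (index range free of edge effects),
#'   `edge` (excluded samples per side), `f_center`, `bandwidth`, `fs`.
#' @export
analytic_decompose <- function(rec, channel, f_center, bandwidth) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- channel_data(rec, channel)
  ab <- analytic_band_vec(x, rec$fs, f_center, bandwidth)
  structure(
    c(ab, list(f_center = f_center, bandwidth = bandwidth, fs = rec$fs)),
    class = "analytic_band"
  )
}

#' @export
print.analytic_band <- function(x, ...) {
  cat(sprintf("<analytic_band> %g Hz +/- %g Hz, %d samples (%d per edge excluded)\n",
              x$f_center, x$bandwidth / 2, length(x$amplitude), x$edge))
  invisible(x)
}

# vector-level decomposition shared with the comodulogram grid; `tw` is the
# FIR transition width (amplitude bands use bandwidth/4 so that modulation
# side-bands near the band edges pass at full gain)
analytic_band_vec <- function(x, fs, f_center, bandwidth, tw = bandwidth / 2) {
  lo <- f_center - bandwidth / 2
  hi <- f_center + bandwidth / 2
  if (hi >= fs / 2)
    stop_param("band [", lo, ", ", hi, "] Hz exceeds the Nyquist frequency ",
               fs / 2, " Hz")
  if (f_center <= 0 || bandwidth <= 0)
    stop_param("f_center and bandwidth must be positive")
  lo <- max(lo, 0.05)
  f <- fir_bandpass_vec(x, fs, lo, hi, tw = tw)
  a <- analytic_signal(f$y)
  edge <- f$ntaps
  n <- length(x)
  valid <- if (2L * edge + 2L >= n) integer(0) else (edge + 1L):(n - edge)
  list(amplitude = Mod(a), phase = Arg(a), valid = valid, edge = edge)
}

#' Modulation index
#'
#' `MI = | mean( A_H(t) * exp(i * phi_L(t)) ) |`, the modulus of the
#' time-averaged composite signal. Zero (up to estimation noise) when the
#' amplitude envelope is unrelated to the phase; for a sinusoidally
#' modulated envelope `A = A0 * (1 + kappa * cos(phi))` over whole cycles,
#' `MI = kappa * A0 / 2`.
#'
#' @param phase phase series, radians.
#' @param amp amplitude series, same length (µV).
#' @return Scalar MI (µV), non-negative.
#' @export
modulation_index <- function(phase, amp) {
  if (length(phase) != length(amp))
    stop_param("phase and amplitude series must have equal length (",
               length(phase), " vs ", length(amp), ")")
  if (!length(phase))
    stop_param("empty series")
  Mod(mean(amp * exp(1i * phase)))
}

# largest 5-smooth integer <= n, so circular FFTs stay fast
prev_fft_n <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m - 1L
  }
}

# shared engine: band series, MI grid, optionally surrogate z/sig
pac_engine <- function(x, fs, phase_freqs, amp_freqs, phase_bandwidth,
                       amp_bandwidth, n_surrogates = 0L, alpha = 0.05,
                       min_shift = 1, seed = NULL) {
  np <- length(phase_freqs)
  na <- length(amp_freqs)
  if (max(amp_freqs) + amp_bandwidth / 2 >= fs / 2)
    stop_param("amplitude grid up to ", max(amp_freqs), " Hz (+",
               amp_bandwidth / 2, " Hz bandwidth) exceeds Nyquist at fs = ", fs)
  ph <- vector("list", np)
  am <- vector("list", na)
  edge <- 0L
  for (i in seq_len(np)) {
    b <- analytic_band_vec(x, fs, phase_freqs[i], phase_bandwidth)
    ph[[i]] <- b$phase
    edge <- max(edge, b$edge)
  }
  for (j in seq_len(na)) {
    b <- analytic_band_vec(x, fs, amp_freqs[j], amp_bandwidth,
                           tw = amp_bandwidth / 4)
    am[[j]] <- b$amplitude
    edge <- max(edge, b$edge)
  }
  n <- length(x)
  if (2L * edge + round(fs) >= n)
    stop_param("segment too short for the filter edge exclusion (",
               edge, " samples per side at n = ", n, ")")
  nv <- prev_fft_n(n - 2L * edge)
  valid <- (edge + 1L):(edge + nv)

  mi <- matrix(0, np, na, dimnames = list(phase_freqs, amp_freqs))
  z <- sig <- NULL
  if (n_surrogates > 0L) {
    if (!is.null(seed)) set.seed(seed)
    max_lag <- nv - round(min_shift * fs)
    min_lag <- round(min_shift * fs)
    if (max_lag <= min_lag)
      stop_param("segment too short for circular shifts of >= ", min_shift, " s")
    lag_pool <- seq.int(min_lag, max_lag)
    lags <- sample(lag_pool, n_surrogates,
                   replace = length(lag_pool) < n_surrogates)
    z <- p_surr <- matrix(NA_real_, np, na, dimnames = dimnames(mi))
    sig <- matrix(FALSE, np, na, dimnames = dimnames(mi))
    crit <- stats::qnorm(1 - alpha / (np * na))
    FE <- lapply(ph, function(p) stats::fft(exp(1i * p[valid])))
    for (j in seq_len(na)) {
      A <- am[[j]][valid]
      FA <- stats::fft(A)
      for (i in seq_len(np)) {
        # circular cross-correlation via FFT: entry k is
        # | sum_t A(t+k) e^{i phi(t)} | / nv, i.e. the MI after a shift of k
        cc <- Mod(stats::fft(FA * Conj(FE[[i]]), inverse = TRUE)) / as.numeric(nv)^2
        mi[i, j] <- cc[1L]
        s <- cc[lags + 1L]
        sds <- stats::sd(s)
        if (is.finite(sds) && sds > 0) {
          z[i, j] <- (mi[i, j] - mean(s)) / sds
          # the null MI is the modulus of a complex mean, i.e. Rayleigh;
          # its scale is estimated from the surrogates and the cell must
          # clear the Bonferroni level under that Rayleigh tail as well as
          # the z criterion (the Gaussian threshold alone is
          # anticonservative for a Rayleigh-tailed statistic). The tail is
          # compounded over the Gamma sampling noise of the scale estimate:
          # with m surrogates, P(T > t) = (1 + t/m)^(-m) instead of e^(-t).
          sigma2 <- mean(s^2) / 2
          tstat <- mi[i, j]^2 / (2 * sigma2)
          m <- length(s)
          p_surr[i, j] <- (1 + tstat / m)^(-m)
          sig[i, j] <- z[i, j] > crit && p_surr[i, j] <= alpha / (np * na)
        }
      }
    }
  } else {
    for (j in seq_len(na)) {
      A <- am[[j]][valid]
      for (i in seq_len(np))
        mi[i, j] <- modulation_index(ph[[i]][valid], A)
    }
    p_surr <- NULL
  }
  list(mi = mi, z = z, sig = sig, p_surr = p_surr)
}

#' Phase-amplitude comodulogram
#'
#' Modulation index over the default grid of 6 phase frequencies
#' (2-12 Hz, step 2) by 39 amplitude frequencies (10-200 Hz, step 5),
#' computed on one channel over a segment of the recording. Phase bands are
#' 2 Hz wide; amplitude bands are `max(10, 2 * max(phase_freqs))` Hz wide so
#' that modulation side-bands are admitted.
#'
#' @param rec an [recording()].
#' @param channel channel label.
#' @param segment `c(start, end)` in seconds. `NULL` (default) selects
#'   minutes 15-60 of the recording when it is long enough, otherwise the
#'   whole recording.
#' @param phase_freqs,amp_freqs grid of phase and amplitude frequencies, Hz.
#' @param phase_bandwidth phase band full width, Hz (default 2).
#' @param amp_bandwidth amplitude band full width, Hz; default
#'   `max(10, 2 * max(phase_freqs))`.
#' @param n_surrogates if > 0, surrogate z-scores and the significance mask
#'   are filled in directly (equivalent to following with
#'   [surrogate_significance()]).
#' @param alpha significance level for the Bonferroni-corrected surrogate
#'   test (default 0.05).
#' @param seed optional RNG seed for the surrogate shifts.
#' @return A `comodulogram` object: `mi` (phase x amplitude matrix, µV),
#'   `z`, `sig`, `n_surrogates`, grid and band parameters.
#' @export
comodulogram <- function(rec, channel, segment = NULL,
                         phase_freqs = seq(2, 12, by = 2),
                         amp_freqs = seq(10, 200, by = 5),
                         phase_bandwidth = 2, amp_bandwidth = NULL,
                         n_surrogates = 0, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- channel_data(rec, channel)
  dur <- duration(rec)
  if (is.null(segment))
    segment <- if (dur >= 3600) c(900, 3600) else c(0, dur)
  if (segment[1] < 0 || segment[2] > dur + 1e-9 || segment[1] >= segment[2])
    stop_param("segment [", segment[1], ", ", segment[2],
               "] s must lie within the recording (0-", dur, " s)")
  if ((segment[2] - segment[1]) * min(phase_freqs) < 5)
    stop_param("segment shorter than 5 cycles of the slowest phase frequency (",
               min(phase_freqs), " Hz)")
  i0 <- floor(segment[1] * rec$fs) + 1L
  i1 <- min(length(x), floor(segment[2] * rec$fs))
  xs <- x[i0:i1]
  if (is.null(amp_bandwidth)) amp_bandwidth <- max(10, 2 * max(phase_freqs))
  eng <- pac_engine(xs, rec$fs, phase_freqs, amp_freqs, phase_bandwidth,
                    amp_bandwidth, n_surrogates = n_surrogates, alpha = alpha,
                    seed = seed)
  structure(
    list(phase_freqs = phase_freqs, amp_freqs = amp_freqs,
         mi = eng$mi, z = eng$z, sig = eng$sig, p_surr = eng$p_surr,
         n_surrogates = as.integer(n_surrogates), alpha = alpha,
         channel = channel, segment = segment,
         phase_bandwidth = phase_bandwidth, amp_bandwidth = amp_bandwidth),
    class = "comodulogram"
  )
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %s, %d x %d grid (phase %g-%g Hz, amplitude %g-%g Hz)\n",
              x$channel, length(x$phase_freqs), length(x$amp_freqs),
              min(x$phase_freqs), max(x$phase_freqs),
              min(x$amp_freqs), max(x$amp_freqs)))
  am <- arrayInd(which.max(x$mi), dim(x$mi))
  cat(sprintf("  max MI %.4g at (%g, %g) Hz; surrogates: %d%s\n",
              max(x$mi), x$phase_freqs[am[1]], x$amp_freqs[am[2]],
              x$n_surrogates,
              if (!is.null(x$sig)) sprintf("; significant cells: %d", sum(x$sig, na.rm = TRUE))
              else ""))
  invisible(x)
}

#' @export
as.data.frame.comodulogram <- function(x, ...) {
  d <- data.frame(
    f_phase = rep(x$phase_freqs, times = length(x$amp_freqs)),
    f_amp = rep(x$amp_freqs, each = length(x$phase_freqs)),
    mi = as.vector(x$mi), stringsAsFactors = FALSE)
  d$z <- if (is.null(x$z)) NA_real_ else as.vector(x$z)
  d$p_surr <- if (is.null(x$p_surr)) NA_real_ else as.vector(x$p_surr)
  d$sig <- if (is.null(x$sig)) NA else as.vector(x$sig)
  d
}

#' Surrogate-based significance of a comodulogram
#'
#' Builds `n_surrogates` surrogate modulation indices per grid cell by
#' circularly time-shifting the amplitude series against the phase series by
#' random offsets of at least `min_shift` seconds (this preserves both
#' spectra while destroying their temporal alignment), then z-scores the
#' observed MI against the surrogate distribution. A cell is significant
#' when (i) its z exceeds the one-sided normal critical value at
#' `alpha / (number of grid cells)` (Bonferroni) and (ii) its Rayleigh-tail
#' surrogate p-value `exp(-MI^2 / (2 * sigma^2))`, with the Rayleigh scale
#' `sigma^2 = mean(surrogate MI^2) / 2` estimated from the surrogates,
#' clears the same Bonferroni level. The null MI is the modulus of a
#' complex-valued time average and is therefore Rayleigh- rather than
#' normal-tailed; the additional Rayleigh condition keeps the family-wise
#' false-positive rate at the nominal level. The Rayleigh tail is
#' compounded over the sampling noise of the scale estimate (with `m`
#' surrogates, `P(T > t) = (1 + t/m)^(-m)`). Cells whose surrogate spread
#' is zero are marked undefined and never significant.
#'
#' @param com a [comodulogram()].
#' @param rec,channel the same recording and channel the comodulogram was
#'   computed from.
#' @param n_surrogates number of surrogates (default 50).
#' @param alpha significance level (default 0.05).
#' @param min_shift minimum circular shift, seconds (default 1).
#' @param seed optional RNG seed for the shifts.
#' @return The comodulogram with `z`, `sig` and `n_surrogates` filled in.
#' @export
surrogate_significance <- function(com, rec, channel, n_surrogates = 50,
                                   alpha = 0.05, min_shift = 1, seed = NULL) {
  stopifnot(inherits(com, "comodulogram"), inherits(rec, "eeg_recording"))
  if (n_surrogates < 2)
    stop_param("need at least 2 surrogates")
  x <- channel_data(rec, channel)
  i0 <- floor(com$segment[1] * rec$fs) + 1L
  i1 <- min(length(x), floor(com$segment[2] * rec$fs))
  eng <- pac_engine(x[i0:i1], rec$fs, com$phase_freqs, com$amp_freqs,
                    com$phase_bandwidth, com$amp_bandwidth,
                    n_surrogates = n_surrogates, alpha = alpha,
                    min_shift = min_shift, seed = seed)
  com$mi <- eng$mi
  com$z <- eng$z
  com$sig <- eng$sig
  com$p_surr <- eng$p_surr
  com$n_surrogates <- as.integer(n_surrogates)
  com$alpha <- alpha
  com
}
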