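# Synthetic-data generator. Emulates the study's recordings so that every
# analysis stage can be checked against known ground truth: 1/f background,
# band-limited oscillators, shared sources controlling inter-channel
# coherence, theta-phase-modulated gamma carriers with tunable coupling
# strength kappa, passive-oddball sessions with embedded ERP templates and
# evoked gamma bursts, two-group (buffer vs K18-seeded) effect profiles, and
# DAB-stained micrographs with an exact positive-area fraction.

#' Simulation specification
#'
#' Full parameterization of one simulated animal's recording. Defaults model
#' a control ("buffer") animal of the six-electrode montage: pink background
#' (50 µV RMS), a per-channel independent theta oscillator (8 Hz, 10 µV RMS),
#' one theta-band source (8 Hz, 20 µV RMS) shared by all channels - which
#' yields a theta coherence of about 0.55 between any pair - and
#' theta-gamma coupling (f_L = 8 Hz, f_H = 70 Hz, kappa = 0.8, 10 µV
#' carrier) on both hippocampal CA1 channels.
#'
#' @param seed integer RNG seed; the same spec and seed give bit-identical
#'   output.
#' @param fs sampling rate, Hz (default 2000).
#' @param duration recording length, seconds (default 60).
#' @param channels named list: per channel, a list with element `oscillators`
#'   (list of `list(center, bandwidth, rms)` in Hz/Hz/µV).
#' @param background `list(exponent, rms)` of the 1/f^exponent noise floor.
#' @param sources list of shared sources `list(center, bandwidth, rms)`;
#'   `center = NULL` gives a spectrally white source.
#' @param mixing channels x sources weight matrix (rows follow `channels`).
#' @param pac named list: per channel, `list(f_L, f_H, kappa, carrier_amp)`;
#'   the carrier at `f_H` has envelope `carrier_amp * (1 + kappa *
#'   cos(phi_L))` where `phi_L` is the phase of that channel's f_L-band
#'   oscillation (own oscillator plus shared-source contributions at f_L).
#' @param group_effect multiplicative effect profile
#'   `list(theta, source, kappa, erp, gamma)`; all 1 for the control
#'   condition. `theta` scales oscillator RMS for oscillators centred in
#'   4-12 Hz, `source` scales mixing weights, `kappa` the coupling
#'   strength, `erp` and `gamma` the oddball template and evoked burst.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(seed = 1, fs = 2000, duration = 60,
                     channels = NULL, background = list(exponent = 1, rms = 50),
                     sources = NULL, mixing = NULL, pac = NULL,
                     group_effect = list(theta = 1, source = 1, kappa = 1,
                                         erp = 1, gamma = 1)) {
  if (is.null(channels)) {
    labs <- c("PFC_L", "PFC_R", "CA1_L", "CA1_R", "CA3_L", "CA3_R")
    channels <- stats::setNames(lapply(labs, function(l)
      list(oscillators = list(list(center = 8, bandwidth = 2, rms = 10)))),
      labs)
  }
  if (is.null(sources))
    sources <- list(list(center = 8, bandwidth = 2, rms = 20))
  if (is.null(mixing))
    mixing <- matrix(1, nrow = length(channels), ncol = length(sources),
                     dimnames = list(names(channels), NULL))
  if (is.null(pac)) {
    pac <- list()
    for (l in intersect(c("CA1_L", "CA1_R"), names(channels)))
      pac[[l]] <- list(f_L = 8, f_H = 70, kappa = 0.8, carrier_amp = 10)
  }
  ge <- utils::modifyList(list(theta = 1, source = 1, kappa = 1, erp = 1,
                               gamma = 1), group_effect)
  spec <- structure(
    list(seed = as.integer(seed), fs = fs, duration = duration,
         channels = channels, background = background, sources = sources,
         mixing = mixing, pac = pac, group_effect = ge),
    class = "sim_spec"
  )
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  if (spec$fs <= 0 || spec$duration <= 0)
    stop_param("fs and duration must be positive")
  if (spec$background$rms < 0)
    stop_param("background rms must be >= 0")
  for (ch in spec$channels)
    for (o in ch$oscillators)
      if (o$rms < 0) stop_param("oscillator rms must be >= 0")
  for (s in spec$sources)
    if (s$rms < 0) stop_param("source rms must be >= 0")
  if (!all(is.finite(spec$mixing)))
    stop_param("mixing weights must be finite")
  if (nrow(spec$mixing) != length(spec$channels) ||
      ncol(spec$mixing) != length(spec$sources))
    stop_param("mixing must be a channels x sources matrix")
  for (p in spec$pac) {
    if (p$kappa < 0 || p$kappa > 1)
      stop_param("coupling strength kappa must lie in [0, 1]")
    if (p$carrier_amp < 0) stop_param("carrier amplitude must be >= 0")
  }
  invisible(spec)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> seed %d, %d channel(s), %g s @ %g Hz, %d source(s), PAC on: %s\n",
              x$seed, length(x$channels), x$duration, x$fs, length(x$sources),
              if (length(x$pac)) paste(names(x$pac), collapse = ", ") else "none"))
  invisible(x)
}

#' Simulate a multichannel recording
#'
#' Per channel: pink background + band-limited oscillators + weighted shared
#' sources + (where configured) a theta-phase-modulated gamma carrier. The
#' group-effect profile of the spec is applied multiplicatively. Output is
#' reproducible from `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return An [recording()].
#' @export
simulate_recording <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  validate_sim_spec(spec)
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  fs <- spec$fs
  ge <- spec$group_effect
  t <- (0:(n - 1)) / fs
  src <- lapply(spec$sources, function(s) {
    if (is.null(s$center)) rms_scale(stats::rnorm(n), s$rms)
    else narrowband_noise(n, fs, s$center, s$bandwidth, s$rms)
  })
  labs <- names(spec$channels)
  data <- matrix(0, length(labs), n, dimnames = list(labs, NULL))
  for (i in seq_along(labs)) {
    ch <- spec$channels[[i]]
    x <- pink_noise(n, fs, spec$background$exponent, spec$background$rms)
    p <- spec$pac[[labs[i]]]
    fl_component <- numeric(n)
    for (o in ch$oscillators) {
      rms <- o$rms * if (o$center >= 4 && o$center < 12) ge$theta else 1
      osc <- narrowband_noise(n, fs, o$center, o$bandwidth, rms)
      x <- x + osc
      if (!is.null(p) && isTRUE(all.equal(o$center, p$f_L)))
        fl_component <- fl_component + osc
    }
    for (j in seq_along(src)) {
      w <- spec$mixing[i, j] * ge$source
      x <- x + w * src[[j]]
      s <- spec$sources[[j]]
      if (!is.null(p) && !is.null(s$center) &&
          isTRUE(all.equal(s$center, p$f_L)))
        fl_component <- fl_component + w * src[[j]]
    }
    if (!is.null(p) && p$carrier_amp > 0) {
      phi <- Arg(analytic_signal(fl_component))
      kappa <- p$kappa * ge$kappa
      psi0 <- stats::runif(1, -pi, pi)
      x <- x + p$carrier_amp * (1 + kappa * cos(phi)) *
        cos(2 * pi * p$f_H * t + psi0)
    }
    data[i, ] <- x
  }
  recording(data, fs = fs, labels = labs)
}

#' Simulate a single-channel phase-amplitude-coupled signal
#'
#' Closed-form test signal
#' `x(t) = theta_amp * cos(w_L t + phi0) + carrier_amp * (1 + kappa *
#' cos(w_L t + phi0)) * cos(w_H t + psi0) + noise`; the modulation index at
#' the (f_L, f_H) grid cell approaches `kappa * carrier_amp / 2`.
#'
#' @param f_L,f_H phase and amplitude frequency, Hz (`f_L < f_H < fs/2`).
#' @param kappa coupling strength in `[0, 1]`.
#' @param duration length in seconds.
#' @param fs sampling rate, Hz (default 2000).
#' @param noise_rms white-noise RMS in µV (default 0).
#' @param seed optional RNG seed (drives noise and the random initial phases).
#' @param carrier_amp carrier amplitude A0 in µV (default 1).
#' @param theta_amp slow-oscillation amplitude in µV (default 1).
#' @return A single-channel [recording()] labelled `"PAC"`.
#' @export
simulate_pac_signal <- function(f_L, f_H, kappa, duration, fs = 2000,
                                noise_rms = 0, seed = NULL,
                                carrier_amp = 1, theta_amp = 1) {
  if (!(f_L > 0 && f_L < f_H && f_H < fs / 2))
    stop_param("need 0 < f_L < f_H < fs/2")
  if (kappa < 0 || kappa > 1) stop_param("kappa must lie in [0, 1]")
  if (noise_rms < 0 || carrier_amp < 0) stop_param("amplitudes must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  phi0 <- stats::runif(1, -pi, pi)
  psi0 <- stats::runif(1, -pi, pi)
  x <- theta_amp * cos(2 * pi * f_L * t + phi0) +
    carrier_amp * (1 + kappa * cos(2 * pi * f_L * t + phi0)) *
      cos(2 * pi * f_H * t + psi0)
  if (noise_rms > 0) x <- x + noise_rms * stats::rnorm(n)
  recording(matrix(x, nrow = 1), fs = fs, labels = "PAC")
}

#' Oddball session specification
#'
#' Parameters of the passive-oddball stimulus train and its embedded
#' responses: 240 standard tones and, at a 20% deviant probability, 60
#' deviants, with a 4 s inter-stimulus interval. Each stimulus adds a
#' condition-specific ERP template (sum of Gaussian components) and a
#' Gaussian-windowed evoked gamma burst to the ongoing EEG.
#'
#' @param n_standard number of standard tones (default 240).
#' @param p_deviant deviant probability (default 0.2).
#' @param isi inter-stimulus interval, seconds (default 4; must exceed the
#'   0.5 s analysis window).
#' @param tone_duration tone length, seconds (default 0.02; bookkeeping only).
#' @param t0 onset of the first stimulus, seconds (default `isi`).
#' @param templates per-condition ERP templates: `list(standard, deviant)`,
#'   each `list(amp, lat, width)` (µV, ms, ms) of the P1/N1/P2/N2 Gaussian
#'   components. The default deviant differs by a larger N1 (the
#'   mismatch-negativity-like response).
#' @param gamma evoked-burst parameters `list(freq, center_ms, sd_ms, amp)`
#'   with per-condition amplitudes (µV); default 60 Hz burst around 100 ms,
#'   deviant 1.5x standard.
#' @return An `oddball_spec` object.
#' @export
oddball_spec <- function(n_standard = 240, p_deviant = 0.2, isi = 4,
                         tone_duration = 0.02, t0 = isi,
                         templates = NULL, gamma = NULL) {
  if (p_deviant <= 0 || p_deviant >= 1)
    stop_param("p_deviant must lie strictly between 0 and 1")
  if (isi <= 0.5)
    stop_param("isi must exceed the 0.5 s epoch window")
  if (is.null(templates)) {
    base <- list(amp = c(P1 = 30, N1 = -55, P2 = 35, N2 = -15),
                 lat = c(20, 40, 80, 150), width = c(6, 8, 15, 25))
    dev <- base
    dev$amp["N1"] <- -75
    templates <- list(standard = base, deviant = dev)
  }
  if (is.null(gamma))
    gamma <- list(freq = 60, center_ms = 100, sd_ms = 25,
                  amp = c(standard = 10, deviant = 15))
  structure(
    list(n_standard = n_standard, p_deviant = p_deviant, isi = isi,
         tone_duration = tone_duration, t0 = t0, templates = templates,
         gamma = gamma),
    class = "oddball_spec"
  )
}

# ERP template: sum of Gaussian bumps, evaluated at times t_ms after onset
erp_template_waveform <- function(t_ms, tpl) {
  y <- numeric(length(t_ms))
  for (k in seq_along(tpl$amp))
    y <- y + tpl$amp[k] * exp(-0.5 * ((t_ms - tpl$lat[k]) / tpl$width[k])^2)
  y
}

# deviant placement with no two consecutive deviants, uniform over the valid
# arrangements: each of the n_standard + 1 gaps between standards holds at
# most one deviant
oddball_codes <- function(n_standard, n_deviant) {
  if (n_deviant > n_standard + 1)
    stop_param("cannot place ", n_deviant,
               " deviants without adjacency among ", n_standard, " standards")
  gaps <- sort(sample.int(n_standard + 1L, n_deviant))
  codes <- character(0)
  for (g in seq_len(n_standard + 1L)) {
    if (g %in% gaps) codes <- c(codes, "deviant")
    if (g <= n_standard) codes <- c(codes, "standard")
  }
  codes
}

#' Simulate a passive-oddball session
#'
#' Generates the stimulus train (total events =
#' `round(n_standard / (1 - p_deviant))`, deviants at exactly the deviant
#' proportion, seeded-random placement with no two consecutive deviants,
#' onsets spaced by `isi`) and an ongoing EEG recording from `base` long
#' enough to cover it, then adds the condition-specific ERP template and
#' evoked gamma burst to every channel at each onset. The base spec's
#' `group_effect$erp` and `group_effect$gamma` scale the injected template
#' and burst.
#'
#' @param ospec an [oddball_spec()].
#' @param base a [sim_spec()]; its `duration` is overridden to cover the
#'   session and its `seed` makes the session reproducible.
#' @return `list(recording, events, n_deviant, n_standard)`.
#' @export
simulate_oddball_session <- function(ospec, base = sim_spec()) {
  stopifnot(inherits(ospec, "oddball_spec"), inherits(base, "sim_spec"))
  n_total_exact <- ospec$n_standard / (1 - ospec$p_deviant)
  n_total <- round(n_total_exact)
  if (abs(n_total - n_total_exact) > 1e-9)
    warning("n_standard / (1 - p_deviant) = ", n_total_exact,
            " is not integral; rounding to ", n_total, " total events")
  n_dev <- n_total - ospec$n_standard
  set.seed(base$seed)
  codes <- oddball_codes(ospec$n_standard, n_dev)
  onsets <- ospec$t0 + (seq_len(n_total) - 1L) * ospec$isi
  events <- event_list(onsets, codes)
  base$duration <- ceiling(ospec$t0 + n_total * ospec$isi + 0.5)
  base$seed <- sample.int(.Machine$integer.max - 1L, 1L)
  rec <- simulate_recording(base)
  fs <- base$fs
  ge <- base$group_effect
  n_resp <- round(0.45 * fs)
  t_ms <- (0:(n_resp - 1)) / fs * 1000
  resp <- list()
  for (cond in c("standard", "deviant")) {
    wav <- ge$erp * erp_template_waveform(t_ms, ospec$templates[[cond]])
    burst <- ge$gamma * ospec$gamma$amp[[cond]] *
      exp(-0.5 * ((t_ms - ospec$gamma$center_ms) / ospec$gamma$sd_ms)^2) *
      cos(2 * pi * ospec$gamma$freq * t_ms / 1000)
    resp[[cond]] <- wav + burst
  }
  for (e in seq_len(n_total)) {
    i0 <- round(onsets[e] * fs) + 1L
    idx <- i0:(i0 + n_resp - 1L)
    rec$data[, idx] <- sweep(rec$data[, idx, drop = FALSE], 2,
                             resp[[codes[e]]], `+`)
  }
  list(recording = rec, events = events, n_deviant = n_dev,
       n_standard = ospec$n_standard)
}

#' Simulate a two-group (buffer vs K18-seeded) cohort study
#'
#' Buffer animals are drawn from `base`; K18 animals from `base` with the
#' multiplicative effect profile applied (defaults: theta oscillator RMS and
#' shared-source weights x0.7, coupling kappa x0.5, ERP template and evoked
#' gamma x0.7, emulating the seeded-tau phenotype). Per-animal seeds are
#' derived deterministically from the master seed.
#'
#' @param n_buffer,n_k18 animals per group (defaults 9 and 8; each >= 2).
#' @param base a [sim_spec()] for the control condition.
#' @param k18_effect multiplicative effect profile for the K18 group.
#' @param oddball an [oddball_spec()] to run a full oddball session per
#'   animal, or `NULL` for plain recordings only.
#' @param seed master seed.
#' @return `list(buffer = <animals>, k18 = <animals>)`; each animal is
#'   `list(id, group, seed, recording, events)` (`events` is `NULL` without
#'   an oddball session).
#' @export
simulate_group_study <- function(n_buffer = 9, n_k18 = 8, base = sim_spec(),
                                 k18_effect = list(theta = 0.7, source = 0.7,
                                                   kappa = 0.5, erp = 0.7,
                                                   gamma = 0.7),
                                 oddball = NULL, seed = 1) {
  if (n_buffer < 2 || n_k18 < 2)
    stop_param("each group needs at least 2 animals")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_buffer + n_k18)
  make_animal <- function(i, group) {
    spec <- base
    spec$seed <- seeds[i]
    if (group == "k18")
      spec$group_effect <- utils::modifyList(spec$group_effect, k18_effect)
    if (is.null(oddball)) {
      list(id = sprintf("%s_%02d", group, i), group = group, seed = seeds[i],
           recording = simulate_recording(spec), events = NULL)
    } else {
      ses <- simulate_oddball_session(oddball, spec)
      list(id = sprintf("%s_%02d", group, i), group = group, seed = seeds[i],
           recording = ses$recording, events = ses$events)
    }
  }
  list(buffer = lapply(seq_len(n_buffer), make_animal, group = "buffer"),
       k18 = lapply(n_buffer + seq_len(n_k18), make_animal, group = "k18"))
}

#' Simulate a DAB-stained micrograph with a known positive fraction
#'
#' Constructs an RGB image in which exactly `round(p * <ROI pixel count>)`
#' pixels inside the ROI satisfy the DAB-positivity rule
#' `(R - G)/B >= 0.5` (with margin, so 8-bit quantization cannot flip a
#' pixel) and every other pixel falls strictly below the rule.
#'
#' @param width,height image size in pixels.
#' @param positive_fraction target DAB-positive fraction `p` in `[0, 1]`.
#' @param roi optional logical matrix (height x width) marking the region of
#'   interest; default the whole image.
#' @param seed optional RNG seed.
#' @return `list(image, roi, positive_fraction)`; `image` is a
#'   height x width x 3 array with channels in `[0, 1]`.
#' @export
simulate_dab_image <- function(width, height, positive_fraction, roi = NULL,
                               seed = NULL) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stop_param("positive_fraction must lie in [0, 1]")
  if (is.null(roi)) roi <- matrix(TRUE, height, width)
  if (!is.matrix(roi) || nrow(roi) != height || ncol(roi) != width)
    stop_param("roi must be a height x width logical matrix")
  if (!any(roi)) stop_param("roi is empty")
  if (!is.null(seed)) set.seed(seed)
  npx <- width * height
  B <- matrix(stats::runif(npx, 0.3, 0.7), height, width)
  G <- matrix(stats::runif(npx, 0.1, 0.4), height, width)
  r <- matrix(stats::runif(npx, -0.3, 0.4), height, width)   # below threshold
  n_pos <- round(positive_fraction * sum(roi))
  pos_idx <- sample(which(roi), n_pos)
  G[pos_idx] <- stats::runif(n_pos, 0.0, 0.3)
  r[pos_idx] <- stats::runif(n_pos, 0.6, 0.95)               # above threshold
  R <- pmin(pmax(G + r * B, 0), 1)
  list(image = array(c(R, G, B), dim = c(height, width, 3)),
       roi = roi, positive_fraction = n_pos / sum(roi))
}
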