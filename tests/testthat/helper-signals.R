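# Shared fixtures, all generated in code.

# single-channel recording holding a pure sinusoid
tone_recording <- function(freq, fs = 1000, dur = 4, amp = 1, label = "x") {
  t <- (0:(dur * fs - 1)) / fs
  recording(matrix(amp * sin(2 * pi * freq * t), nrow = 1), fs, label)
}

# amplitude at a frequency via a Hann-tapered DFT -- the independent
# spectral oracle used against the filters
fft_amplitude <- function(x, f, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  2 * Mod(stats::fft(x * w)[round(f * n / fs) + 1]) / sum(w)
}

# epoch_set of white-noise epochs, channels x epochs as requested
noise_epochs <- function(n_ep, fs, epoch_len = 4, n_ch = 1, sd = 1,
                         labels = paste0("ch", seq_len(n_ch))) {
  w <- round(epoch_len * fs)
  arr <- array(stats::rnorm(n_ep * n_ch * w, sd = sd), dim = c(n_ep, n_ch, w))
  epoch_set(arr, fs, epoch_len, labels = labels)
}

# ERP-style epoch_set: template (channels x samples) plus white noise,
# anchored at tmin seconds
template_epochs <- function(template, n_ep, fs, tmin = -0.05, noise_sd = 0) {
  n_sp <- length(template)
  arr <- array(0, dim = c(n_ep, 1, n_sp))
  for (e in seq_len(n_ep))
    arr[e, 1, ] <- template + stats::rnorm(n_sp, sd = noise_sd)
  meta <- data.frame(state = rep("unknown", n_ep),
                     condition = rep("standard", n_ep),
                     artifact = rep(FALSE, n_ep), onset = seq_len(n_ep),
                     stringsAsFactors = FALSE)
  epoch_set(arr, fs, n_sp / fs, meta, labels = "ch1", tmin = tmin)
}

# small two-channel sim spec used by the cohort-level tests (kept light so
# the suite stays fast; the methods vignette states these sizes)
small_base_spec <- function(seed = 1, fs = 500) {
  sim_spec(seed = seed, fs = fs,
           channels = list(
             PFC_R = list(oscillators = list(list(center = 8, bandwidth = 2, rms = 10))),
             CA1_R = list(oscillators = list(list(center = 8, bandwidth = 2, rms = 10)))),
           mixing = matrix(1, 2, 1),
           pac = list(CA1_R = list(f_L = 8, f_H = 70, kappa = 0.8,
                                   carrier_amp = 10)))
}
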