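# Oddball ERP analysis: epoching, averaging, components, Morlet maps.

# Gaussian-bump template on the -50..450 ms grid, zero before onset
bump_template <- function(times_ms, amp, lat, width) {
  y <- numeric(length(times_ms))
  for (k in seq_along(amp))
    y <- y + amp[k] * exp(-0.5 * ((times_ms - lat[k]) / width[k])^2)
  y[times_ms < 0] <- 0
  y
}

test_that("extract_erp_epochs copies condition labels and skips edge events", {
  fs <- 500
  rec <- recording(matrix(rnorm(20 * fs), 1), fs, "x")
  ev <- event_list(c(0.01, 2, 4, 6, 19.9),
                   c("standard", "standard", "deviant", "artifact", "standard"))
  ep <- extract_erp_epochs(rec, ev)
  # first underruns the baseline, last overruns the tail, artifact dropped
  expect_equal(n_epochs(ep), 2)
  expect_equal(ep$meta$condition, c("standard", "deviant"))
  expect_equal(attr(ep, "n_skipped"), 2)
  expect_equal(dim(ep$data)[3], round(0.5 * fs))
  expect_error(extract_erp_epochs(rec, event_list(0.001, "standard")),
               "no extractable")
})

test_that("averaging is baseline-corrected and reduces noise as sqrt(N)", {
  fs <- 2000
  n_sp <- round(0.5 * fs)
  times <- (-0.05 + (0:(n_sp - 1)) / fs) * 1000
  tpl <- bump_template(times, c(5, -8, 6, -3), c(20, 40, 80, 150),
                       c(6, 8, 15, 25))
  # identical epochs: average equals any single corrected epoch
  ep0 <- template_epochs(tpl + 2, 5, fs)   # constant offset removed by baseline
  avg0 <- average_erp(ep0, "standard")
  expect_equal(avg0$waveform[1, ], tpl, tolerance = 1e-9)
  expect_lt(abs(mean(avg0$waveform[1, avg0$times < 0])), 1e-9)
  # sqrt(N) noise reduction at N = 240
  set.seed(71)
  sigma <- 4
  ep <- template_epochs(tpl, 240, fs, noise_sd = sigma)
  avg <- average_erp(ep, "standard")
  rmse <- sqrt(mean((avg$waveform[1, ] - tpl)^2))
  expect_lt(abs(rmse - sigma / sqrt(240)) / (sigma / sqrt(240)), 0.2)
  expect_equal(avg$n_trials, 240)
  expect_error(average_erp(ep, "deviant"), "no usable")
})

test_that("grand_average is the unweighted mean across animals", {
  fs <- 500
  n_sp <- round(0.5 * fs)
  times <- (-0.05 + (0:(n_sp - 1)) / fs) * 1000
  tpl <- bump_template(times, c(5, -8), c(20, 40), c(6, 8))
  mk <- function(scale) {
    avg <- average_erp(template_epochs(scale * tpl, 2, fs), "standard")
    avg
  }
  g <- grand_average(list(mk(1), mk(2), mk(3)))
  expect_equal(g$waveform[1, ], 2 * tpl, tolerance = 1e-9)
  expect_equal(g$n_trials, 3)
  expect_equal(grand_average(list(mk(1)))$waveform, mk(1)$waveform)
  opp <- mk(1); opp$waveform <- -opp$waveform
  expect_equal(max(abs(grand_average(list(mk(1), opp))$waveform)), 0)
  dev <- mk(1); dev$condition <- "deviant"
  expect_error(grand_average(list(mk(1), dev)), "same time grid and condition")
})

test_that("detect_components recovers a constructed template exactly", {
  fs <- 2000
  n_sp <- round(0.5 * fs)
  times <- (-0.05 + (0:(n_sp - 1)) / fs) * 1000
  tpl <- bump_template(times, c(5, -8, 6, -3), c(20, 40, 80, 150),
                       c(4, 4, 8, 12))
  avg <- average_erp(template_epochs(tpl, 1, fs), "standard")
  ct <- detect_components(avg)
  expect_equal(ct$P1_amp, 5, tolerance = 1e-3)
  expect_equal(ct$N1_amp, -8, tolerance = 1e-3)
  expect_equal(ct$P2_amp, 6, tolerance = 1e-3)
  expect_equal(ct$N2_amp, -3, tolerance = 1e-3)
  expect_equal(c(ct$P1_lat, ct$N1_lat, ct$P2_lat, ct$N2_lat),
               c(20, 40, 80, 150), tolerance = 0.51)
  expect_equal(ct$N1P1, 13, tolerance = 2e-3)
  expect_equal(ct$N1P2, 14, tolerance = 2e-3)
})

test_that("flat waveforms yield not-found components; ties break earlier", {
  fs <- 1000
  n_sp <- round(0.5 * fs)
  times <- (-0.05 + (0:(n_sp - 1)) / fs) * 1000
  avg <- average_erp(template_epochs(numeric(n_sp), 1, fs), "standard")
  ct <- detect_components(avg)
  expect_true(all(is.na(c(ct$P1_amp, ct$N1_amp, ct$P2_amp, ct$N2_amp,
                          ct$N1P1, ct$N1P2))))
  # two equal maxima in the P1 window: the earlier latency is reported
  two <- bump_template(times, c(4, 4), c(15, 25), c(1.5, 1.5))
  avg2 <- average_erp(template_epochs(two, 1, fs), "standard")
  ct2 <- detect_components(avg2)
  expect_equal(ct2$P1_lat, 15, tolerance = 0.51)
})

test_that("component detection is translation-covariant", {
  fs <- 1000
  n_sp <- round(0.5 * fs)
  times <- (-0.05 + (0:(n_sp - 1)) / fs) * 1000
  base <- c(5, -8, 6, -3)
  ct0 <- detect_components(average_erp(template_epochs(
    bump_template(times, base, c(20, 40, 80, 150), c(4, 4, 8, 12)), 1, fs),
    "standard"))
  dt <- 30
  wins <- list(P1 = c(10, 30) + dt, N1 = c(30, 50) + dt,
               P2 = c(50, 100) + dt, N2 = c(100, 200) + dt)
  ct1 <- detect_components(average_erp(template_epochs(
    bump_template(times, base, c(20, 40, 80, 150) + dt, c(4, 4, 8, 12)), 1, fs),
    "standard"), windows = wins)
  expect_equal(c(ct1$P1_lat, ct1$N1_lat, ct1$P2_lat, ct1$N2_lat),
               c(ct0$P1_lat, ct0$N1_lat, ct0$P2_lat, ct0$N2_lat) + dt,
               tolerance = 0.51)
})

test_that("Morlet map localizes bursts in time and frequency", {
  fs <- 500
  n_sp <- round(0.5 * fs)
  times <- (-0.05 + (0:(n_sp - 1)) / fs) * 1000
  burst <- function(f, lo, hi) {
    ifelse(times >= lo & times < hi, sin(2 * pi * f * times / 1000), 0)
  }
  x <- burst(60, 50, 150)
  tf <- morlet_spectrogram(template_epochs(x, 1, fs), freqs = 5:100)
  inwin <- which(tf$times >= 75 & tf$times < 125)
  prof <- rowMeans(tf$power[, inwin, 1])
  expect_equal(tf$freqs[which.max(prof)], 60, tolerance = 2.1)
  expect_true(all(tf$power >= 0))
  # two disjoint bursts give two disjoint ridges
  x2 <- burst(30, 50, 150) + burst(70, 250, 350)
  tf2 <- morlet_spectrogram(template_epochs(x2, 1, fs), freqs = 5:100)
  p1 <- rowMeans(tf2$power[, tf2$times >= 75 & tf2$times < 125, 1])
  p2 <- rowMeans(tf2$power[, tf2$times >= 275 & tf2$times < 325, 1])
  expect_equal(tf2$freqs[which.max(p1)], 30, tolerance = 2.1)
  expect_equal(tf2$freqs[which.max(p2)], 70, tolerance = 2.1)
  expect_error(morlet_spectrogram(template_epochs(x, 1, fs), freqs = 5:400),
               "Nyquist")
})

test_that("evoked_band_power averages its selection and flags gamma bursts", {
  fs <- 500
  n_sp <- round(0.5 * fs)
  times <- (-0.05 + (0:(n_sp - 1)) / fs) * 1000
  x <- ifelse(times >= 50 & times < 150,
              3 * sin(2 * pi * 60 * times / 1000), 0)
  tf <- morlet_spectrogram(template_epochs(x, 1, fs), freqs = 10:100)
  during <- evoked_band_power(tf, c(40, 80), c(50, 150))
  before <- evoked_band_power(tf, c(40, 80), c(-50, 0))
  expect_gt(during, before)
  tfc <- tf
  tfc$power[] <- 2.5
  expect_equal(evoked_band_power(tfc, c(40, 80), c(0, 100)), 2.5)
  expect_error(evoked_band_power(tf, c(500, 600), c(0, 100)), "empty")
})
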