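# Ground-truth generator: determinism, parameter recovery, oddball design.

test_that("simulation is deterministic under the seed", {
  spec <- small_base_spec(seed = 17)
  spec$duration <- 5
  r1 <- simulate_recording(spec)
  r2 <- simulate_recording(spec)
  expect_identical(r1$data, r2$data)
  spec2 <- spec
  spec2$seed <- 18L
  expect_false(identical(simulate_recording(spec2)$data, r1$data))
})

test_that("spec validation rejects bad parameters", {
  expect_error(sim_spec(pac = list(CA1_R = list(f_L = 8, f_H = 70,
                                                kappa = 1.4, carrier_amp = 1))),
               "kappa")
  expect_error(sim_spec(background = list(exponent = 1, rms = -2)), ">= 0")
  expect_error(simulate_pac_signal(8, 70, 0.5, 2, fs = 100), "f_H < fs/2")
})

test_that("doubling the theta oscillator RMS quadruples theta power", {
  mk <- function(rms) {
    spec <- sim_spec(seed = 23, fs = 250, duration = 60,
                     channels = list(ch = list(oscillators = list(
                       list(center = 8, bandwidth = 2, rms = rms)))),
                     background = list(exponent = 1, rms = 2),
                     sources = list(), mixing = matrix(0, 1, 0), pac = list())
    ps <- power_spectrum(segment_epochs(simulate_recording(spec), 4), fmax = 100)
    sum(ps$abs_power[1, ps$freqs %in% 5:11])
  }
  expect_equal(mk(20) / mk(10), 4, tolerance = 0.1 * 4)
})

test_that("shared-source weights produce the closed-form coherence", {
  # white common source and white noise with equal variances:
  # coh = (s^2 / (s^2 + n^2))^2 = 0.5 when s^2 = n^2 (sqrt2 - 1) ... solved
  # for coh 0.5: s2/(s2+n2) = sqrt(0.5)
  s_rms <- 10
  n_rms <- s_rms * sqrt(sqrt(2) - 1)
  spec <- sim_spec(seed = 29, fs = 250, duration = 240,
                   channels = list(
                     A = list(oscillators = list()),
                     B = list(oscillators = list())),
                   background = list(exponent = 0, rms = n_rms),
                   sources = list(list(center = NULL, rms = s_rms)),
                   mixing = matrix(1, 2, 1), pac = list())
  ep <- segment_epochs(simulate_recording(spec), 4)
  cs <- msc_coherence(ep, c("A", "B"))
  expect_equal(mean(cs$coh), 0.5, tolerance = 0.05)
})

test_that("the clean PAC signal carries MI = kappa * A0 / 2 at its cell", {
  rec <- simulate_pac_signal(8, 70, 0.8, duration = 60, fs = 500,
                             noise_rms = 0, seed = 31, carrier_amp = 2)
  com <- comodulogram(rec, "PAC", phase_freqs = 8, amp_freqs = 70,
                      amp_bandwidth = 24)
  expect_equal(com$mi[1, 1], 0.4 * 2, tolerance = 0.01 * 0.8)
})

test_that("oddball sessions follow the 240/60 design with 4 s spacing", {
  ses <- simulate_oddball_session(oddball_spec(n_standard = 24),
                                  small_base_spec(seed = 37))
  expect_equal(nrow(ses$events), 30)
  expect_equal(sum(ses$events$code == "deviant"), 6)
  expect_true(all(abs(diff(ses$events$onset_s) - 4) < 1e-12))
  # no two consecutive deviants
  expect_false(any(rle(ses$events$code)$lengths[
    rle(ses$events$code)$values == "deviant"] > 1))
  # default design numbers (event table only; construction is cheap)
  set.seed(1)
  codes <- tauconn:::oddball_codes(240, 60)
  expect_equal(length(codes), 300)
  expect_equal(sum(codes == "deviant"), 60)
})

test_that("the injected standard template is recovered from the session", {
  ob <- oddball_spec(n_standard = 240)
  ses <- simulate_oddball_session(ob, small_base_spec(seed = 41))
  # standard preprocessing: the acquisition band-pass (1-100 Hz)
  rec <- bandpass_filter(ses$recording, 1, 100)
  avg <- average_erp(extract_erp_epochs(rec, ses$events), "standard")
  times <- avg$times
  tpl <- tauconn:::erp_template_waveform(times, ob$templates$standard) +
    ob$gamma$amp[["standard"]] *
      exp(-0.5 * ((times - ob$gamma$center_ms) / ob$gamma$sd_ms)^2) *
      cos(2 * pi * ob$gamma$freq * times / 1000)
  tpl[times < 0] <- 0
  # the comparison target is the template as seen through the same band-pass
  fs <- rec$fs
  pad <- round(2 * fs)
  tlong <- c(numeric(pad), tpl, numeric(pad))
  tfilt <- bandpass_filter(recording(matrix(tlong, 1), fs, "t"), 1, 100)
  tpl_f <- tfilt$data[1, pad + seq_along(tpl)]
  rmse <- sqrt(mean((avg$waveform["PFC_R", ] - tpl_f)^2))
  expect_lt(rmse, 0.1 * max(abs(tpl)))
})

test_that("group studies are reproducible and apply the effect profile", {
  base <- small_base_spec(seed = 1)
  base$duration <- 10
  s1 <- simulate_group_study(2, 2, base = base, seed = 7)
  s2 <- simulate_group_study(2, 2, base = base, seed = 7)
  expect_identical(s1$buffer[[1]]$recording$data, s2$buffer[[1]]$recording$data)
  expect_identical(s1$k18[[2]]$recording$data, s2$k18[[2]]$recording$data)
  expect_error(simulate_group_study(1, 5), "at least 2")
})

test_that("DAB images carry the constructed fraction exactly", {
  img <- simulate_dab_image(100, 100, 0.37, seed = 5)
  expect_equal(img$positive_fraction, 0.37)
  res <- dab_positive_fraction(img)
  expect_equal(res$fraction, 0.37)
  img0 <- simulate_dab_image(50, 50, 0, seed = 5)
  expect_equal(dab_positive_fraction(img0)$fraction, 0)
  # determinism
  a <- simulate_dab_image(40, 40, 0.2, seed = 9)
  b <- simulate_dab_image(40, 40, 0.2, seed = 9)
  expect_identical(a$image, b$image)
  expect_error(simulate_dab_image(10, 10, 1.5), "\\[0, 1\\]")
  expect_error(simulate_dab_image(10, 10, 0.5, roi = matrix(FALSE, 10, 10)),
               "empty")
})
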