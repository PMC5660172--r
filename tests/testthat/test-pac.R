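# Phase-amplitude coupling: analytic decomposition, modulation index,
# comodulograms and surrogate significance.

test_that("analytic decomposition recovers amplitude and phase of a cosine", {
  fs <- 500
  rec <- tone_recording(8, fs = fs, dur = 20)
  ab <- analytic_decompose(rec, "x", 8, 4)
  v <- ab$valid
  expect_lt(max(abs(ab$amplitude[v] - 1)), 0.02)
  slope <- stats::coef(stats::lm(unwrap_phase ~ tt,
    data = data.frame(unwrap_phase = cumsum(c(ab$phase[v][1],
      (diff(ab$phase[v]) + pi) %% (2 * pi) - pi)), tt = v / fs)))[2]
  expect_lt(abs(slope / (2 * pi * 8) - 1), 0.01)
  expect_error(analytic_decompose(rec, "x", 1000, 200), "Nyquist")
})

test_that("an AM envelope is recovered from the carrier band", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  env <- 1 + 0.5 * cos(2 * pi * 8 * t)
  rec <- recording(matrix(env * cos(2 * pi * 70 * t), 1), fs, "x")
  ab <- analytic_decompose(rec, "x", 70, 24)
  v <- ab$valid
  expect_gt(stats::cor(ab$amplitude[v], env[v]), 0.99)
})

test_that("modulation index matches its closed form and scales with amplitude", {
  fs <- 1000
  t <- (0:(60 * fs - 1)) / fs
  phi <- ((2 * pi * 8 * t + pi) %% (2 * pi)) - pi
  # numeric-integration oracle of |mean((1+k cos(phi)) e^{i phi})| over a cycle
  oracle <- function(k) {
    g <- seq(-pi, pi, length.out = 20001)[-1]
    Mod(mean((1 + k * cos(g)) * exp(1i * g)))
  }
  for (k in c(0.2, 0.5, 0.8)) {
    A <- 1 + k * cos(phi)
    expect_equal(modulation_index(phi, A), oracle(k), tolerance = 1e-6)
    expect_equal(modulation_index(phi, A), k / 2, tolerance = 0.01 * k / 2)
    # scale covariance
    expect_equal(modulation_index(phi, 7 * A), 7 * modulation_index(phi, A),
                 tolerance = 1e-12)
  }
  # constant amplitude over whole cycles: MI vanishes
  expect_lt(modulation_index(phi, rep(2, length(phi))), 1e-6 * 2)
  expect_error(modulation_index(phi, A[-1]), "equal length")
})

test_that("comodulogram grid has the default 6 x 39 shape", {
  rec <- simulate_pac_signal(8, 70, 0.8, duration = 8, fs = 500, seed = 1)
  com <- comodulogram(rec, "PAC")
  expect_equal(dim(com$mi), c(6, 39))
  expect_equal(com$phase_freqs, seq(2, 12, by = 2))
  expect_equal(com$amp_freqs, seq(10, 200, by = 5))
  expect_true(all(com$mi >= 0))
  expect_error(comodulogram(rec, "PAC", segment = c(0, 1)), "5 cycles")
})

test_that("seeded coupling is recovered at the correct grid cell", {
  hits <- 0
  for (s in 1:10) {
    rec <- simulate_pac_signal(8, 70, 0.8, duration = 30, fs = 1000,
                               noise_rms = 0.5, seed = s)
    com <- comodulogram(rec, "PAC")
    am <- arrayInd(which.max(com$mi), dim(com$mi))
    if (com$phase_freqs[am[1]] == 8 && com$amp_freqs[am[2]] == 70)
      hits <- hits + 1
  }
  expect_gte(hits, 10)
})

test_that("measured MI rises monotonically with the generated coupling", {
  kappas <- c(0, 0.2, 0.4, 0.6, 0.8)
  mis <- sapply(kappas, function(k) {
    mean(sapply(1:10, function(s) {
      rec <- simulate_pac_signal(8, 70, k, duration = 12, fs = 500,
                                 noise_rms = 0.3, seed = 100 * s + k * 10)
      com <- comodulogram(rec, "PAC", phase_freqs = 8, amp_freqs = 70)
      com$mi[1, 1]
    }))
  })
  expect_true(all(diff(mis) > 0))
})

test_that("surrogate z is amplitude-scale invariant and obvious coupling is significant", {
  spec <- small_base_spec(seed = 5)
  spec$duration <- 30
  rec <- simulate_recording(spec)
  com <- comodulogram(rec, "CA1_R", n_surrogates = 50, seed = 9)
  expect_true(com$sig["8", "70"])
  expect_gt(com$z["8", "70"], qnorm(1 - 0.05 / 234))
  expect_equal(com$n_surrogates, 50L)
  # sig implies z above the corrected critical value everywhere
  expect_true(all(com$z[which(com$sig)] > qnorm(1 - 0.05 / 234)))
  # scaling the recording rescales MI but not z
  rec2 <- rec
  rec2$data <- rec2$data * 3
  com2 <- comodulogram(rec2, "CA1_R", n_surrogates = 50, seed = 9)
  expect_equal(com2$mi, 3 * com$mi, tolerance = 1e-9)
  expect_equal(com2$z, com$z, tolerance = 1e-6)
})

test_that("surrogate_significance fills z/sig consistently with one-shot computation", {
  rec <- simulate_pac_signal(8, 70, 0.6, duration = 10, fs = 500,
                             noise_rms = 0.5, seed = 4)
  com0 <- comodulogram(rec, "PAC", phase_freqs = c(6, 8),
                       amp_freqs = c(40, 70, 100))
  com1 <- surrogate_significance(com0, rec, "PAC", n_surrogates = 20, seed = 3)
  com2 <- comodulogram(rec, "PAC", phase_freqs = c(6, 8),
                       amp_freqs = c(40, 70, 100), n_surrogates = 20, seed = 3)
  expect_equal(com1$mi, com0$mi, tolerance = 1e-12)
  expect_equal(com1$z, com2$z, tolerance = 1e-12)
  expect_identical(com1$sig, com2$sig)
  expect_equal(com1$n_surrogates, 20L)
})
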