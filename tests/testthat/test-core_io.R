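# Recording containers, readers/writers, filtering and epoch segmentation.

test_that("recording validates its invariants", {
  expect_error(recording(matrix(c(1, NA), 1), 100, "a"), "finite")
  expect_error(recording(matrix(1:4, 2), -1, c("a", "b")), "positive")
  expect_error(recording(matrix(1:4, 2), 100, c("a", "a")), "unique")
  rec <- recording(matrix(1:6, 2), 3, c("a", "b"))
  expect_equal(duration(rec), 1)
})

test_that("event_list requires ordered non-negative onsets", {
  expect_error(event_list(c(2, 1), "standard"), "non-decreasing")
  expect_error(event_list(c(-1, 1), "standard"), ">= 0")
  ev <- event_list(c(1, 5, 9), c("standard", "deviant", "standard"))
  expect_equal(nrow(ev), 3)
})

test_that("EDF round trip preserves header fields and samples to quantization", {
  rec <- simulate_recording(sim_spec(seed = 3, fs = 500, duration = 4))
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path, "edf")
  back <- read_recording(path, "edf")
  expect_identical(back$labels, rec$labels)
  expect_equal(back$fs, rec$fs)
  expect_equal(nrow(back$data), 6)
  # 16-bit quantization bound over each channel's physical range
  qstep <- (apply(rec$data, 1, max) - apply(rec$data, 1, min)) / 65535
  err <- apply(abs(back$data - rec$data), 1, max)
  expect_true(all(err <= qstep * 1.01))
})

test_that("delimited round trip is exact and an empty/missing file errors", {
  rec <- recording(matrix(rnorm(400), 2), 100, c("PFC_L", "PFC_R"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path, "delimited")
  back <- read_recording(path, "delimited")
  expect_equal(back$data, rec$data, tolerance = 1e-10)
  expect_identical(back$labels, rec$labels)
  expect_error(read_recording(file.path(tempdir(), "nope.edf"), "edf"),
               "no such file")
  empty <- withr::local_tempfile(fileext = ".edf")
  file.create(empty)
  expect_error(read_recording(empty, "edf"), "EDF")
})

test_that("event table round trip", {
  ev <- event_list(c(4, 8, 12), c("standard", "deviant", "standard"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, path)
  expect_equal(as.data.frame(read_events(path)), as.data.frame(ev))
})

test_that("notch filter kills 50 Hz, leaves the pass band and DC unchanged", {
  fs <- 2000
  t <- (0:(10 * fs - 1)) / fs
  rec <- recording(rbind(sin(2 * pi * 50 * t), sin(2 * pi * 10 * t),
                         rep(5, length(t))),
                   fs, c("mains", "theta10", "dc"))
  out <- notch_filter(rec)
  atten_db <- 20 * log10(fft_amplitude(out$data[1, ], 50, fs) /
                         fft_amplitude(rec$data[1, ], 50, fs))
  expect_lt(atten_db, -40)
  ripple_db <- abs(20 * log10(fft_amplitude(out$data[2, ], 10, fs) /
                              fft_amplitude(rec$data[2, ], 10, fs)))
  expect_lt(ripple_db, 0.5)
  expect_lt(max(abs(out$data[3, ] - 5)), 1e-6)
  expect_error(notch_filter(rec, f0 = 1200), "fs/2")
})

test_that("band-pass keeps in-band tones and rejects slow drift", {
  fs <- 2000
  t <- (0:(20 * fs - 1)) / fs
  rec <- recording(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 0.2 * t)),
                   fs, c("inband", "drift"))
  out <- bandpass_filter(rec, 1, 100)
  ratio10 <- fft_amplitude(out$data[1, ], 10, fs) /
    fft_amplitude(rec$data[1, ], 10, fs)
  expect_lt(abs(ratio10 - 1), 0.05)
  atten_db <- 20 * log10(fft_amplitude(out$data[2, ], 0.2, fs) /
                         fft_amplitude(rec$data[2, ], 0.2, fs))
  expect_lt(atten_db, -20)
  expect_error(bandpass_filter(rec, 100, 1), "lo < hi")
})

test_that("filters are linear and zero-phase", {
  fs <- 500
  set.seed(11)
  x <- rnorm(4 * fs)
  y <- rnorm(4 * fs)
  rx <- recording(matrix(x, 1), fs, "x")
  ry <- recording(matrix(y, 1), fs, "y")
  rxy <- recording(matrix(2 * x - 3 * y, 1), fs, "xy")
  f <- function(r) bandpass_filter(r, 2, 80)$data[1, ]
  lhs <- f(rxy)
  rhs <- 2 * f(rx) - 3 * f(ry)
  expect_lt(max(abs(lhs - rhs)) / stats::sd(rhs), 1e-6)
  # zero-phase: cross-correlation of a band-limited tone with its filtered
  # version peaks at lag 0
  tone <- tone_recording(12, fs = fs, dur = 4)
  filt <- bandpass_filter(tone, 2, 80)$data[1, ]
  cc <- stats::ccf(tone$data[1, ], filt, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("segment_epochs cuts half-open epochs and flags artifacts", {
  fs <- 100
  rec <- recording(matrix(rnorm(60 * fs), 1), fs, "x")
  ep <- segment_epochs(rec, 4)
  expect_equal(n_epochs(ep), 15)
  expect_equal(dim(ep$data)[3], 400)
  # a single extreme sample flags only its own epoch
  x <- rnorm(60 * fs)
  x[2 * 4 * fs + 10] <- 10 * 1000
  ep2 <- segment_epochs(recording(matrix(x, 1), fs, "x"), 4)
  expect_identical(which(ep2$meta$artifact), 3L)
  # flat channel is rejected
  ep3 <- segment_epochs(recording(matrix(0, 1, 8 * fs), fs, "x"), 4)
  expect_true(all(ep3$meta$artifact))
  # shorter than one epoch: empty set, not an error
  ep4 <- segment_epochs(recording(matrix(rnorm(3 * fs), 1), fs, "x"), 4)
  expect_equal(n_epochs(ep4), 0)
  # sample conservation
  expect_true(n_epochs(ep) * 400 <= 60 * fs &&
              60 * fs < (n_epochs(ep) + 1) * 400)
  # state labels attach
  ep5 <- segment_epochs(rec, 4, state_labels = rep(c("waking", "NREM", "REM"), 5))
  expect_equal(ep5$meta$state[2], "NREM")
})
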