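# Internal numerical helpers: FFT convolution, analytic signal, noise synthesis.

# periodic Hann window (DFT-even), the taper used by every Welch-type estimate
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

# FFT length with small prime factors (R's fft is mixed-radix)
next_fft_n <- function(n) stats::nextn(n, factors = c(2, 3, 5))

# linear convolution of x with an odd-length symmetric FIR kernel b,
# returning the centre-aligned segment (zero phase for symmetric b)
fft_conv_centered <- function(x, b) {
  nx <- length(x)
  nb <- length(b)
  stopifnot(nb %% 2L == 1L)
  nf <- next_fft_n(nx + nb - 1L)
  X <- stats::fft(c(x, numeric(nf - nx)))
  B <- stats::fft(c(b, numeric(nf - nb)))
  y <- Re(stats::fft(X * B, inverse = TRUE)) / nf
  half <- (nb - 1L) %/% 2L
  y[(half + 1L):(half + nx)]
}

# zero-phase FIR application: odd (point-symmetric) edge padding to suppress
# boundary transients, two passes so stop-band attenuation is squared --
# equivalent in magnitude/phase to forward-backward filtering for a
# linear-phase kernel
apply_fir_zerophase <- function(x, b, passes = 2L) {
  nx <- length(x)
  pad <- min(length(b), nx - 1L)
  y <- x
  for (p in seq_len(passes)) {
    xp <- c(2 * y[1] - y[(pad + 1L):2L], y, 2 * y[nx] - y[(nx - 1L):(nx - pad)])
    yp <- fft_conv_centered(xp, b)
    y <- yp[(pad + 1L):(pad + nx)]
  }
  y
}

# analytic signal via frequency-domain Hilbert construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

rms_scale <- function(x, rms) {
  s <- sqrt(mean(x^2))
  if (s == 0) return(x)
  x * (rms / s)
}

# 1/f^exponent background noise by spectral shaping of Gaussian white noise
pink_noise <- function(n, fs, exponent = 1, rms = 1) {
  w <- stats::rnorm(n)
  if (rms == 0) return(numeric(n))
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]      # fold to physical frequency
  shape <- numeric(n)
  nz <- f > 0
  shape[nz] <- f[nz]^(-exponent / 2)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  rms_scale(x - mean(x), rms)
}

# band-limited oscillator: white noise shaped by a Gaussian spectral mask
# centred on `center` with sd = bandwidth/2 (Hz)
narrowband_noise <- function(n, fs, center, bandwidth, rms = 1) {
  w <- stats::rnorm(n)
  if (rms == 0) return(numeric(n))
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  sdf <- bandwidth / 2
  shape <- exp(-0.5 * ((f - center) / sdf)^2)
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  rms_scale(x - mean(x), rms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
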