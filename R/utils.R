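#' Frequency grid shared by all click spectra
#'
#' All click spectra in the package live on a common 10--100 kHz grid at
#' 0.5 kHz spacing (181 bins), regardless of the sampling rate of the
#' recording they were cut from. This keeps spectra comparable across
#' deployments recorded at 200 and 320 kHz.
#'
#' @return Numeric vector of 181 frequencies in kHz.
#' @export
click_freq_grid <- function() {
  seq(10, 100, by = 0.5)
}

#' Centers of the inter-click-interval histogram bins
#'
#' ICI distributions are truncated at 0.6 s and histogrammed at 10 ms
#' resolution (60 bins), fine enough to resolve the narrowest modal ICI
#' among the built-in click types (28.4 ms).
#'
#' @return Numeric vector of 60 bin centers in seconds.
#' @export
ici_bin_centers <- function() {
  seq(0.005, 0.595, by = 0.01)
}

# breaks matching ici_bin_centers()
ici_bin_breaks <- function() seq(0, 0.6, by = 0.01)

#' @rdname ici_bin_centers
#' @export
ici_max_s <- function() 0.6

n_envelope_points <- function() 100L

# Deterministic child seed so independent generators driven by one user seed
# do not share streams. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Half-up decimal rounding (R's round() is round-half-even); printed tables
# in the acoustic literature use half-up percentages.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Tukey (tapered cosine) window; r = total taper fraction.
tukey_window <- function(n, r = 0.25) {
  if (n == 1) return(1)
  t <- (0:(n - 1)) / (n - 1)
  w <- rep(1, n)
  edge <- r / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / edge - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + edge) / edge)))
  w
}

# Analytic signal via FFT; Mod() of the result is the waveform envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# O(n) centered moving average via cumulative sums.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + (k - half - 1L))
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Linear resample of a vector to n points.
resample_vector <- function(x, n) {
  if (length(x) == n) return(x)
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n))$y
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
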