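#' Split a BOLD time course into analysis windows
#'
#' Consecutive non-overlapping windows of `window_len` samples. When the
#' signal is shorter than one window it is zero-padded to a single full
#' window; otherwise any trailing remainder shorter than a window is
#' discarded.
#'
#' @param samples Numeric vector, the BOLD time course.
#' @param window_len Window length in samples (>= 2).
#' @return A list of numeric vectors, each of length `window_len`.
#' @export
#' @examples
#' length(window_signal(rnorm(595), 256))  # 2 windows, 83 samples dropped
window_signal <- function(samples, window_len) {
  stopifnot(window_len >= 2)
  n <- length(samples)
  if (n == 0) stop("empty signal")
  if (!all(is.finite(samples))) stop("signal contains non-finite values")
  if (n < window_len) {
    return(list(c(samples, rep(0, window_len - n))))
  }
  k <- n %/% window_len
  lapply(seq_len(k), function(i) {
    samples[((i - 1) * window_len + 1):(i * window_len)]
  })
}

## B3-spline scaling filter of the a-trous (starlet) scheme.
ATROUS_H <- c(1, 4, 6, 4, 1) / 16

## circular convolution of x with the filter h upsampled by `hole` zeros
atrous_smooth <- function(x, hole) {
  n <- length(x)
  out <- numeric(n)
  taps <- c(-2L, -1L, 0L, 1L, 2L)
  for (k in seq_along(taps)) {
    sh <- taps[k] * hole
    idx <- ((seq_len(n) - 1 + sh) %% n) + 1
    out <- out + ATROUS_H[k] * x[idx]
  }
  out
}

#' Undecimated (a trous) wavelet decomposition of a window
#'
#' Shift-invariant spline-family wavelet transform: at each level the
#' running approximation is smoothed with the B3-spline kernel whose taps
#' are spread by growing holes, and the detail band is the difference
#' between successive approximations. The transform is linear and admits
#' exact reconstruction as the sum of all detail bands plus the final
#' approximation ([activelet_reconstruct()]). It plays the role of the
#' activelet (hemodynamic exponential-spline) transform: burst-like BOLD
#' transients concentrate in few detail coefficients.
#'
#' @param window Numeric vector of length >= `2^levels`.
#' @param levels Number of detail levels.
#' @return A list with `details` (a `levels` x `length(window)` matrix,
#'   one row per level, fine to coarse) and `approx` (the final smooth).
#' @export
activelet_decompose <- function(window, levels = 4) {
  n <- length(window)
  if (n < 2^levels) stop("window too short for ", levels, " levels")
  stopifnot(all(is.finite(window)))
  details <- matrix(0, nrow = levels, ncol = n)
  approx <- window
  for (j in seq_len(levels)) {
    sm <- atrous_smooth(approx, hole = 2^(j - 1))
    details[j, ] <- approx - sm
    approx <- sm
  }
  list(details = details, approx = approx)
}

#' @rdname activelet_decompose
#' @param coeffs A list as returned by [activelet_decompose()].
#' @export
activelet_reconstruct <- function(coeffs) {
  colSums(coeffs$details) + coeffs$approx
}

#' Gini index of coefficient magnitudes
#'
#' Lerman–Yitzhaki form: with magnitudes sorted ascending `c(1)..c(N)` and
#' `S` their sum, `G = 1 - 2 * sum_k (c(k)/S) * ((N - k + 0.5)/N)`.
#' Scale-invariant; 0 for uniform magnitudes (and, by convention, for the
#' all-zero vector), approaching 1 for a one-hot vector
#' (`G = (N-1)/N` exactly).
#'
#' @param coeffs Numeric vector of coefficients (signs ignored).
#' @return Scalar in `[0, 1)`.
#' @export
gini_index <- function(coeffs) {
  stopifnot(all(is.finite(coeffs)))
  c_sorted <- sort(abs(coeffs))
  s <- sum(c_sorted)
  if (s == 0) return(0)
  n <- length(c_sorted)
  k <- seq_len(n)
  1 - 2 * sum((c_sorted / s) * ((n - k + 0.5) / n))
}

## Unit-norm sine/cosine dictionary on a frequency grid spanning band_hz.
sine_dictionary <- function(n, band_hz, tr_seconds) {
  delta <- 1 / (n * tr_seconds)
  nyq <- 1 / (2 * tr_seconds)
  lo <- max(band_hz[1], delta)
  hi <- min(band_hz[2], nyq)
  k_lo <- ceiling(lo / delta - 1e-9)
  k_hi <- floor(hi / delta + 1e-9)
  if (k_hi < max(k_lo, 1)) {
    stop("sine dictionary empty: band below frequency resolution")
  }
  ks <- seq.int(max(k_lo, 1), k_hi)
  freqs <- ks * delta
  t <- (seq_len(n) - 1) * tr_seconds
  atoms <- matrix(0, nrow = n, ncol = 2 * length(freqs))
  for (i in seq_along(freqs)) {
    s <- sin(2 * pi * freqs[i] * t)
    co <- cos(2 * pi * freqs[i] * t)
    atoms[, 2 * i - 1] <- s / sqrt(sum(s^2))
    atoms[, 2 * i] <- co / sqrt(sum(co^2))
  }
  list(atoms = atoms, freqs = rep(freqs, each = 2))
}

#' Matching pursuit on a band-limited sine dictionary
#'
#' Greedy matching pursuit over unit-norm sine and cosine atoms on the
#' frequency grid `k / (window_len * TR)` restricted to `band_hz`. Stops
#' after `n_atoms` iterations or once residual energy falls below 1% of
#' the window energy. `sine_mp_gini()` returns the Gini index of the
#' coefficient magnitudes over the full dictionary (zeros included), the
#' sparsity feature used by the white-matter-noise override.
#'
#' @param window Numeric vector.
#' @param band_hz Length-2 band (Hz), within (0, Nyquist].
#' @param tr_seconds Sampling interval (s).
#' @param n_atoms Maximum iterations.
#' @return `sine_mp()`: a list with `coeffs` (per-atom accumulated
#'   coefficients), `freqs`, `residual_energy` (energy after each
#'   iteration, first element the input energy) and `n_iter`.
#'   `sine_mp_gini()`: the scalar Gini index.
#' @export
sine_mp <- function(window, band_hz, tr_seconds, n_atoms = 10) {
  n <- length(window)
  nyq <- 1 / (2 * tr_seconds)
  if (band_hz[1] <= 0 || band_hz[2] > nyq + 1e-12) {
    stop("matching-pursuit band outside (0, Nyquist]")
  }
  dict <- sine_dictionary(n, band_hz, tr_seconds)
  m <- ncol(dict$atoms)
  coeffs <- numeric(m)
  r <- window
  e0 <- sum(r^2)
  energies <- e0
  iter <- 0L
  if (e0 > 0) {
    for (i in seq_len(n_atoms)) {
      corr <- as.numeric(crossprod(dict$atoms, r))
      j <- which.max(abs(corr))
      coeffs[j] <- coeffs[j] + corr[j]
      r <- r - corr[j] * dict$atoms[, j]
      e <- sum(r^2)
      energies <- c(energies, e)
      iter <- i
      if (e < 0.01 * e0) break
    }
  }
  list(coeffs = coeffs, freqs = dict$freqs, residual_energy = energies,
       n_iter = iter)
}

#' @rdname sine_mp
#' @export
sine_mp_gini <- function(window, band_hz, tr_seconds, n_atoms = 10) {
  fit <- sine_mp(window, band_hz, tr_seconds, n_atoms)
  gini_index(fit$coeffs)
}

#' Dominant frequency of a BOLD time course
#'
#' Frequency of maximal periodogram power within `[band_hz[1], Nyquist]`
#' after mean removal. A signal with no power in the band returns the
#' band's low edge with attribute `zero_power = TRUE`.
#'
#' @param samples Numeric vector, length >= 8.
#' @param tr_seconds Sampling interval (s).
#' @param band_hz Length-2 band (Hz); only the low edge bounds the search,
#'   the high end of the search is the Nyquist frequency.
#' @return Scalar frequency (Hz).
#' @export
dominant_frequency <- function(samples, tr_seconds, band_hz = c(0.01, 0.1)) {
  n <- length(samples)
  if (n < 8) stop("time course too short for spectral analysis")
  x <- samples - mean(samples)
  pw <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) / (n * tr_seconds)
  keep <- freqs >= band_hz[1] & freqs <= 1 / (2 * tr_seconds) + 1e-12
  if (!any(keep) || max(pw[keep]) <= 1e-12 * max(1, sum(x^2))) {
    out <- band_hz[1]
    attr(out, "zero_power") <- TRUE
    return(out)
  }
  f <- freqs[keep][which.max(pw[keep])]
  attr(f, "zero_power") <- FALSE
  f
}

#' Temporal feature set of one IC time course
#'
#' Windows the signal, computes per-window wavelet-domain sparsity (Gini
#' index of the concatenated detail bands; the approximation carries
#' baseline, not transients, and is excluded) and sine-dictionary
#' matching-pursuit sparsity, aggregates across windows (`max` by
#' default), and measures the dominant frequency of the full signal.
#' An all-zero signal yields all-zero features.
#'
#' @param samples Numeric vector, the BOLD time course.
#' @param tr_seconds Sampling interval (s).
#' @param config An [ic_config()].
#' @return List of class `"temporal_features"` with `gini_activelet`,
#'   `gini_sine_mp`, `dominant_freq_hz`, `windows_used`.
#' @export
temporal_features <- function(samples, tr_seconds, config = ic_config()) {
  wins <- window_signal(samples, config$window_len)
  g_act <- vapply(wins, function(w) {
    dec <- activelet_decompose(w, config$wavelet_levels)
    gini_index(as.numeric(dec$details))
  }, numeric(1))
  g_sin <- vapply(wins, function(w) {
    if (all(w == 0)) return(0)
    sine_mp_gini(w, config$mp_band_hz, tr_seconds, config$mp_n_atoms)
  }, numeric(1))
  agg <- if (config$window_aggregate == "max") max else mean
  dfreq <- if (all(samples == 0)) {
    0
  } else {
    f <- dominant_frequency(samples, tr_seconds, config$mp_band_hz)
    if (isTRUE(attr(f, "zero_power"))) 0 else as.numeric(f)
  }
  structure(list(
    gini_activelet = agg(g_act),
    gini_sine_mp = agg(g_sin),
    dominant_freq_hz = dfreq,
    windows_used = length(wins)
  ), class = "temporal_features")
}
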