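#' Complex Morlet wavelet family
#'
#' Builds one unit-energy complex Morlet kernel per analysis frequency on
#' the inclusive grid `seq(f_min, f_max, f_step)`:
#'
#'   `g(t) = A' * exp(-t^2 / (2 sigma_t^2)) * exp(i 2 pi f0 t)`
#'
#' The family is parameterized by the constant ratio `m = f0 / sigma_f`,
#' where `sigma_f` is the spectral standard deviation of the kernel as
#' measured on its (discrete Fourier) energy spectrum; the Gaussian
#' envelope width follows as `sigma_t = 1 / (2 sqrt(2) pi sigma_f)`, so
#' that the second moment of `|G(f)|^2` about `f0` equals `f0/m` exactly in
#' the continuum.  `A'` is fixed numerically so each sampled kernel has
#' unit energy (`sum(|g|^2) / fs == 1`).  Kernels are truncated at
#' `+/- 4 sigma_t` and forced to odd length (symmetric support).
#'
#' @param f_min,f_max,f_step analysis-frequency grid in Hz (defaults 8, 80,
#'   1).
#' @param m ratio `f0 / sigma_f` (default 9).
#' @param fs sampling rate in Hz (default 512).
#' @return an object of class `WaveletFamily` with fields `f0_list`, `m`,
#'   `fs`, `sigma_f`, `sigma_t`, `A_prime` and `kernels` (list of complex
#'   vectors).
#' @export
build_wavelet_family <- function(f_min = 8, f_max = 80, f_step = 1,
                                 m = 9, fs = 512) {
  if (m <= 0) stop_wavepls("m must be positive", "wavepls_format_error")
  if (f_min <= 0 || f_min > f_max)
    stop_wavepls("need 0 < f_min <= f_max", "wavepls_format_error")
  if (f_max >= fs / 2)
    stop_wavepls("f_max must be below the Nyquist frequency fs/2",
                 "wavepls_format_error")
  f0 <- seq(f_min, f_max, by = f_step)
  sigma_f <- f0 / m
  sigma_t <- 1 / (2 * sqrt(2) * pi * sigma_f)
  kernels <- vector("list", length(f0))
  A_prime <- numeric(length(f0))
  for (i in seq_along(f0)) {
    half <- max(1L, floor(4 * sigma_t[i] * fs))
    t <- (-half:half) / fs
    g <- exp(-t^2 / (2 * sigma_t[i]^2)) * exp(2i * pi * f0[i] * t)
    a <- 1 / sqrt(sum(Mod(g)^2) / fs)
    kernels[[i]] <- a * g
    A_prime[i] <- a
  }
  structure(list(f0_list = f0, m = m, fs = fs, sigma_f = sigma_f,
                 sigma_t = sigma_t, A_prime = A_prime, kernels = kernels),
            class = "WaveletFamily")
}

#' @export
print.WaveletFamily <- function(x, ...) {
  cat(sprintf("WaveletFamily: %d kernels, %g-%g Hz, m = %g, fs = %g Hz\n",
              length(x$f0_list), min(x$f0_list), max(x$f0_list), x$m, x$fs))
  invisible(x)
}

#' Spectral standard deviation of a kernel measured by FFT second moment
#'
#' Zero-pads the kernel, takes its discrete energy spectrum and returns the
#' square root of the energy-weighted second moment of frequency about the
#' energy-weighted mean.  For a well-sampled family kernel this equals
#' `f0 / m` to within discretization error.
#'
#' @param fam a [build_wavelet_family()] object.
#' @param which kernel index.
#' @param pad_factor zero-padding factor for spectral resolution.
#' @return list with `center` (Hz) and `sigma` (Hz).
#' @export
measure_spectral_sigma <- function(fam, which, pad_factor = 16) {
  g <- fam$kernels[[which]]
  n <- next_pow2(length(g) * pad_factor)
  spec <- Mod(stats::fft(c(g, rep(0 + 0i, n - length(g)))))^2
  f <- (seq_len(n) - 1L) * fam$fs / n
  keep <- f <= fam$fs / 2      # analytic kernel: energy in [0, Nyquist]
  spec <- spec[keep]; f <- f[keep]
  w <- spec / sum(spec)
  mu <- sum(w * f)
  list(center = mu, sigma = sqrt(sum(w * (f - mu)^2)))
}

#' Cosine-square taper
#'
#' Multiplies the first and last `taper_fraction` of the span by
#' cosine-squared ramps rising smoothly from 0 to 1; the middle of the
#' signal is untouched.  `taper_fraction = 0.5` gives the full Hann window.
#'
#' @param signal numeric vector, or a matrix tapered column-wise.
#' @param taper_fraction fraction of the span tapered at each end, in
#'   `(0, 0.5]`.
#' @return the tapered signal.
#' @export
cosine_square_taper <- function(signal, taper_fraction = 0.1) {
  if (taper_fraction <= 0 || taper_fraction > 0.5)
    stop_wavepls("taper_fraction must lie in (0, 0.5]",
                 "wavepls_format_error")
  n <- if (is.matrix(signal)) nrow(signal) else length(signal)
  w <- taper_window(n, taper_fraction)
  if (is.matrix(signal)) signal * w else signal * w
}

taper_window <- function(n, taper_fraction) {
  x <- (seq_len(n) - 1L) / (n - 1L)   # position as fraction of the span
  w <- rep(1, n)
  lo <- x < taper_fraction
  w[lo] <- sin(pi / 2 * x[lo] / taper_fraction)^2
  hi <- x > 1 - taper_fraction
  w[hi] <- sin(pi / 2 * (1 - x[hi]) / taper_fraction)^2
  w
}

# FFT-based 'same' convolution of columns of sig (n x k) with each kernel;
# returns complex array k x n_freq x n  (series x frequency x time).
# Division by fs approximates the continuous-time integral.
tf_convolve <- function(sig, fam, freq_idx = seq_along(fam$f0_list)) {
  n <- nrow(sig); k <- ncol(sig)
  lens <- vapply(fam$kernels[freq_idx], length, 0L)
  N <- next_pow2(n + max(lens) - 1L)
  SIG <- stats::mvfft(rbind(sig, matrix(0, N - n, k)))
  out <- array(0 + 0i, c(k, length(freq_idx), n))
  for (j in seq_along(freq_idx)) {
    ker <- fam$kernels[[freq_idx[j]]]
    L <- length(ker)
    KER <- stats::fft(c(ker, rep(0 + 0i, N - L)))
    conv <- stats::mvfft(SIG * KER, inverse = TRUE) / N / fam$fs
    idx <- ((L - 1L) %/% 2L) + seq_len(n)   # centre-aligned 'same' slice
    out[, j, ] <- t(conv[idx, , drop = FALSE])
  }
  out
}

# per-frequency edge mask: TRUE where the estimate sits within 2 sigma_t of
# either epoch edge
edge_mask_matrix <- function(fam, freq_idx, times) {
  t0 <- times[1L]; t1 <- times[length(times)]
  mask <- matrix(FALSE, length(freq_idx), length(times))
  for (j in seq_along(freq_idx)) {
    w <- 2000 * fam$sigma_t[freq_idx[j]]     # 2 sigma_t in ms
    mask[j, ] <- (times - t0 < w) | (t1 - times < w)
  }
  mask
}

#' Single-trial time-frequency transform
#'
#' Convolves the cosine-square-tapered signal of every trial and channel
#' with each wavelet of the family (frequency-domain product with zero
#' padding, centre-aligned), returning the complex time-by-frequency
#' representation at full time resolution.  Estimates within
#' `2 sigma_t(f0)` of an epoch edge are flagged in `edge_mask` but kept.
#'
#' @param es an [epoch_set()]; its sampling rate must match the family's.
#' @param fam a [build_wavelet_family()].
#' @param taper_fraction per-edge taper fraction (default 0.1).
#' @param channels,freq_idx optional channel-name / frequency-index subsets.
#' @return an object of class `TFComplex`: `values` (complex array
#'   `trials x channels x frequencies x timepoints`), `freqs`, `times`,
#'   `channel_names`, `edge_mask`.
#' @export
tf_transform <- function(es, fam, taper_fraction = 0.1, channels = NULL,
                         freq_idx = seq_along(fam$f0_list)) {
  if (abs(es$fs - fam$fs) > 1e-9)
    stop_wavepls("sampling rates of EpochSet and WaveletFamily differ",
                 "wavepls_format_error")
  channels <- channels %||% es$channel_names
  ci <- channel_index(es, channels)
  n <- dim(es$data)[3L]
  # a kernel whose 2 sigma_t core spans the whole epoch leaves no usable
  # samples at that frequency
  core <- 4 * fam$sigma_t[freq_idx] * fam$fs
  if (any(core >= n))
    stop_wavepls(paste("wavelet support exceeds the epoch at the lowest",
                       "analysis frequencies: use longer epochs or a higher",
                       "f_min"), "wavepls_format_error")
  times <- epoch_times(es)
  n_ch <- length(ci)
  n_tr <- dim(es$data)[1L]
  w <- taper_window(n, taper_fraction)
  vals <- array(0 + 0i, c(n_tr, n_ch, length(freq_idx), n))
  for (c0 in seq_len(n_ch)) {
    sig <- t(es$data[, ci[c0], , drop = TRUE])
    if (n_tr == 1L) sig <- matrix(es$data[1L, ci[c0], ], ncol = 1L)
    tf <- tf_convolve(sig * w, fam, freq_idx)
    vals[, c0, , ] <- tf
  }
  structure(list(values = vals, freqs = fam$f0_list[freq_idx],
                 times = times, fs = fam$fs,
                 channel_names = channels,
                 edge_mask = edge_mask_matrix(fam, freq_idx, times)),
            class = "TFComplex")
}

#' @export
print.TFComplex <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "TFComplex: %d trials x %d channels x %d frequencies x %d timepoints\n",
    d[1L], d[2L], d[3L], d[4L]))
  invisible(x)
}

#' Trial-averaged spectral power (evolutionary spectrum)
#'
#' Mean over trials of the squared modulus of the complex time-frequency
#' values.
#'
#' @param tfc a [tf_transform()] result.
#' @param trial_subset optional integer/logical trial selection.
#' @return an object of class `TFPower`: `values`
#'   (`channels x frequencies x timepoints`, microvolt squared), axes as in
#'   `tfc`, `n_trials`, `baseline_applied = FALSE`.
#' @export
average_power <- function(tfc, trial_subset = NULL) {
  d <- dim(tfc$values)
  idx <- trial_subset %||% seq_len(d[1L])
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0L)
    stop_wavepls("empty trial subset", "wavepls_format_error")
  p <- Mod(tfc$values[idx, , , , drop = FALSE])^2
  vals <- colMeans(p, dims = 1L)       # channels x freq x time
  structure(list(values = vals, freqs = tfc$freqs, times = tfc$times,
                 channel_names = tfc$channel_names,
                 edge_mask = tfc$edge_mask, n_trials = length(idx),
                 baseline_applied = FALSE, baseline_window = NULL),
            class = "TFPower")
}

#' @export
print.TFPower <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("TFPower: %d channels x %d frequencies x %d timepoints (%d trials)%s\n",
              d[1L], d[2L], d[3L], x$n_trials,
              if (x$baseline_applied) ", baseline-corrected" else ""))
  invisible(x)
}

#' Subtract the pre-stimulus baseline mean
#'
#' For each channel and frequency, the mean power over the baseline window
#' (default 280 to 100 ms before stimulus onset, half-open
#' `[start, end)`) is subtracted from every timepoint.  Subtraction only;
#' no division or dB scaling.
#'
#' @param tp a [average_power()] result with `baseline_applied = FALSE`.
#' @param window `(start, end)` in ms.
#' @return the corrected `TFPower` (values may now be negative).
#' @export
baseline_correct <- function(tp, window = c(-280, -100)) {
  if (isTRUE(tp$baseline_applied))
    stop_wavepls("baseline correction already applied",
                 "wavepls_format_error")
  sel <- tp$times >= window[1L] & tp$times < window[2L]
  if (!any(sel))
    stop_wavepls("baseline window outside the epoch", "wavepls_format_error")
  base <- apply(tp$values[, , sel, drop = FALSE], c(1L, 2L), mean)
  tp$values <- tp$values - as.vector(base)   # recycles over the time dim
  tp$baseline_applied <- TRUE
  tp$baseline_window <- window
  tp
}
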