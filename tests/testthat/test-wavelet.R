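test_that("the default wavelet family matches its design parameters", {
  fam <- build_wavelet_family()
  expect_length(fam$f0_list, 73)               # 8..80 Hz at 1 Hz
  expect_equal(fam$sigma_f, fam$f0_list / 9)
  # unit energy within 1e-6, odd symmetric support
  energy <- vapply(fam$kernels, function(g) sum(Mod(g)^2) / fam$fs, 0)
  expect_true(all(abs(energy - 1) < 1e-6))
  expect_true(all(vapply(fam$kernels, length, 0L) %% 2 == 1))
  expect_error(build_wavelet_family(8, 300, 1, 9, 512), "Nyquist")
  expect_error(build_wavelet_family(0, 80, 1, 9, 512), "f_min")
  expect_error(build_wavelet_family(8, 80, 1, -2, 512), "m must be")
})

test_that("measured spectral width equals f0/m for every kernel", {
  fam <- build_wavelet_family()
  for (i in seq_along(fam$f0_list)) {
    ms <- measure_spectral_sigma(fam, i)
    expect_lt(abs(ms$sigma - fam$f0_list[i] / 9) / (fam$f0_list[i] / 9),
              0.02)
  }
  # 45 Hz kernel: sigma_f = 5 Hz
  i45 <- match(45, fam$f0_list)
  expect_equal(measure_spectral_sigma(fam, i45)$sigma, 5, tolerance = 0.02)
  # 10 Hz kernel: FFT second-moment oracle gives ~1.111 Hz
  i10 <- match(10, fam$f0_list)
  expect_equal(measure_spectral_sigma(fam, i10)$sigma, 10 / 9,
               tolerance = 0.02)
})

test_that("cosine-square taper endpoints, plateau and Hann limit", {
  s <- cosine_square_taper(rep(1, 100), 0.1)
  expect_equal(s[1], 0)
  expect_equal(s[100], 0)
  expect_true(all(s[20:80] == 1))              # plateau untouched
  # fraction 0.5 reproduces the full Hann window
  h <- cosine_square_taper(rep(1, 101), 0.5)
  expect_equal(h, sin(pi * (0:100) / 100)^2, tolerance = 1e-12)
  # |w| <= 1 so tapering never adds energy
  x <- rnorm(128)
  expect_lte(sum(cosine_square_taper(x, 0.2)^2), sum(x^2))
  expect_error(cosine_square_taper(x, 0), "taper_fraction")
  expect_error(cosine_square_taper(x, 0.6), "taper_fraction")
})

test_that("tf_transform recovers frequency, amplitude law and mixtures", {
  fam <- build_wavelet_family(8, 80, 1, 9, 512)
  tt <- (-300 + (0:511) * 1000 / 512) / 1000
  mk <- function(f, a = 1) {
    arr <- array(a * cos(2 * pi * f * tt), c(1, 1, 512))
    epoch_set(arr, 512, -300, "Cz")
  }
  centre <- tt * 1000 >= 0 & tt * 1000 < 400
  band_power <- function(es) {
    pw <- average_power(tf_transform(es, fam))
    apply(pw$values[1, , centre], 1, mean)
  }
  # pure 40 Hz sinusoid: power peak exactly at 40 Hz on the 1 Hz grid
  p40 <- band_power(mk(40))
  expect_equal(fam$f0_list[which.max(p40)], 40)
  # amplitude a -> power a^2 (ratio 4 within 1 percent)
  p40_2 <- band_power(mk(40, 2))
  expect_equal(p40_2[33] / p40[33], 4, tolerance = 0.01)
  # 20 + 60 Hz mixture: two distinct spectral bumps; with unit-energy
  # kernels the measured peak may sit one grid step low at high f0
  es_mix <- mk(20); es_mix$data[1, 1, ] <- cos(2 * pi * 20 * tt) +
    cos(2 * pi * 60 * tt)
  pmix <- band_power(es_mix)
  loc_max <- which(diff(sign(diff(pmix))) == -2) + 1
  expect_length(loc_max, 2)
  expect_true(all(abs(fam$f0_list[loc_max] - c(20, 60)) <= 1))
  # FFT cross-check oracle on the same signal: exact line frequencies
  spec <- (Mod(fft(as.vector(es_mix$data[1, 1, ])))^2)[1:256]
  fft_freqs <- 0:255
  expect_setequal(fft_freqs[order(spec, decreasing = TRUE)[1:2]], c(20, 60))
})

test_that("frequency recovery is exact in-band and near-exact above", {
  fam <- build_wavelet_family(8, 80, 1, 9, 512)
  tt <- (-300 + (0:511) * 1000 / 512) / 1000
  centre <- tt * 1000 >= -100 & tt * 1000 < 500
  peak_at <- function(f) {
    es <- epoch_set(array(cos(2 * pi * f * tt), c(1, 1, 512)), 512, -300, "A")
    pw <- average_power(tf_transform(es, fam))
    fam$f0_list[which.max(apply(pw$values[1, , centre], 1, mean))]
  }
  # exact on the grid through the alpha band and the centre of gamma
  for (f in c(12, 18, 25, 33, 41)) expect_equal(peak_at(f), f)
  # unit-energy normalization weights kernel spectra by 1/f0, so at higher
  # frequencies the peak may sit one grid step below the true frequency
  for (f in c(45, 58, 76)) expect_lte(abs(peak_at(f) - f), 1)
})

test_that("the impulse response width follows the time-frequency tradeoff", {
  fam <- build_wavelet_family(20, 60, 20, 9, 512)
  arr <- array(0, c(1, 1, 512)); arr[1, 1, 256] <- 1
  es <- epoch_set(arr, 512, -300, "A")
  tfc <- tf_transform(es, fam, taper_fraction = 0.5)
  tt <- epoch_times(es) / 1000
  for (j in seq_along(fam$f0_list)) {
    pw <- Mod(tfc$values[1, 1, j, ])^2
    w <- pw / sum(pw)
    mu <- sum(w * tt)
    sd_t <- sqrt(sum(w * (tt - mu)^2))
    # power envelope of a Gaussian kernel has std sigma_t / sqrt(2)
    expect_equal(sd_t, fam$sigma_t[j] / sqrt(2), tolerance = 0.05)
  }
})

test_that("average_power equals the brute-force trial mean", {
  set.seed(13)
  fam <- build_wavelet_family(30, 40, 5, 9, 512)
  es <- epoch_set(array(rnorm(8 * 2 * 512), c(8, 2, 512)), 512, -300,
                  c("A", "B"))
  tfc <- tf_transform(es, fam)
  pw <- average_power(tfc)
  manual <- array(0, dim(pw$values))
  for (i in 1:8) manual <- manual + Mod(tfc$values[i, , , ])^2 / 8
  expect_equal(pw$values, manual, tolerance = 1e-12)
  # single-trial subset is that trial's power; scaling check 2 trials
  p1 <- average_power(tfc, 1)
  expect_equal(p1$values, array(Mod(tfc$values[1, , , ])^2, dim(p1$values)),
               tolerance = 1e-12)
  expect_error(average_power(tfc, integer()), "empty")
})

test_that("baseline correction subtracts the [-280, -100) ms mean", {
  fam <- build_wavelet_family(40, 40, 1, 9, 512)
  es <- epoch_set(array(rnorm(2 * 1 * 512), c(2, 1, 512)), 512, -300, "A")
  pw <- average_power(tf_transform(es, fam))
  # index-arithmetic oracle: samples at t0 + k/fs in [-280, -100) ms
  tt <- epoch_times(es)
  expected_idx <- which(tt >= -280 & tt < -100)
  expect_length(expected_idx, 92)
  expect_identical(expected_idx, 12:103)       # k = 11..102 (0-based)
  bc <- baseline_correct(pw)
  base_mean <- mean(pw$values[1, 1, expected_idx])
  expect_equal(bc$values[1, 1, ], pw$values[1, 1, ] - base_mean)
  # constant map -> all zeros; arithmetic case
  pw2 <- pw; pw2$values[] <- 2
  pw2$values[1, 1, tt >= 0] <- 5
  bc2 <- baseline_correct(pw2)
  expect_equal(unique(as.vector(bc2$values[1, 1, tt >= 0])), 3)
  expect_error(baseline_correct(bc), "already applied")
  expect_error(baseline_correct(pw, c(-900, -800)), "outside")
})

test_that("kernels that swallow the whole epoch are refused", {
  fam <- build_wavelet_family(8, 20, 4, 9, 512)
  es <- epoch_set(array(rnorm(2 * 1 * 256), c(2, 1, 256)), 512, -300, "A")
  expect_error(tf_transform(es, fam), "f_min")
  # dropping the offending low frequencies makes it legal
  expect_s3_class(tf_transform(es, fam, freq_idx = 3:4), "TFComplex")
})

test_that("edge mask flags estimates within 2 sigma_t of the epoch edges", {
  fam <- build_wavelet_family(10, 40, 30, 9, 512)
  es <- epoch_set(array(rnorm(512), c(1, 1, 512)), 512, -300, "A")
  tfc <- tf_transform(es, fam)
  tt <- epoch_times(es)
  for (j in 1:2) {
    w <- 2000 * fam$sigma_t[j]
    expect_identical(tfc$edge_mask[j, ],
                     (tt - tt[1] < w) | (tt[512] - tt < w))
  }
  # gamma analysis window is unmasked even at the lowest gamma frequency
  fam_g <- build_wavelet_family(28, 50, 1, 9, 512)
  tfg <- tf_transform(es, fam_g)
  win <- tt >= 200 & tt < 400
  expect_false(any(tfg$edge_mask[1, win]))
})
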