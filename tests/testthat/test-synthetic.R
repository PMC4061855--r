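test_that("pink noise has the requested spectral slope and RMS", {
  # white-noise limit: periodogram slope ~ 0
  x0 <- pink_noise(100, 1, 512, exponent = 0, rms = 5, seed = 2)
  P0 <- rowMeans(sapply(1:100, function(i) Mod(stats::fft(x0[i, 1, ]))^2))
  s0 <- coef(lm(log(P0[2:256]) ~ log(1:255)))[2]
  expect_lt(abs(s0), 0.1)
  # 1/f: log-log periodogram regression oracle, slope -1 +/- 0.1
  x1 <- pink_noise(400, 1, 512, exponent = 1, rms = 10, seed = 3)
  P1 <- rowMeans(sapply(1:400, function(i) Mod(stats::fft(x1[i, 1, ]))^2))
  s1 <- coef(lm(log(P1[2:256]) ~ log(1:255)))[2]
  expect_lt(abs(s1 + 1), 0.1)
  # per-series RMS within 5 percent of requested
  rms <- sqrt(apply(x1^2, c(1, 2), mean))
  expect_true(all(abs(rms - 10) / 10 < 0.05))
  expect_error(pink_noise(2, 1, 64, 1, rms = 0), "positive")
  expect_error(pink_noise(2, 1, 64, 3, rms = 1), "0, 2")
})

test_that("pink noise is deterministic under a fixed seed", {
  a <- pink_noise(5, 3, 128, 1, 8, seed = 42)
  b <- pink_noise(5, 3, 128, 1, 8, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, pink_noise(5, 3, 128, 1, 8, seed = 43)))
})

test_that("von Mises sampler matches circular-statistics theory", {
  set.seed(1)
  # kappa = 0: uniform, resultant length near 0
  r0 <- Mod(mean(exp(1i * rvonmises(1e5, 0, 0))))
  expect_lt(r0, 3 / sqrt(1e5) * 3)
  # kappa = 2: resultant length -> I1(2)/I0(2) (Bessel-ratio oracle)
  th <- rvonmises(2e5, 0, 2)
  expect_lt(abs(Mod(mean(exp(1i * th))) - besselI(2, 1) / besselI(2, 0)),
            0.01)
  expect_lt(abs(mean(sin(th))), 0.01)          # mean direction 0
  # very large kappa: tight lock
  expect_lt(max(abs(rvonmises(100, 0, 1e9))), 1e-3)
  expect_error(rvonmises(5, 0, -1), "kappa")
})

test_that("injected oscillations carry the stated amplitude and coupling", {
  tt <- -300 + (0:511) * 1000 / 512
  dat <- array(0, c(200, 2, 512))
  spec <- oscillation_spec("gamma", 40, 2.5, c(200, 400), kappa = 1e9,
                           target_channels = "B", reference_channel = "A")
  out <- inject_oscillation(dat, spec, c("A", "B"), tt, seed = 5)
  # amplitude exactly spec$amplitude at window centre (envelope = 1 there)
  centre <- which(tt >= 250 & tt < 350)
  env_amp <- apply(out[, 1, centre], 1, function(v) max(abs(v)))
  expect_true(all(abs(env_amp - 2.5) < 0.05))
  # outside the window: silence
  expect_true(all(out[, , tt < 200 | tt >= 400][, , 1:10] == 0))
  # kappa -> infinity: target tracks the reference within each trial
  expect_lt(max(abs(out[, 1, centre] - out[, 2, centre])), 0.02)
  expect_error(
    inject_oscillation(dat, spec, c("A", "X"), tt), "absent")
})

test_that("oscillation energy adds monotonically in amplitude", {
  tt <- -300 + (0:511) * 1000 / 512
  fam <- build_wavelet_family(38, 42, 1, 9, 512)
  pows <- sapply(c(0, 1, 2, 4), function(a) {
    base <- pink_noise(30, 1, 512, 1, 5, seed = 9)
    spec <- oscillation_spec("gamma", 40, a, c(200, 400), 2,
                             target_channels = character(),
                             reference_channel = "A")
    dat <- inject_oscillation(base, spec, "A", tt, seed = 10)
    es <- epoch_set(dat, 512, -300, "A")
    pw <- average_power(tf_transform(es, fam))
    mean(extract_band_mean(pw, band_window("gamma", f_range = c(38, 42))))
  })
  expect_true(all(diff(pows) > 0))
})

test_that("oddball blocks have the paradigm's trial structure", {
  des <- tiny_design()
  es <- generate_block(des, 1, "English", "pre", 1,
                       channels = c("Fz", "FCz", "Cz", "M2"))
  expect_equal(n_trials(es), 9)
  expect_equal(sum(es$trial_labels$condition == "deviant"), 3)
  # block 1 of the crossed layout: standards low-falling, deviants high-rising
  expect_setequal(unique(es$trial_labels$tone[es$trial_labels$condition ==
                                                "standard"]), "low-falling")
  expect_setequal(unique(es$trial_labels$tone[es$trial_labels$condition ==
                                                "deviant"]), "high-rising")
  expect_error(generate_block(des, 1, "French", "pre", 1), "unknown group")
  expect_error(generate_block(des, 1, "English", "mid", 1), "unknown session")
  # determinism
  e1 <- generate_block(des, 2, "Chinese", "post", 2, channels = c("Cz", "M2"))
  e2 <- generate_block(des, 2, "Chinese", "post", 2, channels = c("Cz", "M2"))
  expect_identical(e1$data, e2$data)
  expect_identical(e1$trial_labels, e2$trial_labels)
})

test_that("artifact contamination is recovered by the rejection filter", {
  des <- study_design(groups = c(Chinese = 1), standards_per_block = 360,
                      deviants_per_block = 40, blocks = blocks_crossed(),
                      artifact_rate = 0.24, seed = 6)
  es <- generate_block(des, 1, "Chinese", "pre", 1,
                       channels = c("Fz", "Cz", "Pz", "M2"))
  es <- reject_artifacts(es, 150)
  expect_equal(mean(es$reject_mask), 0.24, tolerance = 0.02)
  # artifact_rate 0 -> nothing masked at the default threshold
  des0 <- tiny_design()
  es0 <- reject_artifacts(generate_block(des0, 1, "English", "pre", 1,
                                         channels = c("Fz", "Cz", "M2")), 150)
  expect_false(any(es0$reject_mask))
})

test_that("generate_study yields one epoch set per subject and session", {
  des <- study_design(groups = c(English = 10, Chinese = 10, Thai = 11),
                      standards_per_block = 4, deviants_per_block = 2,
                      blocks = blocks_crossed(), artifact_rate = 0, seed = 12)
  study <- generate_study(des, channels = c("Cz", "FCz", "M2"))
  expect_length(study$epochs, 31 * 2)
  sess <- sub(".*\\.", "", names(study$epochs))
  expect_equal(sum(sess == "pre"), 31)
  expect_equal(sum(sess == "post"), 31)
  gt <- study$ground_truth
  # one ground-truth row per subject x session x tone x condition x band
  expect_equal(nrow(gt), 31 * 2 * 2 * 2 * 2)
  expect_true(all(c("amplitude", "kappa", "subject_factor") %in% names(gt)))
  # English post-training gamma amplitude raised relative to pre
  g <- gt[gt$band == "gamma" & gt$group == "English", ]
  expect_gt(mean(g$amplitude[g$session == "post"]),
            mean(g$amplitude[g$session == "pre"]))
  ch <- gt[gt$band == "gamma" & gt$group == "Chinese", ]
  expect_equal(mean(ch$amplitude[ch$session == "post"]),
               mean(ch$amplitude[ch$session == "pre"]))
})

test_that("a design with uniform amplitudes produces a flat ground truth", {
  des <- tiny_design(groups = c(English = 1, Thai = 1))
  des$effects <- des$effects[0, ]
  des$subject_sd_log <- 0
  gt <- generate_study(des, channels = c("Cz", "FCz", "M2"))$ground_truth
  expect_equal(length(unique(gt$amplitude[gt$band == "gamma"])), 1L)
  expect_equal(length(unique(gt$amplitude[gt$band == "alpha"])), 1L)
})
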