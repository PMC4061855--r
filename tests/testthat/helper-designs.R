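# shared fixtures: small designs and epoch builders, all generated in code

# two-block layout in which each analysed tone occurs as standard and deviant
blocks_crossed <- function() {
  data.frame(standard_tone = c("low-falling", "high-rising"),
             deviant_tone  = c("high-rising", "low-falling"),
             stringsAsFactors = FALSE)
}

tiny_design <- function(groups = c(English = 2, Chinese = 2),
                        standards = 6, deviants = 3, seed = 11, ...) {
  study_design(groups = groups, standards_per_block = standards,
               deviants_per_block = deviants, blocks = blocks_crossed(),
               artifact_rate = 0, seed = seed, ...)
}

# epoch set with deterministic sinusoidal content on named channels
sine_epochs <- function(n_trials, channels, freq = 40, amp = 1,
                        phase_fun = NULL, fs = 512, n = 512, t0 = -300,
                        labels = NULL) {
  tt <- (t0 + (seq_len(n) - 1) * 1000 / fs) / 1000
  arr <- array(0, c(n_trials, length(channels), n))
  for (i in seq_len(n_trials)) {
    for (j in seq_along(channels)) {
      ph <- if (is.null(phase_fun)) 0 else phase_fun(i, j)
      arr[i, j, ] <- amp * cos(2 * pi * freq * tt + ph)
    }
  }
  epoch_set(arr, fs = fs, t0 = t0, channel_names = channels,
            trial_labels = labels)
}

# TFComplex built directly from per-trial unit phasors (one freq, few times)
phasor_tfc <- function(phases_by_channel, times = c(0, 10), freq = 40) {
  n_tr <- nrow(phases_by_channel[[1]])
  n_ch <- length(phases_by_channel)
  vals <- array(0 + 0i, c(n_tr, n_ch, 1L, length(times)))
  for (j in seq_len(n_ch))
    for (k in seq_along(times))
      vals[, j, 1L, k] <- exp(1i * phases_by_channel[[j]][, k])
  structure(list(values = vals, freqs = freq, times = times, fs = 512,
                 channel_names = names(phases_by_channel),
                 edge_mask = matrix(FALSE, 1L, length(times))),
            class = "TFComplex")
}
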