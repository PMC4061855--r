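#' 1/f background noise
#'
#' Spectral-synthesis pink noise: random-phase Gaussian spectrum with
#' amplitude proportional to `f^(-exponent/2)`, inverse-transformed and
#' scaled per series to the requested RMS.  `exponent = 0` gives white
#' noise; `exponent = 1` the classic 1/f EEG background stand-in.
#'
#' @param n_trials,n_channels,n_samples output dimensions.
#' @param exponent spectral exponent in `[0, 2]`.
#' @param rms per-channel root-mean-square amplitude (microvolt).
#' @param seed optional integer seed.
#' @return numeric array `n_trials x n_channels x n_samples`.
#' @export
pink_noise <- function(n_trials, n_channels, n_samples, exponent = 1,
                       rms = 10, seed = NULL) {
  if (rms <= 0) stop_wavepls("rms must be positive", "wavepls_format_error")
  if (exponent < 0 || exponent > 2)
    stop_wavepls("exponent must lie in [0, 2]", "wavepls_format_error")
  with_seed(seed, {
    n_series <- n_trials * n_channels
    half <- n_samples %/% 2L
    k <- seq_len(half)                      # positive-frequency bins
    amp <- k^(-exponent / 2)
    out <- matrix(0, n_samples, n_series)
    # build Hermitian spectra in blocks to bound memory
    block <- max(1L, min(n_series, floor(2e6 / n_samples)))
    i0 <- 1L
    while (i0 <= n_series) {
      i1 <- min(n_series, i0 + block - 1L)
      nb <- i1 - i0 + 1L
      z <- matrix(complex(real = stats::rnorm(half * nb),
                          imaginary = stats::rnorm(half * nb)),
                  half, nb) * amp
      spec <- matrix(0 + 0i, n_samples, nb)
      spec[1L + k, ] <- z
      # Hermitian mirror for a real signal (Nyquist bin made real)
      spec[n_samples + 1L - k[k < half | n_samples %% 2L == 1L], ] <-
        Conj(z[k[k < half | n_samples %% 2L == 1L], ])
      if (n_samples %% 2L == 0L) spec[half + 1L, ] <- Re(z[half, ])
      x <- Re(stats::mvfft(spec, inverse = TRUE)) / n_samples
      sd_x <- sqrt(colMeans(x^2))
      sd_x[sd_x == 0] <- 1
      out[, i0:i1] <- sweep(x, 2L, rms / sd_x, "*")
      i0 <- i1 + 1L
    }
    aperm(array(out, c(n_samples, n_trials, n_channels)), c(2L, 3L, 1L))
  })
}

#' Von Mises random deviates
#'
#' Best-Fisher rejection sampler; `kappa = 0` returns uniform angles, very
#' large `kappa` (> 1e6) falls back to the wrapped-normal limit
#' `N(mu, 1/kappa)`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, `>= 0`.
#' @return angles in `(-pi, pi]` (plus `mu`).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop_wavepls("kappa must be >= 0", "wavepls_format_error")
  if (n == 0L) return(numeric())
  if (kappa < 1e-9) return(stats::runif(n, -pi, pi) + mu)
  if (kappa > 1e6) {
    th <- stats::rnorm(n, 0, 1 / sqrt(kappa))
    return(((th + mu + pi) %% (2 * pi)) - pi)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  ((out[seq_len(n)] + mu + pi) %% (2 * pi)) - pi
}

#' Specification of one injected oscillation
#'
#' Describes a band-limited oscillatory component added to synthetic
#' epochs: a windowed sinusoid with trialwise random phase on a reference
#' channel and von Mises phase jitter (concentration `kappa`) on the target
#' channels, so the expected phase-locking statistic against the reference
#' is the Bessel ratio `I1(kappa)/I0(kappa)`.
#'
#' @param band `"alpha"` or `"gamma"` (bookkeeping only).
#' @param center_freq oscillation frequency, Hz.
#' @param amplitude peak amplitude at window centre, microvolt; `>= 0`.
#' @param window `(start, end)` ms relative to stimulus onset.
#' @param kappa von Mises concentration of the trialwise phase offset
#'   between target and reference channels; `>= 0` (0 = no coupling).
#' @param target_channels channels receiving the jittered oscillation.
#' @param reference_channel channel carrying the reference phase.
#' @param ramp_ms cosine-squared on/off ramp inside the window (default 50).
#' @return an object of class `OscillationSpec`.
#' @export
oscillation_spec <- function(band, center_freq, amplitude, window, kappa,
                             target_channels, reference_channel,
                             ramp_ms = 50) {
  stopifnot(band %in% c("alpha", "gamma"), length(window) == 2L)
  if (amplitude < 0) stop_wavepls("amplitude must be >= 0", "wavepls_format_error")
  if (kappa < 0) stop_wavepls("kappa must be >= 0", "wavepls_format_error")
  structure(list(band = band, center_freq = center_freq,
                 amplitude = amplitude, window = window, kappa = kappa,
                 target_channels = target_channels,
                 reference_channel = reference_channel, ramp_ms = ramp_ms),
            class = "OscillationSpec")
}

oscillation_envelope <- function(times, window, ramp_ms) {
  env <- numeric(length(times))
  inside <- times >= window[1L] & times < window[2L]
  env[inside] <- 1
  if (ramp_ms > 0) {
    up <- inside & times < window[1L] + ramp_ms
    env[up] <- cos(pi / 2 * (window[1L] + ramp_ms - times[up]) / ramp_ms)^2
    down <- inside & times >= window[2L] - ramp_ms
    env[down] <- cos(pi / 2 * (times[down] - (window[2L] - ramp_ms)) / ramp_ms)^2
  }
  env
}

#' Add a phase-coupled oscillation to epoch data
#'
#' Adds `amplitude * envelope(t) * cos(2 pi f t + phi_trial + delta)` where
#' `phi_trial` is uniform per trial on the reference channel and `delta` is
#' an independent von Mises(0, kappa) draw per trial and target channel.
#' The envelope is 1 over the window except for `ramp_ms` cosine-squared
#' ramps, so the amplitude at the window centre is exactly `amplitude`.
#'
#' @param data numeric array `trials x channels x samples`.
#' @param spec an [oscillation_spec()].
#' @param channel_names channel labels for the second dimension.
#' @param times epoch time axis in ms (length = third dimension).
#' @param seed optional integer seed.
#' @return the array with the oscillation added.
#' @export
inject_oscillation <- function(data, spec, channel_names, times,
                               seed = NULL) {
  chs <- unique(c(spec$reference_channel, spec$target_channels))
  ci <- match(chs, channel_names)
  if (anyNA(ci))
    stop_wavepls(paste("target/reference channel absent:",
                       paste(chs[is.na(ci)], collapse = ", ")),
                 "wavepls_channel_error")
  if (spec$window[1L] < times[1L] || spec$window[2L] > times[length(times)] + 1e-9)
    stop_wavepls("oscillation window outside epoch span",
                 "wavepls_format_error")
  n_tr <- dim(data)[1L]
  env <- oscillation_envelope(times, spec$window, spec$ramp_ms)
  carrier <- 2 * pi * spec$center_freq * times / 1000
  with_seed(seed, {
    phi <- stats::runif(n_tr, -pi, pi)
    for (ch in chs) {
      j <- match(ch, channel_names)
      delta <- if (ch == spec$reference_channel) 0 else
        rvonmises(n_tr, 0, spec$kappa)
      # outer(trial phase, carrier) -> trials x samples
      wave <- spec$amplitude *
        cos(outer(phi + delta, carrier, "+")) *
        rep(env, each = n_tr)
      data[, j, ] <- data[, j, ] + wave
    }
    data
  })
}

#' Study design for the synthetic oddball experiment
#'
#' Encodes the paradigm (oddball blocks of standards and deviants over
#' pre/post sessions for several language groups), the background-noise
#' model, artifact contamination, the base alpha/gamma oscillations, and a
#' multiplicative effects table that makes amplitude or phase coupling
#' depend on group, session, tone or condition.
#'
#' @param groups named integer vector of subjects per group, e.g.
#'   `c(English = 10, Chinese = 10, Thai = 11)`.
#' @param standards_per_block,deviants_per_block trials per oddball block
#'   (defaults 1080 and 120, a 10 percent deviant rate).
#' @param blocks data frame with columns `standard_tone`, `deviant_tone`;
#'   default: mid-level standards with low-falling deviants, the reverse,
#'   and the same pair with high-rising tones (4 blocks), so each analysed
#'   tone occurs both as standard and as deviant.
#' @param noise_exponent,noise_rms 1/f background parameters.
#' @param artifact_rate fraction of contaminated trials; either a single
#'   number or a named vector per group (default the per-group rejection
#'   fractions 0.18/0.24/0.26 for English/Chinese/Thai).
#' @param artifact_amp_uv spike amplitude used to contaminate trials.
#' @param alpha,gamma base [oscillation_spec()]s (defaults: 10 Hz, 100-500
#'   ms, reference Cz; 40 Hz, 200-400 ms, reference FCz).
#' @param effects data frame of multiplicative modifiers with columns
#'   `band, group, session, tone, condition, amp_scale, kappa_scale` where
#'   `"*"` matches anything; rows apply cumulatively.
#' @param subject_sd_log lognormal SD of a per-subject amplitude scaling
#'   (stable across sessions), giving between-subject variability.
#' @param montage the recording [montage()].
#' @param seed master seed; every subject/session/block derives its own
#'   seed from it via [child_seed()].
#' @return an object of class `StudyDesign`.
#' @export
study_design <- function(groups = c(English = 10, Chinese = 10, Thai = 11),
                         standards_per_block = 1080,
                         deviants_per_block = 120,
                         blocks = default_blocks(),
                         noise_exponent = 1, noise_rms = 10,
                         artifact_rate = c(English = 0.18, Chinese = 0.24,
                                           Thai = 0.26),
                         artifact_amp_uv = 400,
                         alpha = NULL, gamma = NULL,
                         effects = default_effects(),
                         subject_sd_log = 0.15,
                         montage = default_montage(),
                         seed = 1L) {
  if (any(groups <= 0)) stop_wavepls("subject counts must be positive",
                                     "wavepls_format_error")
  lat <- unlist(montage$lateral_regions, use.names = FALSE)
  if (is.null(alpha))
    alpha <- oscillation_spec("alpha", 10, 6, c(100, 500), 1,
                              target_channels = setdiff(analysis_channels(montage), "Cz"),
                              reference_channel = "Cz")
  if (is.null(gamma))
    gamma <- oscillation_spec("gamma", 40, 3, c(200, 400), 1,
                              target_channels = setdiff(analysis_channels(montage), "FCz"),
                              reference_channel = "FCz")
  structure(list(groups = groups, sessions = c("pre", "post"),
                 standards_per_block = standards_per_block,
                 deviants_per_block = deviants_per_block,
                 blocks = blocks,
                 noise_exponent = noise_exponent, noise_rms = noise_rms,
                 artifact_rate = artifact_rate,
                 artifact_amp_uv = artifact_amp_uv,
                 alpha = alpha, gamma = gamma, effects = effects,
                 subject_sd_log = subject_sd_log,
                 montage = montage, seed = seed),
            class = "StudyDesign")
}

#' Default oddball block layout (four blocks)
#' @return data frame with `standard_tone` / `deviant_tone` per block.
#' @export
default_blocks <- function() {
  data.frame(
    standard_tone = c("mid-level", "low-falling", "mid-level", "high-rising"),
    deviant_tone  = c("low-falling", "mid-level", "high-rising", "mid-level"),
    stringsAsFactors = FALSE)
}

#' Default group/session/condition effect table
#'
#' Illustrative effect structure mirroring the qualitative training
#' patterns the analyses are meant to recover: deviants carry somewhat
#' stronger oscillatory responses than standards; after training, gamma
#' amplitude rises for the English group (1.5x) but not the Chinese, rises
#' mildly for the Thai; alpha amplitude falls post-training for English and
#' Chinese; phase coupling (kappa) strengthens post-training in both bands.
#' These are generator settings, not estimates of any real data set.
#'
#' @return data frame consumed by [study_design()].
#' @export
default_effects <- function() {
  e <- function(band, group, session, tone, condition, amp, kap)
    data.frame(band = band, group = group, session = session, tone = tone,
               condition = condition, amp_scale = amp, kappa_scale = kap,
               stringsAsFactors = FALSE)
  rbind(
    e("gamma", "*", "*", "*", "deviant", 1.3, 1.0),
    e("alpha", "*", "*", "*", "deviant", 1.2, 1.0),
    e("gamma", "English", "post", "*", "*", 1.5, 1.5),
    e("gamma", "Thai",    "post", "*", "*", 1.2, 1.0),
    e("alpha", "English", "post", "*", "*", 0.8, 2.0),
    e("alpha", "Chinese", "post", "*", "*", 0.8, 1.5),
    e("alpha", "Thai",    "post", "*", "*", 1.0, 2.0)
  )
}

# resolve the base spec for (group, session, tone, condition), applying the
# effects table cumulatively and a per-subject amplitude factor
resolve_spec <- function(design, band, group, session, tone, condition,
                         subject_factor = 1) {
  spec <- design[[band]]
  eff <- design$effects
  if (!is.null(eff) && nrow(eff)) {
    hit <- (eff$band == band) &
      (eff$group == "*" | eff$group == group) &
      (eff$session == "*" | eff$session == session) &
      (eff$tone == "*" | eff$tone == tone) &
      (eff$condition == "*" | eff$condition == condition)
    for (i in which(hit)) {
      spec$amplitude <- spec$amplitude * eff$amp_scale[i]
      spec$kappa <- spec$kappa * eff$kappa_scale[i]
    }
  }
  spec$amplitude <- spec$amplitude * subject_factor
  spec
}

subject_amp_factor <- function(design, subject_id) {
  if (design$subject_sd_log <= 0) return(1)
  with_seed(child_seed(design$seed, 777L, subject_id),
            exp(stats::rnorm(1L, 0, design$subject_sd_log)))
}

#' Generate one oddball block of synthetic EEG
#'
#' Pink-noise background on every recorded channel, alpha and gamma
#' oscillations injected per the design's resolved cell specifications, and
#' a fraction `artifact_rate` of trials contaminated with a super-threshold
#' square spike on one random channel.  Deviant positions are randomised
#' within the block.
#'
#' @param design a [study_design()].
#' @param subject integer subject index within its group.
#' @param group group name.
#' @param session `"pre"` or `"post"`.
#' @param block block number (row of `design$blocks`).
#' @param seed optional; defaults to a [child_seed()] of the design seed.
#' @param fs,t0,n_samples epoch geometry (defaults 512 Hz, -300 ms, 512
#'   samples, i.e. -300..700 ms).
#' @param channels optional subset of the montage's recorded channels to
#'   generate (keeps scaled simulation studies cheap); oscillation targets
#'   are intersected with it.
#' @return an [epoch_set()] with full trial labels.
#' @export
generate_block <- function(design, subject, group, session, block,
                           seed = NULL, fs = 512, t0 = -300,
                           n_samples = 512, channels = NULL) {
  if (!group %in% names(design$groups))
    stop_wavepls(paste("unknown group:", group), "wavepls_label_error")
  if (!session %in% design$sessions)
    stop_wavepls(paste("unknown session:", session), "wavepls_label_error")
  gi <- match(group, names(design$groups))
  si <- match(session, design$sessions)
  subj_id <- gi * 1000L + subject
  if (is.null(seed))
    seed <- child_seed(design$seed, gi, subject, si, block)
  chans <- recorded_channels(design$montage)
  if (!is.null(channels)) {
    bad <- setdiff(channels, chans)
    if (length(bad))
      stop_wavepls(paste("channels not in montage:",
                         paste(bad, collapse = ", ")),
                   "wavepls_channel_error")
    chans <- intersect(chans, channels)
  }
  n_std <- design$standards_per_block
  n_dev <- design$deviants_per_block
  n_tr <- n_std + n_dev
  times <- t0 + (seq_len(n_samples) - 1L) * 1000 / fs
  bl <- design$blocks[block, ]
  subj_fac <- subject_amp_factor(design, subj_id)
  with_seed(seed, {
    data <- pink_noise(n_tr, length(chans), n_samples,
                       design$noise_exponent, design$noise_rms)
    dev_pos <- sort(sample.int(n_tr, n_dev))
    condition <- rep("standard", n_tr)
    condition[dev_pos] <- "deviant"
    tone <- ifelse(condition == "deviant", bl$deviant_tone, bl$standard_tone)
    for (cond in c("standard", "deviant")) {
      tr <- which(condition == cond)
      if (!length(tr)) next
      tn <- tone[tr[1L]]
      for (band in c("alpha", "gamma")) {
        spec <- resolve_spec(design, band, group, session, tn, cond, subj_fac)
        if (spec$amplitude <= 0) next
        spec$target_channels <- intersect(spec$target_channels, chans)
        if (!(spec$reference_channel %in% chans)) next
        data[tr, , ] <- inject_oscillation(
          data[tr, , , drop = FALSE], spec, chans, times)
      }
    }
    rate <- design$artifact_rate
    if (!is.null(names(rate))) rate <- unname(rate[group])
    if (is.na(rate)) rate <- 0
    n_bad <- round(rate * n_tr)
    if (n_bad > 0) {
      bad <- sample.int(n_tr, n_bad)
      cand <- which(chans %in% analysis_channels(design$montage))
      if (!length(cand)) cand <- seq_along(chans)
      spike_ch <- cand[sample.int(length(cand), n_bad, replace = TRUE)]
      k0 <- sample.int(n_samples - 12L, n_bad)
      for (i in seq_len(n_bad))
        data[bad[i], spike_ch[i], k0[i] + 0:11] <-
          data[bad[i], spike_ch[i], k0[i] + 0:11] + design$artifact_amp_uv
    }
    labels <- data.frame(trial = seq_len(n_tr), tone = tone,
                         condition = condition, block = block,
                         session = session, subject = subj_id,
                         group = group, stringsAsFactors = FALSE)
    epoch_set(data, fs = fs, t0 = t0, channel_names = chans,
              trial_labels = labels)
  })
}

#' Generate a whole study and its ground-truth table
#'
#' One [epoch_set()] per subject x session (all blocks concatenated), plus
#' a table of the true per-cell oscillation amplitude and kappa after all
#' design effects (excluding the per-subject lognormal factor, which is
#' listed separately).
#'
#' @param design a [study_design()].
#' @param fs,t0,n_samples,channels epoch geometry and optional channel
#'   subset, as in [generate_block()].
#' @return list with elements `epochs` (named list
#'   `"<group><subject>.<session>"` of `EpochSet`s), `ground_truth`
#'   (data frame) and `design`.
#' @export
generate_study <- function(design, fs = 512, t0 = -300, n_samples = 512,
                           channels = NULL) {
  epochs <- list()
  gt <- list()
  for (gi in seq_along(design$groups)) {
    group <- names(design$groups)[gi]
    for (subject in seq_len(design$groups[[gi]])) {
      subj_id <- gi * 1000L + subject
      fac <- subject_amp_factor(design, subj_id)
      for (si in seq_along(design$sessions)) {
        session <- design$sessions[si]
        parts <- lapply(seq_len(nrow(design$blocks)), function(b)
          generate_block(design, subject, group, session, b,
                         fs = fs, t0 = t0, n_samples = n_samples,
                         channels = channels))
        epochs[[paste0(group, subject, ".", session)]] <- bind_epochs(parts)
        for (band in c("alpha", "gamma"))
          for (tone in c("low-falling", "high-rising"))
            for (cond in c("standard", "deviant")) {
              sp <- resolve_spec(design, band, group, session, tone, cond)
              gt[[length(gt) + 1L]] <- data.frame(
                group = group, subject = subj_id, session = session,
                tone = tone, condition = cond, band = band,
                amplitude = sp$amplitude, kappa = sp$kappa,
                subject_factor = fac, stringsAsFactors = FALSE)
            }
      }
    }
  }
  list(epochs = epochs, ground_truth = do.call(rbind, gt), design = design)
}

#' Concatenate EpochSets trial-wise
#' @param sets list of [epoch_set()]s sharing fs, t0 and channels.
#' @return one combined `EpochSet`.
#' @export
bind_epochs <- function(sets) {
  if (length(sets) == 1L) return(sets[[1L]])
  e1 <- sets[[1L]]
  for (s in sets[-1L])
    if (!identical(s$channel_names, e1$channel_names) ||
        s$fs != e1$fs || s$t0 != e1$t0)
      stop_wavepls("EpochSets differ in channels, fs or t0",
                   "wavepls_format_error")
  n <- sum(vapply(sets, n_trials, 0L))
  d <- dim(e1$data)
  data <- array(0, c(n, d[2L], d[3L]))
  at <- 1L
  for (s in sets) {
    k <- n_trials(s)
    data[at:(at + k - 1L), , ] <- s$data
    at <- at + k
  }
  labs <- do.call(rbind, lapply(sets, function(s) s$trial_labels))
  labs$trial <- seq_len(n)
  epoch_set(data, fs = e1$fs, t0 = e1$t0, channel_names = e1$channel_names,
            trial_labels = labs,
            reject_mask = unlist(lapply(sets, function(s) s$reject_mask)))
}
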