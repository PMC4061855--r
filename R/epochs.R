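#' Epoched multi-channel EEG
#'
#' The central data container: a `trials x channels x samples` array of
#' voltages in microvolt, with the sampling rate, the time of the first
#' sample relative to stimulus onset, ordered channel labels, one record of
#' factor labels per trial, and a per-trial artifact mask.
#'
#' The epoch time axis is `t0 + k * 1000/fs` ms for `k = 0 .. n_samples-1`
#' (half-open convention: an epoch of -300..700 ms at 512 Hz has exactly 512
#' samples, the last one at 698.05 ms).
#'
#' @param data numeric array `trials x channels x samples`, microvolt.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample relative to stimulus onset, ms
#'   (negative = pre-stimulus).
#' @param channel_names character, one label per channel.
#' @param trial_labels data frame with one row per trial; columns among
#'   `trial, tone, condition, block, session, subject, group` (missing
#'   columns are filled with `NA`).
#' @param reject_mask logical per trial, `TRUE` = artifact-contaminated.
#' @return an object of class `EpochSet`.
#' @export
epoch_set <- function(data, fs, t0 = -300, channel_names,
                      trial_labels = NULL, reject_mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_wavepls("data must be a trials x channels x samples array",
                 "wavepls_format_error")
  d <- dim(data)
  if (length(channel_names) != d[2L])
    stop_wavepls("channel_names length does not match channel dimension",
                 "wavepls_format_error")
  if (anyDuplicated(channel_names))
    stop_wavepls("duplicate channel names", "wavepls_format_error")
  if (is.null(trial_labels)) trial_labels <- data.frame(trial = seq_len(d[1L]))
  if (nrow(trial_labels) != d[1L])
    stop_wavepls("trial_labels must have one row per trial",
                 "wavepls_label_error")
  for (col in c("trial", "tone", "condition", "block", "session",
                "subject", "group"))
    if (is.null(trial_labels[[col]]))
      trial_labels[[col]] <- if (col == "trial") seq_len(d[1L]) else NA
  check_vocab(trial_labels$tone, c("low-falling", "mid-level", "high-rising"),
              "tone")
  check_vocab(trial_labels$condition, c("standard", "deviant"), "condition")
  check_vocab(trial_labels$session, c("pre", "post"), "session")
  if (is.null(reject_mask)) reject_mask <- rep(FALSE, d[1L])
  if (length(reject_mask) != d[1L])
    stop_wavepls("reject_mask must have one entry per trial",
                 "wavepls_format_error")
  dimnames(data) <- list(NULL, channel_names, NULL)
  structure(list(data = data, fs = fs, t0 = t0,
                 channel_names = as.character(channel_names),
                 trial_labels = trial_labels,
                 reject_mask = as.logical(reject_mask)),
            class = "EpochSet")
}

check_vocab <- function(x, vocab, what) {
  bad <- !is.na(x) & !(x %in% vocab)
  if (any(bad))
    stop_wavepls(sprintf("invalid %s label(s): %s", what,
                         paste(unique(x[bad]), collapse = ", ")),
                 "wavepls_label_error")
  invisible(TRUE)
}

#' Epoch time axis in milliseconds
#' @param es an [epoch_set()].
#' @return numeric vector, one time per sample.
#' @export
epoch_times <- function(es) {
  es$t0 + (seq_len(dim(es$data)[3L]) - 1L) * 1000 / es$fs
}

#' @export
print.EpochSet <- function(x, ...) {
  d <- dim(x$data)
  tt <- epoch_times(x)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  time axis %.1f .. %.1f ms; %d trials masked as artifacts\n",
              tt[1L], tt[length(tt)], sum(x$reject_mask)))
  invisible(x)
}

#' @export
summary.EpochSet <- function(object, ...) {
  print(object)
  lab <- object$trial_labels
  keep <- !object$reject_mask
  if (!all(is.na(lab$tone))) {
    cat("  artifact-free trials per tone x condition:\n")
    print(table(tone = lab$tone[keep], condition = lab$condition[keep]))
  }
  invisible(object)
}

#' Number of trials in an EpochSet
#' @param es an [epoch_set()].
#' @return integer trial count.
#' @export
n_trials <- function(es) dim(es$data)[1L]

channel_index <- function(es, ch) {
  i <- match(ch, es$channel_names)
  if (anyNA(i))
    stop_wavepls(paste("channel(s) not present:",
                       paste(ch[is.na(i)], collapse = ", ")),
                 "wavepls_channel_error")
  i
}

#' Re-reference a left-mastoid-referenced recording to averaged mastoids
#'
#' Recordings referenced to the left mastoid are arithmetically
#' re-referenced to the mean of the two mastoids.  With the left mastoid as
#' the implicit zero channel this amounts to subtracting half the right
#' mastoid from every channel.  The mastoid channels are excluded from the
#' downstream analysis set (recorded in `attr(, "excluded_channels")`).
#'
#' @param es an [epoch_set()] referenced to the left mastoid.
#' @param montage a [montage()]; its second mastoid label must be a channel
#'   of `es`.
#' @return the re-referenced `EpochSet`.
#' @export
rereference_to_average_mastoids <- function(es, montage = default_montage()) {
  rm_ch <- montage$mastoids[2L]
  ri <- match(rm_ch, es$channel_names)
  if (is.na(ri))
    stop_wavepls(sprintf("right mastoid channel '%s' missing", rm_ch),
                 "wavepls_channel_error")
  half <- es$data[, ri, , drop = FALSE] / 2
  es$data <- es$data - half[, rep(1L, dim(es$data)[2L]), , drop = FALSE]
  attr(es, "reference") <- "average_mastoids"
  attr(es, "excluded_channels") <- intersect(montage$mastoids, es$channel_names)
  es
}

#' Mask trials whose peak-to-peak amplitude exceeds a threshold
#'
#' Artifact screening by peak-to-peak amplitude: a trial is masked when the
#' max-minus-min voltage on any analysis channel exceeds the threshold.  The
#' data themselves are left untouched; only `reject_mask` is set.
#'
#' @param es an [epoch_set()].
#' @param ptp_threshold peak-to-peak threshold in microvolt (default 150).
#' @param channels channels inspected; default all channels except mastoids.
#' @return `es` with `reject_mask` updated.
#' @export
reject_artifacts <- function(es, ptp_threshold = 150, channels = NULL) {
  if (!is.finite(ptp_threshold) && !is.infinite(ptp_threshold))
    stop_wavepls("ptp_threshold must be numeric", "wavepls_format_error")
  if (ptp_threshold <= 0)
    stop_wavepls("ptp_threshold must be positive", "wavepls_format_error")
  if (is.null(channels))
    channels <- setdiff(es$channel_names, c("M1", "M2"))
  ci <- channel_index(es, channels)
  x <- es$data[, ci, , drop = FALSE]
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L])  # rows = (trial, channel) pairs
  hi <- m[, 1L]; lo <- m[, 1L]
  for (j in seq_len(d[3L])[-1L]) {
    hi <- pmax(hi, m[, j]); lo <- pmin(lo, m[, j])
  }
  bad <- matrix(hi - lo > ptp_threshold, d[1L], d[2L])
  es$reject_mask <- rowSums(bad) > 0L
  es
}

#' Does a subject retain enough artifact-free trials per condition cell?
#'
#' Inclusion rule: every tone x condition cell (over the analysed tones)
#' must keep at least `min_trials` unmasked trials.
#'
#' @param es an [epoch_set()] with `reject_mask` populated.
#' @param min_trials minimum artifact-free trials per cell (default 50).
#' @param tones tones whose cells are screened (default the two analysed
#'   tones, low-falling and high-rising).
#' @return `TRUE` if the subject passes screening.
#' @export
screen_subject <- function(es, min_trials = 50,
                           tones = c("low-falling", "high-rising")) {
  lab <- es$trial_labels
  if (all(is.na(lab$tone)) || all(is.na(lab$condition)))
    stop_wavepls("tone/condition labels required for screening",
                 "wavepls_label_error")
  counts <- matrix(NA_integer_, length(tones), 2,
                   dimnames = list(tones, c("standard", "deviant")))
  for (tn in tones) for (cond in colnames(counts)) {
    in_cell <- !is.na(lab$tone) & lab$tone == tn &
      !is.na(lab$condition) & lab$condition == cond
    if (!any(in_cell))
      stop_wavepls(sprintf("condition cell absent: %s / %s", tn, cond),
                   "wavepls_label_error")
    counts[tn, cond] <- sum(in_cell & !es$reject_mask)
  }
  all(counts >= min_trials)
}

#' Select trials of an EpochSet
#' @param es an [epoch_set()].
#' @param idx integer or logical trial index.
#' @return the subsetted `EpochSet`.
#' @export
subset_trials <- function(es, idx) {
  if (is.logical(idx)) idx <- which(idx)
  es$data <- es$data[idx, , , drop = FALSE]
  es$trial_labels <- es$trial_labels[idx, , drop = FALSE]
  es$reject_mask <- es$reject_mask[idx]
  es
}
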