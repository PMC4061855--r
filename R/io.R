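#' Write epoched EEG to disk
#'
#' Two dialects are supported.  `"fixture"` writes the raw array as
#' little-endian doubles with a JSON sidecar (`<path>.json`) carrying
#' dimensions, sampling rate, epoch start, channel names, trial labels and
#' the reject mask; the round trip is lossless.  `"edf"` writes plain EDF
#' with one data record per trial (16-bit samples, so the round trip is
#' exact only up to the per-channel quantization step) plus a tab-delimited
#' label sidecar `<path>.labels.tsv`; the epoch start time is stored in the
#' EDF reserved header field as `t0_ms=<value>`.
#'
#' @param es an [epoch_set()] with at least one trial.
#' @param path output file path.
#' @param dialect `"fixture"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(es, path, dialect = c("fixture", "edf")) {
  dialect <- match.arg(dialect)
  if (n_trials(es) == 0L)
    stop_wavepls("refusing to write an EpochSet with 0 trials",
                 "wavepls_format_error")
  switch(dialect,
         fixture = write_epochs_fixture(es, path),
         edf = write_epochs_edf(es, path))
  invisible(path)
}

#' Read epoched EEG from disk
#'
#' @param path file written by [write_epochs()].
#' @param dialect `"fixture"` or `"edf"`.
#' @return an [epoch_set()].
#' @export
read_epochs <- function(path, dialect = c("fixture", "edf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_wavepls(paste("file not found:", path), "wavepls_format_error")
  switch(dialect,
         fixture = read_epochs_fixture(path),
         edf = read_epochs_edf(path))
}

labels_to_df <- function(lab, n) {
  out <- data.frame(trial = seq_len(n))
  for (col in c("trial", "tone", "condition", "block", "session",
                "subject", "group")) {
    v <- lab[[col]]
    if (!is.null(v) && length(v) == n) out[[col]] <- unlist(v)
  }
  out
}

## ---- fixture dialect: flat binary doubles + JSON metadata -----------------

write_epochs_fixture <- function(es, path) {
  meta <- list(
    format = "wavepls-epochs", version = 1L,
    dim = dim(es$data), fs = es$fs, t0 = es$t0,
    channel_names = es$channel_names,
    trial_labels = es$trial_labels,
    reject_mask = es$reject_mask
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(es$data), con, size = 8L, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
}

read_epochs_fixture <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop_wavepls("fixture metadata sidecar missing (.json)",
                 "wavepls_format_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  n_vals <- prod(d)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n_vals + 1L, size = 8L, endian = "little")
  if (length(vals) != n_vals)
    stop_wavepls("fixture payload length does not match declared dimensions",
                 "wavepls_format_error")
  lab <- labels_to_df(meta$trial_labels, d[1L])
  epoch_set(array(vals, d), fs = meta$fs, t0 = meta$t0,
            channel_names = meta$channel_names,
            trial_labels = lab,
            reject_mask = as.logical(meta$reject_mask))
}

## ---- EDF dialect ----------------------------------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

write_epochs_edf <- function(es, path) {
  d <- dim(es$data)
  n_rec <- d[1L]; ns <- d[2L]; spr <- d[3L]
  # per-channel symmetric physical range -> 16-bit digital scale
  absmax <- apply(abs(es$data), 2L, max)
  absmax[absmax == 0] <- 1
  phys_max <- signif(absmax * 1.0001, 6)
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad(sprintf("t0_ms=%g", es$t0), 44),
    edf_pad(n_rec, 8), edf_pad(format(spr / es$fs, digits = 10), 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(es$channel_names, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(format(-phys_max, digits = 6), 8)
  field(format(phys_max, digits = 6), 8)
  field(rep(-dig_max, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(spr, ns), 32)
  field(rep("", ns), 32)                       # reserved
  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    # record r: channel-major blocks of spr samples
    block <- t(es$data[r, , , drop = TRUE] * scale)  # spr x ns
    if (ns == 1L) block <- matrix(es$data[r, 1L, ] * scale, ncol = 1L)
    writeBin(as.integer(round(block)), con, size = 2L, endian = "little")
  }
  lab_path <- paste0(path, ".labels.tsv")
  lab <- es$trial_labels
  lab$reject <- es$reject_mask
  utils::write.table(lab, lab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_epochs_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(32)); rdv(32)
  if (length(unique(spr)) != 1L)
    stop_wavepls("EDF signals disagree on samples per record",
                 "wavepls_format_error")
  spr1 <- spr[1L]
  fs <- spr1 / rec_dur
  t0 <- -300
  m <- regmatches(reserved, regexec("t0_ms=(-?[0-9.]+)", reserved))[[1L]]
  if (length(m) == 2L) t0 <- as.numeric(m[2L])
  raw <- readBin(con, "integer", n = n_rec * ns * spr1, size = 2L,
                 endian = "little")
  if (length(raw) != n_rec * ns * spr1)
    stop_wavepls("EDF payload truncated: trials of unequal length",
                 "wavepls_format_error")
  # raw layout: record-major, then channel, then sample
  arr <- aperm(array(as.numeric(raw), c(spr1, ns, n_rec)), c(3L, 2L, 1L))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (ch in seq_len(ns))
    arr[, ch, ] <- (arr[, ch, ] - dig_min[ch]) * gain[ch] + phys_min[ch]
  lab_path <- paste0(path, ".labels.tsv")
  reject <- NULL; lab <- NULL
  if (file.exists(lab_path)) {
    lab <- utils::read.delim(lab_path, stringsAsFactors = FALSE)
    if (nrow(lab) != n_rec)
      stop_wavepls("label sidecar row count does not match trial count",
                   "wavepls_label_error")
    reject <- lab$reject
    lab <- labels_to_df(lab, n_rec)
  } else {
    stop_wavepls("EDF label sidecar missing (.labels.tsv)",
                 "wavepls_label_error")
  }
  epoch_set(arr, fs = fs, t0 = t0, channel_names = labels,
            trial_labels = lab, reject_mask = reject %||% rep(FALSE, n_rec))
}
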