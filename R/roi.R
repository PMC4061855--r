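#' Band / time-window definition for ROI extraction
#'
#' Defaults follow the two analysis windows: early alpha (8-13 Hz,
#' 100-500 ms, PLS reference Cz) and mid-latency gamma (28-50 Hz,
#' 200-400 ms, PLS reference FCz).  Frequency limits are inclusive grid
#' points; time windows are half-open `[start, end)` like the epoch axis.
#'
#' @param name `"alpha"` or `"gamma"`.
#' @param f_range `(low, high)` Hz; default per band.
#' @param t_range `(start, end)` ms; default per band.
#' @param reference PLS reference channel; default Cz (alpha) / FCz (gamma).
#' @return an object of class `BandWindow`.
#' @export
band_window <- function(name = c("alpha", "gamma"), f_range = NULL,
                        t_range = NULL, reference = NULL) {
  name <- match.arg(name)
  defaults <- list(alpha = list(f = c(8, 13), t = c(100, 500), ref = "Cz"),
                   gamma = list(f = c(28, 50), t = c(200, 400), ref = "FCz"))
  d <- defaults[[name]]
  structure(list(name = name, f_range = f_range %||% d$f,
                 t_range = t_range %||% d$t,
                 reference = reference %||% d$ref),
            class = "BandWindow")
}

#' Default band windows (alpha and gamma)
#' @return named list of [band_window()]s.
#' @export
default_band_windows <- function() {
  list(alpha = band_window("alpha"), gamma = band_window("gamma"))
}

#' Mean over a band/time window, per channel
#'
#' Averages a `TFPower` or `PLSMap` over the inclusive frequency grid
#' points and the half-open `[start, end)` time samples of a
#' [band_window()].
#'
#' @param map a [average_power()] or [pls()] result.
#' @param bw a [band_window()].
#' @param channels optional channel subset (default all).
#' @return named numeric vector, one mean per channel.
#' @export
extract_band_mean <- function(map, bw, channels = NULL) {
  fi <- which(map$freqs >= bw$f_range[1L] - 1e-9 &
              map$freqs <= bw$f_range[2L] + 1e-9)
  ti <- which(map$times >= bw$t_range[1L] & map$times < bw$t_range[2L])
  if (!length(fi) || !length(ti))
    stop_wavepls("band/time window outside the map axes",
                 "wavepls_format_error")
  channels <- channels %||% map$channel_names
  ci <- match(channels, map$channel_names)
  if (anyNA(ci))
    stop_wavepls(paste("channel(s) not in map:",
                       paste(channels[is.na(ci)], collapse = ", ")),
                 "wavepls_channel_error")
  out <- apply(map$values[ci, fi, ti, drop = FALSE], 1L, mean)
  names(out) <- channels
  out
}

#' Aggregate per-channel values into montage locations
#'
#' `"midline"` returns the five midline electrodes as single-electrode
#' locations; `"lateral"` returns the 10 anteriority x hemisphere region
#' means of three electrodes each.
#'
#' @param values named numeric vector of per-channel values.
#' @param montage a [montage()].
#' @param scheme `"midline"` or `"lateral"`.
#' @return data frame with columns `location`, `anteriority`, `hemisphere`
#'   (NA for midline) and `value`.
#' @export
aggregate_regions <- function(values, montage, scheme = c("midline", "lateral")) {
  scheme <- match.arg(scheme)
  if (scheme == "midline") {
    miss <- setdiff(montage$midline, names(values))
    if (length(miss))
      stop_wavepls(paste("montage channels missing from values:",
                         paste(miss, collapse = ", ")),
                   "wavepls_channel_error")
    return(data.frame(location = montage$midline,
                      anteriority = anteriority_levels(),
                      hemisphere = NA_character_,
                      value = unname(values[montage$midline]),
                      stringsAsFactors = FALSE))
  }
  locs <- names(montage$lateral_regions)
  vals <- vapply(locs, function(l) {
    chs <- montage$lateral_regions[[l]]
    miss <- setdiff(chs, names(values))
    if (length(miss))
      stop_wavepls(paste("montage channels missing from values:",
                         paste(miss, collapse = ", ")),
                   "wavepls_channel_error")
    mean(values[chs])
  }, 0)
  parts <- strsplit(locs, ".", fixed = TRUE)
  data.frame(location = locs,
             anteriority = vapply(parts, `[`, "", 1L),
             hemisphere = vapply(parts, `[`, "", 2L),
             value = unname(vals), stringsAsFactors = FALSE)
}

# Streaming per-cell band measures for one subject/session EpochSet.
# For every tone x condition cell: trial-averaged baseline-corrected power
# and PLS (per band against its reference), extracted as band-window means
# per analysis channel.  Trials are processed in chunks so the full
# trials x channels x freq x time array is never materialized.
subject_band_measures <- function(es, montage = default_montage(),
                                  bands = default_band_windows(),
                                  fam = NULL, taper_fraction = 0.1,
                                  baseline = c(-280, -100),
                                  tones = c("low-falling", "high-rising"),
                                  channels = NULL,
                                  measures = c("power", "pls"),
                                  chunk = 64L) {
  if (is.null(fam)) {
    freqs_needed <- sort(unique(unlist(lapply(bands, function(b)
      seq(b$f_range[1L], b$f_range[2L])))))
    fam <- build_wavelet_family(min(freqs_needed), max(freqs_needed), 1,
                                m = 9, fs = es$fs)
  }
  freqs_avail <- fam$f0_list
  freqs_needed <- sort(unique(unlist(lapply(bands, function(b)
    freqs_avail[freqs_avail >= b$f_range[1L] - 1e-9 &
                freqs_avail <= b$f_range[2L] + 1e-9]))))
  chans <- intersect(channels %||% analysis_channels(montage),
                     es$channel_names)
  refs <- unique(vapply(bands, function(b) b$reference, ""))
  need <- union(chans, refs)
  miss <- setdiff(need, es$channel_names)
  if (length(miss))
    stop_wavepls(paste("channels missing for ROI analysis:",
                       paste(miss, collapse = ", ")),
                 "wavepls_channel_error")
  freq_idx <- match(freqs_needed, fam$f0_list)
  if (!length(freq_idx) || anyNA(freq_idx))
    stop_wavepls("wavelet family lacks required band frequencies",
                 "wavepls_format_error")
  times <- epoch_times(es)
  n <- length(times)
  nf <- length(freq_idx)
  w <- taper_window(n, taper_fraction)
  lab <- es$trial_labels
  keep <- !es$reject_mask
  do_pls <- "pls" %in% measures
  # each band's PLS only needs its own reference, frequency range and
  # time window
  ref_freqs <- lapply(refs, function(r) {
    sub <- bands[vapply(bands, function(b) b$reference == r, TRUE)]
    which(freqs_needed %in% unlist(lapply(sub, function(b)
      freqs_needed[freqs_needed >= b$f_range[1L] - 1e-9 &
                   freqs_needed <= b$f_range[2L] + 1e-9])))
  })
  names(ref_freqs) <- refs
  ref_times <- lapply(refs, function(r) {
    sub <- bands[vapply(bands, function(b) b$reference == r, TRUE)]
    sel <- rep(FALSE, n)
    for (b in sub)
      sel <- sel | (times >= b$t_range[1L] & times < b$t_range[2L])
    which(sel)
  })
  names(ref_times) <- refs
  if (!do_pls) refs <- character()
  cells <- expand.grid(cond = c("standard", "deviant"), tone = tones,
                       stringsAsFactors = FALSE)
  cell_of <- rep(NA_integer_, n_trials(es))
  for (i in seq_len(nrow(cells))) {
    sel <- keep & lab$tone == cells$tone[i] & lab$condition == cells$cond[i]
    cell_of[sel] <- i
  }
  tr <- which(!is.na(cell_of))
  n_per_cell <- tabulate(cell_of[tr], nrow(cells))
  use_cell <- n_per_cell >= 2L
  tr <- tr[use_cell[cell_of[tr]]]
  if (!length(tr)) return(NULL)
  n_cells <- nrow(cells)
  pow_sum <- array(0, c(n_cells, length(chans), nf, n))
  pls_sum <- lapply(refs, function(r)
    array(0 + 0i, c(n_cells, length(chans), length(ref_freqs[[r]]),
                    length(ref_times[[r]]))))
  names(pls_sum) <- refs
  for (i0 in seq(1L, length(tr), by = chunk)) {
    ti <- tr[i0:min(length(tr), i0 + chunk - 1L)]
    # cell indicator matrix: per-cell sums are one matrix product
    Gm <- matrix(0, n_cells, length(ti))
    Gm[cbind(cell_of[ti], seq_along(ti))] <- 1
    conv_one <- function(ch) {
      sig <- t(es$data[ti, match(ch, es$channel_names), , drop = TRUE])
      if (length(ti) == 1L)
        sig <- matrix(es$data[ti, match(ch, es$channel_names), ], ncol = 1L)
      tf_convolve(sig * w, fam, freq_idx)
    }
    unit <- function(z) { m <- Mod(z); m[m == 0] <- 1; z / m }
    # reference phasors for this chunk (restricted to the band frequencies)
    uref <- list()
    tf_cache <- list()
    for (r in refs) {
      tfr <- conv_one(r)
      if (r %in% chans) tf_cache[[r]] <- tfr
      uref[[r]] <- Conj(unit(tfr[, ref_freqs[[r]], ref_times[[r]],
                                 drop = FALSE]))
    }
    for (c0 in seq_along(chans)) {
      ch <- chans[c0]
      tfc <- tf_cache[[ch]] %||% conv_one(ch)
      pw <- Gm %*% matrix(Mod(tfc)^2, length(ti))
      pow_sum[, c0, , ] <- pow_sum[, c0, , , drop = FALSE] +
        array(pw, c(n_cells, 1L, nf, n))
      for (r in refs) {
        z <- unit(tfc[, ref_freqs[[r]], ref_times[[r]], drop = FALSE]) *
          uref[[r]]
        s <- Gm %*% matrix(z, length(ti))
        pls_sum[[r]][, c0, , ] <- pls_sum[[r]][, c0, , , drop = FALSE] +
          array(s, c(n_cells, 1L, length(ref_freqs[[r]]),
                     length(ref_times[[r]])))
      }
    }
  }
  rows <- list()
  for (ci in which(use_cell)) {
    tn <- cells$tone[ci]; cond <- cells$cond[ci]
    n_cell <- n_per_cell[ci]
    tr1 <- which(cell_of == ci)[1L]
    pow <- structure(list(values = array(pow_sum[ci, , , ] / n_cell,
                                         c(length(chans), nf, n)),
                          freqs = freqs_needed, times = times,
                          channel_names = chans,
                          edge_mask = edge_mask_matrix(fam, freq_idx, times),
                          n_trials = n_cell, baseline_applied = FALSE,
                          baseline_window = NULL),
                     class = "TFPower")
    pow <- baseline_correct(pow, baseline)
    for (bname in names(bands)) {
      bw <- bands[[bname]]
      pvals <- extract_band_mean(pow, bw, chans)
      svals <- rep(NA_real_, length(chans))
      if (do_pls) {
        r <- bw$reference
        fsub <- ref_freqs[[r]]; tsub <- ref_times[[r]]
        plsmap <- structure(
          list(values = array(Mod(pls_sum[[r]][ci, , , ] / n_cell),
                              c(length(chans), length(fsub), length(tsub))),
               freqs = freqs_needed[fsub], times = times[tsub],
               channel_names = chans,
               edge_mask = pow$edge_mask[fsub, tsub, drop = FALSE],
               reference_channel = r,
               n_trials = n_cell),
          class = "PLSMap")
        svals <- unname(extract_band_mean(plsmap, bw, chans))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = lab$subject[tr1], group = lab$group[tr1],
        session = lab$session[tr1], tone = tn, condition = cond,
        band = bname, channel = chans, n_trials = n_cell,
        power = unname(pvals), pls = svals,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Build the long-format ROI table feeding the statistics layer
#'
#' Takes per-subject/session channel-level band measures (power and PLS as
#' produced internally from each [epoch_set()]) and aggregates them over
#' the montage's midline and lateral schemes into one row per subject x
#' session x tone x condition x measure x band x location.  PLS rows are
#' produced for lateral locations only, because the statistic is computed
#' against a midline reference electrode.
#'
#' @param epochs named list of [epoch_set()]s (one per subject x session),
#'   e.g. `generate_study()$epochs`, already re-referenced/screened as
#'   desired.
#' @param montage a [montage()].
#' @param bands [band_window()] list (default alpha + gamma).
#' @param fam optional [build_wavelet_family()] restricted to the band
#'   frequencies; built automatically when `NULL`.
#' @param taper_fraction,baseline passed to the TF stage.
#' @param schemes location schemes to emit, `"midline"` and/or
#'   `"lateral"` (default both); only the channels the requested schemes
#'   need are transformed.
#' @param require_complete error when a subject misses a session
#'   (default TRUE).
#' @return a `RoiTable` data frame with columns `subject, group, session,
#'   tone, condition, measure, band, scheme, location, anteriority,
#'   hemisphere, value`.
#' @export
build_roi_table <- function(epochs, montage = default_montage(),
                            bands = default_band_windows(), fam = NULL,
                            taper_fraction = 0.1, baseline = c(-280, -100),
                            schemes = c("midline", "lateral"),
                            measures = c("power", "pls"),
                            require_complete = TRUE) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  measures <- match.arg(measures, several.ok = TRUE)
  chans <- character()
  if ("midline" %in% schemes) chans <- c(chans, montage$midline)
  if ("lateral" %in% schemes)
    chans <- c(chans, unlist(montage$lateral_regions, use.names = FALSE))
  meas <- lapply(epochs, subject_band_measures, montage = montage,
                 bands = bands, fam = fam, taper_fraction = taper_fraction,
                 baseline = baseline, channels = unique(chans),
                 measures = measures)
  meas <- do.call(rbind, meas[!vapply(meas, is.null, TRUE)])
  if (is.null(meas))
    stop_wavepls("no usable trials in any EpochSet", "wavepls_format_error")
  if (require_complete) {
    tab <- unique(meas[, c("subject", "session")])
    cnt <- table(tab$subject)
    n_sess <- length(unique(meas$session))
    bad <- names(cnt)[cnt < n_sess]
    if (length(bad))
      stop_wavepls(paste("incomplete sessions for subject(s):",
                         paste(bad, collapse = ", ")),
                   "wavepls_label_error")
  }
  key_cols <- c("subject", "group", "session", "tone", "condition", "band")
  keys <- unique(meas[, key_cols])
  rows <- vector("list", nrow(keys) * 3L)
  k <- 0L
  for (i in seq_len(nrow(keys))) {
    sl <- merge(keys[i, , drop = FALSE], meas, by = key_cols)
    for (measure in measures) {
      v <- sl[[measure]]
      names(v) <- sl$channel
      sc_use <- if (measure == "pls") intersect(schemes, "lateral")
                else schemes
      for (sc in sc_use) {
        agg <- aggregate_regions(v, montage, sc)
        k <- k + 1L
        rows[[k]] <- cbind(keys[i, , drop = FALSE], measure = measure,
                           scheme = sc, agg, row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  key_all <- do.call(paste, c(out[c(key_cols, "measure", "location")], sep = "|"))
  if (anyDuplicated(key_all))
    stop_wavepls("duplicate ROI rows produced", "wavepls_format_error")
  out
}

#' Write / read a RoiTable as tab-delimited text
#' @param roi data frame from [build_roi_table()].
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_roi_table <- function(roi, path) {
  utils::write.table(roi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
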