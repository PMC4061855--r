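#' Assemble a pipeline configuration
#'
#' Bundles every knob of the analysis chain: the synthetic design (or
#' paths to epoch files), wavelet-family parameters, taper and baseline
#' settings, band windows, location schemes, screening thresholds, the
#' statistics plan, the output directory and the master seed.
#'
#' @param design a [study_design()], or `NULL` when `epoch_paths` is given.
#' @param epoch_paths optional named character vector of files readable by
#'   [read_epochs()] (one per subject x session).
#' @param dialect dialect for `epoch_paths`.
#' @param out_dir output directory.
#' @param wavelet list of [build_wavelet_family()] arguments.
#' @param taper_fraction,baseline TF-stage settings.
#' @param bands [band_window()] list.
#' @param schemes `"midline"`, `"lateral"` or both.
#' @param ptp_threshold artifact peak-to-peak threshold, microvolt.
#' @param min_trials screening threshold per tone x condition cell.
#' @param stats_plan list of analyses, each a list with `name, measure,
#'   band, scheme, within, between`.
#' @param channels optional generator channel subset for scaled runs.
#' @param seed master seed (required for synthetic designs).
#' @return an object of class `PipelineConfig`.
#' @export
pipeline_config <- function(design = study_design(), epoch_paths = NULL,
                            dialect = "fixture", out_dir = tempfile("wavepls_run_"),
                            wavelet = list(f_min = 8, f_max = 80, f_step = 1,
                                           m = 9, fs = 512),
                            taper_fraction = 0.1, baseline = c(-280, -100),
                            bands = default_band_windows(),
                            schemes = c("midline", "lateral"),
                            ptp_threshold = 150, min_trials = 50,
                            stats_plan = default_stats_plan(),
                            channels = NULL, seed = NULL) {
  structure(list(design = design, epoch_paths = epoch_paths,
                 dialect = dialect, out_dir = out_dir, wavelet = wavelet,
                 taper_fraction = taper_fraction, baseline = baseline,
                 bands = bands, schemes = schemes,
                 ptp_threshold = ptp_threshold, min_trials = min_trials,
                 stats_plan = stats_plan, channels = channels,
                 seed = seed %||% if (!is.null(design)) design$seed else NULL),
            class = "PipelineConfig")
}

#' Default statistics plan: band power (midline + lateral) and lateral PLS
#' @return list of analysis descriptions for [pipeline_config()].
#' @export
default_stats_plan <- function() {
  plan <- list()
  for (band in c("alpha", "gamma")) {
    plan[[paste0(band, "_power_midline")]] <- list(
      measure = "power", band = band, scheme = "midline",
      within = c("session", "tone", "condition", "location"),
      between = "group")
    plan[[paste0(band, "_power_lateral")]] <- list(
      measure = "power", band = band, scheme = "lateral",
      within = c("session", "tone", "condition", "anteriority", "hemisphere"),
      between = "group")
    plan[[paste0(band, "_pls_lateral")]] <- list(
      measure = "pls", band = band, scheme = "lateral",
      within = c("session", "tone", "condition", "anteriority", "hemisphere"),
      between = "group")
  }
  plan
}

#' Validate a pipeline configuration
#'
#' @param cfg a [pipeline_config()].
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(cfg) {
  v <- character()
  wl <- cfg$wavelet
  if (wl$f_max >= wl$fs / 2)
    v <- c(v, sprintf("f_max (%g Hz) at or above Nyquist (%g Hz)",
                      wl$f_max, wl$fs / 2))
  if (wl$f_min <= 0 || wl$f_min > wl$f_max)
    v <- c(v, "need 0 < f_min <= f_max")
  if (cfg$taper_fraction <= 0 || cfg$taper_fraction > 0.5)
    v <- c(v, "taper_fraction must lie in (0, 0.5]")
  epoch_span <- c(-300, 700)   # default generator geometry
  if (cfg$baseline[1L] < epoch_span[1L] || cfg$baseline[2L] > epoch_span[2L])
    v <- c(v, "baseline window outside the epoch")
  mont <- if (!is.null(cfg$design)) cfg$design$montage else default_montage()
  for (b in cfg$bands) {
    if (b$t_range[1L] < epoch_span[1L] || b$t_range[2L] > epoch_span[2L])
      v <- c(v, sprintf("%s time window outside the epoch", b$name))
    if (b$f_range[1L] < wl$f_min || b$f_range[2L] > wl$f_max)
      v <- c(v, sprintf("%s band outside the wavelet family grid", b$name))
    if (!b$reference %in% recorded_channels(mont))
      v <- c(v, sprintf("reference channel %s not in montage", b$reference))
  }
  if (is.null(cfg$epoch_paths) && is.null(cfg$design))
    v <- c(v, "either a design or epoch_paths is required")
  if (!is.null(cfg$design) && is.null(cfg$seed))
    v <- c(v, "seed required for synthetic designs")
  v
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(cfg, NULL, version = 2L), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> re-reference -> artifact rejection -> subject
#' screening -> wavelet transform -> power / PLS -> ROI table -> ANOVAs.
#' All tables are written under `cfg$out_dir` with the configuration hash
#' in a header comment; a JSON manifest records seeds, stage row counts
#' and per-file MD5 hashes.  A completed run with an unchanged
#' configuration is not recomputed unless `force = TRUE`.
#'
#' @param cfg a [pipeline_config()].
#' @param force recompute even when an up-to-date manifest exists.
#' @return the manifest, invisibly; stored at `out_dir/manifest.json`.
#' @export
run_pipeline <- function(cfg, force = FALSE) {
  viol <- validate_config(cfg)
  if (length(viol))
    stop_wavepls(paste("invalid configuration:",
                       paste(viol, collapse = "; ")),
                 "wavepls_config_error")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  man_path <- file.path(cfg$out_dir, "manifest.json")
  if (!force && file.exists(man_path)) {
    old <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    if (identical(old$config_hash, unname(hash))) {
      message("run up to date (config hash ", substr(hash, 1, 8),
              "); use force = TRUE to recompute")
      return(invisible(old))
    }
  }
  stage <- "simulate"
  epochs <- tryCatch({
    if (!is.null(cfg$epoch_paths)) {
      lapply(cfg$epoch_paths, read_epochs, dialect = cfg$dialect)
    } else {
      generate_study(cfg$design, channels = cfg$channels)$epochs
    }
  }, error = function(e) stop_wavepls(
    paste0("stage ", stage, ": ", conditionMessage(e)), "wavepls_stage_error"))
  mont <- if (!is.null(cfg$design)) cfg$design$montage else default_montage()
  stage <- "preprocess"
  epochs <- lapply(names(epochs), function(nm) {
    tryCatch({
      es <- rereference_to_average_mastoids(epochs[[nm]], mont)
      reject_artifacts(es, cfg$ptp_threshold)
    }, error = function(e) stop_wavepls(
      paste0("stage ", stage, " [", nm, "]: ", conditionMessage(e)),
      "wavepls_stage_error"))
  }) |> stats::setNames(names(epochs))
  screened_out <- character()
  if (cfg$min_trials > 0) {
    keep <- vapply(epochs, screen_subject, TRUE, min_trials = cfg$min_trials)
    screened_out <- names(epochs)[!keep]
    epochs <- epochs[keep]
  }
  stage <- "tf_roi"
  fam <- do.call(build_wavelet_family, cfg$wavelet)
  roi <- tryCatch(
    build_roi_table(epochs, montage = mont, bands = cfg$bands, fam = fam,
                    taper_fraction = cfg$taper_fraction,
                    baseline = cfg$baseline, schemes = cfg$schemes),
    error = function(e) stop_wavepls(
      paste0("stage ", stage, ": ", conditionMessage(e)),
      "wavepls_stage_error"))
  roi_path <- file.path(cfg$out_dir, "roi_table.tsv")
  writeLines(paste0("# config_hash=", hash), roi_path)
  suppressWarnings(utils::write.table(roi, roi_path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  stage <- "stats"
  stats_files <- character()
  for (nm in names(cfg$stats_plan)) {
    pl <- cfg$stats_plan[[nm]]
    sl <- roi[roi$measure == pl$measure & roi$band == pl$band &
                roi$scheme == pl$scheme, ]
    if (!nrow(sl)) next
    an <- tryCatch(
      rm_anova(sl, dv = "value", within = pl$within, between = pl$between),
      error = function(e) stop_wavepls(
        paste0("stage ", stage, " [", nm, "]: ", conditionMessage(e)),
        "wavepls_stage_error"))
    f <- file.path(cfg$out_dir, paste0("anova_", nm, ".tsv"))
    writeLines(paste0("# config_hash=", hash), f)
    suppressWarnings(utils::write.table(as.data.frame(an), f, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
    stats_files <- c(stats_files, f)
  }
  files <- c(roi_table = roi_path, stats::setNames(stats_files,
                                                   basename(stats_files)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("wavepls")),
    config_hash = unname(hash), seed = cfg$seed,
    n_epoch_sets = length(epochs), screened_out = as.list(screened_out),
    roi_rows = nrow(roi),
    files = lapply(files, function(f) list(path = f,
                                           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a pipeline configuration from YAML
#'
#' Reconstructs a [pipeline_config()] from a YAML file holding scalar
#' settings (wavelet parameters, thresholds, band overrides, seed) plus an
#' optional `design` block of [study_design()] arguments.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  des_args <- y$design %||% list()
  if (!is.null(des_args$groups)) des_args$groups <- unlist(des_args$groups)
  design <- do.call(study_design, des_args)
  bands <- default_band_windows()
  for (nm in names(y$bands %||% list())) {
    b <- y$bands[[nm]]
    bands[[nm]] <- band_window(nm, f_range = unlist(b$f_range),
                               t_range = unlist(b$t_range),
                               reference = b$reference)
  }
  args <- list(design = design, bands = bands)
  for (nm in c("out_dir", "taper_fraction", "baseline", "schemes",
               "ptp_threshold", "min_trials", "channels", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$wavelet)) args$wavelet <- utils::modifyList(
    list(f_min = 8, f_max = 80, f_step = 1, m = 9, fs = 512), y$wavelet)
  do.call(pipeline_config, args)
}
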