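#' Electrode montage with midline and lateral analysis regions
#'
#' A `Montage` describes the channel set and its grouping into the five
#' midline analysis electrodes, the 5 (anteriority) x 2 (hemisphere) x 3
#' (electrode) lateral scheme, and the mastoid reference channels.
#'
#' @param midline character(5), anterior-to-posterior midline electrodes.
#' @param lateral_regions named list mapping `"<anteriority>.<L|R>"` to a
#'   character(3) of electrode labels; exactly 5 anteriority levels x 2
#'   hemispheres.
#' @param mastoids character(2), `(left, right)` mastoid labels.  The left
#'   mastoid is the recording reference and normally carries no data channel.
#' @param extra character, additional recorded channels that take no part in
#'   the region analyses.
#' @return an object of class `Montage`.
#' @export
montage <- function(midline, lateral_regions, mastoids = c("M1", "M2"),
                    extra = character()) {
  if (length(midline) != 5L)
    stop_wavepls("midline must name exactly 5 channels", "wavepls_montage_error")
  lat <- unlist(lateral_regions, use.names = FALSE)
  if (length(lateral_regions) != 10L || length(lat) != 30L)
    stop_wavepls("lateral scheme must be 5 anteriority levels x 2 hemispheres x 3 channels",
                 "wavepls_montage_error")
  all_ch <- c(midline, lat, mastoids, extra)
  if (anyDuplicated(all_ch))
    stop_wavepls("channel appears twice in montage", "wavepls_montage_error")
  structure(list(midline = midline, lateral_regions = lateral_regions,
                 mastoids = mastoids, extra = extra),
            class = "Montage")
}

#' Default 39-channel montage
#'
#' Midline Fz/FCz/Cz/CPz/Pz; lateral regions frontal (F3/4, F5/6, F7/8),
#' fronto-central (FC3/4, FC5/6, FT7/8), central (C3/4, C5/6, T7/8),
#' centro-parietal (CP3/4, CP5/6, TP7/8) and parietal (P3/4, P5/6, P7/8);
#' right mastoid M2 recorded (left mastoid M1 is the implicit recording
#' reference); Fp1/Fp2/Oz recorded but outside the region scheme.
#'
#' @return a [montage()] object.
#' @export
default_montage <- function() {
  lat <- list(
    frontal.L        = c("F3",  "F5",  "F7"),
    frontal.R        = c("F4",  "F6",  "F8"),
    frontocentral.L  = c("FC3", "FC5", "FT7"),
    frontocentral.R  = c("FC4", "FC6", "FT8"),
    central.L        = c("C3",  "C5",  "T7"),
    central.R        = c("C4",  "C6",  "T8"),
    centroparietal.L = c("CP3", "CP5", "TP7"),
    centroparietal.R = c("CP4", "CP6", "TP8"),
    parietal.L       = c("P3",  "P5",  "P7"),
    parietal.R       = c("P4",  "P6",  "P8")
  )
  montage(midline = c("Fz", "FCz", "Cz", "CPz", "Pz"),
          lateral_regions = lat,
          mastoids = c("M1", "M2"),
          extra = c("Fp1", "Fp2", "Oz"))
}

#' Channels entering the region analyses (midline + lateral)
#' @param m a [montage()] object.
#' @return character vector of 35 analysis channels.
#' @export
analysis_channels <- function(m) {
  c(m$midline, unlist(m$lateral_regions, use.names = FALSE))
}

#' All recorded channels of a montage
#'
#' Analysis channels plus the recorded (right) mastoid and any extra
#' channels; the left mastoid is the implicit recording reference and has no
#' data channel.
#' @param m a [montage()] object.
#' @return character vector (39 channels for [default_montage()]).
#' @export
recorded_channels <- function(m) {
  c(analysis_channels(m), m$mastoids[2L], m$extra)
}

#' @export
print.Montage <- function(x, ...) {
  cat("Montage:", length(recorded_channels(x)), "recorded channels\n")
  cat("  midline :", paste(x$midline, collapse = " "), "\n")
  cat("  lateral :", length(x$lateral_regions), "regions x 3 electrodes\n")
  cat("  mastoids:", paste(x$mastoids, collapse = " "),
      "(left = recording reference)\n")
  if (length(x$extra)) cat("  extra   :", paste(x$extra, collapse = " "), "\n")
  invisible(x)
}

anteriority_levels <- function() {
  c("frontal", "frontocentral", "central", "centroparietal", "parietal")
}
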