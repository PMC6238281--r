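#' Threshold configuration
#'
#' Gray-value detection thresholds and the co-localization distance cutoff.
#' Peaks are counted at gray value >= 300 for all experiments; on TEEN-buffer
#' fibers, antibody channels use 200 while streptavidin/biotin stays at 300.
#' Two peaks closer than `coloc_um` (0.192 um = 3 pixels at 0.064 um/px) are
#' co-localizing.
#'
#' @param default_gray Default peak threshold (gray value).
#' @param teen_antibody_gray Threshold for antibody channels on TEEN fibers.
#' @param streptavidin_gray Threshold for the biotin/streptavidin channel.
#' @param coloc_um Co-localization distance threshold (um).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(default_gray = 300, teen_antibody_gray = 200,
                             streptavidin_gray = 300, coloc_um = 0.192) {
  vals <- c(default_gray, teen_antibody_gray, streptavidin_gray, coloc_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be positive")
  }
  structure(list(default_gray = default_gray,
                 teen_antibody_gray = teen_antibody_gray,
                 streptavidin_gray = streptavidin_gray,
                 coloc_um = coloc_um),
            class = "threshold_config")
}

biotin_channels <- c("biotin", "streptavidin")

#' Resolve the detection threshold for a channel
#'
#' Returns 200 only for antibody channels on TEEN preparations; 300 otherwise,
#' including the streptavidin-detected biotin channel on TEEN fibers.
#'
#' @param channel Channel label.
#' @param preparation `"double_lysis"`, `"single_lysis"`, or `"TEEN"`.
#' @param config A [threshold_config()].
#' @return The gray-value threshold to use for [call_peaks()].
#' @export
resolve_threshold <- function(channel, preparation,
                              config = threshold_config()) {
  preparation <- match.arg(preparation,
                           c("double_lysis", "single_lysis", "TEEN"))
  if (identical(preparation, "TEEN") && !(channel %in% biotin_channels)) {
    config$teen_antibody_gray
  } else if (channel %in% biotin_channels) {
    config$streptavidin_gray
  } else {
    config$default_gray
  }
}

#' Call peaks on an intensity profile
#'
#' Segments the profile into maximal runs of consecutive samples at or above
#' the threshold; each run yields exactly one peak at the run's maximum
#' sample. A fluorescent punctum a few pixels wide produces one such run, so
#' this counts puncta rather than every noise ripple. Ties among equal maxima
#' within a run resolve to the midpoint tied sample, rounding to the lower
#' index.
#'
#' @param profile An [intensity_profile()].
#' @param threshold Gray-value threshold (> 0).
#' @return Data frame with columns `position_um`, `height`, `channel`, sorted
#'   by position; zero rows when nothing exceeds the threshold.
#' @export
call_peaks <- function(profile, threshold) {
  stopifnot(inherits(profile, "intensity_profile"),
            is.numeric(threshold), threshold > 0)
  v <- profile$values
  above <- v >= threshold
  empty <- data.frame(position_um = numeric(0), height = numeric(0),
                      channel = character(0), stringsAsFactors = FALSE)
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  idx <- vapply(runs, function(j) {
    seg <- v[starts[j]:ends[j]]
    ties <- which(seg == max(seg))
    starts[j] + ties[floor((length(ties) + 1L) / 2L)] - 1L
  }, integer(1))
  data.frame(position_um = profile$positions[idx], height = v[idx],
             channel = profile$channel, stringsAsFactors = FALSE)
}

#' Call peaks on every channel of a fiber record
#'
#' Applies [resolve_threshold()] per channel and [call_peaks()] per profile.
#'
#' @param record A [fiber_record()].
#' @param config A [threshold_config()].
#' @return Named list of peak data frames, one per channel.
#' @export
call_fiber_peaks <- function(record, config = threshold_config()) {
  lapply(record$profiles, function(p) {
    call_peaks(p, resolve_threshold(p$channel, record$preparation, config))
  })
}
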