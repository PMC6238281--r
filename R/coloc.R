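#' Nearest-peak distances between two channels
#'
#' For each query peak, the distance (um) to its closest reference peak. The
#' pairing is independent per query peak: a single reference peak may be the
#' closest partner of several query peaks, which is why the co-localization
#' percentage is directional (biotin-vs-CENP-A differs from
#' CENP-A-vs-biotin).
#'
#' @param query,ref Numeric vectors of peak positions (um), or peak data
#'   frames as returned by [call_peaks()].
#' @param coloc_um Distance at or below which a pair counts as co-localizing.
#' @return A list with `distances` (per query peak) and `coloc` (logical,
#'   `distance <= coloc_um`).
#' @export
nearest_distances <- function(query, ref, coloc_um = 0.192) {
  query <- peak_positions(query)
  ref <- peak_positions(ref)
  if (length(ref) == 0L) {
    stop("reference peak list is empty: nearest distances undefined")
  }
  d <- if (length(query) == 0L) numeric(0) else {
    apply(abs(outer(query, ref, "-")), 1L, min)
  }
  list(distances = d, coloc = d <= coloc_um)
}

#' Co-localization percentage
#'
#' Percentage of query peaks whose nearest reference peak lies within
#' `coloc_um` (a distance exactly equal to the threshold counts).
#'
#' @inheritParams nearest_distances
#' @return Percentage in \[0, 100\].
#' @export
coloc_percent <- function(query, ref, coloc_um = 0.192) {
  query <- peak_positions(query)
  if (length(query) == 0L) {
    stop("query peak list is empty: co-localization percentage undefined")
  }
  nd <- nearest_distances(query, ref, coloc_um)
  100 * mean(nd$coloc)
}

peak_positions <- function(x) {
  if (is.data.frame(x)) as.numeric(x$position_um) else as.numeric(x)
}
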