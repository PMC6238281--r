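#' Centromere reference domain
#'
#' The interval spanned by the first and last reference-channel peak of a
#' fiber; its size is the distance between them (zero for a single peak).
#'
#' @param ref_peaks Peak positions (vector or peak data frame).
#' @return List with `start_um`, `end_um`, `size_um`.
#' @export
reference_domain <- function(ref_peaks) {
  p <- peak_positions(ref_peaks)
  if (length(p) == 0L) {
    stop("no reference peaks: domain undefined")
  }
  list(start_um = min(p), end_um = max(p), size_um = max(p) - min(p))
}

#' Classify query peaks into three categories
#'
#' Each query peak is "coloc" if its nearest reference peak is within
#' `coloc_um`; otherwise "outside" if it lies beyond a domain edge by more
#' than `coloc_um`; otherwise "inside_noncoloc". The edge tolerance keeps the
#' outside category consistent with the spreading rule, under which a peak at
#' most `coloc_um` beyond the edge still co-localizes with the edge and does
#' not count as spreading.
#'
#' @param query,ref Peak positions (vector or peak data frame).
#' @param domain Output of [reference_domain()] (computed from `ref` if
#'   omitted).
#' @param coloc_um Co-localization distance threshold (um).
#' @return List with `labels` (per query peak) and percentages `pct_coloc`,
#'   `pct_inside_noncoloc`, `pct_outside` (sum to 100).
#' @export
classify_peaks <- function(query, ref, domain = reference_domain(ref),
                           coloc_um = 0.192) {
  q <- peak_positions(query)
  if (length(q) == 0L) {
    stop("query peak list is empty: category distribution undefined")
  }
  nd <- nearest_distances(q, ref, coloc_um)
  outside <- q < domain$start_um - coloc_um | q > domain$end_um + coloc_um
  labels <- ifelse(nd$coloc, "coloc",
                   ifelse(outside, "outside", "inside_noncoloc"))
  list(labels = labels,
       pct_coloc = 100 * mean(labels == "coloc"),
       pct_inside_noncoloc = 100 * mean(labels == "inside_noncoloc"),
       pct_outside = 100 * mean(labels == "outside"))
}

#' Spreading distances beyond the domain edges
#'
#' Distance of the furthest query peak beyond each domain edge. A side's
#' distance is set to zero when no query peak lies beyond that edge or when
#' the furthest one is within `coloc_um` of the edge (it then co-localizes
#' with the boundary reference peak rather than spreading).
#'
#' @param query Peak positions (vector or peak data frame).
#' @param domain Output of [reference_domain()].
#' @param coloc_um Co-localization distance threshold (um).
#' @return List with `ds_left_um` and `ds_right_um` (both >= 0).
#' @export
spreading_distances <- function(query, domain, coloc_um = 0.192) {
  q <- peak_positions(query)
  left <- domain$start_um - q[q < domain$start_um]
  right <- q[q > domain$end_um] - domain$end_um
  ds_left <- if (length(left)) max(left) else 0
  ds_right <- if (length(right)) max(right) else 0
  if (ds_left <= coloc_um) ds_left <- 0
  if (ds_right <= coloc_um) ds_right <- 0
  list(ds_left_um = ds_left, ds_right_um = ds_right)
}

#' Does a fiber show spreading?
#'
#' @param ds_left,ds_right Spreading distances from [spreading_distances()].
#' @return `TRUE` iff either side's spreading distance is positive.
#' @export
fiber_spreads <- function(ds_left, ds_right) {
  ds_left > 0 || ds_right > 0
}

#' Per-fiber metrics
#'
#' Composes peak calling, nearest-peak co-localization, domain metrics,
#' three-category classification and spreading into one row of per-fiber
#' readouts. The reference channel is CENP-A (CENP-C on triple-stain TEEN
#' fibers); `query_channel` defaults to the single remaining channel.
#'
#' A fiber whose reference or query channel yields zero peaks cannot be
#' quantified; such fibers raise a condition of class `fiber_excluded` whose
#' message names the fiber and reason, so callers can log the exclusion.
#'
#' @param record A [fiber_record()].
#' @param config A [threshold_config()].
#' @param query_channel Query channel name; required when more than one
#'   non-reference channel is present.
#' @return One-row data frame of fiber metrics.
#' @export
compute_fiber_metrics <- function(record, config = threshold_config(),
                                  query_channel = NULL) {
  ref_chan <- reference_channel(record)
  others <- setdiff(names(record$profiles), ref_chan)
  if (is.null(query_channel)) {
    if (length(others) != 1L) {
      stop("fiber ", record$fiber_id, ": query_channel must be given when ",
           length(others), " non-reference channels are present")
    }
    query_channel <- others
  }
  if (!query_channel %in% names(record$profiles)) {
    stop("fiber ", record$fiber_id, ": no channel ", query_channel)
  }
  peaks <- call_fiber_peaks(record, config)
  ref <- peaks[[ref_chan]]
  query <- peaks[[query_channel]]
  if (nrow(ref) == 0L) {
    exclude_fiber(record$fiber_id, paste0("no peaks in reference channel ",
                                          ref_chan))
  }
  if (nrow(query) == 0L) {
    exclude_fiber(record$fiber_id, paste0("no peaks in query channel ",
                                          query_channel))
  }
  ref_dom <- reference_domain(ref)
  query_dom <- reference_domain(query)
  cats <- classify_peaks(query, ref, ref_dom, config$coloc_um)
  ds <- spreading_distances(query, ref_dom, config$coloc_um)
  data.frame(
    fiber_id = record$fiber_id,
    construct = record$construct,
    preparation = record$preparation,
    ref_channel = ref_chan,
    query_channel = query_channel,
    n_ref_peaks = nrow(ref),
    n_query_peaks = nrow(query),
    peak_count_ratio = nrow(query) / nrow(ref),
    ref_domain_size_um = ref_dom$size_um,
    query_domain_size_um = query_dom$size_um,
    domain_size_ratio = if (ref_dom$size_um > 0) {
      query_dom$size_um / ref_dom$size_um
    } else NA_real_,
    pct_query_coloc = cats$pct_coloc,
    pct_ref_coloc = coloc_percent(ref, query, config$coloc_um),
    pct_inside_noncoloc = cats$pct_inside_noncoloc,
    pct_outside = cats$pct_outside,
    ds_left_um = ds$ds_left_um,
    ds_right_um = ds$ds_right_um,
    spreads = fiber_spreads(ds$ds_left_um, ds$ds_right_um),
    stringsAsFactors = FALSE
  )
}

exclude_fiber <- function(fiber_id, reason) {
  stop(structure(
    class = c("fiber_excluded", "error", "condition"),
    list(message = paste0("fiber ", fiber_id, " excluded: ", reason),
         call = NULL, fiber_id = fiber_id, reason = reason)
  ))
}

#' Side occupancy of spreading for one channel
#'
#' @keywords internal
spread_sides <- function(query, domain, coloc_um) {
  ds <- spreading_distances(query, domain, coloc_um)
  c(left = ds$ds_left_um > 0, right = ds$ds_right_um > 0)
}

#' Co-spreading pattern of two proteins on a triple-stain fiber
#'
#' On TEEN fibers stained for CENP-C (domain reference) plus CENP-B and
#' CENP-I, classifies whether both proteins, only one, or neither spreads
#' beyond the CENP-C domain, and - when both spread - whether they occupy the
#' same side, opposite sides, or a mixed pattern (at least one protein on both
#' sides, or a shared side with one protein also on the other side).
#'
#' @param record A [fiber_record()] with channels CENP-C, CENP-B and CENP-I.
#' @param config A [threshold_config()].
#' @param proteins The two query channels (default CENP-B and CENP-I).
#' @return One-row data frame with `which` (`both`/`only_B`/`only_I`/`none`),
#'   `side_pattern` (`same_side`/`opposite_sides`/`mixed`, `NA` unless
#'   `both`), and the raw per-protein side occupancy flags.
#' @export
classify_cospreading <- function(record, config = threshold_config(),
                                 proteins = c("CENP-B", "CENP-I")) {
  ref_chan <- reference_channel(record)
  missing <- setdiff(c(ref_chan, proteins), names(record$profiles))
  if (length(missing)) {
    stop("fiber ", record$fiber_id, ": missing channel(s) ",
         paste(missing, collapse = ", "))
  }
  peaks <- call_fiber_peaks(record, config)
  ref <- peaks[[ref_chan]]
  if (nrow(ref) == 0L) {
    exclude_fiber(record$fiber_id, paste0("no peaks in reference channel ",
                                          ref_chan))
  }
  dom <- reference_domain(ref)
  sides <- lapply(proteins, function(ch) {
    q <- peaks[[ch]]
    if (nrow(q) == 0L) {
      exclude_fiber(record$fiber_id, paste0("no peaks in channel ", ch))
    }
    spread_sides(q, dom, config$coloc_um)
  })
  a <- sides[[1L]]; b <- sides[[2L]]
  a_spreads <- any(a); b_spreads <- any(b)
  which_cat <- if (a_spreads && b_spreads) "both"
  else if (a_spreads) "only_B"
  else if (b_spreads) "only_I"
  else "none"
  side_pattern <- NA_character_
  if (which_cat == "both") {
    side_pattern <- if (sum(a) == 1L && sum(b) == 1L) {
      if (all(a == b)) "same_side" else "opposite_sides"
    } else {
      "mixed"
    }
  }
  data.frame(fiber_id = record$fiber_id, construct = record$construct,
             which = which_cat, side_pattern = side_pattern,
             B_left = unname(a["left"]), B_right = unname(a["right"]),
             I_left = unname(b["left"]), I_right = unname(b["right"]),
             stringsAsFactors = FALSE)
}
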