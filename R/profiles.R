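#' Construct an intensity profile
#'
#' One channel's gray values sampled at increasing positions (in micrometers)
#' along a stretched chromatin fiber, as exported from a plot-profile table.
#'
#' @param fiber_id Character scalar identifying the fiber.
#' @param channel Channel label, e.g. `"CENP-A"`, `"biotin"`, `"CENP-B"`.
#' @param positions Numeric vector of strictly increasing positions (um).
#' @param values Numeric vector of non-negative gray values, same length as
#'   `positions`.
#' @param pixel_size_um Sampling step in um per pixel (default 0.064).
#'
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(fiber_id, channel, positions, values,
                              pixel_size_um = 0.064) {
  stopifnot(is.character(fiber_id), length(fiber_id) == 1L,
            is.character(channel), length(channel) == 1L)
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values)) {
    stop("positions and values must have equal length (fiber ", fiber_id, ")")
  }
  if (length(positions) > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing within a channel (fiber ",
         fiber_id, ", channel ", channel, ")")
  }
  if (any(values < 0)) {
    stop("gray values must be non-negative (fiber ", fiber_id, ")")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be positive")
  }
  structure(
    list(fiber_id = fiber_id, channel = channel,
         positions = positions, values = values,
         pixel_size_um = pixel_size_um),
    class = "intensity_profile"
  )
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat("<intensity_profile> fiber", x$fiber_id, "channel", x$channel,
      sprintf("| %d samples over %.3f um\n",
              length(x$positions), diff(range(x$positions))))
  invisible(x)
}

#' Construct a fiber record
#'
#' Bundles the per-channel intensity profiles of one fiber. All channels of a
#' fiber share one position grid because a single segmented line is traced per
#' fiber and each staining is profiled along it.
#'
#' @param fiber_id Character scalar.
#' @param construct Construct label (e.g. `"APEX-CENP-A"`).
#' @param preparation One of `"double_lysis"`, `"single_lysis"`, `"TEEN"`.
#' @param profiles Named list of [intensity_profile()] objects, one per
#'   channel; names must match each profile's channel label.
#'
#' @return An object of class `fiber_record`.
#' @export
fiber_record <- function(fiber_id, construct, preparation, profiles) {
  preparation <- match.arg(preparation,
                           c("double_lysis", "single_lysis", "TEEN"))
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  chans <- vapply(profiles, function(p) p$channel, character(1))
  names(profiles) <- chans
  if (anyDuplicated(chans)) {
    stop("duplicate channel in fiber ", fiber_id)
  }
  ref <- profiles[[1L]]
  for (p in profiles) {
    if (p$fiber_id != fiber_id) {
      stop("profile fiber_id mismatch in fiber ", fiber_id)
    }
    if (p$pixel_size_um != ref$pixel_size_um) {
      stop("channels of fiber ", fiber_id, " differ in pixel_size_um")
    }
    if (length(p$positions) != length(ref$positions) ||
        any(p$positions != ref$positions)) {
      stop("channels of fiber ", fiber_id,
           " must share an identical position grid")
    }
  }
  structure(
    list(fiber_id = fiber_id, construct = construct,
         preparation = preparation, profiles = profiles),
    class = "fiber_record"
  )
}

#' @export
print.fiber_record <- function(x, ...) {
  cat("<fiber_record>", x$fiber_id, "|", x$construct, "|", x$preparation,
      "| channels:", paste(names(x$profiles), collapse = ", "), "\n")
  invisible(x)
}

#' Resolve the reference channel of a fiber record
#'
#' The centromere reference is CENP-A when present; triple-stain TEEN fibers
#' use CENP-C as the domain reference instead.
#'
#' @param record A [fiber_record()].
#' @return The reference channel name.
#' @export
reference_channel <- function(record) {
  chans <- names(record$profiles)
  if ("CENP-A" %in% chans) return("CENP-A")
  if ("CENP-C" %in% chans) return("CENP-C")
  stop("fiber ", record$fiber_id,
       ": no reference channel (expected CENP-A, or CENP-C for triple stains)")
}

fiber_table_cols <- c("fiber_id", "construct", "preparation",
                      "channel", "position_um", "gray_value")

#' Read a fiber table
#'
#' Reads a long-format CSV (one row per profile sample) into a list of
#' [fiber_record()] objects. Required columns: `fiber_id`, `construct`,
#' `preparation`, `channel`, `position_um`, `gray_value`.
#'
#' @param path Path to a CSV file.
#' @param pixel_size_um Pixel size assigned to the profiles (um).
#' @return Named list of `fiber_record` objects (names = fiber ids).
#' @export
read_fiber_table <- function(path, pixel_size_um = 0.064) {
  if (!file.exists(path)) stop("no such file: ", path)
  # base read.csv: correctly rounded decimal-to-double conversion, so the
  # write/read round trip is bit-exact
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(fiber_table_cols, names(tab))
  if (length(missing)) {
    stop("fiber table is missing column(s): ", paste(missing, collapse = ", "))
  }
  fiber_records_from_table(tab, pixel_size_um = pixel_size_um)
}

#' Build fiber records from a long-format data frame
#'
#' @param tab Data frame with the fiber-table columns (see
#'   [read_fiber_table()]).
#' @param pixel_size_um Pixel size (um).
#' @return Named list of `fiber_record` objects.
#' @export
fiber_records_from_table <- function(tab, pixel_size_um = 0.064) {
  missing <- setdiff(fiber_table_cols, names(tab))
  if (length(missing)) {
    stop("fiber table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  key <- paste(tab$fiber_id, tab$channel, tab$position_um, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab$fiber_id[duplicated(key)][1L]
    stop("duplicated (fiber_id, channel, position) rows (fiber ", dup, ")")
  }
  records <- lapply(split(tab, tab$fiber_id), function(ft) {
    ft <- ft[order(match(ft$channel, unique(ft$channel))), , drop = FALSE]
    profs <- lapply(split(ft, factor(ft$channel, levels = unique(ft$channel))),
                    function(ct) {
      ct <- ct[order(ct$position_um), , drop = FALSE]
      intensity_profile(ct$fiber_id[1L], ct$channel[1L],
                        ct$position_um, ct$gray_value,
                        pixel_size_um = pixel_size_um)
    })
    fiber_record(ft$fiber_id[1L], ft$construct[1L], ft$preparation[1L],
                 profs)
  })
  records[unique(tab$fiber_id)]
}

#' Flatten fiber records into a long-format data frame
#'
#' @param records List of [fiber_record()] objects.
#' @return Data frame with the standard fiber-table columns.
#' @export
fiber_table <- function(records) {
  rows <- lapply(records, function(r) {
    chans <- lapply(r$profiles, function(p) {
      data.frame(fiber_id = r$fiber_id, construct = r$construct,
                 preparation = r$preparation, channel = p$channel,
                 position_um = p$positions, gray_value = p$values,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, unname(chans))
  })
  out <- do.call(rbind, unname(rows))
  if (is.null(out)) {
    out <- data.frame(fiber_id = character(0), construct = character(0),
                      preparation = character(0), channel = character(0),
                      position_um = numeric(0), gray_value = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a fiber table
#'
#' Writes records as long-format CSV at full numeric precision, so that
#' `read_fiber_table(write_fiber_table(records))` reproduces the records
#' exactly.
#'
#' @param records List of [fiber_record()] objects (may be empty).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiber_table <- function(records, path) {
  tab <- fiber_table(records)
  # 17 significant digits guarantee bit-exact double round-trips
  tab$position_um <- sprintf("%.17g", tab$position_um)
  tab$gray_value <- sprintf("%.17g", tab$gray_value)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Extract a line-scan profile from an image
#'
#' Samples a 2-D gray-value image along a polyline at unit-pixel arc-length
#' steps with nearest-pixel lookup, mirroring a segmented-line plot profile
#' with line width 1. Positions start at 0 at the first vertex and advance by
#' `pixel_size_um` per step.
#'
#' @param image Numeric matrix; `image[row, col]` with 0-based pixel
#'   coordinates `x = col - 1`, `y = row - 1`.
#' @param polyline Two-column matrix of vertices `(x, y)` in 0-based pixel
#'   coordinates; at least two vertices, all inside the image.
#' @param pixel_size_um um per pixel step.
#' @param fiber_id,channel Labels for the resulting profile.
#' @return An [intensity_profile()].
#' @export
extract_line_profile <- function(image, polyline, pixel_size_um = 0.064,
                                 fiber_id = "roi", channel = "gray") {
  stopifnot(is.matrix(image), is.numeric(image))
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L || ncol(polyline) != 2L) {
    stop("polyline must have >= 2 (x, y) vertices")
  }
  nx <- ncol(image); ny <- nrow(image)
  if (any(polyline[, 1] < 0 | polyline[, 1] > nx - 1 |
          polyline[, 2] < 0 | polyline[, 2] > ny - 1)) {
    stop("polyline vertex outside image bounds")
  }
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  t_arc <- seq(0, total, by = 1)
  cum <- c(0, cumsum(seg_len))
  pts <- vapply(t_arc, function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(seg))
    f <- if (seg_len[i] > 0) (s - cum[i]) / seg_len[i] else 0
    polyline[i, ] + f * seg[i, ]
  }, numeric(2))
  col_idx <- round(pts[1, ]) + 1L
  row_idx <- round(pts[2, ]) + 1L
  vals <- image[cbind(row_idx, col_idx)]
  intensity_profile(fiber_id, channel,
                    positions = t_arc * pixel_size_um, values = vals,
                    pixel_size_um = pixel_size_um)
}
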