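#' Construct-preset constructor
#'
#' Parameters of the synthetic-fiber generator for one construct: ground-truth
#' category mix of the query channel, reference coverage, spreading behavior,
#' fiber geometry and rendering parameters. See [builtin_presets()] for the
#' shipped presets.
#'
#' @param name Preset name.
#' @param preparation Fiber preparation (`"double_lysis"` or `"TEEN"`).
#' @param ref_channel,query_channels Channel labels.
#' @param n_ref_peaks Integer range for reference peaks per fiber (before the
#'   resolvability cap, see Details).
#' @param domain_length_um Range of centromere-domain lengths (um).
#' @param frac_query_coloc,frac_query_inside,frac_query_outside Ground-truth
#'   category fractions of query peaks (renormalized to sum 1).
#' @param frac_ref_covered Fraction of reference peaks receiving a
#'   co-localizing query partner.
#' @param spread_fiber_frac Fraction of fibers designated as spreading.
#' @param force_spread When `TRUE`, every designated spreading fiber carries
#'   at least one outside peak (the conditional outside rate is compensated so
#'   the cohort mean outside fraction still equals `frac_query_outside`).
#' @param outside_distance_um Range of outside-peak offsets beyond the domain
#'   edge plus the co-localization threshold (um).
#' @param punctum_sigma_px Gaussian punctum sigma in pixels (~4-5 px dot
#'   width).
#' @param amplitude Gray-value amplitude range of rendered puncta.
#' @param noise_sd SD of the half-normal background noise (gray values).
#' @param pixel_size_um um per pixel.
#' @param coloc_um Co-localization threshold used for ground-truth placement.
#' @param min_ref_spacing_um Minimum reference peak spacing enforced for
#'   punctum resolvability (caps the realized number of reference peaks at
#'   `floor(domain / min_ref_spacing_um) + 1`).
#' @param cospread_mix,side_mix For triple-stain presets: probabilities of
#'   `both`/`only_B`/`only_I` among spreading fibers, and of
#'   `same_side`/`opposite_sides`/`mixed` among `both` fibers.
#' @return An object of class `construct_preset`.
#' @export
construct_preset <- function(name,
                             preparation = "double_lysis",
                             ref_channel = "CENP-A",
                             query_channels = "biotin",
                             n_ref_peaks = c(8L, 25L),
                             domain_length_um = c(5, 15),
                             frac_query_coloc = 0.86,
                             frac_query_inside = 0.127,
                             frac_query_outside = 0.013,
                             frac_ref_covered = 0.70,
                             spread_fiber_frac = 0.10,
                             force_spread = FALSE,
                             outside_distance_um = c(0.3, 3.0),
                             punctum_sigma_px = 2.0,
                             amplitude = c(400, 3000),
                             noise_sd = 40,
                             pixel_size_um = 0.064,
                             coloc_um = 0.192,
                             min_ref_spacing_um = 1.8,
                             cospread_mix = NULL,
                             side_mix = NULL) {
  fr <- c(frac_query_coloc, frac_query_inside, frac_query_outside)
  if (any(fr < 0) || sum(fr) <= 0) stop("category fractions must be >= 0")
  fr <- fr / sum(fr)
  p <- structure(list(
    name = name, preparation = preparation, ref_channel = ref_channel,
    query_channels = query_channels,
    n_ref_peaks = as.integer(n_ref_peaks),
    domain_length_um = domain_length_um,
    frac_query_coloc = fr[1], frac_query_inside = fr[2],
    frac_query_outside = fr[3],
    frac_ref_covered = frac_ref_covered,
    spread_fiber_frac = spread_fiber_frac,
    force_spread = force_spread,
    outside_distance_um = outside_distance_um,
    punctum_sigma_px = punctum_sigma_px,
    amplitude = amplitude, noise_sd = noise_sd,
    pixel_size_um = pixel_size_um, coloc_um = coloc_um,
    min_ref_spacing_um = min_ref_spacing_um,
    cospread_mix = cospread_mix, side_mix = side_mix),
    class = "construct_preset")
  validate_preset(p)
  p
}

validate_preset <- function(p) {
  stopifnot(p$pixel_size_um > 0, p$punctum_sigma_px > 0,
            length(p$n_ref_peaks) == 2L, p$n_ref_peaks[1] >= 2L,
            p$n_ref_peaks[2] >= p$n_ref_peaks[1],
            length(p$domain_length_um) == 2L, p$domain_length_um[1] > 0,
            p$frac_ref_covered > 0, p$frac_ref_covered <= 1,
            p$spread_fiber_frac >= 0, p$spread_fiber_frac <= 1,
            p$outside_distance_um[1] > 0,
            p$amplitude[1] <= p$amplitude[2], p$noise_sd >= 0)
  if (p$frac_query_outside > p$spread_fiber_frac + 1e-12) {
    stop("preset ", p$name, ": frac_query_outside exceeds spread_fiber_frac")
  }
  thr <- if (identical(p$preparation, "TEEN")) 200 else 300
  if (p$amplitude[1] <= 300) {
    stop("preset ", p$name,
         ": minimum amplitude must exceed the detection threshold (300)")
  }
  if (p$noise_sd > thr / 5) {
    stop("preset ", p$name, ": noise_sd too large; background noise would ",
         "cross the detection threshold")
  }
  if (!is.null(p$cospread_mix)) {
    stopifnot(length(p$cospread_mix) == 3L, abs(sum(p$cospread_mix) - 1) < 1e-9,
              length(p$side_mix) == 3L, abs(sum(p$side_mix) - 1) < 1e-9,
              length(p$query_channels) == 2L)
  }
  invisible(p)
}

#' @export
print.construct_preset <- function(x, ...) {
  cat("<construct_preset>", x$name, "|", x$preparation,
      "| ref", x$ref_channel, "| query",
      paste(x$query_channels, collapse = "+"), "\n",
      sprintf("  category mix %.1f/%.1f/%.1f%% | ref covered %.0f%% | %.0f%% fibers spread\n",
              100 * x$frac_query_coloc, 100 * x$frac_query_inside,
              100 * x$frac_query_outside, 100 * x$frac_ref_covered,
              100 * x$spread_fiber_frac))
  invisible(x)
}

#' Built-in construct presets
#'
#' One preset per mapped construct, with the query-peak category mixes set to
#' the printed cohort-level fractions: APEX-CENP-A 86/12.7/1.3 with 70% of
#' reference peaks covered; CENP-C and CENP-T 72/28/0; CENP-N 66/34/0;
#' CENP-P/K/M share the APEX-CENP-A mix; CENP-I 11.7% outside with 60% of
#' fibers spreading (printed bound: more than half); CENP-B 16.2% outside
#' with 75% of fibers spreading (printed bound: more than 70%). The
#' triple-stain TEEN preset draws, per spreading fiber, both/only-B/only-I at
#' 29/29/42 and, among fibers where both proteins spread,
#' same/opposite/mixed sides at 70/12/18.
#'
#' @return Named list of [construct_preset()] objects.
#' @export
builtin_presets <- function() {
  apex <- construct_preset("APEX-CENP-A")
  confined <- function(name, coloc) {
    construct_preset(name, frac_query_coloc = coloc,
                     frac_query_inside = 1 - coloc, frac_query_outside = 0,
                     spread_fiber_frac = 0)
  }
  like_apex <- function(name) construct_preset(name)
  spreading <- function(name, outside, spread_frac) {
    construct_preset(name,
                     frac_query_coloc = 0.55,
                     frac_query_inside = 1 - 0.55 - outside,
                     frac_query_outside = outside,
                     spread_fiber_frac = spread_frac,
                     force_spread = TRUE)
  }
  teen <- construct_preset("TEEN-triple",
                           preparation = "TEEN",
                           ref_channel = "CENP-C",
                           query_channels = c("CENP-B", "CENP-I"),
                           domain_length_um = c(3, 8),
                           frac_query_coloc = 0.70,
                           frac_query_inside = 0.30,
                           frac_query_outside = 0,
                           spread_fiber_frac = 0.60,
                           force_spread = TRUE,
                           cospread_mix = c(both = 0.29, only_B = 0.29,
                                            only_I = 0.42),
                           side_mix = c(same_side = 0.70,
                                        opposite_sides = 0.12,
                                        mixed = 0.18))
  list(
    "APEX-CENP-A" = apex,
    "CENP-C" = confined("CENP-C", 0.72),
    "CENP-N" = confined("CENP-N", 0.66),
    "CENP-T" = confined("CENP-T", 0.72),
    "CENP-P" = like_apex("CENP-P"),
    "CENP-K" = like_apex("CENP-K"),
    "CENP-M" = like_apex("CENP-M"),
    "CENP-I" = spreading("CENP-I", 0.117, 0.60),
    "CENP-B" = spreading("CENP-B", 0.162, 0.75),
    "TEEN-triple" = teen
  )
}

# Placement guard bands (um). An inside-non-coloc peak keeps
# inside_ref_clearance from every reference peak (so calling noise cannot turn
# it co-localizing) and any two same-channel peaks keep min_same_channel_sep
# (so two rendered puncta at maximal amplitude still dip below threshold
# between them and are called as two runs).
.inside_ref_clearance <- 0.40
.min_same_channel_sep <- 0.70
.fiber_margin_um <- 4.0

#' Simulate one fiber
#'
#' Draws fiber geometry (domain length, reference peaks on a jittered regular
#' grid), designates spreading, draws query-peak category counts so that
#' cohort means recover the preset fractions, places peaks with resolvability
#' guard bands, and renders every channel as a sum of Gaussian puncta plus
#' half-normal background noise on a shared position grid.
#'
#' @param preset A [construct_preset()].
#' @param seed Integer seed; the same (preset, seed) pair reproduces the fiber
#'   bit-identically.
#' @param fiber_id Fiber identifier.
#' @return List with `record` (a [fiber_record()]) and `truth` (true peak
#'   positions, per-peak category labels and sides, true domain bounds).
#' @export
simulate_fiber <- function(preset, seed, fiber_id = NULL) {
  validate_preset(preset)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.null(fiber_id)) fiber_id <- sprintf("%s_s%d", preset$name, seed)
  set.seed(as.integer(seed))
  for (attempt in seq_len(30L)) {
    out <- try(simulate_fiber_once(preset, fiber_id), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  stop("fiber placement infeasible after 30 attempts for preset ",
       preset$name, ": ", attr(out, "condition")$message)
}

simulate_fiber_once <- function(preset, fiber_id) {
  px <- preset$pixel_size_um
  coloc <- preset$coloc_um
  # geometry: reference peaks on a jittered regular grid; density capped so
  # adjacent puncta remain resolvable above threshold
  dom_len <- stats::runif(1, preset$domain_length_um[1],
                          preset$domain_length_um[2])
  n_cap <- floor(dom_len / preset$min_ref_spacing_um) + 1L
  n_ref <- sample(seq.int(preset$n_ref_peaks[1], preset$n_ref_peaks[2]), 1L)
  n_ref <- max(2L, min(n_ref, n_cap))
  spacing <- dom_len / (n_ref - 1L)
  ref_pos <- .fiber_margin_um + (seq_len(n_ref) - 1L) * spacing +
    stats::runif(n_ref, -0.05, 0.05) * spacing
  ref_pos <- sort(ref_pos)
  dom_start <- ref_pos[1L]
  dom_end <- ref_pos[n_ref]

  # spreading plan
  if (!is.null(preset$cospread_mix)) {
    plan <- cospread_plan(preset)
  } else {
    spreads <- stats::runif(1) < preset$spread_fiber_frac
    plan <- list(spreads = spreads, sides = NULL)
  }

  queries <- list()
  truth_q <- list()
  for (ci in seq_along(preset$query_channels)) {
    ch <- preset$query_channels[ci]
    triple <- !is.null(preset$cospread_mix)
    sides <- if (triple) plan$sides[[ci]] else NULL
    spreads_ch <- if (triple) length(sides) > 0 else plan$spreads
    q <- place_query_channel(preset, ref_pos, dom_start, dom_end,
                             spreads_ch, sides)
    queries[[ch]] <- q$positions
    truth_q[[ch]] <- data.frame(position_um = q$positions,
                                label = q$labels, side = q$sides,
                                stringsAsFactors = FALSE)
  }

  # shared position grid covering the domain plus margins
  extent <- dom_end + .fiber_margin_um
  n_samples <- floor(extent / px) + 1L
  grid <- (seq_len(n_samples) - 1L) * px
  sigma_um <- preset$punctum_sigma_px * px

  render <- function(mu) {
    v <- numeric(n_samples)
    if (length(mu)) {
      amp <- stats::runif(length(mu), preset$amplitude[1], preset$amplitude[2])
      for (j in seq_along(mu)) {
        v <- v + amp[j] * exp(-(grid - mu[j])^2 / (2 * sigma_um^2))
      }
    }
    if (preset$noise_sd > 0) {
      v <- v + abs(stats::rnorm(n_samples, 0, preset$noise_sd))
    }
    v
  }

  profiles <- list()
  profiles[[preset$ref_channel]] <-
    intensity_profile(fiber_id, preset$ref_channel, grid, render(ref_pos),
                      pixel_size_um = px)
  for (ch in preset$query_channels) {
    profiles[[ch]] <- intensity_profile(fiber_id, ch, grid,
                                        render(queries[[ch]]),
                                        pixel_size_um = px)
  }
  record <- fiber_record(fiber_id, preset$name, preset$preparation, profiles)
  truth <- list(fiber_id = fiber_id,
                ref_positions = ref_pos,
                domain_start_um = dom_start, domain_end_um = dom_end,
                query = truth_q,
                cospread = if (!is.null(preset$cospread_mix)) plan$category
                else NULL,
                side_pattern = if (!is.null(preset$cospread_mix)) plan$pattern
                else NULL)
  list(record = record, truth = truth)
}

# Per-fiber spreading plan for triple-stain presets: which proteins spread
# and on which sides.
cospread_plan <- function(preset) {
  if (stats::runif(1) >= preset$spread_fiber_frac) {
    return(list(spreads = FALSE, category = "none", pattern = NA_character_,
                sides = list(character(0), character(0))))
  }
  category <- sample(c("both", "only_B", "only_I"), 1L,
                     prob = preset$cospread_mix)
  pattern <- NA_character_
  one_side <- function() sample(c("left", "right"), 1L)
  solo_sides <- function() {
    u <- stats::runif(1)
    if (u < 0.45) "left" else if (u < 0.90) "right" else c("left", "right")
  }
  if (category == "both") {
    pattern <- sample(c("same_side", "opposite_sides", "mixed"), 1L,
                      prob = preset$side_mix)
    if (pattern == "same_side") {
      s <- one_side()
      sides <- list(s, s)
    } else if (pattern == "opposite_sides") {
      s <- one_side()
      sides <- list(s, setdiff(c("left", "right"), s))
    } else {
      combos <- list(list(c("left", "right"), "left"),
                     list(c("left", "right"), "right"),
                     list("left", c("left", "right")),
                     list("right", c("left", "right")),
                     list(c("left", "right"), c("left", "right")))
      sides <- combos[[sample.int(5L, 1L)]]
    }
  } else if (category == "only_B") {
    sides <- list(solo_sides(), character(0))
  } else {
    sides <- list(character(0), solo_sides())
  }
  list(spreads = TRUE, category = category, pattern = pattern, sides = sides)
}

# Draw category counts and place one query channel's peaks.
place_query_channel <- function(preset, ref_pos, dom_start, dom_end,
                                spreads, sides = NULL) {
  coloc <- preset$coloc_um
  n_ref <- length(ref_pos)
  fr_c <- preset$frac_query_coloc
  fr_i <- preset$frac_query_inside
  fr_o <- preset$frac_query_outside
  c_share <- fr_c / (fr_c + fr_i)
  o_cond <- if (spreads && preset$spread_fiber_frac > 0) {
    min(fr_o / preset$spread_fiber_frac, 0.95)
  } else 0

  if (!is.null(sides)) {
    # triple-stain plan: outside counts come from the designated sides
    n_rest <- max(2L, round(preset$frac_ref_covered * n_ref / c_share))
    n_out <- if (length(sides)) {
      length(sides) + stats::rbinom(1L, 1L, 0.3)
    } else 0L
    side_draw <- if (n_out > 0) {
      c(sides, sample(sides, n_out - length(sides), replace = TRUE))
    } else character(0)
  } else {
    n_query <- max(2L, round(preset$frac_ref_covered * n_ref /
                               ((1 - o_cond) * c_share)))
    if (spreads && preset$force_spread && o_cond > 0) {
      # at least one outside peak, with the remaining outside rate
      # compensated so E[outside fraction] stays at o_cond
      n_query <- max(n_query, ceiling(1 / o_cond))
      q2 <- (n_query * o_cond - 1) / (n_query - 1)
      q2 <- min(max(q2, 0), 1)
      n_out <- 1L + stats::rbinom(1L, n_query - 1L, q2)
    } else {
      n_out <- stats::rbinom(1L, n_query, o_cond)
    }
    n_rest <- n_query - n_out
    side_draw <- sample(c("left", "right"), n_out, replace = TRUE)
  }
  n_coloc <- stats::rbinom(1L, n_rest, c_share)
  n_in <- n_rest - n_coloc

  positions <- numeric(0)
  labels <- character(0)
  side_out <- character(0)

  # co-localizing peaks: one partner per distinct covered reference peak
  n_coloc <- min(n_coloc, n_ref)
  if (n_coloc > 0) {
    covered <- sample.int(n_ref, n_coloc)
    pos_c <- ref_pos[covered] + stats::runif(n_coloc, -coloc / 2, coloc / 2)
    positions <- c(positions, pos_c)
    labels <- c(labels, rep("coloc", n_coloc))
    side_out <- c(side_out, rep(NA_character_, n_coloc))
  }

  # outside peaks: beyond edge + coloc threshold by a sampled offset
  for (s in side_draw) {
    pos <- place_with_rejection(function() {
      off <- coloc + stats::runif(1, preset$outside_distance_um[1],
                                  preset$outside_distance_um[2])
      if (s == "left") dom_start - off else dom_end + off
    }, positions, min_sep = .min_same_channel_sep)
    positions <- c(positions, pos)
    labels <- c(labels, "outside")
    side_out <- c(side_out, s)
  }

  # inside-non-co-localizing peaks: within the domain, clear of every
  # reference peak and of already placed query peaks
  for (j in seq_len(n_in)) {
    pos <- place_with_rejection(function() {
      stats::runif(1, dom_start + 0.1, dom_end - 0.1)
    }, positions, min_sep = .min_same_channel_sep,
    extra_check = function(p) {
      min(abs(p - ref_pos)) >= .inside_ref_clearance
    })
    positions <- c(positions, pos)
    labels <- c(labels, "inside")
    side_out <- c(side_out, NA_character_)
  }

  ord <- order(positions)
  list(positions = positions[ord], labels = labels[ord],
       sides = side_out[ord])
}

place_with_rejection <- function(draw, existing, min_sep,
                                 extra_check = NULL, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    p <- draw()
    if (length(existing) && min(abs(p - existing)) < min_sep) next
    if (!is.null(extra_check) && !extra_check(p)) next
    return(p)
  }
  stop("could not place a query peak within ", max_tries, " tries")
}

#' Simulate a cohort of fibers
#'
#' Independent fibers from per-fiber seeds derived from the master seed
#' (`seed + fiber index`), so cohorts are reproducible and any fiber can be
#' regenerated in isolation.
#'
#' @param preset A [construct_preset()] or the name of a built-in preset.
#' @param n_fibers Number of fibers (>= 1).
#' @param seed Master integer seed.
#' @return List with `records` (named list of [fiber_record()]) and `truths`
#'   (named list of per-fiber ground truths).
#' @export
simulate_cohort <- function(preset, n_fibers, seed) {
  if (is.character(preset)) {
    presets <- builtin_presets()
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    }
    preset <- presets[[preset]]
  }
  stopifnot(n_fibers >= 1)
  sims <- lapply(seq_len(n_fibers), function(i) {
    simulate_fiber(preset, seed + i,
                   fiber_id = sprintf("%s_f%04d", preset$name, i))
  })
  records <- lapply(sims, `[[`, "record")
  truths <- lapply(sims, `[[`, "truth")
  ids <- vapply(records, `[[`, character(1), "fiber_id")
  names(records) <- ids
  names(truths) <- ids
  list(records = records, truths = truths)
}

#' Ground-truth table of a simulated cohort
#'
#' @param truths `truths` element from [simulate_cohort()].
#' @return Long data frame of true query peaks (fiber, channel, position,
#'   label, side) with the true domain bounds.
#' @export
ground_truth_table <- function(truths) {
  rows <- lapply(truths, function(tr) {
    per_ch <- lapply(names(tr$query), function(ch) {
      q <- tr$query[[ch]]
      if (nrow(q) == 0L) return(NULL)
      data.frame(fiber_id = tr$fiber_id, channel = ch, q,
                 domain_start_um = tr$domain_start_um,
                 domain_end_um = tr$domain_end_um,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_ch)
  })
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out
}
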