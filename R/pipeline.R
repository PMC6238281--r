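#' Analyze a cohort of fiber records
#'
#' Runs the full per-fiber quantification over a cohort: peak calling with the
#' preparation-aware thresholds, co-localization, domain metrics, category
#' classification and spreading; triple-stain fibers additionally get a
#' co-spreading classification. Fibers with an empty reference or query
#' channel are excluded with a reason, never silently dropped; every input
#' fiber appears exactly once in either the metrics table or the exclusion
#' list. The analysis path draws no random numbers, so identical inputs give
#' identical outputs.
#'
#' @param records List of [fiber_record()] objects (or a fiber-table data
#'   frame / CSV path, which is read first).
#' @param config A [threshold_config()].
#' @return List with `metrics` (per-fiber data frame), `exclusions`
#'   (fiber_id + reason), and `cospreading` (per-fiber co-spreading table,
#'   `NULL` unless triple-stain fibers are present).
#' @export
analyze_cohort <- function(records, config = threshold_config()) {
  if (is.character(records)) records <- read_fiber_table(records)
  if (is.data.frame(records)) records <- fiber_records_from_table(records)
  metrics <- list()
  cospread <- list()
  exclusions <- list()
  for (r in records) {
    chans <- names(r$profiles)
    triple <- all(c("CENP-B", "CENP-I") %in% chans) &&
      reference_channel(r) == "CENP-C"
    res <- tryCatch({
      if (triple) {
        cs <- classify_cospreading(r, config)
        mB <- compute_fiber_metrics(r, config, query_channel = "CENP-B")
        list(cospread = cs, metrics = mB)
      } else {
        list(cospread = NULL, metrics = compute_fiber_metrics(r, config))
      }
    }, fiber_excluded = function(e) e)
    if (inherits(res, "fiber_excluded")) {
      exclusions[[r$fiber_id]] <- data.frame(
        fiber_id = res$fiber_id, reason = res$reason,
        stringsAsFactors = FALSE)
      next
    }
    metrics[[r$fiber_id]] <- res$metrics
    if (!is.null(res$cospread)) cospread[[r$fiber_id]] <- res$cospread
  }
  bindr <- function(x) if (length(x)) {
    out <- do.call(rbind, unname(x)); rownames(out) <- NULL; out
  } else NULL
  list(metrics = bindr(metrics),
       exclusions = if (length(exclusions)) bindr(exclusions) else
         data.frame(fiber_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE),
       cospreading = bindr(cospread))
}

#' Simulate a cohort and write its files
#'
#' Orchestration wrapper around [simulate_cohort()]: writes the fiber table
#' and the ground-truth table under `out_dir` and logs a one-line summary.
#'
#' @param preset Preset name (see [builtin_presets()]) or a
#'   [construct_preset()].
#' @param n_fibers Number of fibers.
#' @param seed Master seed; when omitted, one is drawn and logged so the run
#'   stays reproducible.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the written paths and the simulated cohort.
#' @export
run_simulate <- function(preset, n_fibers, seed = NULL, out_dir = ".") {
  if (is.null(seed)) {
    seed <- sample.int(1e6, 1L)
    message("no seed given; drew seed = ", seed)
  }
  cohort <- simulate_cohort(preset, n_fibers, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  name <- if (is.character(preset)) preset else preset$name
  fiber_path <- file.path(out_dir, paste0(name, "_fibers.csv"))
  truth_path <- file.path(out_dir, paste0(name, "_truth.csv"))
  write_fiber_table(cohort$records, fiber_path)
  readr::write_csv(ground_truth_table(cohort$truths), truth_path,
                   progress = FALSE)
  message("simulated ", n_fibers, " fibers (preset ", name,
          ", seed ", seed, ") -> ", fiber_path)
  invisible(list(fiber_table = fiber_path, truth_table = truth_path,
                 cohort = cohort, seed = seed))
}

#' Analyze fiber tables and write report files
#'
#' End-to-end batch analysis: reads one or more fiber tables, computes
#' per-fiber metrics and exclusions, per-construct summaries, and statistical
#' comparisons against the reference construct (FDR-adjusted within each
#' metric), writing each as CSV under `out_dir`. Per-fiber intensity plots
#' are optional so headless runs need no graphics device.
#'
#' @param input Fiber-table CSV path(s), a data frame, or a list of
#'   [fiber_record()] objects.
#' @param out_dir Output directory.
#' @param config A [threshold_config()].
#' @param reference Reference construct for comparisons (skipped, with a
#'   message, when absent from the data).
#' @param plots If `TRUE`, writes one intensity-profile plot per fiber.
#' @return Invisibly, a list with `metrics`, `exclusions`, `cospreading`,
#'   `summaries`, `comparisons` and the written paths.
#' @export
run_analyze <- function(input, out_dir = ".", config = threshold_config(),
                        reference = "APEX-CENP-A", plots = FALSE) {
  records <- if (is.character(input)) {
    recs <- lapply(input, read_fiber_table)
    do.call(c, recs)
  } else if (is.data.frame(input)) {
    fiber_records_from_table(input)
  } else input
  res <- analyze_cohort(records, config)
  if (is.null(res$metrics)) stop("no fiber could be analyzed")
  for (ex in seq_len(nrow(res$exclusions))) {
    message("WARN excluded ", res$exclusions$fiber_id[ex], ": ",
            res$exclusions$reason[ex])
  }
  constructs <- unique(res$metrics$construct)
  summaries <- do.call(rbind, lapply(constructs, function(cn) {
    cbind(construct = cn, summarize_construct(res$metrics, cn))
  }))
  comparisons <- NULL
  if (reference %in% constructs && length(constructs) > 1L) {
    comparisons <- compare_constructs(res$metrics, reference)
  } else if (length(constructs) > 1L) {
    message("reference construct ", reference,
            " not in data; skipping comparisons")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(metrics = file.path(out_dir, "fiber_metrics.csv"),
                exclusions = file.path(out_dir, "exclusions.csv"),
                summaries = file.path(out_dir, "construct_summaries.csv"))
  readr::write_csv(res$metrics, paths$metrics, progress = FALSE)
  readr::write_csv(res$exclusions, paths$exclusions, progress = FALSE)
  readr::write_csv(summaries, paths$summaries, progress = FALSE)
  if (!is.null(res$cospreading)) {
    paths$cospreading <- file.path(out_dir, "cospreading.csv")
    readr::write_csv(res$cospreading, paths$cospreading, progress = FALSE)
  }
  if (!is.null(comparisons)) {
    paths$comparisons <- file.path(out_dir, "stats_report.csv")
    readr::write_csv(comparisons, paths$comparisons, progress = FALSE)
  }
  if (isTRUE(plots)) {
    plot_dir <- file.path(out_dir, "plots")
    dir.create(plot_dir, showWarnings = FALSE)
    for (r in records) {
      p <- plot_fiber_profile(r)
      ggplot2::ggsave(file.path(plot_dir, paste0(r$fiber_id, ".png")),
                      p, width = 8, height = 2 + length(r$profiles),
                      dpi = 120)
    }
  }
  invisible(c(res, list(summaries = summaries, comparisons = comparisons,
                        paths = paths)))
}

#' Intensity-profile plot for one fiber
#'
#' Gray value against position (um) along the fiber, one panel per channel,
#' with the detection threshold drawn as a dashed line.
#'
#' @param record A [fiber_record()].
#' @param config A [threshold_config()] (for the threshold lines).
#' @return A ggplot object.
#' @export
plot_fiber_profile <- function(record, config = threshold_config()) {
  dat <- do.call(rbind, lapply(record$profiles, function(p) {
    data.frame(channel = p$channel, position_um = p$positions,
               gray_value = p$values, stringsAsFactors = FALSE)
  }))
  thr <- do.call(rbind, lapply(names(record$profiles), function(ch) {
    data.frame(channel = ch,
               threshold = resolve_threshold(ch, record$preparation, config),
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = position_um, y = gray_value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Position along fiber (µm)", y = "Gray value",
                  title = record$fiber_id) +
    ggplot2::theme_minimal(base_size = 10)
}
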