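# fiberscan

Peak-based quantification of fluorescence line scans from stretched
chromatin fibers.

Centromeres live on megabases of near-identical satellite repeats, where
sequencing-based protein maps (ChIP-seq) break down. A
microscopy alternative is to stretch interphase chromatin into quasi-1-D
fibers, stain the centromere reference (CENP-A, or CENP-C on triple stains)
alongside a protein of interest or an APEX-deposited biotin mark, and trace
each staining as an intensity profile along the fiber. `fiberscan` turns
those profiles into per-fiber and per-construct numbers:

- **Peak calling** — one peak per maximal run of samples at or above the
  gray-value threshold (300; 200 for antibody channels on TEEN-buffer
  fibers), at the run maximum.
- **Co-localization** — per-peak nearest-neighbor distances between
  channels; a pair within d ≤ 0.192 µm (3 px) co-localizes. The statistic is
  directional: %biotin peaks near CENP-A ≠ %CENP-A peaks near biotin.
- **Domain metrics** — the centromere domain [first, last] reference peak;
  peak-count and domain-size ratios; the three-category split of query peaks
  (co-localizing / inside-non-co-localizing / outside); spreading distances
  ds beyond each edge (zero within the co-localization tolerance) and a
  per-fiber spreading flag; two-protein co-spreading patterns
  (both/only-B/only-I; same/opposite/mixed sides) on CENP-C + CENP-B +
  CENP-I triple stains.
- **Statistics** — across-fiber mean/SD/SEM per construct; Shapiro–Wilk
  normality check selecting an unpaired t test or a two-sample
  Kolmogorov–Smirnov test; Benjamini–Hochberg FDR adjustment within each
  metric's comparison family; `ns` / `*` / `**` annotations.
- **Synthetic-fiber generator** — construct presets that encode published
  cohort fractions as ground truth, rendering Gaussian puncta plus
  sub-threshold noise, so every stage is testable by parameter recovery
  without microscopy data.

## Worked example

Simulate a 42-fiber APEX-CENP-A-like cohort and quantify it:

```r
library(fiberscan)
co  <- simulate_cohort("APEX-CENP-A", 42, seed = 7)
res <- analyze_cohort(co$records)
head(res$metrics[, c("fiber_id", "n_ref_peaks", "n_query_peaks",
                     "pct_query_coloc", "pct_ref_coloc", "pct_outside")], 4)
#>           fiber_id n_ref_peaks n_query_peaks pct_query_coloc pct_ref_coloc pct_outside
#>  APEX-CENP-A_f0001           6             5             100      83.33333           0
#>  APEX-CENP-A_f0002           5             4              50      40.00000           0
#>  APEX-CENP-A_f0003           6             5             100      83.33333           0
#>  APEX-CENP-A_f0004           5             4              75      60.00000           0

s <- summarize_construct(res$metrics)
s[s$metric %in% c("pct_query_coloc", "pct_ref_coloc",
                  "pct_inside_noncoloc", "pct_outside"), ]
#>               metric   mean    sd    sem n_fibers single_fiber
#>      pct_query_coloc 86.502 18.39 2.8381       42        FALSE
#>        pct_ref_coloc 69.742 14.92 2.3029       42        FALSE
#>  pct_inside_noncoloc 11.910 16.05 2.4768       42        FALSE
#>          pct_outside  1.587  6.17 0.9521       42        FALSE
```

Read the summary as: on this cohort 86.5% of biotin peaks co-localize with a
CENP-A peak while only 69.7% of CENP-A peaks have a biotin partner
(proximity labeling does not cover every reference peak); 11.9% of biotin
peaks sit inside the centromere domain without co-localizing, and 1.6% fall
outside it — all as per-fiber percentages averaged over n = 42 fibers with
their SEM.

`run_simulate()` / `run_analyze()` write the same results as CSV reports
(metrics, exclusions with reasons, per-construct summaries, FDR-adjusted
comparisons, optional per-fiber intensity plots), and
`inst/scripts/fiberscan` exposes both as shell subcommands. Real data enter
through `read_fiber_table()` (long-format CSV: `fiber_id, construct,
preparation, channel, position_um, gray_value`) or
`extract_line_profile()`, which samples a gray-value image along a traced
polyline exactly like a width-1 segmented-line plot profile.

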