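---
title: "Quantifying protein distributions on stretched chromatin fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein distributions on stretched chromatin fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberscan)
```

## The measurement problem

Centromeres sit on megabases of near-identical satellite repeats, so
sequencing-based maps of protein binding collapse there. An alternative is to
stretch interphase chromatin into quasi-1-D fibers, stain two or three
proteins (or a proximity-deposited biotin mark), and read each staining as a
line-scan intensity profile along the fiber. The centromere is then the
interval delimited by the reference staining (CENP-A, or CENP-C on
triple-stain fibers), and every other protein's position is described
relative to it.

`fiberscan` implements that quantification as a deterministic pipeline:

1. **Peak calling.** A profile sample belongs to a peak when its gray value
   reaches the detection threshold: 300 for all channels, except antibody
   channels on gently lysed (TEEN) fibers, which use 200 (the
   streptavidin-read biotin channel keeps 300). Each *maximal run* of
   consecutive above-threshold samples yields exactly one peak at the run's
   maximum. A fluorescent punctum is ~4–5 px wide and produces one run, so
   this counts puncta rather than sub-threshold ripples or sub-maxima. Ties
   on a plateau resolve to the midpoint sample, rounding to the lower index —
   deterministic, and symmetric in expectation under profile reversal.
2. **Nearest-peak co-localization.** For each query peak the distance to its
   closest reference peak (and vice versa); a pair at distance ≤ 0.192 µm
   (3 px at 0.064 µm/px, matching the punctum width and the optical
   resolution limit) co-localizes. The pairing is independent per peak, not
   one-to-one: that is why the two directions of the statistic differ and
   both are reported.
3. **Domain metrics.** The reference domain spans the first to the last
   reference peak. Per fiber we report peak counts and their ratio, domain
   sizes and their ratio, directional co-localization percentages, the
   three-category split of query peaks (co-localizing / inside but not
   co-localizing / outside the domain), spreading distances beyond each edge,
   and a per-fiber spreading flag.
4. **Statistics.** Per-fiber percentages are averaged across fibers (mean,
   SD, SEM) — fibers, not peaks, are the unit of replication. Two-sample
   comparisons check both groups with Shapiro–Wilk (α = 0.05); when both look
   normal an unpaired two-sided Student's t test is used, otherwise a
   two-sample Kolmogorov–Smirnov test. p values are Benjamini–Hochberg
   adjusted within one metric's family of construct-vs-reference
   comparisons, and annotated `ns` (> 0.05), `*` (≤ 0.05) or `**` (< 0.001).

## Decisions where the procedure was underdetermined

**One peak per run, not per local maximum.** Two touching puncta bridged
above threshold are counted once. A consequence worth knowing: run-based
counting is *not* monotone in the threshold — raising the threshold can split
a bridged run into two peaks. The test suite documents this with an explicit
counterexample; monotonicity does hold for resolvable (unimodal-run) puncta.

**The "outside" category tolerates the co-localization distance at the
edges.** A query peak at most 0.192 µm beyond a domain edge co-localizes
with the boundary reference peak, so it is *inside* for the category split
and contributes zero spreading distance. This harmonization makes
`pct_outside > 0` and the spreading flag exactly equivalent, which the
property tests assert. The alternative (strictly outside the interval) would
let the two readouts disagree on the same fiber.

**Spreading distances** are measured from the outermost reference peak on
each side to the furthest query peak beyond it, zero when none lies further
than 0.192 µm out. Left/right follow the profile's position order; the pair
is treated as unordered in cohort statistics (each fiber contributes two
values).

**Co-spreading patterns.** On CENP-C/CENP-B/CENP-I triple stains, fibers are
classified `both`/`only_B`/`only_I`/`none` by each protein's spreading flag.
Among `both` fibers: `same_side` when each protein spreads on exactly one,
identical side; `opposite_sides` when on exactly one side each but different;
`mixed` whenever at least one protein occupies both sides. The raw four side
flags are kept in the output so alternative tabulations of the mixed class
can be derived without re-analysis.

**Exclusions.** A fiber whose reference or query channel yields no peak
cannot be quantified; it is excluded with a recorded reason and counted,
never silently dropped. Every input fiber appears exactly once in the
metrics table or the exclusion list.

**"FDR method"** is read as Benjamini–Hochberg (`p.adjust(method = "fdr")`);
a Welch t variant is available behind `var_equal = FALSE`.

## The synthetic-fiber generator

No fiber micrographs ship with the package, so validation rests on a
generator that produces fibers with known ground truth and profiles that
look like the real inputs: Gaussian puncta (σ = 2 px) of amplitude
400–3000 gray values on a 0.064 µm grid, over half-normal background noise
(SD 40) that stays safely below the detection threshold.

Each built-in preset encodes one construct's published cohort-level readouts
as ground-truth generating fractions:

```{r presets}
pr <- builtin_presets()
t(sapply(pr[c("APEX-CENP-A", "CENP-C", "CENP-N", "CENP-B", "CENP-I")],
         function(p) c(coloc = p$frac_query_coloc,
                       inside = p$frac_query_inside,
                       outside = p$frac_query_outside,
                       spread_frac = p$spread_fiber_frac)))
```

Per fiber, the generator samples a domain length (5–15 µm for salt-detergent
double-lysis fibers, 3–8 µm for the shorter TEEN fibers), lays reference
peaks on a jittered regular grid — emulating interspersed blocks of
reference-positive chromatin — and then realizes query peaks:

* a **spreading indicator** with probability `spread_fiber_frac`; category
  counts are drawn from the *conditional* mixture given that indicator, so
  the cohort mean of every category recovers the preset fraction exactly in
  expectation while finite cohorts fluctuate realistically;
* **co-localizing** peaks sit at a distinct covered reference peak plus a
  uniform offset capped at half the co-localization threshold, so grid
  rounding can never push a true partner past the threshold; the number of
  covered reference peaks is binomial with rate `frac_ref_covered` (0.70),
  which is what makes the two directions of the co-localization percentage
  differ;
* **inside** peaks are rejection-sampled in the domain with guard bands (see
  below); **outside** peaks sit beyond an edge by the threshold plus a
  0.3–3.0 µm offset, on a uniformly chosen side — or on sides prescribed by
  the triple-stain co-spreading plan (`both`/`only_B`/`only_I` drawn at
  29/29/42 among spreading fibers; among `both`, same/opposite/mixed sides at
  70/12/18, the mixed pattern uniform over its five side-occupancy
  combinations).

For constructs whose published spreading rate is only a bound, a designated
spreading fiber is guaranteed at least one outside peak and the residual
outside rate is compensated so the cohort mean outside fraction is
preserved. Where only bounds or no values are printed, the generator commits
to one value and documents it here: fibers spreading — CENP-B 0.75 (bound:
above 0.70), CENP-I 0.60 (bound: above half), APEX-CENP-A 0.10 and
triple-stain TEEN 0.60 (not printed); solo-spreading proteins occupy
left/right/both sides at 0.45/0.45/0.10; query channels on TEEN triple
stains use a 70/30 coloc/inside baseline. These are conditions of the
simulated study, fixed once, not tuning knobs.

### Resolvability guard bands

Exact recovery — the pipeline reproducing every generated label — requires
that rendering, sampling and calling cannot blur two puncta into one run or
move a called position across a classification boundary. With σ = 2 px and
amplitudes up to 3000, the midpoint of two equal puncta falls below the 300
threshold once their separation exceeds 2σ√(2 ln 20) ≈ 9.8 px ≈ 0.63 µm.
The generator therefore enforces:

* same-channel peak separation ≥ 0.70 µm (run separation plus grid
  rounding);
* reference spacing ≥ 1.8 µm, capping the realized reference peak count at
  `floor(domain / 1.8) + 1` — dense defaults are clamped so that an inside
  peak always has room between two covered reference peaks;
* inside peaks ≥ 0.40 µm from every reference peak (the classification
  boundary 0.192 µm plus the worst-case called-position error);
* fibers extend 4 µm beyond the domain on both sides so outside peaks
  (≤ 3.2 µm beyond an edge) never clip the profile.

Placements are rejection-sampled (200 tries per peak, 30 restarts per
fiber); a genuinely infeasible preset errors rather than degrades. With
noise off, recovery is exact (asserted on 50 fibers); with default noise,
run-merging and argmax shifts are rare enough that cohort means recover the
presets within Monte-Carlo error (asserted at 3 SEM on 200-fiber cohorts).

### What the generator does not emulate

Fiber curvature and entanglement, photobleaching, chromatic shift between
channels, uneven stretching along one fiber, and structured (non-white)
background. Passing parameter-recovery tests therefore demonstrates that the
*quantification* is faithful, not that the pipeline is robust to every
artifact of real micrographs — the pipeline's inputs are profiles that have
already been traced.

## Determinism and problem sizes

`simulate_fiber(preset, seed)` is bit-reproducible; cohorts derive per-fiber
seeds as `seed + index`, so any fiber can be regenerated alone. The analysis
path consumes no randomness, making simulate-and-analyze byte-identical
across runs, which the test suite checks on written CSVs. Validation runs
use 200-fiber cohorts (a few seconds each); the type-I-error check of the
select-then-test procedure uses 2000 null replicates at n = 20 per group and
expects a rejection rate of 0.05 ± 0.02.

## Known limitations

* Peak calling is threshold-only by design (no prominence or sub-pixel
  interpolation); a punctum dimmer than the threshold is invisible, and the
  bridged-run behavior above is inherent to the definition.
* Distances are measured along the traced line; physical distances on a
  curved fiber are underestimated by the tracing, an effect outside this
  package's scope.
* With a single reference peak the domain has zero size and the domain-size
  ratio is undefined (reported `NA`); cohort statistics skip missing values
  and flag single-fiber groups.
* The Kolmogorov–Smirnov branch uses the asymptotic p value in the presence
  of ties, which percentage data produce freely; exact small-sample p values
  are not attempted.
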