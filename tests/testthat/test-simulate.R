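test_that("built-in presets encode the published category mixes", {
  pr <- builtin_presets()
  apex <- pr[["APEX-CENP-A"]]
  expect_equal(apex$frac_query_coloc, 0.86, tolerance = 1e-9)
  expect_equal(apex$frac_query_inside, 0.127, tolerance = 1e-9)
  expect_equal(apex$frac_query_outside, 0.013, tolerance = 1e-9)
  expect_equal(apex$frac_ref_covered, 0.70)
  expect_equal(apex$frac_query_coloc + apex$frac_query_inside +
                 apex$frac_query_outside, 1, tolerance = 1e-12)

  expect_equal(pr[["CENP-C"]]$frac_query_outside, 0)
  expect_equal(pr[["CENP-C"]]$frac_query_coloc, 0.72)
  expect_equal(pr[["CENP-N"]]$frac_query_coloc, 0.66)
  expect_equal(pr[["CENP-B"]]$frac_query_outside, 0.162)
  expect_gt(pr[["CENP-B"]]$spread_fiber_frac, 0.70)
  expect_equal(pr[["CENP-I"]]$frac_query_outside, 0.117)
  expect_gt(pr[["CENP-I"]]$spread_fiber_frac, 0.50)
  expect_equal(unname(pr[["TEEN-triple"]]$cospread_mix),
               c(0.29, 0.29, 0.42))
  expect_equal(unname(pr[["TEEN-triple"]]$side_mix), c(0.70, 0.12, 0.18))
})

test_that("preset validation rejects unusable parameter combinations", {
  expect_error(construct_preset("bad", amplitude = c(250, 3000)),
               "detection threshold")
  expect_error(construct_preset("bad", noise_sd = 100), "noise_sd")
  expect_error(construct_preset("bad", frac_query_outside = 0.3,
                                frac_query_coloc = 0.5,
                                frac_query_inside = 0.2,
                                spread_fiber_frac = 0.1),
               "spread_fiber_frac")
})

test_that("simulation is deterministic in (preset, seed)", {
  pr <- builtin_presets()[["APEX-CENP-A"]]
  a <- simulate_fiber(pr, seed = 17)
  b <- simulate_fiber(pr, seed = 17)
  expect_identical(a, b)
  c <- simulate_fiber(pr, seed = 18)
  expect_false(identical(a$record, c$record))

  co1 <- simulate_cohort(pr, 4, seed = 5)
  co2 <- simulate_cohort(pr, 4, seed = 5)
  expect_identical(co1, co2)
})

test_that("ground-truth labels are self-consistent with their positions", {
  for (pn in c("APEX-CENP-A", "CENP-B", "TEEN-triple")) {
    co <- simulate_cohort(pn, 20, seed = 3)
    for (tr in co$truths) {
      for (ch in names(tr$query)) {
        q <- tr$query[[ch]]
        if (nrow(q) == 0) next
        rederived <- oracle_classify(q$position_um, tr$ref_positions)
        rederived[rederived == "inside_noncoloc"] <- "inside"
        expect_identical(q$label, rederived)
      }
    }
  }
})

test_that("noise-free rendering recovers true peaks within one pixel", {
  pr <- builtin_presets()[["APEX-CENP-A"]]
  pr$noise_sd <- 0
  for (seed in 1:10) {
    sim <- simulate_fiber(pr, seed)
    peaks <- call_fiber_peaks(sim$record)
    expect_equal(nrow(peaks[["CENP-A"]]), length(sim$truth$ref_positions))
    expect_true(all(abs(peaks[["CENP-A"]]$position_um -
                          sim$truth$ref_positions) <= 0.064))
    qtruth <- sim$truth$query[["biotin"]]
    expect_equal(nrow(peaks[["biotin"]]), nrow(qtruth))
    expect_true(all(abs(peaks[["biotin"]]$position_um -
                          qtruth$position_um) <= 0.064))
  }
})

test_that("a zero-outside preset never yields outside peaks", {
  co <- simulate_cohort("CENP-C", 30, seed = 6)
  m <- analyze_cohort(co$records)$metrics
  expect_true(all(m$pct_outside == 0))
  expect_true(all(!m$spreads))
})

test_that("cohort means recover preset fractions within Monte-Carlo error", {
  co <- simulate_cohort("APEX-CENP-A", 200, seed = 97)
  m <- analyze_cohort(co$records)$metrics
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(m$pct_query_coloc) - 86), 3 * sem(m$pct_query_coloc))
  expect_lt(abs(mean(m$pct_ref_coloc) - 70), 3 * sem(m$pct_ref_coloc))
})

test_that("unknown presets are rejected with the available names listed", {
  expect_error(simulate_cohort("CENP-Z", 2, seed = 1), "APEX-CENP-A")
})

test_that("ground_truth_table flattens cohorts to one row per query peak", {
  co <- simulate_cohort("APEX-CENP-A", 3, seed = 12)
  tab <- ground_truth_table(co$truths)
  n_expected <- sum(vapply(co$truths,
                           function(tr) nrow(tr$query[["biotin"]]),
                           numeric(1)))
  expect_equal(nrow(tab), n_expected)
  expect_true(all(tab$label %in% c("coloc", "inside", "outside")))
  expect_true(all(tab$side[tab$label == "outside"] %in% c("left", "right")))
})
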