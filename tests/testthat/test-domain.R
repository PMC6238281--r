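test_that("reference_domain spans first to last peak", {
  d <- reference_domain(2.0)
  expect_equal(c(d$start_um, d$end_um, d$size_um), c(2, 2, 0))
  expect_equal(reference_domain(c(1.0, 2.2, 4.5))$size_um, 3.5)
  expect_equal(reference_domain(rev(c(1.0, 2.2, 4.5)))$size_um, 3.5)
  expect_error(reference_domain(numeric(0)), "domain undefined")
})

test_that("classify_peaks matches hand-worked examples", {
  ident <- classify_peaks(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ident$pct_coloc, ident$pct_inside_noncoloc,
                 ident$pct_outside), c(100, 0, 0))

  # a peak 0.1 um beyond the edge co-localizes with the edge peak and is
  # never counted outside
  near_edge <- classify_peaks(query = 3.1, ref = c(1, 3))
  expect_equal(near_edge$labels, "coloc")
  expect_equal(near_edge$pct_outside, 0)

  three <- classify_peaks(query = c(1.05, 2.0, 4.0), ref = c(1.0, 3.0))
  expect_equal(three$labels, c("coloc", "inside_noncoloc", "outside"))
  expect_equal(three$pct_coloc, 100 / 3)
  expect_equal(three$pct_inside_noncoloc, 100 / 3)
  expect_equal(three$pct_outside, 100 / 3)
})

test_that("classify_peaks matches the brute-force oracle on random fibers", {
  set.seed(21)
  for (i in 1:300) {
    r <- sort(runif(sample(2:20, 1), 0, 15))
    q <- runif(sample(1:30, 1), -2, 17)
    got <- classify_peaks(q, r)
    expect_identical(got$labels, oracle_classify(q, r))
    expect_equal(got$pct_coloc + got$pct_inside_noncoloc + got$pct_outside,
                 100, tolerance = 1e-12)
  }
})

test_that("spreading distances follow the edge-tolerance rule", {
  dom <- reference_domain(c(2, 5))
  expect_equal(spreading_distances(c(2.5, 3, 4.9), dom),
               list(ds_left_um = 0, ds_right_um = 0))
  # 0.1 um beyond the edge is within the coloc threshold: not spreading
  expect_equal(spreading_distances(c(3, 5.1), dom)$ds_right_um, 0)
  expect_equal(spreading_distances(c(1.5, 3, 6.0), dom),
               list(ds_left_um = 0.5, ds_right_um = 1.0))
})

test_that("fiber_spreads is the ds > 0 disjunction", {
  expect_false(fiber_spreads(0, 0))
  expect_true(fiber_spreads(0.5, 0))
  expect_true(fiber_spreads(0, 0.193))
})

test_that("outside category and spreading flag are mutually consistent", {
  set.seed(22)
  for (i in 1:200) {
    r <- sort(runif(5, 2, 10))
    q <- runif(8, 0, 12)
    dom <- reference_domain(r)
    cats <- classify_peaks(q, r, dom)
    ds <- spreading_distances(q, dom)
    spreads <- fiber_spreads(ds$ds_left_um, ds$ds_right_um)
    expect_identical(cats$pct_outside > 0, spreads)
  }
})

test_that("identical query and reference channels give identity metrics", {
  rec <- make_fiber(c(1, 2.5, 4), c(1, 2.5, 4))
  m <- compute_fiber_metrics(rec)
  expect_equal(m$peak_count_ratio, 1)
  expect_equal(m$domain_size_ratio, 1)
  expect_equal(m$pct_query_coloc, 100)
  expect_equal(m$pct_ref_coloc, 100)
  expect_equal(m$pct_outside, 0)
  expect_false(m$spreads)
})

test_that("metrics are mirror-symmetric with ds sides swapped", {
  ref <- c(4, 5.5, 7)
  query <- c(2.5, 4.05, 6.2, 9)   # left-spreading and right-spreading peaks
  rec <- make_fiber(ref, query)
  m <- compute_fiber_metrics(rec)
  # mirror about the fiber midpoint
  mid <- 6
  rec_rev <- make_fiber(sort(2 * mid - ref), sort(2 * mid - query))
  m_rev <- compute_fiber_metrics(rec_rev)
  expect_equal(m_rev$pct_query_coloc, m$pct_query_coloc)
  expect_equal(m_rev$pct_outside, m$pct_outside)
  expect_lt(abs(m_rev$ds_left_um - m$ds_right_um), 0.13)
  expect_lt(abs(m_rev$ds_right_um - m$ds_left_um), 0.13)
})

test_that("fibers with an empty channel raise a fiber_excluded condition", {
  rec <- make_fiber(c(1, 2), c(1, 2))
  # query channel rendered at amplitude below threshold
  weak <- make_fiber(c(1, 2), c(1, 2), amplitude = 100)
  weak$profiles[["CENP-A"]]$values <-
    rec$profiles[["CENP-A"]]$values[seq_along(weak$profiles[["CENP-A"]]$values)]
  expect_error(compute_fiber_metrics(weak), class = "fiber_excluded")
})

test_that("cospreading classification covers the side-occupancy space", {
  mk <- function(b_sides, i_sides) {
    dom <- c(4, 8)
    place <- function(sides) {
      pos <- c(4.05, 7.9)  # co-localizing backbone inside the domain
      if ("left" %in% sides) pos <- c(2.8, pos)
      if ("right" %in% sides) pos <- c(pos, 9.2)
      sort(pos)
    }
    extent <- 12
    px <- 0.064
    grid <- seq(0, extent, by = px)
    render <- function(mu) {
      v <- numeric(length(grid))
      for (m in mu) v <- v + 1000 * exp(-(grid - m)^2 / (2 * (2 * px)^2))
      v
    }
    fiber_record("f1", "TEEN", "TEEN", list(
      intensity_profile("f1", "CENP-C", grid, render(dom), px),
      intensity_profile("f1", "CENP-B", grid, render(place(b_sides)), px),
      intensity_profile("f1", "CENP-I", grid, render(place(i_sides)), px)
    ))
  }
  expect_equal(classify_cospreading(mk(character(0), character(0)))$which,
               "none")
  expect_equal(classify_cospreading(mk("right", character(0)))$which,
               "only_B")
  expect_equal(classify_cospreading(mk(character(0), "left"))$which,
               "only_I")

  both_same <- classify_cospreading(mk("right", "right"))
  expect_equal(both_same$which, "both")
  expect_equal(both_same$side_pattern, "same_side")

  both_opp <- classify_cospreading(mk("left", "right"))
  expect_equal(both_opp$side_pattern, "opposite_sides")

  # enumeration: any combination with a protein on both sides is mixed
  for (b in list("left", "right", c("left", "right"))) {
    for (i in list("left", "right", c("left", "right"))) {
      got <- classify_cospreading(mk(b, i))$side_pattern
      want <- if (length(b) == 1 && length(i) == 1) {
        if (identical(b, i)) "same_side" else "opposite_sides"
      } else "mixed"
      expect_equal(got, want)
    }
  }
})

test_that("cospreading requires the triple-stain channels", {
  rec <- make_fiber(c(1, 2), c(1, 2), ref_channel = "CENP-C",
                    query_channel = "CENP-B", preparation = "TEEN")
  expect_error(classify_cospreading(rec), "missing channel")
})
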