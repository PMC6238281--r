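test_that("intensity_profile and fiber_record enforce their invariants", {
  expect_error(intensity_profile("f1", "CENP-A", c(0, 0.064, 0.064),
                                 c(1, 2, 3)),
               "strictly increasing")
  expect_error(intensity_profile("f1", "CENP-A", c(0, 0.064), c(1, -2)),
               "non-negative")
  expect_error(intensity_profile("f1", "CENP-A", c(0, 0.064), c(1, 2, 3)),
               "equal length")
  p1 <- make_profile(c(0, 1, 2), channel = "CENP-A")
  p2 <- intensity_profile("f1", "biotin", c(0, 0.1, 0.3), c(0, 1, 2))
  expect_error(fiber_record("f1", "x", "double_lysis", list(p1, p2)),
               "identical position grid")
  expect_error(fiber_record("f1", "x", "double_lysis", list(p1, p1)),
               "duplicate channel")
})

test_that("reference channel resolution prefers CENP-A, then CENP-C", {
  rec <- make_fiber(c(1, 2), c(1, 2))
  expect_identical(reference_channel(rec), "CENP-A")
  rec_c <- make_fiber(c(1, 2), c(1, 2), ref_channel = "CENP-C",
                      query_channel = "CENP-B", preparation = "TEEN")
  expect_identical(reference_channel(rec_c), "CENP-C")
  rec_none <- make_fiber(c(1, 2), c(1, 2), ref_channel = "myc",
                         query_channel = "biotin")
  expect_error(reference_channel(rec_none), "no reference channel")
})

test_that("fiber table round-trips exactly through write and read", {
  co <- simulate_cohort("APEX-CENP-A", 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fiber_table(co$records, path)
  back <- read_fiber_table(path)
  expect_identical(names(back), names(co$records))
  for (id in names(back)) {
    orig <- co$records[[id]]
    got <- back[[id]]
    expect_identical(names(got$profiles), names(orig$profiles))
    for (ch in names(got$profiles)) {
      expect_identical(got$profiles[[ch]]$positions,
                       orig$profiles[[ch]]$positions)
      expect_identical(got$profiles[[ch]]$values,
                       orig$profiles[[ch]]$values)
    }
  }
})

test_that("empty and malformed fiber tables are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fiber_table(list(), path)
  expect_length(read_fiber_table(path), 0)

  tab <- fiber_table(simulate_cohort("APEX-CENP-A", 1, seed = 2)$records)
  expect_error(fiber_records_from_table(tab[, -4]), "channel")
  dup <- rbind(tab, tab[1, ])
  expect_error(fiber_records_from_table(dup), "duplicated")
})

test_that("three-channel records survive the table round-trip", {
  co <- simulate_cohort("TEEN-triple", 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fiber_table(co$records, path)
  back <- read_fiber_table(path)
  expect_length(back[[1]]$profiles, 3)
  expect_setequal(names(back[[1]]$profiles), c("CENP-C", "CENP-B", "CENP-I"))
})

test_that("extract_line_profile samples a constant image correctly", {
  img <- matrix(100, nrow = 5, ncol = 20)
  prof <- extract_line_profile(img, rbind(c(0, 2), c(10, 2)))
  expect_true(length(prof$positions) %in% c(10L, 11L))
  expect_true(all(prof$values == 100))
  expect_equal(prof$positions[1], 0)
  # total length 10 px at 0.064 um/px ends at 0.64 um
  expect_equal(max(prof$positions), 0.64)
})

test_that("extract_line_profile recovers a rendered punctum position", {
  img <- render_fiber_image(width = 60, height = 9, centers_x_px = 25,
                            y_px = 4, amplitude = 800, sigma_px = 2)
  prof <- extract_line_profile(img, rbind(c(0, 4), c(59, 4)))
  # direct evaluation of the rendering function along the scan line
  direct <- 800 * exp(-((0:59) - 25)^2 / (2 * 4))
  expect_equal(prof$values, direct, tolerance = 1e-12)
  peak <- call_peaks(prof, 300)
  expect_equal(nrow(peak), 1L)
  expect_lt(abs(peak$position_um - 25 * 0.064), 0.064 + 1e-12)
})

test_that("extract_line_profile rejects out-of-bounds vertices", {
  img <- matrix(0, 5, 5)
  expect_error(extract_line_profile(img, rbind(c(0, 0), c(10, 0))),
               "bounds")
})
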