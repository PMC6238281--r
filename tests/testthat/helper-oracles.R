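# Independent brute-force oracles used to cross-check the implementation.

# Run-length scan over samples: one peak per maximal above-threshold run,
# written as an explicit loop independent of call_peaks().
oracle_call_peaks <- function(values, positions, threshold) {
  idx <- integer(0)
  i <- 1L
  n <- length(values)
  while (i <= n) {
    if (values[i] >= threshold) {
      j <- i
      while (j < n && values[j + 1L] >= threshold) j <- j + 1L
      seg <- values[i:j]
      ties <- which(seg == max(seg))
      mid <- ties[floor((length(ties) + 1L) / 2L)]
      idx <- c(idx, i + mid - 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(position_um = positions[idx], height = values[idx])
}

# All-pairs nearest distances.
oracle_nearest <- function(query, ref) {
  vapply(query, function(q) min(abs(q - ref)), numeric(1))
}

# Per-peak three-category classification.
oracle_classify <- function(query, ref, coloc_um = 0.192) {
  start <- min(ref); end <- max(ref)
  vapply(query, function(q) {
    if (min(abs(q - ref)) <= coloc_um) "coloc"
    else if (q < start - coloc_um || q > end + coloc_um) "outside"
    else "inside_noncoloc"
  }, character(1))
}

# Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(sorted[i:m] * m / (i:m))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Quick profile builder on the default grid.
make_profile <- function(values, channel = "CENP-A", fiber_id = "f1",
                         pixel_size_um = 0.064) {
  intensity_profile(fiber_id, channel,
                    positions = (seq_along(values) - 1L) * pixel_size_um,
                    values = values, pixel_size_um = pixel_size_um)
}

# Two-channel fiber built from explicit peak positions, rendered noise-free.
make_fiber <- function(ref_pos, query_pos, fiber_id = "f1",
                       construct = "test", preparation = "double_lysis",
                       amplitude = 1000, sigma_px = 2, px = 0.064,
                       ref_channel = "CENP-A", query_channel = "biotin") {
  extent <- max(c(ref_pos, query_pos)) + 2
  grid <- seq(0, extent, by = px)
  render <- function(mu) {
    v <- numeric(length(grid))
    for (m in mu) v <- v + amplitude * exp(-(grid - m)^2 / (2 * (sigma_px * px)^2))
    v
  }
  fiber_record(fiber_id, construct, preparation, list(
    intensity_profile(fiber_id, ref_channel, grid, render(ref_pos), px),
    intensity_profile(fiber_id, query_channel, grid, render(query_pos), px)
  ))
}
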