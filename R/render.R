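#' Render a synthetic fiber image
#'
#' Draws 2-D Gaussian puncta on a blank single-channel image, for exercising
#' [extract_line_profile()] against a known rendering. Coordinates are
#' 0-based pixels; the fiber axis runs horizontally at row `y_px`.
#'
#' @param width,height Image size in pixels.
#' @param centers_x_px Punctum centers along x (0-based pixels).
#' @param y_px Fiber axis y coordinate (0-based).
#' @param amplitude Peak gray value(s), recycled over puncta.
#' @param sigma_px Gaussian sigma in pixels.
#' @return Numeric matrix `height x width` (`image[row, col]`).
#' @export
render_fiber_image <- function(width, height, centers_x_px, y_px,
                               amplitude = 1000, sigma_px = 2) {
  amplitude <- rep_len(amplitude, length(centers_x_px))
  img <- matrix(0, nrow = height, ncol = width)
  xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1), times = width), nrow = height)
  for (j in seq_along(centers_x_px)) {
    img <- img + amplitude[j] *
      exp(-((xs - centers_x_px[j])^2 + (ys - y_px)^2) / (2 * sigma_px^2))
  }
  img
}
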