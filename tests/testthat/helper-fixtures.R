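# Shared fixtures, all built in code.

# Half-resolution embryo (same physical geometry as the default, 0.8 um/px):
# nuclei cover ~175 strip pixels here, so pipeline calls use min_size = 100.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(image_size = c(512L, 512L), pixel_size = 0.8)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}
SMALL_MIN_SIZE <- 100L

one_frame_traj <- function(A = 10, B = 2, mu = 0, sigma = 0.15)
  data.frame(A = A, B = B, mu = mu, sigma = sigma)

# Uniform disk image (circle radius r px), for analytic geometry checks.
circle_image <- function(size = 400L, r = 150, value = 8, center = NULL) {
  if (is.null(center)) center <- (size + 1) / 2
  d2 <- outer((seq_len(size) - center)^2, (seq_len(size) - center)^2, "+")
  m <- matrix(0, size, size)
  m[d2 <= r^2] <- value
  m
}

# Match pipeline records to generator ground truth by nearest centroid.
match_ground_truth <- function(records, gt_nuclei, max_dist = 8) {
  d <- outer(gt_nuclei$row, records$row, "-")^2 +
       outer(gt_nuclei$col, records$col, "-")^2
  nn <- apply(d, 2, which.min)
  nd <- sqrt(apply(d, 2, min))
  list(gt_index = nn, dist = nd, matched = nd < max_dist)
}

# Signed DV difference respecting the +/-1 wrap at the ventral midline.
dv_diff <- function(a, b) {
  d <- a - b
  d - 2 * round(d / 2)
}

# The worked 10-nucleus half: nuclei at 0.05..0.50, dots at the 3 most
# dorsal positions.
toy_half_calls <- function() {
  data.frame(label = 1:10, dv = seq(0.05, 0.50, by = 0.05),
             is_dot = rep(c(TRUE, FALSE), c(3, 7)))
}
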