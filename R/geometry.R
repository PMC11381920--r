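#' Detect the embryo outline in a nuclear-channel frame
#'
#' The frame is smoothed with a 2-D Gaussian filter of radius `filter_radius`
#' pixels, thresholded by Otsu's method, and the largest connected bright
#' region (hole-filled) is taken as the embryo.  Its outer boundary is
#' returned as an ordered closed contour.
#'
#' @param image numeric matrix (nuclear channel).
#' @param filter_radius Gaussian filter radius in pixels (default 5).
#' @param min_fraction minimum fraction of image pixels the embryo must
#'   cover.
#' @return an `n x 2` matrix of (row, col) contour coordinates, ordered so
#'   that arc length increases clockwise on screen starting near the top of
#'   the region; the filled region mask is attached as attribute `"mask"`.
#' @export
detect_embryo_boundary <- function(image, filter_radius = 5, min_fraction = 0.05) {
  image <- as_matrix_image(image)
  rng <- range(image)
  if (diff(rng) <= 0) stop_dv("no_embryo", "no embryo found: blank image")
  sm <- EBImage::gblur(EBImage::Image((image - rng[1]) / diff(rng)),
                       sigma = filter_radius)
  smv <- EBImage::imageData(sm)
  # Otsu can latch onto bright sub-structure (the nuclear layer) instead of
  # the embryo-versus-background split; if the largest region is too small,
  # descend the histogram by re-applying Otsu below the current threshold.
  th <- EBImage::otsu(sm, range = c(0, 1))
  areas <- integer(0); lab <- NULL
  for (iter in 1:3) {
    mask <- EBImage::fillHull(sm > th)
    lab <- EBImage::bwlabel(mask)
    areas <- tabulate(as.integer(EBImage::imageData(lab)))
    if (length(areas) && max(areas) >= min_fraction * length(image)) break
    below <- smv[smv < th]
    th2 <- if (length(below) > 1) otsu_threshold(below) else NA
    if (!is.finite(th2) || th2 >= th) break
    th <- th2
  }
  if (length(areas) == 0 || max(areas) < min_fraction * length(image))
    stop_dv("no_embryo", "no embryo found: no bright region above size floor")
  ord <- order(areas, decreasing = TRUE)
  if (length(areas) > 1 && areas[ord[2]] >= 0.5 * areas[ord[1]])
    stop_dv("multiple_embryos", "multiple embryos: two comparable regions present")
  biggest <- EBImage::imageData(lab) == ord[1]
  ct <- EBImage::ocontour(EBImage::Image(biggest * 1))[[1]] + 1  # 0-based
  contour <- cbind(row = ct[, 1], col = ct[, 2])
  contour <- orient_contour(contour)
  attr(contour, "mask") <- biggest
  contour
}

# Rotate/reverse a closed contour so that it starts at its topmost point and
# proceeds clockwise on screen (towards increasing column first).
orient_contour <- function(contour) {
  i0 <- which.min(contour[, 1])
  contour <- rbind(contour[i0:nrow(contour), , drop = FALSE],
                   contour[seq_len(i0 - 1L), , drop = FALSE])
  k <- max(3L, round(nrow(contour) / 8))
  if (mean(contour[2:k, 2]) < contour[1, 2])
    contour <- rbind(contour[1, , drop = FALSE], contour[nrow(contour):2, , drop = FALSE])
  contour
}

# Smooth a closed contour periodically and resample it to `n` points of
# equal arc spacing.
resample_contour <- function(contour, n = NULL, smooth_window = 21L) {
  m <- nrow(contour)
  wrap <- function(x) {
    ext <- c(tail(x, smooth_window), x, head(x, smooth_window))
    moving_average(ext, smooth_window)[(smooth_window + 1):(smooth_window + m)]
  }
  r <- wrap(contour[, 1]); c <- wrap(contour[, 2])
  r <- c(r, r[1]); c <- c(c, c[1])
  seg <- sqrt(diff(r)^2 + diff(c)^2)
  s <- c(0, cumsum(seg))
  perim <- s[length(s)]
  if (is.null(n)) n <- max(32L, round(perim))
  st <- (seq_len(n) - 0.5) / n * perim
  rr <- approx(s, r, xout = st)$y
  cc <- approx(s, c, xout = st)$y
  # re-anchor the arc origin at the topmost point of the *smoothed* contour:
  # on a flat apex the raw pixel chain's topmost pixel can sit well off the
  # symmetry point, which would bias every DV coordinate.  The anchor is the
  # circular mean of all points within one pixel of the top, so a flat apex
  # anchors at its center rather than wherever the pixel chain dips first.
  cand <- which(rr < min(rr) + 1)
  th <- 2 * pi * (cand - 1) / n
  i0 <- (round(atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * n) %% n) + 1L
  if (i0 > 1L) {
    idx <- c(i0:n, seq_len(i0 - 1L))
    rr <- rr[idx]; cc <- cc[idx]
  }
  k <- max(3L, n %/% 8L)
  if (mean(cc[2:k]) < cc[1]) {
    rr <- c(rr[1], rev(rr[-1])); cc <- c(cc[1], rev(cc[-1]))
  }
  cbind(row = rr, col = cc, s = st)
}

#' Offset a contour inward to form the inner annulus boundary
#'
#' Each point of the (smoothed, resampled) outer contour is moved a distance
#' `depth / pixel_size` along its inward normal.
#'
#' @param outer contour matrix (row, col) as from [detect_embryo_boundary()].
#' @param depth offset depth in microns (default 18.36, a liberal estimate of
#'   the apical-basal nuclear height).
#' @param pixel_size microns per pixel.
#' @return an `n x 2` matrix of inner contour coordinates.
#' @export
compute_inner_boundary <- function(outer, depth = 18.36, pixel_size = 1) {
  depth_px <- depth / pixel_size
  rs <- resample_contour(outer)
  nrm <- contour_normals(rs)
  inner <- rs[, 1:2] + depth_px * nrm
  if (depth_px > 0) check_annulus(rs[, 1:2], inner)
  inner
}

# Inward unit normals of a resampled closed contour.  Tangents use a wide
# (+/- 7 point) stencil and are smoothed periodically so that a constant
# inward offset cannot fold on pixel-scale contour noise.
contour_normals <- function(rs, stencil = 7L, smooth_window = 21L) {
  n <- nrow(rs)
  k <- min(stencil, max(1L, n %/% 4L))
  nxt <- ((seq_len(n) - 1L + k) %% n) + 1L
  prv <- ((seq_len(n) - 1L - k) %% n) + 1L
  tr <- rs[nxt, 1] - rs[prv, 1]
  tc <- rs[nxt, 2] - rs[prv, 2]
  wrap_smooth <- function(x) {
    w <- min(smooth_window, n)
    ext <- c(tail(x, w), x, head(x, w))
    moving_average(ext, w)[(w + 1):(w + n)]
  }
  tr <- wrap_smooth(tr); tc <- wrap_smooth(tc)
  tl <- sqrt(tr^2 + tc^2)
  tr <- tr / tl; tc <- tc / tl
  ctr <- colMeans(rs[, 1:2])
  nr <- -tc; nc <- tr
  flip <- (ctr[1] - rs[, 1]) * nr + (ctr[2] - rs[, 2]) * nc < 0
  nr[flip] <- -nr[flip]; nc[flip] <- -nc[flip]
  cbind(nr, nc)
}

# The offset contour must progress in the same direction as the outer one;
# reversals indicate self-intersection (depth beyond the local radius of
# curvature).
check_annulus <- function(outer, inner) {
  n <- nrow(outer)
  nxt <- c(2:n, 1)
  dot <- (inner[nxt, 1] - inner[, 1]) * (outer[nxt, 1] - outer[, 1]) +
         (inner[nxt, 2] - inner[, 2]) * (outer[nxt, 2] - outer[, 2])
  if (mean(dot <= 0) > 0.02)
    stop_dv("annulus_degenerate",
            "annulus degenerate: inner boundary self-intersects at this depth")
  invisible(TRUE)
}

#' Build the annulus transform of one cross-section
#'
#' Detects the embryo outline, offsets it inward by `depth` to enclose the
#' nuclear layer, and constructs the strip-to-image correspondence used by
#' [unroll()], [map_mask_back()] and [assign_dv_coordinate()].  Strip columns
#' follow arc length along the outer boundary (one column per pixel of
#' perimeter, starting at the topmost point, clockwise on screen); strip rows
#' run from the outer boundary inward.
#'
#' @param image nuclear-channel matrix.
#' @param pixel_size microns per pixel.
#' @param depth annulus depth in microns.
#' @param filter_radius boundary-detection filter radius, pixels.
#' @return an object of class `annulus_transform`.
#' @export
annulus_transform <- function(image, pixel_size, depth = 18.36,
                              filter_radius = 5) {
  image <- as_matrix_image(image)
  contour <- detect_embryo_boundary(image, filter_radius)
  mask <- attr(contour, "mask")
  depth_px <- depth / pixel_size
  inradius <- max(EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1))))
  if (depth_px >= inradius)
    stop_dv("annulus_degenerate",
            "annulus degenerate: depth %.1f px exceeds the region inradius %.1f px",
            depth_px, inradius)
  rs <- resample_contour(contour)
  nrm <- contour_normals(rs)
  inner <- rs[, 1:2] + depth_px * nrm
  if (depth_px > 0) check_annulus(rs[, 1:2], inner)
  structure(list(outer = rs[, 1:2], inner = inner, normals = nrm,
                 arc = rs[, 3], perimeter = max(rs[, 3]) + diff(rs[1:2, 3]),
                 depth_px = depth_px, pixel_size = pixel_size,
                 strip_size = c(height = max(1L, round(depth_px)),
                                width = nrow(rs)),
                 image_dim = dim(image)),
            class = "annulus_transform")
}

#' @export
print.annulus_transform <- function(x, ...) {
  cat("annulus_transform:", x$strip_size[2], "x", x$strip_size[1],
      "strip, perimeter", round(x$perimeter, 1), "px, depth",
      round(x$depth_px, 2), "px\n")
  invisible(x)
}

# Image-frame coordinates of every strip pixel (rows vary fastest).
forward_map <- function(transform) {
  H <- transform$strip_size[1]; W <- transform$strip_size[2]
  d <- (seq_len(H) - 0.5) / H * transform$depth_px
  rows <- rep(transform$outer[, 1], each = H) + d * rep(transform$normals[, 1], each = H)
  cols <- rep(transform$outer[, 2], each = H) + d * rep(transform$normals[, 2], each = H)
  list(row = rows, col = cols, H = H, W = W)
}

#' Unroll the nuclear annulus into a rectangular strip
#'
#' Samples the image along the annulus by bilinear interpolation: strip
#' column = arc-length position on the outer boundary, strip row = depth
#' below it.
#'
#' @param image numeric matrix in the frame the transform was built from.
#' @param transform an [annulus_transform()].
#' @return numeric matrix of dimension `transform$strip_size`.
#' @export
unroll <- function(image, transform) {
  image <- as_matrix_image(image)
  fm <- forward_map(transform)
  matrix(bilinear_sample(image, fm$row, fm$col), fm$H, fm$W)
}

#' Map a strip-frame mask back to image coordinates
#'
#' Labels are carried over by nearest-neighbour assignment of each strip
#' pixel's image-frame position; label identities are preserved.
#'
#' @param mask labeled (or binary) matrix of the strip's dimensions.
#' @param transform the [annulus_transform()] the strip came from.
#' @return labeled matrix of the original image's dimensions.
#' @export
map_mask_back <- function(mask, transform) {
  if (!all(dim(mask) == transform$strip_size))
    stop_dv("bad_mask", "mask dimensions do not match the strip size")
  out <- matrix(0L, transform$image_dim[1], transform$image_dim[2])
  keep <- which(mask > 0)
  if (!length(keep)) return(out)
  H <- transform$strip_size[1]; W <- transform$strip_size[2]
  rr <- ((keep - 1L) %% H) + 1L
  cc <- ((keep - 1L) %/% H) + 1L
  lab <- as.integer(mask[keep])
  # 2x2 subsamples per strip pixel: nearest-neighbour painting of pixel
  # centers alone leaves pinholes where the mapping locally expands
  for (dr in c(-0.25, 0.25)) for (dc in c(-0.25, 0.25)) {
    ci <- pmin(pmax(round(cc + dc), 1L), W)
    d <- (rr + dr - 0.5) / H * transform$depth_px
    ir <- transform$outer[ci, 1] + d * transform$normals[ci, 1]
    ic <- transform$outer[ci, 2] + d * transform$normals[ci, 2]
    r <- pmin(pmax(round(ir), 1L), transform$image_dim[1])
    c <- pmin(pmax(round(ic), 1L), transform$image_dim[2])
    out[cbind(r, c)] <- lab
  }
  out
}

#' Assign signed dorsoventral coordinates to image-frame points
#'
#' The DV coordinate of a point is the arc-length fraction from the dorsal
#' midline along the outer boundary, measured on the half-perimeter and
#' signed by side: 0 at the midline, +1/-1 at the antipode, positive on the
#' half reached first when moving clockwise on screen.
#'
#' @param points numeric vector `c(row, col)` or an `n x 2` matrix of points.
#' @param transform an [annulus_transform()].
#' @param midline arc-length fraction (of the full perimeter) of the dorsal
#'   midline relative to the transform origin (default 0, the topmost point).
#' @param tol tolerance in pixels for the inside-annulus check.
#' @return numeric vector of signed DV coordinates in `[-1, 1]`.
#' @export
assign_dv_coordinate <- function(points, transform, midline = 0, tol = 2) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  W <- transform$strip_size[2]
  dv <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- (transform$outer[, 1] - points[i, 1])^2 +
          (transform$outer[, 2] - points[i, 2])^2
    j <- which.min(d2)
    depth <- (points[i, 1] - transform$outer[j, 1]) * transform$normals[j, 1] +
             (points[i, 2] - transform$outer[j, 2]) * transform$normals[j, 2]
    if (depth < -tol || depth > transform$depth_px + tol)
      stop_dv("outside_annulus", "point (%.1f, %.1f) lies outside the annulus",
              points[i, 1], points[i, 2])
    f <- (j - 0.5) / W - midline
    f <- f - round(f)                    # wrap to (-0.5, 0.5]
    dv[i] <- 2 * f
  }
  dv
}
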