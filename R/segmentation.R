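#' Find watershed markers in an unrolled strip
#'
#' Regional maxima of the lightly smoothed strip, labeled.  Spurious maxima
#' arising from cytoplasmic noise are deliberately kept: they create extra
#' compartments that tighten the fit around true nuclei.
#'
#' @param strip numeric matrix (unrolled nuclear channel).
#' @param smooth_sigma Gaussian pre-smoothing s.d. in pixels.
#' @return integer label matrix of markers (connected plateau components).
#' @export
find_markers <- function(strip, smooth_sigma = 1.5) {
  strip <- as_matrix_image(strip)
  img <- EBImage::Image(strip)
  if (smooth_sigma > 0) img <- EBImage::gblur(img, sigma = smooth_sigma)
  mx <- EBImage::dilate(img, EBImage::makeBrush(3, "box"))
  maxima <- EBImage::imageData(img) >= EBImage::imageData(mx)
  lab <- EBImage::bwlabel(EBImage::Image(maxima * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow(strip), ncol(strip))
}

#' Partition the strip into one compartment per marker
#'
#' Marker-based watershed: markers grow over the whole strip along ridge
#' lines of the intensity landscape, yielding an exhaustive, disjoint
#' partition with exactly one marker per compartment.
#'
#' @param strip numeric matrix.
#' @param markers integer label matrix from [find_markers()].
#' @param lambda regularization of the growth metric (small values weight
#'   intensity changes heavily, placing boundaries on ridges).
#' @return integer compartment label matrix.
#' @export
watershed_compartments <- function(strip, markers, lambda = 1e-4) {
  strip <- as_matrix_image(strip)
  if (!any(markers > 0)) stop_dv("no_markers", "no markers supplied")
  rng <- range(strip)
  norm <- if (diff(rng) > 0) (strip - rng[1]) / diff(rng) else strip * 0
  lab <- EBImage::propagate(EBImage::Image(norm),
                            seeds = EBImage::Image(matrix(as.integer(markers),
                                                          nrow(strip), ncol(strip))),
                            lambda = lambda)
  matrix(as.integer(EBImage::imageData(lab)), nrow(strip), ncol(strip))
}

#' Locate the nuclear band in each strip column
#'
#' For every 1-pixel column the smoothed intensity profile is scanned for
#' its first and last crossing of a scale-free criterion (midway between the
#' column's 10th and 90th intensity percentiles); the resulting top/bottom
#' limits are smoothed across columns.  Columns without a crossing (gaps
#' between nuclei, or a flat profile) inherit their neighbours' band by
#' interpolation.
#'
#' @param strip numeric matrix.
#' @param row_smooth moving-average window (rows) for the column profile.
#' @param col_smooth moving-average window (columns) for the band limits.
#' @param min_contrast minimum 10-90 percentile spread, as a fraction of the
#'   strip's global range, for a column to count as crossed.
#' @return list with numeric vectors `top` and `bottom` (one entry per
#'   column) and logical `degenerate` (no column had a crossing).
#' @export
nuclear_band_outline <- function(strip, row_smooth = 5L, col_smooth = 31L,
                                 min_contrast = 0.05) {
  strip <- as_matrix_image(strip)
  H <- nrow(strip); W <- ncol(strip)
  global_range <- diff(range(strip))
  top <- rep(NA_real_, W); bottom <- rep(NA_real_, W)
  for (j in seq_len(W)) {
    p <- moving_average(strip[, j], row_smooth)
    q <- quantile(p, c(0.1, 0.9), names = FALSE)
    if (global_range <= 0 || (q[2] - q[1]) < min_contrast * global_range) next
    th <- (q[1] + q[2]) / 2
    hit <- which(p >= th)
    top[j] <- hit[1]; bottom[j] <- hit[length(hit)]
  }
  degenerate <- all(is.na(top))
  if (degenerate) {
    top <- rep(1, W); bottom <- rep(H, W)
  } else {
    fill <- function(x) {
      ok <- which(!is.na(x))
      approx(ok, x[ok], xout = seq_len(W), rule = 2)$y
    }
    top <- moving_average(fill(top), col_smooth)
    bottom <- moving_average(fill(bottom), col_smooth)
  }
  list(top = top, bottom = bottom, degenerate = degenerate)
}

#' Threshold each nucleus-bearing compartment independently
#'
#' Applies Otsu's method within every compartment whose marker lies inside
#' the nuclear band, and unions the per-compartment binary masks.  A
#' compartment-specific threshold copes with brightness variation across the
#' strip that defeats a single global threshold.
#'
#' @param strip numeric matrix.
#' @param compartments label matrix from [watershed_compartments()].
#' @param markers marker label matrix (used to test band membership).
#' @param band output of [nuclear_band_outline()]; `NULL` keeps all
#'   compartments.
#' @param min_pixels compartments smaller than this contribute an empty mask.
#' @return logical matrix; the number of skipped (too small or flat)
#'   compartments is attached as attribute `"skipped"`.
#' @export
per_compartment_otsu <- function(strip, compartments, markers = NULL,
                                 band = NULL, min_pixels = 16L) {
  strip <- as_matrix_image(strip)
  mask <- matrix(FALSE, nrow(strip), ncol(strip))
  keep_ids <- sort(unique(compartments[compartments > 0]))
  if (!is.null(band) && !is.null(markers) && !band$degenerate) {
    mpos <- which(markers > 0, arr.ind = TRUE)
    mid <- markers[mpos]
    inside <- mpos[, 1] >= band$top[mpos[, 2]] - 1 &
              mpos[, 1] <= band$bottom[mpos[, 2]] + 1
    in_band <- unique(mid[inside])
    comp_of_marker <- compartments[mpos]
    keep_ids <- intersect(keep_ids, unique(comp_of_marker[mid %in% in_band]))
  }
  skipped <- 0L
  idx_by_comp <- split(seq_along(compartments), compartments)
  idx_by_comp[["0"]] <- NULL
  for (id in keep_ids) {
    idx <- idx_by_comp[[as.character(id)]]
    if (is.null(idx) || length(idx) < min_pixels) { skipped <- skipped + 1L; next }
    v <- strip[idx]
    th <- otsu_threshold(v)
    if (is.na(th)) { skipped <- skipped + 1L; next }
    mask[idx] <- v > th
  }
  attr(mask, "skipped") <- skipped
  mask
}

#' Clean a binary nuclear mask and label its components
#'
#' Morphological opening (disk of radius `open_radius`) removes watershed
#' stubble, then components strictly below `min_size` pixels and above
#' `max_size` pixels are discarded and the survivors relabeled.
#'
#' @param mask logical or 0/1 matrix.
#' @param min_size strict lower area bound in pixels: components with area
#'   `< min_size` are removed, area `>= min_size` survives (default 400).
#' @param max_size upper area bound; `NULL` uses 10x the median component
#'   area of the frame.
#' @param open_radius radius of the opening structuring element, pixels.
#' @return integer label matrix.
#' @export
clean_mask <- function(mask, min_size = 400L, max_size = NULL, open_radius = 2L) {
  m <- EBImage::Image((mask > 0) * 1)
  if (open_radius > 0)
    m <- EBImage::opening(m, EBImage::makeBrush(2L * open_radius + 1L, "disc"))
  lab <- EBImage::bwlabel(m)
  labm <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  areas <- tabulate(labm[labm > 0])
  if (length(areas) == 0) return(labm)
  if (is.null(max_size)) {
    med <- median(areas[areas >= min_size])
    max_size <- if (is.finite(med)) 10 * med else Inf
  }
  keep <- which(areas >= min_size & areas <= max_size)
  relabel <- integer(length(areas))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labm), ncol(labm))
  nz <- labm > 0
  out[nz] <- relabel[labm[nz]]
  out
}

#' Segment nuclei in an unrolled strip
#'
#' Convenience wrapper chaining [find_markers()], [watershed_compartments()],
#' [nuclear_band_outline()], [per_compartment_otsu()] and [clean_mask()].
#'
#' @param strip unrolled nuclear-channel matrix.
#' @param min_size,max_size,open_radius passed to [clean_mask()].
#' @param smooth_sigma passed to [find_markers()].
#' @return integer label matrix in strip coordinates.
#' @export
segment_strip <- function(strip, min_size = 400L, max_size = NULL,
                          open_radius = 2L, smooth_sigma = 1.5) {
  markers <- find_markers(strip, smooth_sigma)
  comp <- watershed_compartments(strip, markers)
  band <- nuclear_band_outline(strip)
  mask <- per_compartment_otsu(strip, comp, markers, band)
  clean_mask(mask, min_size = min_size, max_size = max_size,
             open_radius = open_radius)
}

#' Extract per-nucleus intensity records
#'
#' Computes, for every label of an image-frame nuclear mask and every
#' z-slice of the signal channel, the quantities used downstream: area,
#' centroid, signed DV coordinate, mean nuclear intensity (`I_nuc`), mean
#' and max signal intensity (`I_max`), and the signal mean after removing
#' the 5x5 neighbourhood of the max pixel (`I_mean`, the off-spot mean).
#'
#' @param labels integer label matrix in image coordinates (e.g. from
#'   [map_mask_back()]).
#' @param nuclear nuclear-channel matrix.
#' @param signal signal-channel matrix, or a 3-D array (rows, cols, z).
#' @param transform optional [annulus_transform()] for DV assignment.
#' @param midline dorsal-midline arc fraction passed to
#'   [assign_dv_coordinate()].
#' @param frame frame index stored in the records.
#' @return data frame with one row per nucleus per z-slice: `label`, `frame`,
#'   `z`, `row`, `col`, `dv`, `area`, `mean_nuclear`, `mean_signal`,
#'   `max_signal`, `mean_signal_excl`.
#' @export
extract_nuclei <- function(labels, nuclear, signal, transform = NULL,
                           midline = 0, frame = 1L) {
  nuclear <- as_matrix_image(nuclear)
  if (length(dim(signal)) == 2L) signal <- array(signal, dim = c(dim(signal), 1L))
  nz <- dim(signal)[3]
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(data.frame(label = integer(), frame = integer(), z = integer(),
                      row = numeric(), col = numeric(), dv = numeric(),
                      area = integer(), mean_nuclear = numeric(),
                      mean_signal = numeric(), max_signal = numeric(),
                      mean_signal_excl = numeric()))
  h <- nrow(labels)
  idx_by <- split(which(labels > 0), labels[labels > 0])
  rows <- vector("list", length(ids) * nz)
  k <- 0L
  for (lab in ids) {
    idx <- idx_by[[as.character(lab)]]
    pr <- ((idx - 1L) %% h) + 1L
    pc <- ((idx - 1L) %/% h) + 1L
    cy <- mean(pr); cx <- mean(pc)
    dv <- if (is.null(transform)) NA_real_ else
      assign_dv_coordinate(c(cy, cx), transform, midline)
    inuc <- mean(nuclear[idx])
    for (z in seq_len(nz)) {
      v <- signal[idx + (z - 1L) * length(nuclear)]
      im <- which.max(v)
      off <- abs(pr - pr[im]) > 2L | abs(pc - pc[im]) > 2L
      k <- k + 1L
      rows[[k]] <- data.frame(
        label = lab, frame = frame, z = z, row = cy, col = cx, dv = dv,
        area = length(idx), mean_nuclear = inuc, mean_signal = mean(v),
        max_signal = v[im],
        mean_signal_excl = if (any(off)) mean(v[off]) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
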