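#' Segment one cross-section and extract nucleus records
#'
#' Full per-frame chain: boundary detection, annulus transform, unrolling,
#' strip segmentation, mapping the mask back, and record extraction.
#'
#' @param nuclear nuclear-channel matrix.
#' @param signal signal-channel matrix, 3-D array (z-stack), or a list of
#'   channel matrices (multi-channel fixed embryos).
#' @param pixel_size microns per pixel.
#' @param depth annulus depth, microns.
#' @param min_size,max_size nucleus-size bounds in strip pixels (see
#'   [clean_mask()]).
#' @param midline dorsal-midline arc fraction.
#' @param frame frame index recorded in the output.
#' @param transform optional precomputed [annulus_transform()] (frames are
#'   processed independently by default).
#' @return list with `records` (multi-channel input: columns
#'   `mean_signal_ch<i>` etc. are suffixed), `transform`, `labels` (image
#'   frame) and `strip_labels`.
#' @export
analyze_cross_section <- function(nuclear, signal, pixel_size,
                                  depth = 18.36, min_size = 400L,
                                  max_size = NULL, midline = 0, frame = 1L,
                                  transform = NULL) {
  if (is.null(transform))
    transform <- annulus_transform(nuclear, pixel_size, depth)
  strip <- unroll(nuclear, transform)
  strip_labels <- segment_strip(strip, min_size = min_size, max_size = max_size)
  labels <- map_mask_back(strip_labels, transform)
  if (is.list(signal) && !is.data.frame(signal)) {
    recs <- NULL
    for (ch in seq_along(signal)) {
      r <- extract_nuclei(labels, nuclear, signal[[ch]], transform, midline, frame)
      if (is.null(recs)) {
        recs <- r
      } else {
        sig_cols <- c("mean_signal", "max_signal", "mean_signal_excl")
        for (col in sig_cols) recs[[paste0(col, "_ch", ch)]] <- r[[col]]
      }
    }
    sig_cols <- c("mean_signal", "max_signal", "mean_signal_excl")
    for (col in sig_cols) {
      recs[[paste0(col, "_ch1")]] <- recs[[col]]
      recs[[col]] <- NULL
    }
    records <- recs
  } else {
    records <- extract_nuclei(labels, nuclear, signal, transform, midline, frame)
  }
  list(records = records, transform = transform, labels = labels,
       strip_labels = strip_labels)
}

#' Analyze a live gradient time course
#'
#' Segments every frame, applies the multiplicative normalization layers
#' (session and time-course factors plus the DV-axis curve estimated from
#' the nuclear channel), and fits the per-frame Gaussian gradient.  If a
#' frame's fit fails, the previous frame's parameters are carried over and
#' the frame is flagged.
#'
#' @param series an `embryo_series` (e.g. from [generate_time_course()] or
#'   [read_embryo_series()]).
#' @param calib_norm,timecourse_norm normalization factors (see
#'   [session_factor()], [timecourse_factor()]); `timecourse_norm = NULL`
#'   computes `nuc_mean / (100 * nuc_lp)` from the data.
#' @param nuc_lp nuclear-channel laser power (used when `timecourse_norm`
#'   is `NULL`).
#' @param use_dv_curve apply the 151-point DV normalization curve.
#' @param ... passed to [analyze_cross_section()].
#' @return list with `records` (normalized, per nucleus per frame), `fits`
#'   (data frame `frame`, `A`, `B`, `mu`, `sigma`, `residual_norm`,
#'   `n_nuclei`, `carried`), and the `dv_curve`.
#' @export
analyze_live_series <- function(series, calib_norm = 1, timecourse_norm = NULL,
                                nuc_lp = 0.1, use_dv_curve = TRUE, ...) {
  all_recs <- list()
  for (j in seq_along(series$frames)) {
    fr <- series$frames[[j]]
    res <- analyze_cross_section(fr$nuclear, fr$signal,
                                 pixel_size = series$pixel_size,
                                 frame = series$frame_index[j], ...)
    all_recs[[j]] <- res$records
  }
  records <- do.call(rbind, all_recs)
  if (is.null(timecourse_norm))
    timecourse_norm <- timecourse_factor(mean(records$mean_nuclear), nuc_lp)
  curve <- if (use_dv_curve) dv_norm_curve(records) else NULL
  records <- apply_normalization(records, calib_norm, timecourse_norm, curve)
  frames <- sort(unique(records$frame))
  fits <- list(); prev <- NULL
  for (f in frames) {
    sub <- records[records$frame == f, ]
    fit <- tryCatch(fit_gaussian(sub$dv, sub$mean_signal), error = function(e) NULL)
    carried <- is.null(fit)
    if (carried) {
      if (is.null(prev))
        stop_dv("fit_failed", "fit failed on frame %d with no previous frame", f)
      message("analyze_live_series: fit failed on frame ", f,
              "; carrying previous parameters")
      fit <- prev
    }
    prev <- fit
    cf <- coef(fit)
    fits[[length(fits) + 1L]] <-
      data.frame(frame = f, A = cf["A"], B = cf["B"], mu = cf["mu"],
                 sigma = cf["sigma"], residual_norm = fit$residual_norm,
                 n_nuclei = fit$n_nuclei, carried = carried, row.names = NULL)
  }
  list(records = records, fits = do.call(rbind, fits), dv_curve = curve,
       calib_norm = calib_norm, timecourse_norm = timecourse_norm)
}

#' Analyze an MS2 z-stack time course
#'
#' Per time point: segments nuclei from the nuclear channel, extracts
#' per-nucleus records for every z-slice, scores them with
#' [score_nuclei()], calls dots at the `theta` percentile pooled over the
#' stack, and estimates the domain boundary per frame with the penalized
#' score; the width summary is the time-course mean and s.d.
#'
#' The embryo outline is detected on the first frame and reused across the
#' time course by default (cross-sections of an immobilized embryo); set
#' `reuse_transform = FALSE` to re-detect per frame.
#'
#' @param series an `embryo_series` of kind `"ms2"`.
#' @param theta percentile threshold.
#' @param gamma boundary penalty weight (`1 - theta` by construction).
#' @param midline dorsal-midline arc fraction.
#' @param reuse_transform reuse the first frame's annulus transform.
#' @param ... passed to [analyze_cross_section()].
#' @return list with `calls` (records + `S`, `threshold_value`, `is_dot`),
#'   `boundaries`, `mean_width`, `sd_width`.
#' @export
analyze_ms2_series <- function(series, theta = 0.98, gamma = 1 - theta,
                               midline = 0, reuse_transform = TRUE, ...) {
  transform <- NULL
  recs <- list()
  for (j in seq_along(series$frames)) {
    fr <- series$frames[[j]]
    res <- analyze_cross_section(fr$nuclear, fr$signal,
                                 pixel_size = series$pixel_size,
                                 midline = midline,
                                 frame = series$frame_index[j],
                                 transform = transform, ...)
    if (reuse_transform) transform <- res$transform
    recs[[j]] <- res$records
  }
  records <- do.call(rbind, recs)
  records <- records[records$area > 25L & is.finite(records$mean_signal_excl), ]
  calls <- call_dots(score_nuclei(records), theta = theta)
  wt <- width_time_course(calls, gamma = gamma)
  c(list(calls = calls), wt)
}

#' Fixed-embryo two-channel correlation analysis
#'
#' Segments each fixed cross-section, extracts both signal channels and
#' computes the per-embryo normalized nuclear correlation via
#' [correlate_channels()].
#'
#' @param embryos list of fixed embryos, each a list with `nuclear`,
#'   `signal1`, `signal2` matrices (e.g. from [generate_fixed_embryo()]).
#' @param pixel_size microns per pixel.
#' @param ... passed to [analyze_cross_section()].
#' @return the [correlate_channels()] summary, plus `records` per embryo.
#' @export
analyze_fixed_embryos <- function(embryos, pixel_size, ...) {
  tabs <- lapply(embryos, function(e) {
    res <- analyze_cross_section(e$nuclear, list(e$signal1, e$signal2),
                                 pixel_size = pixel_size, ...)
    r <- res$records
    data.frame(dv = r$dv, nuclear = r$mean_nuclear,
               ch1 = r$mean_signal_ch1, ch2 = r$mean_signal_ch2)
  })
  out <- correlate_channels(tabs)
  out$records <- tabs
  out
}
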