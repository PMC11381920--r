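#' Nascent-transcript dot score
#'
#' `S = (I_max - I_mean) / I_nuc`: the nucleus's max signal pixel minus its
#' off-spot signal mean (the mean after removing the 5x5 neighbourhood of
#' the max pixel), scaled by the nuclear-channel mean.  A nucleus carrying a
#' bright sub-nuclear dot scores high; a featureless nucleus scores near 0.
#'
#' @param records data frame from [extract_nuclei()] (needs `max_signal`,
#'   `mean_signal_excl`, `mean_nuclear`, `area`).
#' @param min_area nuclei at or below this area cannot survive the 5x5
#'   removal; scoring them is an error.
#' @return `records` with a new column `S`.
#' @export
score_nuclei <- function(records, min_area = 25L) {
  if (any(records$area <= min_area | !is.finite(records$mean_signal_excl)))
    stop_dv("nucleus_too_small",
            "nucleus too small: 5x5 removal empties a nucleus of <= %d px",
            min_area)
  records$S <- (records$max_signal - records$mean_signal_excl) /
    records$mean_nuclear
  records
}

#' Call dots by per-time-point percentile threshold
#'
#' For each time point, the threshold is the `theta` quantile (linear
#' interpolation between order statistics) of the scores `S` of all nuclei
#' of that time point, pooled over z-slices; records with `S >= threshold`
#' are called dot-positive.  Thresholds are recomputed per time point.
#'
#' @param records data frame with columns `frame` and `S` (see
#'   [score_nuclei()]).
#' @param theta percentile threshold (default 0.98).
#' @param min_records warn when a time point has fewer records than this
#'   (the percentile becomes unstable).
#' @return `records` with columns `threshold_value` and `is_dot`; time
#'   points where all scores are identical are flagged in attribute
#'   `"degenerate_frames"`.
#' @export
call_dots <- function(records, theta = 0.98, min_records = 50L) {
  records$threshold_value <- NA_real_
  records$is_dot <- NA
  degen <- integer(0)
  for (f in unique(records$frame)) {
    idx <- which(records$frame == f)
    s <- records$S[idx]
    if (length(idx) < min_records)
      warning("call_dots: time point ", f, " has only ", length(idx),
              " nuclei; percentile threshold is unstable")
    th <- quantile(s, theta, names = FALSE, type = 7)
    if (diff(range(s)) == 0) degen <- c(degen, f)
    records$threshold_value[idx] <- th
    records$is_dot[idx] <- s >= th
  }
  attr(records, "degenerate_frames") <- degen
  records
}

#' Penalized dorsal-count boundary score
#'
#' `score(x0) = #dots with x <= x0  -  gamma * #non-dots with x <= x0`,
#' over folded DV coordinates of one embryo half.  Many transcript-bearing
#' nuclei dorsal to the candidate boundary raise the score; transcript-free
#' nuclei inside the candidate domain subtract `gamma` each.
#'
#' @param x folded DV coordinates in [0, 1] of one half's nuclei.
#' @param is_dot logical, dot-positive per nucleus.
#' @param x0 candidate boundary position(s).
#' @param gamma penalty weight, `1 - theta` (default 0.02).
#' @return numeric score, one per `x0`.
#' @export
boundary_score <- function(x, is_dot, x0, gamma = 0.02) {
  # half-spacing slack so a nucleus sitting numerically at x0 counts as
  # dorsal of it (the score is piecewise constant between nuclei)
  eps <- 1e-9
  vapply(x0, function(b)
    sum(is_dot & x <= b + eps) - gamma * sum(!is_dot & x <= b + eps),
    numeric(1))
}

#' Expression-domain boundary of one time point
#'
#' Splits the embryo at the dorsal midline into left (`dv < 0`) and right
#' (`dv >= 0`) halves, collapses z-slices (a nucleus is dot-positive at a
#' time point if any of its z records is called), and per half takes the
#' boundary as the candidate position with the highest penalized score,
#' candidates being the observed nucleus positions (the score is piecewise
#' constant between them); ties break toward the more dorsal (smaller)
#' position.  The domain width is the average of the two halves' boundaries,
#' which makes the exact midline location immaterial.
#'
#' @param calls data frame for one time point with columns `label`, `dv`,
#'   `is_dot` (from [call_dots()]).
#' @param gamma penalty weight.
#' @return list with `left_boundary`, `right_boundary`, `width`,
#'   `score_left`, `score_right` (data frames of candidate positions and
#'   scores) and `empty_halves` (halves with no called dot, boundary 0).
#' @export
find_boundary <- function(calls, gamma = 0.02) {
  per_nuc <- aggregate(is_dot ~ label + dv, data = calls, FUN = any)
  halves <- list(right = per_nuc[per_nuc$dv >= 0, ],
                 left = per_nuc[per_nuc$dv < 0, ])
  if (any(vapply(halves, nrow, integer(1)) == 0))
    stop_dv("empty_half", "both halves need at least one nucleus")
  empty <- character(0)
  res <- lapply(names(halves), function(side) {
    h <- halves[[side]]
    x <- abs(h$dv)
    if (!any(h$is_dot)) {
      empty <<- c(empty, side)
      return(list(boundary = 0, profile = data.frame(x0 = sort(unique(x)),
                                                     score = NA_real_)))
    }
    cand <- sort(unique(x))
    sc <- boundary_score(x, h$is_dot, cand, gamma)
    list(boundary = cand[which.max(sc)],        # which.max takes the first
         profile = data.frame(x0 = cand, score = sc))
  })
  names(res) <- names(halves)
  list(left_boundary = res$left$boundary,
       right_boundary = res$right$boundary,
       width = (res$left$boundary + res$right$boundary) / 2,
       score_left = res$left$profile, score_right = res$right$profile,
       empty_halves = empty)
}

#' Per-frame boundaries and time-course width summary
#'
#' Applies [find_boundary()] to every time point and summarizes the widths:
#' the embryo's domain width is the mean over time points, with the
#' standard deviation as spread.
#'
#' @param calls data frame with columns `frame`, `label`, `dv`, `is_dot`.
#' @param gamma penalty weight.
#' @return list with `boundaries` (data frame `frame`, `left_boundary`,
#'   `right_boundary`, `width`), `mean_width`, `sd_width`.
#' @export
width_time_course <- function(calls, gamma = 0.02) {
  frames <- sort(unique(calls$frame))
  rows <- lapply(frames, function(f) {
    b <- find_boundary(calls[calls$frame == f, ], gamma)
    data.frame(frame = f, left_boundary = b$left_boundary,
               right_boundary = b$right_boundary, width = b$width)
  })
  boundaries <- do.call(rbind, rows)
  list(boundaries = boundaries,
       mean_width = mean(boundaries$width),
       sd_width = if (nrow(boundaries) > 1) sd(boundaries$width) else 0)
}

#' Ensemble width summary across embryos
#'
#' Per-time-course mean widths with their s.e.m. across embryos, in the
#' style of a cumulative-distribution comparison of embryo averages.
#'
#' @param widths list of [width_time_course()] results (one per embryo).
#' @return list with `per_embryo` (data frame `embryo`, `mean_width`,
#'   `sd_width`), `mean`, `sem`.
#' @export
ensemble_widths <- function(widths) {
  per <- data.frame(embryo = seq_along(widths),
                    mean_width = vapply(widths, `[[`, numeric(1), "mean_width"),
                    sd_width = vapply(widths, `[[`, numeric(1), "sd_width"))
  list(per_embryo = per, mean = mean(per$mean_width),
       sem = sd(per$mean_width) / sqrt(nrow(per)))
}
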