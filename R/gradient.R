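#' Fit a Gaussian dorsoventral gradient to per-nucleus intensities
#'
#' Nonlinear least-squares fit of the four-parameter model
#' \deqn{I(x) = A \exp\left(-\frac{(x-\mu)^2}{2\sigma^2}\right) + B}
#' to nuclear intensity versus signed DV coordinate, where `A` is the
#' amplitude, `B` the basal level, `mu` the peak location and `sigma` the
#' gradient width (length scale).  Initialization is deterministic:
#' `mu0` is the DV position of the maximum of a 15-nucleus moving-average
#' profile, `B0` the 5th intensity percentile, `A0` the 95th minus the 5th
#' percentile, `sigma0 = 0.15`.  Bounds: `A >= 0`, `sigma` in (0.005, 1].
#'
#' @param x signed DV coordinates, or a data frame with columns `dv` and
#'   `intensity` (in which case `y` is ignored).
#' @param y intensities, same length as `x`.
#' @param init optional named vector overriding the starting values
#'   (`A`, `B`, `mu`, `sigma`).
#' @param min_nuclei minimum number of points accepted for a 4-parameter fit.
#' @return an object of class `gradient_fit` with components `coefficients`
#'   (A, B, mu, sigma), `residual_norm`, `n_nuclei`, `convergence`
#'   (`"converged"` or `"flat"`), and the data.  Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @export
fit_gaussian <- function(x, y = NULL, init = NULL, min_nuclei = 8L) {
  if (is.data.frame(x)) { y <- x$intensity; x <- x$dv }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_nuclei)
    stop_dv("fit_failed", "fit failed: %d nuclei, need at least %d",
            length(x), min_nuclei)
  if (diff(range(x)) < 0.5)
    stop_dv("fit_failed", "fit failed: nuclei span less than half the DV axis")
  qs <- quantile(y, c(0.05, 0.95), names = FALSE)
  if (qs[2] - qs[1] <= max(1e-12, 1e-9 * abs(qs[2]))) {
    # flat data: amplitude indistinguishable from zero
    fit <- structure(list(coefficients = c(A = 0, B = mean(y), mu = 0, sigma = 0.15),
                          residual_norm = sqrt(sum((y - mean(y))^2)),
                          n_nuclei = length(x), convergence = "flat",
                          data = data.frame(dv = x, intensity = y)),
                     class = "gradient_fit")
    return(fit)
  }
  if (is.null(init)) {
    ord <- order(x)
    prof <- moving_average(y[ord], 15L)
    init <- c(A = qs[2] - qs[1], B = qs[1], mu = x[ord][which.max(prof)],
              sigma = 0.15)
  }
  resid_fn <- function(p)
    y - (p["A"] * exp(-(x - p["mu"])^2 / (2 * p["sigma"]^2)) + p["B"])
  jac_fn <- function(p) {
    e <- exp(-(x - p["mu"])^2 / (2 * p["sigma"]^2))
    -cbind(A = e, B = rep(1, length(x)),
           mu = p["A"] * e * (x - p["mu"]) / p["sigma"]^2,
           sigma = p["A"] * e * (x - p["mu"])^2 / p["sigma"]^3)
  }
  mdl <- tryCatch(
    minpack.lm::nls.lm(
      par = init[c("A", "B", "mu", "sigma")], fn = resid_fn, jac = jac_fn,
      lower = c(A = 0, B = -Inf, mu = min(x) - 0.5, sigma = 0.005),
      upper = c(A = Inf, B = Inf, mu = max(x) + 0.5, sigma = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  # info codes 1-4 are Levenberg-Marquardt convergence; 0 and >= 5 are not
  if (is.null(mdl) || !(mdl$info %in% 1:4))
    stop_dv("fit_failed", "fit failed: optimizer did not converge")
  cf <- mdl$par
  if (cf["sigma"] <= 0.005 - 1e-12 || cf["sigma"] > 1 + 1e-12)
    stop_dv("fit_failed", "fit failed: sigma %.4f outside (0.005, 1]", cf["sigma"])
  structure(list(coefficients = cf[c("A", "B", "mu", "sigma")],
                 residual_norm = sqrt(mdl$deviance),
                 n_nuclei = length(x), convergence = "converged",
                 data = data.frame(dv = x, intensity = y)),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, digits = 4, ...) {
  cat("Gaussian DV gradient fit (", x$n_nuclei, " nuclei, ",
      x$convergence, ")\n", sep = "")
  print(round(x$coefficients, digits))
  cat("residual norm:", signif(x$residual_norm, digits), "\n")
  invisible(x)
}

#' @export
summary.gradient_fit <- function(object, ...) {
  cf <- object$coefficients
  cat("Gaussian gradient I(x) = A*exp(-(x-mu)^2/(2*sigma^2)) + B\n")
  print(data.frame(A = cf["A"], B = cf["B"], mu = cf["mu"], sigma = cf["sigma"],
                   residual_norm = object$residual_norm,
                   n_nuclei = object$n_nuclei, row.names = ""))
  invisible(object)
}

#' @export
coef.gradient_fit <- function(object, ...) object$coefficients

#' @export
predict.gradient_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dv
       else if (is.data.frame(newdata)) newdata$dv else newdata
  cf <- object$coefficients
  cf["A"] * exp(-(x - cf["mu"])^2 / (2 * cf["sigma"]^2)) + cf["B"]
}

#' @export
fitted.gradient_fit <- function(object, ...) predict(object)

#' @export
residuals.gradient_fit <- function(object, ...)
  object$data$intensity - fitted(object)

#' @export
plot.gradient_fit <- function(x, ...) {
  plot(x$data$dv, x$data$intensity, xlab = "DV coordinate",
       ylab = "intensity", ...)
  xs <- seq(min(x$data$dv), max(x$data$dv), length.out = 200)
  lines(xs, predict(x, xs), col = "red3", lwd = 2)
  invisible(x)
}

# ---- normalization -----------------------------------------------------------

#' Session normalization factor from the calibration image
#'
#' `Calib_norm = (Calib_mean / 1.74e4) * (0.1 / Calib_LP)`: proportional to
#' the mean of the no-sample calibration image and inversely proportional to
#' the calibration laser power, equal to 1 at the reference constants.
#' Signal-channel intensities of a session are divided by it.
#'
#' @param calib_mean mean intensity of the calibration image.
#' @param calib_lp calibration laser-power setting.
#' @return the session factor `Calib_norm`.
#' @export
session_factor <- function(calib_mean, calib_lp) {
  if (calib_mean <= 0 || calib_lp <= 0)
    stop_dv("bad_normalization", "calibration inputs must be positive")
  (calib_mean / 1.74e4) * (0.1 / calib_lp)
}

#' Time-course normalization factor from the nuclear channel
#'
#' `timecourse_norm = nuc_mean / (100 * nuc_LP)`; corrects for an overall
#' brighter time course (e.g. a different imaging depth).  The embryo's
#' signal channel is divided by it.
#'
#' @param nuc_mean time-course mean nuclear intensity.
#' @param nuc_lp nuclear-channel laser power.
#' @return the embryo factor `timecourse_norm`.
#' @export
timecourse_factor <- function(nuc_mean, nuc_lp) {
  if (nuc_mean <= 0 || nuc_lp <= 0)
    stop_dv("bad_normalization", "nuclear-channel inputs must be positive")
  nuc_mean / (100 * nuc_lp)
}

#' DV-axis normalization curve from nuclear intensities
#'
#' For each frame, per-nucleus nuclear intensity is related to the folded DV
#' coordinate with a sliding window of 30 nuclei; each frame's smoothed curve
#' is linearly interpolated onto an equally spaced 151-point grid on [0, 1],
#' the per-frame curves are averaged, and the result is scaled to unit mean.
#' Frames with fewer than 30 nuclei are excluded.
#'
#' @param records data frame with columns `frame`, `dv`, `mean_nuclear`.
#' @param window sliding-window size in nuclei.
#' @param grid_points number of grid points.
#' @return object of class `dv_norm_curve`: list with `x_grid`, `curve`
#'   (unit mean) and `n_frames` used.
#' @export
dv_norm_curve <- function(records, window = 30L, grid_points = 151L) {
  x_grid <- seq(0, 1, length.out = grid_points)
  per_frame <- list()
  for (f in unique(records$frame)) {
    sub <- records[records$frame == f & is.finite(records$dv), ]
    if (nrow(sub) < window) {
      message("dv_norm_curve: frame ", f, " has fewer than ", window,
              " nuclei; excluded")
      next
    }
    xf <- abs(sub$dv)
    ord <- order(xf)
    xs <- moving_average(xf[ord], window)
    ys <- moving_average(sub$mean_nuclear[ord], window)
    per_frame[[length(per_frame) + 1L]] <-
      approx(xs, ys, xout = x_grid, rule = 2)$y
  }
  if (!length(per_frame))
    stop_dv("bad_normalization", "no frame has enough nuclei for the DV curve")
  curve <- Reduce(`+`, per_frame) / length(per_frame)
  curve <- curve / mean(curve)
  structure(list(x_grid = x_grid, curve = curve, n_frames = length(per_frame)),
            class = "dv_norm_curve")
}

#' Evaluate a DV normalization curve at nucleus positions
#'
#' @param curve a [dv_norm_curve()].
#' @param dv signed or folded DV coordinates.
#' @return interpolated curve values.
#' @export
eval_dv_curve <- function(curve, dv) {
  approx(curve$x_grid, curve$curve, xout = abs(dv), rule = 2)$y
}

#' Apply the multiplicative normalization layers to signal intensities
#'
#' Normalized intensity = raw / (Calib_norm * timecourse_norm *
#' curve_norm(x)).  All three layers are multiplicative, so their order is
#' immaterial; any may be omitted (factor 1).
#'
#' @param records data frame with columns `mean_signal` and `dv`.
#' @param calib_norm session factor (default 1).
#' @param timecourse_norm embryo factor (default 1).
#' @param curve optional [dv_norm_curve()].
#' @return `records` with `mean_signal` replaced by its normalized value and
#'   the raw value kept in `raw_signal`.
#' @export
apply_normalization <- function(records, calib_norm = 1, timecourse_norm = 1,
                                curve = NULL) {
  denom <- calib_norm * timecourse_norm
  cv <- if (is.null(curve)) 1 else eval_dv_curve(curve, records$dv)
  out <- records
  out$raw_signal <- records$mean_signal
  out$mean_signal <- records$mean_signal / (denom * cv)
  out
}

#' Nuclear-ratio and affine normalization for fixed embryos
#'
#' Divides the signal intensity of each nucleus by its nuclear-channel
#' intensity, fits the ratio profile with [fit_gaussian()], and applies the
#' affine normalization `(I - B)/A`.  Nuclei whose nuclear intensity falls
#' below `floor_frac` times the median are dropped.  If the fitted amplitude
#' is indistinguishable from zero (flat channel) the affine step reduces to
#' subtracting the basal level.
#'
#' @param dv signed DV coordinates.
#' @param signal signal-channel nuclear means.
#' @param nuclear nuclear-channel nuclear means.
#' @param floor_frac drop threshold for dim nuclei.
#' @return list with `norm` (normalized intensities), `ratio`, `keep`
#'   (logical), and the `fit`.
#' @export
normalize_fixed <- function(dv, signal, nuclear, floor_frac = 0.1) {
  keep <- nuclear > floor_frac * median(nuclear)
  if (!all(keep))
    message("normalize_fixed: dropped ", sum(!keep), " dim nuclei")
  ratio <- signal[keep] / nuclear[keep]
  fit <- fit_gaussian(dv[keep], ratio)
  cf <- coef(fit)
  norm <- if (cf["A"] > 1e-8) (ratio - cf["B"]) / cf["A"] else ratio - cf["B"]
  list(norm = norm, ratio = ratio, keep = keep, fit = fit)
}

#' Per-embryo two-channel nuclear correlation
#'
#' For each embryo, both signal channels are normalized with
#' [normalize_fixed()] and the Pearson correlation across nuclei (pooled
#' over z-slices) is computed; the ensemble mean and s.d. follow.
#' Zero-variance channels exclude the embryo.
#'
#' @param embryos list of data frames with columns `dv`, `nuclear`, `ch1`,
#'   `ch2`.
#' @param min_nuclei warn below this many nuclei per embryo.
#' @return list with `rho` (per embryo), `mean`, `sd`, `n`.
#' @export
correlate_channels <- function(embryos, min_nuclei = 20L) {
  rho <- vapply(embryos, function(e) {
    if (nrow(e) < min_nuclei)
      warning("correlate_channels: embryo has fewer than ", min_nuclei, " nuclei")
    n1 <- normalize_fixed(e$dv, e$ch1, e$nuclear)
    n2 <- normalize_fixed(e$dv, e$ch2, e$nuclear)
    keep <- n1$keep & n2$keep
    a <- n1$norm[keep[n1$keep]]
    b <- n2$norm[keep[n2$keep]]
    if (sd(a) == 0 || sd(b) == 0) {
      message("correlate_channels: zero-variance channel; embryo excluded")
      return(NA_real_)
    }
    cor(a, b)
  }, numeric(1))
  rho <- rho[is.finite(rho)]
  list(rho = rho, mean = mean(rho), sd = sd(rho), n = length(rho))
}

# ---- averaging ----------------------------------------------------------------

#' Smooth per-frame gradient parameters in time
#'
#' Centered moving average with a 10-frame window (shrunken at the edges).
#'
#' @param fits data frame with columns `A`, `B`, `sigma` (and optionally
#'   others, which are passed through), one row per frame, or a numeric
#'   vector.
#' @param window window length in frames.
#' @return same shape as the input, smoothed.
#' @export
smooth_params <- function(fits, window = 10L) {
  if (is.numeric(fits)) return(moving_average(fits, window))
  out <- fits
  for (col in intersect(c("A", "B", "sigma"), names(fits)))
    out[[col]] <- moving_average(fits[[col]], window)
  out
}

#' The 36-point averaging mesh
#'
#' Equally spaced DV mesh on [0, 1] with 36 points and spacing
#' `dx = 1/35 = 0.0286` (to printed precision).
#'
#' @param n number of mesh points.
#' @return list with `x` (mesh points) and `dx` (spacing).
#' @export
dv_mesh <- function(n = 36L) {
  x <- seq(0, 1, length.out = n)
  list(x = x, dx = x[2] - x[1])
}

# Bin folded DV samples onto the mesh with half-width bins at both edges:
# bin 1 covers [0, dx/2), interior bin i covers [x_i - dx/2, x_i + dx/2),
# bin n covers [1 - dx/2, 1].
bin_on_mesh <- function(x, v, mesh = dv_mesh()) {
  breaks <- c(0, mesh$x[-length(mesh$x)] + mesh$dx / 2, 1 + 1e-9)
  bin <- findInterval(x, breaks, rightmost.closed = FALSE, left.open = FALSE)
  bin[bin > length(mesh$x)] <- length(mesh$x)
  mean_v <- tapply(v, factor(bin, levels = seq_along(mesh$x)), mean)
  sd_v <- tapply(v, factor(bin, levels = seq_along(mesh$x)), sd)
  n_v <- tapply(v, factor(bin, levels = seq_along(mesh$x)), length)
  n_v[is.na(n_v)] <- 0
  sem <- ifelse(n_v > 1, sd_v / sqrt(n_v), NA)
  empty <- n_v == 0
  fill <- function(y) {
    ok <- which(!is.na(y))
    if (length(ok) < 2) return(y)
    approx(mesh$x[ok], y[ok], xout = mesh$x, rule = 2)$y
  }
  list(mean = fill(as.numeric(mean_v)), sem = fill(as.numeric(sem)),
       n = as.integer(n_v), interpolated = as.logical(empty))
}

#' Average gradients across embryos after width rescaling
#'
#' Per-embryo parameter series are smoothed in time (10-frame window) and
#' averaged to ensemble parameters \eqn{\bar A(t), \bar B(t), \bar\sigma(t)}.
#' For each embryo and frame, DV coordinates are multiplied by
#' \eqn{\chi_k(t) = \bar\sigma(t)/\sigma_k(t)} (stretching when
#' \eqn{\chi_k > 1}, compressing when \eqn{\chi_k < 1}); rescaled nuclei with
#' `|x| > 1` are dropped.  Intensities are affinely normalized per embryo
#' (`(I - B_k)/A_k`), pooled across embryos, de-normalized with
#' \eqn{\bar A, \bar B}, the left and right halves are combined (folded to
#' [0, 1]) and the pooled nuclei are binned onto the 36-point mesh with
#' half-width edge bins.  Empty bins are linearly interpolated and flagged.
#'
#' @param embryos list; each element is a list with `fits` (data frame
#'   `frame`, `A`, `B`, `mu`, `sigma`) and `nuclei` (data frame `frame`,
#'   `dv`, `intensity`).
#' @param window parameter-smoothing window, frames.
#' @param mesh mesh from [dv_mesh()].
#' @return object of class `averaged_gradient`: `mesh`, per-frame matrices
#'   `mean`, `sem`, `interpolated` (frames x mesh points), ensemble
#'   parameters `A_bar`, `B_bar`, `sigma_bar`, rescale factors `chi`
#'   (embryos x frames) and the aligned `frames`.
#' @export
average_embryos <- function(embryos, window = 10L, mesh = dv_mesh()) {
  stopifnot(length(embryos) >= 1)
  frames <- Reduce(intersect, lapply(embryos, function(e) e$fits$frame))
  if (length(frames) == 0)
    stop_dv("alignment_failed", "alignment failed: no overlapping frames")
  frames <- sort(frames)
  sm <- lapply(embryos, function(e) {
    f <- e$fits[order(e$fits$frame), ]
    s <- smooth_params(f, window)
    s[match(frames, s$frame), ]
  })
  par_mat <- function(col)   # frames x embryos, robust to a single frame
    matrix(unlist(lapply(sm, `[[`, col)), nrow = length(frames))
  A_bar <- rowMeans(par_mat("A"))
  B_bar <- rowMeans(par_mat("B"))
  sigma_bar <- rowMeans(par_mat("sigma"))
  chi <- t(sigma_bar / par_mat("sigma"))   # embryos x frames
  nm <- length(mesh$x)
  mean_m <- sem_m <- matrix(NA_real_, length(frames), nm)
  interp_m <- matrix(FALSE, length(frames), nm)
  for (ti in seq_along(frames)) {
    t <- frames[ti]
    xs <- numeric(0); vs <- numeric(0)
    for (k in seq_along(embryos)) {
      nuc <- embryos[[k]]$nuclei
      sub <- nuc[nuc$frame == t & is.finite(nuc$dv), ]
      if (!nrow(sub)) next
      xk <- sub$dv * chi[k, ti]
      keep <- abs(xk) <= 1
      Ak <- sm[[k]]$A[ti]; Bk <- sm[[k]]$B[ti]
      vn <- (sub$intensity[keep] - Bk) / Ak
      xs <- c(xs, abs(xk[keep]))
      vs <- c(vs, vn * A_bar[ti] + B_bar[ti])
    }
    b <- bin_on_mesh(xs, vs, mesh)
    mean_m[ti, ] <- b$mean
    sem_m[ti, ] <- b$sem
    interp_m[ti, ] <- b$interpolated
  }
  structure(list(mesh = mesh, frames = frames, mean = mean_m, sem = sem_m,
                 interpolated = interp_m, A_bar = A_bar, B_bar = B_bar,
                 sigma_bar = sigma_bar, chi = chi),
            class = "averaged_gradient")
}

#' @export
print.averaged_gradient <- function(x, ...) {
  cat("averaged_gradient:", length(x$frames), "frames on a",
      length(x$mesh$x), "point mesh (dx =", round(x$mesh$dx, 4), ")\n")
  invisible(x)
}

# ---- control embryos -----------------------------------------------------------

#' Filter and set-normalize control-embryo background curves
#'
#' Each control embryo's DV-averaged signal-vs-time curve is low-pass
#' filtered with a centered moving average spanning `filter_window` seconds
#' (default twice the nominal 9-min oscillation period, which nulls a
#' sinusoid of that period), then the whole set is normalized by
#' `beta_norm`, the mean of the filtered curves over embryos and time.
#'
#' @param curves numeric matrix (time points x embryos) or vector of
#'   DV-averaged background intensities.
#' @param time_step seconds between frames.
#' @param filter_window filter span in seconds.
#' @return list with `filtered` (matrix), `beta_norm`, and `normalized`.
#' @export
control_background <- function(curves, time_step, filter_window = 2 * 9 * 60) {
  curves <- as.matrix(curves)
  wlen <- max(1L, round(filter_window / time_step))
  filtered <- apply(curves, 2, moving_average, window = wlen)
  filtered <- matrix(filtered, nrow(curves), ncol(curves))
  beta_norm <- mean(filtered)
  list(filtered = filtered, beta_norm = beta_norm,
       normalized = filtered / beta_norm)
}

#' DV-averaged signal intensity of a series
#'
#' Runs segmentation on each frame and averages the per-nucleus signal
#' intensity over the whole DV axis, giving an intensity-vs-time curve with
#' no spatial component (used for no-reporter control embryos).
#'
#' @param series an `embryo_series`.
#' @param ... passed to [analyze_cross_section()].
#' @return data frame with `time` and `intensity`.
#' @export
dv_average_series <- function(series, ...) {
  vals <- vapply(seq_along(series$frames), function(j) {
    fr <- series$frames[[j]]
    res <- analyze_cross_section(fr$nuclear, fr$signal,
                                 pixel_size = series$pixel_size, frame = j, ...)
    mean(res$records$mean_signal)
  }, numeric(1))
  data.frame(time = series$time, intensity = vals)
}

#' Mean intensity time course in a DV band
#'
#' Mean (and s.e.m.) of normalized nuclear intensities with folded DV
#' coordinate within `band` of `x0`, per frame.  Frames with no nuclei in
#' the band yield `NA`, not zero.
#'
#' @param records data frame with columns `frame`, `dv`, `intensity`.
#' @param x0 DV position (folded, in [0, 1]).
#' @param band half-width of the band.
#' @return data frame with `frame`, `mean`, `sem`, `n`.
#' @export
time_course_at_dv <- function(records, x0, band = 0.02) {
  frames <- sort(unique(records$frame))
  out <- lapply(frames, function(f) {
    sub <- records[records$frame == f & abs(abs(records$dv) - x0) <= band, ]
    n <- nrow(sub)
    data.frame(frame = f,
               mean = if (n) mean(sub$intensity) else NA_real_,
               sem = if (n > 1) sd(sub$intensity) / sqrt(n) else NA_real_,
               n = n)
  })
  do.call(rbind, out)
}
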