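gauss <- function(x, A, B, mu, sigma) A * exp(-(x - mu)^2 / (2 * sigma^2)) + B

test_that("noiseless Gaussian samples are recovered to machine-level accuracy", {
  x <- seq(-1, 1, length.out = 100)
  fit <- fit_gaussian(x, gauss(x, 10, 2, 0, 0.15))
  expect_equal(unname(coef(fit)), c(10, 2, 0, 0.15), tolerance = 1e-6)
  expect_equal(fit$convergence, "converged")
  # closed form of the fitted model at its own landmarks
  cf <- coef(fit)
  expect_equal(unname(predict(fit, cf["mu"])), unname(cf["A"] + cf["B"]),
               tolerance = 1e-9)
  expect_equal(unname(predict(fit, cf["mu"] + cf["sigma"])),
               unname(cf["B"] + cf["A"] * exp(-0.5)), tolerance = 1e-9)
  # off-center, different width
  fit2 <- fit_gaussian(x, gauss(x, 5, 1, 0.3, 0.4))
  expect_equal(unname(coef(fit2)), c(5, 1, 0.3, 0.4), tolerance = 1e-6)
})

test_that("flat intensity data yield zero amplitude at the data level", {
  fit <- fit_gaussian(seq(-1, 1, length.out = 50), rep(3.7, 50))
  expect_equal(unname(coef(fit)["A"]), 0)
  expect_equal(unname(coef(fit)["B"]), 3.7)
  expect_equal(fit$convergence, "flat")
})

test_that("undersized or degenerate inputs fail loudly", {
  expect_error(fit_gaussian(seq(-1, 1, length.out = 5), rnorm(5)),
               class = "fit_failed")
  x <- seq(-0.1, 0.1, length.out = 30)     # spans too little of the axis
  expect_error(fit_gaussian(x, gauss(x, 10, 2, 0, 0.15)), class = "fit_failed")
})

test_that("fit errors shrink with noise and stay small at default noise", {
  x <- seq(-1, 1, length.out = 120)
  med_err <- vapply(c(0.02, 0.1, 0.4), function(ns) {
    errs <- vapply(1:20, function(s) {
      y <- withr::with_seed(s, gauss(x, 10, 2, 0, 0.15) + rnorm(120, 0, ns))
      cf <- coef(fit_gaussian(x, y))
      max(abs(cf[c("A", "B", "sigma")] / c(10, 2, 0.15) - 1))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[2], 0.05)
  expect_true(all(diff(med_err) > 0))
})

test_that("session and time-course factors follow their canonical forms", {
  expect_equal(session_factor(1.74e4, 0.1), 1)
  expect_equal(session_factor(2 * 1.74e4, 0.1), 2)
  expect_equal(session_factor(1.74e4, 0.2), 0.5)
  expect_error(session_factor(-1, 0.1), class = "bad_normalization")
  expect_equal(timecourse_factor(100 * 0.1, 0.1), 1)
  expect_equal(timecourse_factor(2 * 100 * 0.1, 0.1), 2)
  expect_error(timecourse_factor(10, 0), class = "bad_normalization")
})

test_that("multiplicative normalization layers commute", {
  rec <- data.frame(mean_signal = runif(40, 1, 5),
                    dv = seq(-0.97, 0.97, length.out = 40))
  curve <- structure(list(x_grid = seq(0, 1, length.out = 151),
                          curve = 1 + 0.2 * sin(seq(0, pi, length.out = 151)),
                          n_frames = 1L), class = "dv_norm_curve")
  a <- apply_normalization(rec, calib_norm = 1.3, timecourse_norm = 0.8,
                           curve = curve)
  b <- apply_normalization(
    apply_normalization(
      apply_normalization(rec, curve = curve), timecourse_norm = 0.8),
    calib_norm = 1.3)
  expect_equal(a$mean_signal, b$mean_signal, tolerance = 1e-12)
})

test_that("identical embryos differing by global brightness normalize alike", {
  cfg1 <- small_config(gradient_trajectory = one_frame_traj(), noise_sd = 0)
  cs <- generate_cross_section(cfg1)
  r1 <- analyze_cross_section(cs$nuclear, cs$signal,
                              pixel_size = cfg1$pixel_size,
                              min_size = SMALL_MIN_SIZE)$records
  r2 <- analyze_cross_section(1.3 * cs$nuclear, 1.3 * cs$signal,
                              pixel_size = cfg1$pixel_size,
                              min_size = SMALL_MIN_SIZE)$records
  n1 <- apply_normalization(r1, timecourse_norm = timecourse_factor(
    mean(r1$mean_nuclear), 0.1))
  n2 <- apply_normalization(r2, timecourse_norm = timecourse_factor(
    mean(r2$mean_nuclear), 0.1))
  f1 <- coef(fit_gaussian(n1$dv, n1$mean_signal))
  f2 <- coef(fit_gaussian(n2$dv, n2$mean_signal))
  expect_equal(f1, f2, tolerance = 0.02)
})

test_that("the DV curve has 151 points and undoes an axis-wide ramp", {
  # spatially uniform nuclear channel: unit curve, normalization a no-op
  set.seed(1)
  flat <- data.frame(frame = 1, dv = runif(60, -1, 1), mean_nuclear = 5)
  cv <- dv_norm_curve(flat)
  expect_length(cv$curve, 151L)
  expect_true(all(abs(cv$curve - 1) < 0.01))
  # a 2x linear DV ramp applied to both channels cancels after the curve
  x <- seq(-0.99, 0.99, length.out = 200)
  ramp <- 1 + abs(x)
  rec <- data.frame(frame = 1, dv = x, mean_nuclear = 5 * ramp,
                    mean_signal = gauss(x, 10, 2, 0, 0.2) * ramp)
  cv2 <- dv_norm_curve(rec)
  norm <- apply_normalization(rec, curve = cv2)
  # the curve removes the ramp up to one global scale factor, so the shape
  # parameters and the A:B ratio come back
  cf <- coef(fit_gaussian(norm$dv, norm$mean_signal))
  expect_equal(unname(cf["sigma"]), 0.2, tolerance = 0.03)
  expect_equal(unname(cf["mu"]), 0, tolerance = 0.01)
  expect_equal(unname(cf["A"] / cf["B"]), 5, tolerance = 0.03)
  # normalization strictly improves the Gaussian's account of the profile
  raw <- fit_gaussian(rec$dv, rec$mean_signal)
  norm_fit <- fit_gaussian(norm$dv, norm$mean_signal)
  expect_lt(norm_fit$residual_norm / norm_fit$coefficients["A"],
            raw$residual_norm / raw$coefficients["A"])
  # single frame: the average equals that frame's own curve
  cv3 <- dv_norm_curve(rbind(rec, within(rec, frame <- 2)))
  expect_equal(cv3$curve, cv2$curve, tolerance = 1e-12)
  # undersized frames are excluded
  expect_error(suppressMessages(dv_norm_curve(flat[1:10, ])),
               class = "bad_normalization")
})

test_that("parameter smoothing is a partial-window centered moving average", {
  expect_equal(smooth_params(rep(4, 25)), rep(4, 25))
  spike <- c(rep(0, 9), 10, rep(0, 10))
  expect_equal(smooth_params(spike)[10], 1)          # influence cut 10-fold
  lin <- smooth_params(seq(2, 40, by = 2))
  expect_lt(max(abs(diff(diff(lin[6:15])))), 1e-9)   # linear stays linear
  df <- smooth_params(data.frame(frame = 1:20, A = rep(2, 20),
                                 B = 1:20, sigma = rep(0.2, 20)))
  expect_equal(df$A, rep(2, 20))
  expect_equal(df$frame, 1:20)                       # passthrough untouched
})

test_that("averaging rescales widths onto the ensemble Gaussian", {
  x <- seq(-0.999, 0.999, length.out = 400)
  emb <- function(sig) list(
    fits = data.frame(frame = 1, A = 10, B = 2, mu = 0, sigma = sig),
    nuclei = data.frame(frame = 1, dv = x, intensity = gauss(x, 10, 2, 0, sig)))
  avg <- average_embryos(list(emb(0.10), emb(0.20)))
  expect_equal(avg$mesh$dx, 1 / 35)
  expect_equal(unname(avg$sigma_bar), 0.15)
  expect_equal(unname(avg$chi[, 1]), c(1.5, 0.75))
  target <- gauss(avg$mesh$x, 10, 2, 0, 0.15)
  expect_lt(max(abs(avg$mean[1, ] / target - 1)), 0.02)
  # single embryo: chi = 1 identically, output is its own binned gradient
  one <- average_embryos(list(emb(0.15)))
  expect_equal(unname(one$chi[1, ]), 1)
  expect_lt(max(abs(one$mean[1, ] / target - 1)), 0.02)
  expect_error(average_embryos(list(
    list(fits = data.frame(frame = 1, A = 1, B = 0, mu = 0, sigma = 0.1),
         nuclei = data.frame(frame = 1, dv = 0, intensity = 1)),
    list(fits = data.frame(frame = 2, A = 1, B = 0, mu = 0, sigma = 0.1),
         nuclei = data.frame(frame = 2, dv = 0, intensity = 1)))),
    class = "alignment_failed")
})

test_that("folding a symmetric embryo equals either half's binned profile", {
  xh <- seq(0.001, 0.999, length.out = 180)
  y <- gauss(xh, 8, 1, 0, 0.25)
  emb <- list(fits = data.frame(frame = 1, A = 8, B = 1, mu = 0, sigma = 0.25),
              nuclei = data.frame(frame = 1, dv = c(xh, -xh),
                                  intensity = c(y, y)))
  avg <- average_embryos(list(emb))
  half <- dvquant:::bin_on_mesh(xh, y)
  expect_equal(avg$mean[1, ], half$mean, tolerance = 1e-9)
})

test_that("averaging across embryos shrinks the per-bin standard error", {
  x <- seq(-0.999, 0.999, length.out = 300)
  mk <- function(seed) {
    y <- withr::with_seed(seed, gauss(x, 10, 2, 0, 0.15) + rnorm(300, 0, 0.5))
    list(fits = data.frame(frame = 1, A = 10, B = 2, mu = 0, sigma = 0.15),
         nuclei = data.frame(frame = 1, dv = x, intensity = y))
  }
  five <- average_embryos(lapply(1:5, mk))
  singles <- lapply(1:5, function(s) average_embryos(list(mk(s))))
  for (s in singles)
    expect_gte(sum(five$sem[1, ] < s$sem[1, ], na.rm = TRUE), 30)
})

test_that("empty mesh bins are interpolated and flagged", {
  x <- c(seq(0.01, 0.4, length.out = 60), seq(0.6, 0.99, length.out = 60))
  emb <- list(fits = data.frame(frame = 1, A = 10, B = 2, mu = 0, sigma = 0.3),
              nuclei = data.frame(frame = 1, dv = x,
                                  intensity = gauss(x, 10, 2, 0, 0.3)))
  avg <- average_embryos(list(emb))
  gap <- avg$mesh$x > 0.42 & avg$mesh$x < 0.58
  expect_true(any(avg$interpolated[1, gap]))
  expect_true(all(is.finite(avg$mean[1, ])))
})

test_that("control background filtering nulls the oscillation and set scale", {
  tt <- seq(0, 3000, by = 25)
  const <- control_background(cbind(rep(4, length(tt))), time_step = 25)
  expect_equal(const$filtered[, 1], rep(4, length(tt)))
  expect_equal(const$beta_norm, 4)
  expect_true(all(const$normalized == 1))
  # 9-min sinusoid attenuated below 10% of its amplitude (interior points)
  osc <- 4 + 1 * sin(2 * pi * tt / 540)
  f <- control_background(cbind(osc), time_step = 25)
  interior <- 30:(length(tt) - 30)
  expect_lt(max(abs(f$filtered[interior, 1] - 4)), 0.1)
  # two microscope sets differing 3x in gain collapse onto each other
  s1 <- control_background(cbind(rep(2, 50)), time_step = 25)
  s2 <- control_background(cbind(rep(6, 50)), time_step = 25)
  expect_equal(s1$normalized, s2$normalized)
})

test_that("channel correlation hits the trivial limits", {
  x <- seq(-1, 1, length.out = 60)
  g <- gauss(x, 10, 2, 0, 0.2)
  same <- data.frame(dv = x, nuclear = 5, ch1 = g, ch2 = g)
  out <- correlate_channels(list(same, same))
  expect_equal(out$rho, c(1, 1))
  expect_equal(out$mean, 1)
  # one channel mirrored about its mean: rho = -1
  neg <- within(same, ch2 <- 2 * mean(g) - g)
  expect_equal(suppressMessages(correlate_channels(list(neg)))$rho, -1,
               tolerance = 1e-9)
})

test_that("DV band time courses follow the generating trajectory", {
  # refining gradient with sigma <= 0.2 throughout, so the x0 = 0.6 band
  # sits beyond three gradient widths (tail < exp(-3) of the amplitude)
  traj <- data.frame(A = seq(2, 10, length.out = 20), B = 2, mu = 0,
                     sigma = seq(0.2, 0.12, length.out = 20))
  set.seed(3)
  x <- runif(80, -1, 1)
  rec <- do.call(rbind, lapply(1:20, function(f)
    data.frame(frame = f, dv = x,
               intensity = gauss(x, traj$A[f], traj$B[f], 0, traj$sigma[f]))))
  peak <- time_course_at_dv(rec, x0 = 0, band = 0.05)
  expect_true(all(diff(peak$mean) > 0))              # sustained rise at the peak
  expect_equal(peak$mean, traj$A + traj$B, tolerance = 0.1)
  flank <- time_course_at_dv(rec, x0 = 0.6, band = 0.05)
  expect_lt(max(abs(flank$mean - traj$B)), 0.05)     # tail stays basal
  # band = 0 with a nucleus exactly at x0 returns that nucleus's trace
  rec1 <- rec[abs(rec$dv - rec$dv[7]) < 1e-12, ]
  tc <- time_course_at_dv(rec1, x0 = abs(rec1$dv[1]), band = 0)
  expect_equal(tc$mean, rec1$intensity[order(rec1$frame)])
  expect_true(all(is.na(
    time_course_at_dv(rec[rec$frame == 1, ], x0 = 2, band = 0.01)$mean)))
})

test_that("a transient flank versus sustained peak emerges from refinement", {
  # the refining trajectory makes intensity at 25% DV rise then fall while
  # the dorsal peak keeps rising
  traj <- refinement_trajectory(30L)
  flank <- gauss(0.25, traj$A, traj$B, 0, traj$sigma)
  expect_gt(max(flank), flank[1])
  expect_gt(max(flank), flank[30])
  expect_lt(which.max(flank), 30L)
  peak <- gauss(0.04, traj$A, traj$B, 0, traj$sigma)
  expect_true(all(diff(peak) > 0))
})
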