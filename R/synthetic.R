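#' Configuration for the synthetic embryo-image generator
#'
#' Builds the parameter set used by [generate_cross_section()],
#' [generate_time_course()], [generate_ms2_stack()], [generate_control_embryo()]
#' and [generate_fixed_embryo()].  The generator renders an elliptical embryo
#' cross-section whose cortical nuclear layer occupies an annulus of depth
#' `nuclear_layer_depth` inside the outline.  Nuclei are Gaussian-profiled
#' elliptical disks placed at approximately equal arc-length spacing; the
#' signal channel renders, flat within each nucleus footprint, the Gaussian
#' dorsoventral gradient `B + A * exp(-(x - mu)^2 / (2 * sigma^2))` evaluated
#' at the nucleus's signed DV coordinate `x`, plus a cytoplasmic level equal
#' to `cyto_fraction` of the local gradient value.
#'
#' Intensities are in arbitrary units (au) emulating scaled detector counts;
#' images are rendered as numeric matrices and quantized to 16 bit only when
#' written to TIFF.
#'
#' @param image_size integer vector (rows, cols) of the rendered frame.
#' @param pixel_size microns per pixel.
#' @param embryo_radii semi-axes (horizontal, vertical) of the elliptical
#'   outline, in microns.
#' @param nuclear_layer_depth depth of the nuclear annulus in microns.  The
#'   default 18.36 matches the annulus used by the unrolling stage.
#' @param n_nuclei number of nuclei per cross-section.
#' @param nucleus_radius tangential semi-axis of a nucleus, microns.
#' @param nucleus_elongation radial/tangential axis ratio of the nucleus
#'   footprint (cortical nuclei are elongated along the apical-basal axis).
#' @param nuclear_level peak nuclear-channel intensity (au).
#' @param gradient_trajectory data frame with columns `A`, `B`, `mu`, `sigma`,
#'   one row per frame.  Defaults to [refinement_trajectory()] with
#'   `n_frames` rows.
#' @param n_frames number of frames for the default trajectory.
#' @param noise_sd additive Gaussian noise s.d. per pixel (au), both channels.
#' @param nucleus_cv nucleus-to-nucleus multiplicative brightness variation
#'   (coefficient of variation) of the nuclear channel.
#' @param channel_cv per-channel multiplicative noise of the two-signal
#'   shared-field model used by [generate_fixed_embryo()].
#' @param background imaging background level (au) outside the embryo.
#' @param cyto_fraction cytoplasmic signal as a fraction of the local nuclear
#'   signal (nuclear exclusion/enrichment contrast).
#' @param dot_domain_halfwidth DV half-width (fraction of the half-
#'   circumference) of the domain carrying transcription dots.
#' @param dot_probability probability that an in-domain nucleus carries a dot
#'   in a given frame.
#' @param dot_contrast intensity added at dot pixels (au).
#' @param n_z number of z-slices of an MS2 stack.
#' @param z_spacing slice spacing, microns.
#' @param mcp_level uniform nuclear MCP-GFP level of MS2 embryos (au).
#' @param oscillation_amplitude relative amplitude of the control-embryo
#'   background oscillation.
#' @param oscillation_period oscillation period in seconds (default 9 min).
#' @param control_level mean control-embryo background level (au).
#' @param time_resolution seconds between frames.
#' @param jitter placement jitter as a fraction of the mean nucleus spacing.
#' @param rng_seed integer seed; with a fixed seed all generator output is
#'   bit-identical across calls.
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(image_size = c(1024L, 1024L),
                             pixel_size = 0.4,
                             embryo_radii = c(180, 160),
                             nuclear_layer_depth = 18.36,
                             n_nuclei = 80L,
                             nucleus_radius = 5,
                             nucleus_elongation = 1.6,
                             nuclear_level = 10,
                             gradient_trajectory = NULL,
                             n_frames = 40L,
                             noise_sd = 0.15,
                             nucleus_cv = 0.05,
                             channel_cv = 0.2,
                             background = 0.4,
                             cyto_fraction = 0.5,
                             dot_domain_halfwidth = 0.27,
                             dot_probability = 0.8,
                             dot_contrast = 6,
                             n_z = 10L,
                             z_spacing = 2,
                             mcp_level = 5,
                             oscillation_amplitude = 0.15,
                             oscillation_period = 9 * 60,
                             control_level = 2,
                             time_resolution = 25,
                             jitter = 0.1,
                             rng_seed = 1L) {
  if (is.null(gradient_trajectory))
    gradient_trajectory <- refinement_trajectory(n_frames)
  cfg <- list(image_size = as.integer(image_size), pixel_size = pixel_size,
              embryo_radii = embryo_radii,
              nuclear_layer_depth = nuclear_layer_depth,
              n_nuclei = as.integer(n_nuclei), nucleus_radius = nucleus_radius,
              nucleus_elongation = nucleus_elongation,
              nuclear_level = nuclear_level,
              gradient_trajectory = as.data.frame(gradient_trajectory),
              noise_sd = noise_sd, nucleus_cv = nucleus_cv,
              channel_cv = channel_cv, background = background,
              cyto_fraction = cyto_fraction,
              dot_domain_halfwidth = dot_domain_halfwidth,
              dot_probability = dot_probability, dot_contrast = dot_contrast,
              n_z = as.integer(n_z), z_spacing = z_spacing,
              mcp_level = mcp_level,
              oscillation_amplitude = oscillation_amplitude,
              oscillation_period = oscillation_period,
              control_level = control_level,
              time_resolution = time_resolution, jitter = jitter,
              rng_seed = as.integer(rng_seed))
  geom_pos <- c(cfg$pixel_size, cfg$embryo_radii, cfg$nuclear_layer_depth,
                cfg$nucleus_radius, cfg$nucleus_elongation, cfg$nuclear_level)
  if (any(!is.finite(geom_pos)) || any(geom_pos <= 0))
    stop_dv("config_error", "all geometric parameters must be positive")
  if (cfg$dot_domain_halfwidth < 0 || cfg$dot_domain_halfwidth > 1)
    stop_dv("config_error", "dot_domain_halfwidth must lie in [0, 1]")
  if (cfg$dot_probability < 0 || cfg$dot_probability > 1)
    stop_dv("config_error", "dot_probability must lie in [0, 1]")
  stopifnot(nrow(cfg$gradient_trajectory) >= 1,
            all(c("A", "B", "mu", "sigma") %in% names(cfg$gradient_trajectory)))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default gradient refinement trajectory
#'
#' Per-frame Gaussian parameters emulating a dorsal signaling gradient that
#' starts broad and weak and refines into a narrow, intense peak: `sigma`
#' decreases linearly from 0.35 to 0.12 while `A` rises from 2 to 10;
#' `B = 2` and `mu = 0` throughout.
#'
#' @param n_frames number of frames.
#' @return data frame with columns `A`, `B`, `mu`, `sigma`.
#' @export
refinement_trajectory <- function(n_frames = 40L) {
  n <- max(1L, as.integer(n_frames))
  if (n == 1L) return(data.frame(A = 10, B = 2, mu = 0, sigma = 0.15))
  f <- seq(0, 1, length.out = n)
  data.frame(A = 2 + 8 * f, B = 2, mu = 0, sigma = 0.35 - 0.23 * f)
}

# ---- internal geometry of the generated ellipse -----------------------------

# Dense parameterization of the embryo outline.  The dorsal midline sits at
# the top of the image (minimum row); the parameter angle psi runs over
# [-pi, pi] with psi > 0 on the right half, so that the signed DV coordinate
# (arc-length fraction of the half-perimeter) is positive on the right.
synth_geometry <- function(config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  a <- config$embryo_radii[1] / config$pixel_size
  b <- config$embryo_radii[2] / config$pixel_size
  r0 <- (h + 1) / 2; c0 <- (w + 1) / 2
  if (a * 2 > w - 4 || b * 2 > h - 4)
    stop_dv("config_error", "embryo outline does not fit in the image")
  psi <- seq(-pi, pi, length.out = 8193L)
  pc <- c0 + a * sin(psi)
  pr <- r0 - b * cos(psi)
  seg <- sqrt(diff(pc)^2 + diff(pr)^2)
  s <- c(0, cumsum(seg))                  # arc length from psi = -pi
  perim <- s[length(s)]
  s0 <- s[(length(s) + 1L) / 2L]          # arc length at psi = 0 (dorsal)
  dv <- (s - s0) / (perim / 2)            # signed DV in [-1, 1]
  list(h = h, w = w, a = a, b = b, r0 = r0, c0 = c0,
       psi = psi, dv = dv, perimeter = perim,
       depth_px = config$nuclear_layer_depth / config$pixel_size)
}

# psi angle for a signed DV coordinate.
synth_psi_at_dv <- function(geom, x) {
  approx(geom$dv, geom$psi, xout = x, rule = 2)$y
}

# Nucleus layout: centers, local frames and brightness factors.  Placement
# and brightness depend only on config$rng_seed, so the same embryo keeps the
# same nuclei in every frame.
synth_layout <- function(config, geom) {
  n <- config$n_nuclei
  rt <- config$nucleus_radius / config$pixel_size
  rr <- rt * config$nucleus_elongation
  spacing_dv <- 2 / n
  spacing_px <- geom$perimeter / n
  with_seed(config$rng_seed, {
    dv <- -1 + (seq_len(n) - 0.5) * spacing_dv +
      runif(n, -1, 1) * config$jitter * spacing_dv
    bright <- 1 + rnorm(n, 0, config$nucleus_cv)
  })
  gap <- diff(c(dv, dv[1] + 2)) * geom$perimeter / 2
  if (min(gap) < 2 * rt)
    stop_dv("config_error",
            "cannot place %d nuclei of radius %.1f px without overlap (min gap %.1f px)",
            n, rt, min(gap))
  psi <- synth_psi_at_dv(geom, dv)
  # outline point, inward normal and tangent at each nucleus
  oc <- geom$c0 + geom$a * sin(psi)
  or <- geom$r0 - geom$b * cos(psi)
  nc <- (oc - geom$c0) / geom$a^2
  nr <- (or - geom$r0) / geom$b^2
  nn <- sqrt(nc^2 + nr^2)
  nc <- -nc / nn; nr <- -nr / nn          # inward
  tc <- geom$a * cos(psi); tr <- geom$b * sin(psi)
  tn <- sqrt(tc^2 + tr^2)
  tc <- tc / tn; tr <- tr / tn
  half <- geom$depth_px / 2
  data.frame(id = seq_len(n), dv = dv, psi = psi,
             row = or + half * nr, col = oc + half * nc,
             tan_r = tr, tan_c = tc, nrm_r = nr, nrm_c = nc,
             rt = rt, rr = rr, bright = bright)
}

gradient_value <- function(x, p) p$B + p$A * exp(-(x - p$mu)^2 / (2 * p$sigma^2))

# Render one noiseless frame.  `signal_values` gives the flat per-nucleus
# signal intensity (one column per signal channel).  Returns the nuclear
# matrix, a list of signal matrices, and per-nucleus pixel indices.
synth_render <- function(config, geom, layout, signal_values, params) {
  h <- geom$h; w <- geom$w
  bg <- config$background
  nuc <- matrix(bg, h, w)
  # embryo interior: weak nuclear-channel autofluorescence floor
  rows <- seq_len(h); cols <- seq_len(w)
  rr2 <- ((rows - geom$r0) / geom$b)^2
  cc2 <- ((cols - geom$c0) / geom$a)^2
  rho2 <- outer(rr2, cc2, "+")
  emb <- rho2 <= 1
  nuc[emb] <- bg + 0.15 * config$nuclear_level
  ai <- geom$a - geom$depth_px; bi <- geom$b - geom$depth_px
  rho2_in <- outer(((rows - geom$r0) / bi)^2, ((cols - geom$c0) / ai)^2, "+")
  ann <- emb & rho2_in >= 1
  n_sig <- ncol(signal_values)
  sig <- vector("list", n_sig)
  ann_idx <- which(ann)
  # cytoplasmic gradient value at annulus pixels, via the parameter angle
  pr <- ((ann_idx - 1L) %% h) + 1L
  pc <- ((ann_idx - 1L) %/% h) + 1L
  psi_p <- atan2((pc - geom$c0) / geom$a, -(pr - geom$r0) / geom$b)
  dv_p <- approx(geom$psi, geom$dv, xout = psi_p, rule = 2)$y
  cyto <- config$cyto_fraction * gradient_value(dv_p, params)
  for (ch in seq_len(n_sig)) {
    m <- matrix(bg, h, w)
    m[emb] <- bg
    m[ann_idx] <- cyto
    sig[[ch]] <- m
  }
  # nuclei
  pix <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    L <- layout[i, ]
    rad <- ceiling(L$rr) + 1L
    rs <- max(1L, floor(L$row - rad)):min(h, ceiling(L$row + rad))
    cs <- max(1L, floor(L$col - rad)):min(w, ceiling(L$col + rad))
    dr <- outer(rs - L$row, rep(1, length(cs)))
    dc <- outer(rep(1, length(rs)), cs - L$col)
    u <- dc * L$tan_c + dr * L$tan_r
    v <- dc * L$nrm_c + dr * L$nrm_r
    q <- (u / L$rt)^2 + (v / L$rr)^2
    inside <- q <= 1
    idx <- cbind(rep(rs, length(cs)), rep(cs, each = length(rs)))[inside, , drop = FALSE]
    lin <- idx[, 1] + (idx[, 2] - 1L) * h
    # flat-topped (super-Gaussian) profile: chromatin fills the nucleus and
    # falls off sharply at its rim
    nuc[lin] <- pmax(nuc[lin],
                     config$nuclear_level * L$bright * exp(-1.5 * q[inside]^4))
    for (ch in seq_len(n_sig)) sig[[ch]][lin] <- signal_values[i, ch]
    pix[[i]] <- lin
  }
  list(nuclear = nuc, signal = sig, pixels = pix)
}

synth_add_noise <- function(m, sd, seed) {
  if (sd <= 0) return(m)
  with_seed(seed, m + matrix(rnorm(length(m), 0, sd), nrow(m), ncol(m)))
}

# ---- public generator operations --------------------------------------------

#' Generate a single two-channel synthetic cross-section
#'
#' Renders the nuclear and signal channels of one frame, together with the
#' ground truth needed to verify downstream stages.
#'
#' @param config a [synthetic_config()].
#' @param frame_index which row of `config$gradient_trajectory` to render.
#' @return list with elements `nuclear` and `signal` (numeric matrices, au),
#'   and `ground_truth`: a list carrying the nucleus table (`id`, `row`,
#'   `col`, `dv`, `signal`, and pixel indices), the generating `params`
#'   (A, B, mu, sigma), and the outline geometry.
#' @export
generate_cross_section <- function(config, frame_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (frame_index < 1L || frame_index > nrow(config$gradient_trajectory))
    stop_dv("config_error", "frame_index outside the gradient trajectory")
  geom <- synth_geometry(config)
  layout <- synth_layout(config, geom)
  params <- config$gradient_trajectory[frame_index, ]
  g <- gradient_value(layout$dv, params)
  rend <- synth_render(config, geom, layout, cbind(g), params)
  seed0 <- config$rng_seed + 131L * frame_index
  list(nuclear = synth_add_noise(rend$nuclear, config$noise_sd, seed0 + 1L),
       signal = synth_add_noise(rend$signal[[1]], config$noise_sd, seed0 + 2L),
       ground_truth = list(
         nuclei = data.frame(id = layout$id, row = layout$row, col = layout$col,
                             dv = layout$dv, signal = g,
                             nuclear = config$nuclear_level * layout$bright),
         pixels = rend$pixels,
         params = params,
         geometry = list(center = c(geom$r0, geom$c0),
                         radii_px = c(geom$a, geom$b),
                         depth_px = geom$depth_px,
                         perimeter_px = geom$perimeter)))
}

#' Generate a single-z live time course
#'
#' One cross-section per row of the gradient trajectory; with the default
#' refinement trajectory the true width `sigma` decreases and the amplitude
#' `A` increases across frames.
#'
#' @param config a [synthetic_config()].
#' @param frames optional subset of frame indices to render.
#' @return an `embryo_series` list: `frames` (each with `nuclear`, `signal`),
#'   `time` (seconds), `pixel_size`, `kind = "live"` and `ground_truth`.
#' @export
generate_time_course <- function(config, frames = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  traj <- config$gradient_trajectory
  if (is.null(frames)) frames <- seq_len(nrow(traj))
  out <- lapply(frames, function(j) {
    cs <- generate_cross_section(config, j)
    list(nuclear = cs$nuclear, signal = cs$signal)
  })
  gt <- generate_cross_section(config, frames[1])$ground_truth
  gt$trajectory <- traj[frames, , drop = FALSE]
  structure(list(frames = out, frame_index = frames,
                 time = (frames - 1) * config$time_resolution,
                 pixel_size = config$pixel_size, kind = "live",
                 ground_truth = gt),
            class = "embryo_series")
}

#' Generate an MS2/MCP z-stack time course with planted transcription dots
#'
#' The signal channel is a z-stack of `config$n_z` slices per time point with
#' a uniform nuclear MCP level (no gradient).  In each frame, every nucleus
#' with folded DV coordinate `|x| <= dot_domain_halfwidth` carries, with
#' probability `dot_probability`, a single 3x3 bright dot in one z-slice at a
#' fixed offset from its centroid.
#'
#' @param config a [synthetic_config()].
#' @param n_frames number of time points (defaults to the trajectory length).
#' @return an `embryo_series` with `frames` (each `nuclear` matrix and
#'   `signal` array of dim (rows, cols, n_z)), and `ground_truth` including a
#'   `dots` table (frame, z, id, row, col) and `true_domain_halfwidth`.
#' @export
generate_ms2_stack <- function(config, n_frames = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(n_frames)) n_frames <- nrow(config$gradient_trajectory)
  geom <- synth_geometry(config)
  layout <- synth_layout(config, geom)
  params <- data.frame(A = 0, B = config$mcp_level, mu = 0, sigma = 0.15)
  base <- synth_render(config, geom, layout,
                       cbind(rep(config$mcp_level, nrow(layout))), params)
  nz <- config$n_z
  dots <- list()
  frames <- vector("list", n_frames)
  for (j in seq_len(n_frames)) {
    in_dom <- abs(layout$dv) <= config$dot_domain_halfwidth
    sel <- with_seed(config$rng_seed + 9973L + j, {
      carry <- in_dom & runif(nrow(layout)) < config$dot_probability
      zs <- sample.int(nz, nrow(layout), replace = TRUE)
      list(carry = carry, zs = zs)
    })
    nuc <- synth_add_noise(base$nuclear, config$noise_sd,
                           config$rng_seed + 677L * j)
    sig <- array(0, dim = c(geom$h, geom$w, nz))
    for (z in seq_len(nz)) {
      m <- synth_add_noise(base$signal[[1]], config$noise_sd,
                           config$rng_seed + 677L * j + 7L * z + 3L)
      # a dot is brightest in its own slice and, because the axial PSF spans
      # about one 2-um slice, bleeds at reduced contrast into the adjacent
      # slices
      for (i in which(sel$carry & abs(sel$zs - z) <= 1L)) {
        L <- layout[i, ]
        dr <- round(L$row + 0.3 * L$rr * L$nrm_r)
        dc <- round(L$col + 0.3 * L$rr * L$nrm_c)
        rs <- (dr - 1L):(dr + 1L); cs <- (dc - 1L):(dc + 1L)
        contrast <- config$dot_contrast * if (sel$zs[i] == z) 1 else 0.4
        m[rs, cs] <- m[rs, cs] + contrast
        if (sel$zs[i] == z)
          dots[[length(dots) + 1L]] <-
            data.frame(frame = j, z = z, id = L$id, row = dr, col = dc)
      }
      sig[, , z] <- m
    }
    frames[[j]] <- list(nuclear = nuc, signal = sig)
  }
  dots <- if (length(dots)) do.call(rbind, dots) else
    data.frame(frame = integer(), z = integer(), id = integer(),
               row = numeric(), col = numeric())
  structure(list(frames = frames, frame_index = seq_len(n_frames),
                 time = (seq_len(n_frames) - 1) * config$time_resolution,
                 pixel_size = config$pixel_size, kind = "ms2",
                 ground_truth = list(
                   nuclei = data.frame(id = layout$id, row = layout$row,
                                       col = layout$col, dv = layout$dv),
                   pixels = base$pixels, dots = dots,
                   true_domain_halfwidth = config$dot_domain_halfwidth,
                   geometry = list(center = c(geom$r0, geom$c0),
                                   radii_px = c(geom$a, geom$b),
                                   depth_px = geom$depth_px))),
            class = "embryo_series")
}

#' Generate a control embryo (nuclear marker only, no reporter gradient)
#'
#' The signal channel carries a spatially uniform background whose level
#' oscillates in time with the configured amplitude and period, emulating the
#' slow intensity fluctuations seen in no-reporter control time courses.
#'
#' @param config a [synthetic_config()].
#' @param n_frames number of frames.
#' @return an `embryo_series` (kind `"control"`); `ground_truth$background`
#'   holds the generating intensity-vs-time curve.
#' @export
generate_control_embryo <- function(config, n_frames = 40L) {
  stopifnot(inherits(config, "synthetic_config"))
  geom <- synth_geometry(config)
  layout <- synth_layout(config, geom)
  tt <- (seq_len(n_frames) - 1) * config$time_resolution
  level <- config$control_level *
    (1 + config$oscillation_amplitude * sin(2 * pi * tt / config$oscillation_period))
  params0 <- data.frame(A = 0, B = 1, mu = 0, sigma = 0.15)
  frames <- vector("list", n_frames)
  for (j in seq_len(n_frames)) {
    pj <- data.frame(A = 0, B = level[j], mu = 0, sigma = 0.15)
    rend <- synth_render(config, geom, layout,
                         cbind(rep(level[j], nrow(layout))), pj)
    frames[[j]] <- list(
      nuclear = synth_add_noise(rend$nuclear, config$noise_sd,
                                config$rng_seed + 311L * j),
      signal = synth_add_noise(rend$signal[[1]], config$noise_sd,
                               config$rng_seed + 311L * j + 5L))
  }
  structure(list(frames = frames, frame_index = seq_len(n_frames),
                 time = tt, pixel_size = config$pixel_size, kind = "control",
                 ground_truth = list(
                   nuclei = data.frame(id = layout$id, row = layout$row,
                                       col = layout$col, dv = layout$dv),
                   background = data.frame(time = tt, level = level))),
            class = "embryo_series")
}

#' Generate a fixed-embryo cross-section with two correlated signal channels
#'
#' Both signal channels are rendered from one shared Gaussian signaling field
#' (the per-nucleus gradient value), each multiplied by independent
#' nucleus-wise noise of coefficient of variation `channel_cv`.  This is the
#' shared-field model behind the two-antigen (pMad-like and Med-like)
#' fixed-embryo comparison.
#'
#' @param config a [synthetic_config()].
#' @param frame_index trajectory row used for the shared field.
#' @return list with `nuclear`, `signal1`, `signal2` matrices and
#'   `ground_truth` (shared field per nucleus and channel factors).
#' @export
generate_fixed_embryo <- function(config, frame_index = nrow(config$gradient_trajectory)) {
  stopifnot(inherits(config, "synthetic_config"))
  geom <- synth_geometry(config)
  layout <- synth_layout(config, geom)
  params <- config$gradient_trajectory[frame_index, ]
  g <- gradient_value(layout$dv, params)
  eps <- with_seed(config$rng_seed + 4241L,
                   matrix(rnorm(2 * nrow(layout), 0, config$channel_cv),
                          ncol = 2))
  vals <- cbind(g * (1 + eps[, 1]), g * (1 + eps[, 2]))
  rend <- synth_render(config, geom, layout, vals, params)
  s0 <- config$rng_seed + 8111L
  list(nuclear = synth_add_noise(rend$nuclear, config$noise_sd, s0 + 1L),
       signal1 = synth_add_noise(rend$signal[[1]], config$noise_sd, s0 + 2L),
       signal2 = synth_add_noise(rend$signal[[2]], config$noise_sd, s0 + 3L),
       ground_truth = list(
         nuclei = data.frame(id = layout$id, row = layout$row, col = layout$col,
                             dv = layout$dv, field = g,
                             ch1 = vals[, 1], ch2 = vals[, 2]),
         pixels = rend$pixels, params = params))
}
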