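# Reading and writing: TIFF series, tables with provenance hash, run config.

#' Write an embryo series as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pages are ordered T, C, Z (nuclear channel first, then signal slices);
#' intensities are scaled to the 16-bit range and the scale factor recorded
#' in the sidecar (`<path>.json`) together with dimensions, pixel size,
#' timestamps and a minimal OME-style description.
#'
#' @param series an `embryo_series`.
#' @param path output TIFF path.
#' @param ground_truth also write `<path>.ground_truth.json`.
#' @return `path`, invisibly.
#' @export
write_embryo_series <- function(series, path, ground_truth = TRUE) {
  f1 <- series$frames[[1]]
  nz <- if (length(dim(f1$signal)) == 3L) dim(f1$signal)[3] else 1L
  mx <- max(vapply(series$frames, function(fr)
    max(max(fr$nuclear), max(fr$signal)), numeric(1)))
  scale <- if (mx > 0) 65535 / mx else 1
  pages <- list()
  for (fr in series$frames) {
    pages[[length(pages) + 1L]] <- pmin(pmax(fr$nuclear, 0) * scale / 65535, 1)
    sig <- fr$signal
    if (nz == 1L) {
      pages[[length(pages) + 1L]] <- pmin(pmax(as_matrix_image(sig), 0) * scale / 65535, 1)
    } else for (z in seq_len(nz)) {
      pages[[length(pages) + 1L]] <- pmin(pmax(sig[, , z], 0) * scale / 65535, 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(n_frames = length(series$frames), n_channels = 2L, n_z = nz,
               dim = dim(f1$nuclear), time = series$time,
               frame_index = series$frame_index,
               pixel_size = series$pixel_size, kind = series$kind,
               intensity_scale = scale, page_order = "TCZ")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (ground_truth && !is.null(series$ground_truth)) {
    gt <- series$ground_truth
    gt$pixels <- NULL                    # per-nucleus pixel lists stay in R
    jsonlite::write_json(gt, paste0(path, ".ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(path)
}

#' Read an embryo series written by [write_embryo_series()]
#'
#' @param path TIFF path (the `.json` sidecar must sit beside it).
#' @return an `embryo_series`.
#' @export
read_embryo_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$n_channels) || meta$n_channels < 2L)
    stop_dv("channel_role_unassigned",
            "channel role unassigned: need a nuclear and a signal channel")
  pages <- tiff::readTIFF(path, all = TRUE)
  per_frame <- 1L + meta$n_z
  frames <- vector("list", meta$n_frames)
  k <- 0L
  for (j in seq_len(meta$n_frames)) {
    nuc <- pages[[k + 1L]] * 65535 / meta$intensity_scale
    if (meta$n_z == 1L) {
      sig <- pages[[k + 2L]] * 65535 / meta$intensity_scale
    } else {
      sig <- array(0, dim = c(dim(nuc), meta$n_z))
      for (z in seq_len(meta$n_z))
        sig[, , z] <- pages[[k + 1L + z]] * 65535 / meta$intensity_scale
    }
    frames[[j]] <- list(nuclear = nuc, signal = sig)
    k <- k + per_frame
  }
  structure(list(frames = frames,
                 frame_index = if (!is.null(meta$frame_index)) meta$frame_index
                               else seq_len(meta$n_frames),
                 time = meta$time, pixel_size = meta$pixel_size,
                 kind = meta$kind, ground_truth = NULL),
            class = "embryo_series")
}

#' Write a labeled mask as 16-bit TIFF
#' @param mask integer label matrix.
#' @param path output path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

# CSV tables carry the run's config hash on a leading comment line.
write_table_hashed <- function(df, path, config_hash = "unhashed") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", config_hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV table (skipping the provenance comment line)
#' @param path CSV path written by the pipeline.
#' @return data frame; the config hash is attached as attribute
#'   `"config_hash"`.
#' @export
read_pipeline_table <- function(path) {
  first <- readLines(path, n = 1L)
  df <- read.csv(path, comment.char = "#")
  attr(df, "config_hash") <- sub("^# config_hash=", "", first)
  df
}

#' Build and validate a pipeline run configuration
#'
#' @param run_kind one of `"synth"`, `"fixed_correlation"`, `"live_gradient"`,
#'   `"average_gradients"`, `"ms2_domain"`.
#' @param input input TIFF path(s) (ignored for `"synth"`).
#' @param output_dir output directory.
#' @param pixel_size microns per pixel (overridden by series metadata when
#'   reading).
#' @param rng_seed seed for synthetic generation.
#' @param synthetic named list of [synthetic_config()] overrides.
#' @param synth_kind for `"synth"` runs: `"time_course"`, `"ms2"`,
#'   `"control"` or `"fixed"`.
#' @param calib_mean,calib_lp,nuc_lp normalization inputs.
#' @param gastrulation_time numeric vector, one per embryo, used to align
#'   frames (time before gastrulation) for `"average_gradients"` runs.
#' @param theta,gamma spot-calling and boundary parameters.
#' @param midline dorsal midline arc fraction.
#' @param min_size nucleus size floor, strip pixels.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(run_kind, input = NULL, output_dir = "dvquant_out",
                       pixel_size = 0.4, rng_seed = 1L, synthetic = list(),
                       synth_kind = "time_course", calib_mean = 1.74e4,
                       calib_lp = 0.1, nuc_lp = 0.1,
                       gastrulation_time = NULL, theta = 0.98,
                       gamma = 1 - theta, midline = 0, min_size = 400L) {
  kinds <- c("synth", "fixed_correlation", "live_gradient",
             "average_gradients", "ms2_domain")
  if (!run_kind %in% kinds)
    stop_dv("config_error", "run_kind must be one of: %s",
            paste(kinds, collapse = ", "))
  cfg <- list(run_kind = run_kind, input = input, output_dir = output_dir,
              pixel_size = pixel_size, rng_seed = as.integer(rng_seed),
              synthetic = synthetic, synth_kind = synth_kind,
              calib_mean = calib_mean, calib_lp = calib_lp, nuc_lp = nuc_lp,
              gastrulation_time = gastrulation_time, theta = theta,
              gamma = gamma, midline = midline, min_size = as.integer(min_size))
  if (run_kind != "synth") {
    if (is.null(cfg$input))
      stop_dv("config_error", "field 'input' is required for run_kind '%s'",
              run_kind)
    missing <- cfg$input[!file.exists(cfg$input)]
    if (length(missing))
      stop_dv("config_error", "input path does not exist: %s", missing[1])
  }
  if (run_kind == "average_gradients" && is.null(cfg$gastrulation_time))
    stop_dv("config_error",
            "field 'gastrulation_time' (one per embryo) is required for average_gradients")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML or JSON file
#' @param path config file path.
#' @return validated `run_config`.
#' @export
load_run_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(run_config, lst)
}

config_hash <- function(config) digest::digest(unclass(config), algo = "sha256")

#' Run a complete pipeline
#'
#' Executes the configured run kind end to end and writes stage outputs
#' (CSV tables, JSON summaries, TIFF masks for QC) plus a machine-readable
#' `manifest.json` carrying the package version, seed and config hash.
#' Identical config and seed give identical tables.  Failures leave partial
#' outputs beside a `FAILED` marker naming the stage.
#'
#' @param config a [run_config()].
#' @return list of in-memory results, invisibly; outputs land in
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage <- "setup"
  result <- tryCatch({
    res <- switch(config$run_kind,
      synth = {
        stage <- "synth"
        sc <- do.call(synthetic_config,
                      c(config$synthetic, list(rng_seed = config$rng_seed)))
        series <- switch(config$synth_kind,
          time_course = generate_time_course(sc),
          ms2 = generate_ms2_stack(sc),
          control = generate_control_embryo(sc),
          fixed = stop_dv("config_error",
                          "fixed synthetic output is per-embryo; use generate_fixed_embryo()"),
          stop_dv("config_error", "unknown synth_kind '%s'", config$synth_kind))
        write_embryo_series(series, file.path(config$output_dir, "series.tif"))
        list(series = series)
      },
      live_gradient = {
        stage <- "live_gradient"
        series <- read_embryo_series(config$input[1])
        out <- analyze_live_series(series,
                                   calib_norm = session_factor(config$calib_mean,
                                                               config$calib_lp),
                                   nuc_lp = config$nuc_lp,
                                   min_size = config$min_size,
                                   midline = config$midline)
        write_table_hashed(out$fits,
                           file.path(config$output_dir, "gradient_fits.csv"), hash)
        write_table_hashed(out$records,
                           file.path(config$output_dir, "nuclei.csv"), hash)
        out
      },
      ms2_domain = {
        stage <- "ms2_domain"
        series <- read_embryo_series(config$input[1])
        out <- analyze_ms2_series(series, theta = config$theta,
                                  gamma = config$gamma,
                                  midline = config$midline,
                                  min_size = config$min_size)
        write_table_hashed(out$calls,
                           file.path(config$output_dir, "spot_calls.csv"), hash)
        write_table_hashed(out$boundaries,
                           file.path(config$output_dir, "boundaries.csv"), hash)
        jsonlite::write_json(list(mean_width = out$mean_width,
                                  sd_width = out$sd_width),
                             file.path(config$output_dir, "width_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        out
      },
      fixed_correlation = {
        stage <- "fixed_correlation"
        embryos <- lapply(config$input, function(p) {
          s <- read_embryo_series(p)
          fr <- s$frames[[1]]
          if (length(dim(fr$signal)) != 3L || dim(fr$signal)[3] < 2L)
            stop_dv("channel_role_unassigned",
                    "channel role unassigned: fixed run needs two signal channels")
          list(nuclear = fr$nuclear, signal1 = fr$signal[, , 1],
               signal2 = fr$signal[, , 2])
        })
        out <- analyze_fixed_embryos(embryos, pixel_size = config$pixel_size,
                                     min_size = config$min_size)
        jsonlite::write_json(list(rho = out$rho, mean = out$mean, sd = out$sd),
                             file.path(config$output_dir, "correlation.json"),
                             auto_unbox = TRUE, digits = NA)
        out
      },
      average_gradients = {
        stage <- "average_gradients"
        fits_list <- lapply(config$input, function(p) {
          series <- read_embryo_series(p)
          out <- analyze_live_series(series, min_size = config$min_size,
                                     midline = config$midline)
          list(fits = out$fits,
               nuclei = data.frame(frame = out$records$frame,
                                   dv = out$records$dv,
                                   intensity = out$records$mean_signal))
        })
        avg <- average_embryos(fits_list)
        tab <- data.frame(frame = rep(avg$frames, each = length(avg$mesh$x)),
                          mesh_x = rep(avg$mesh$x, length(avg$frames)),
                          mean = as.vector(t(avg$mean)),
                          sem = as.vector(t(avg$sem)),
                          interpolated = as.vector(t(avg$interpolated)))
        write_table_hashed(tab,
                           file.path(config$output_dir, "averaged_gradient.csv"),
                           hash)
        list(averaged = avg)
      })
    res
  }, dvquant_error = function(e) {
    writeLines(sprintf("stage=%s: %s", stage, conditionMessage(e)),
               file.path(config$output_dir, "FAILED"))
    stop(e)
  })
  manifest <- list(package = "dvquant",
                   version = as.character(utils::packageVersion("dvquant")),
                   r_version = R.version.string,
                   run_kind = config$run_kind, rng_seed = config$rng_seed,
                   config_hash = hash)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}
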