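# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Centered moving average with partial (shrunken) windows at the edges.
moving_average <- function(x, window) {
  if (window <= 1L || length(x) < 2L) return(x)
  zoo::rollapply(x, width = window, FUN = mean, partial = TRUE, align = "center")
}

# Otsu threshold of a numeric vector (histogram search on 256 levels).
# Returns NA for degenerate (zero-variance) input.
otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (!is.finite(diff(r)) || diff(r) <= 0) return(NA_real_)
  img <- EBImage::Image((v - r[1]) / diff(r), dim = c(length(v), 1L))
  th <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  th * diff(r) + r[1]
}

# Bilinear interpolation of matrix `m` at (row, col) positions, clamped
# to the image border.
bilinear_sample <- function(m, row, col) {
  h <- nrow(m); w <- ncol(m)
  row <- pmin(pmax(row, 1), h)
  col <- pmin(pmax(col, 1), w)
  r0 <- pmin(floor(row), h - 1L); c0 <- pmin(floor(col), w - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- m[cbind(r0, c0)]
  i10 <- m[cbind(r0 + 1L, c0)]
  i01 <- m[cbind(r0, c0 + 1L)]
  i11 <- m[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

as_matrix_image <- function(x) {
  if (is.matrix(x)) x else {
    d <- dim(x)
    matrix(as.numeric(x), d[1], d[2])
  }
}

stop_dv <- function(code, msg, ...) {
  stop(structure(class = c(code, "dvquant_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
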