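test_that("the dot score reproduces the hand-enumerated 7x7 nucleus", {
  # 7x7 nucleus: signal 10 everywhere except a 110 pixel at the center,
  # nuclear channel 50.  The 5x5 removal around the max leaves 24 pixels of
  # value 10, so S = (110 - 10) / 50 = 2.
  lbl <- matrix(0L, 11, 11); lbl[3:9, 3:9] <- 1L
  sig <- matrix(10, 11, 11); sig[6, 6] <- 110
  rec <- extract_nuclei(lbl, matrix(50, 11, 11), sig)
  expect_equal(rec$max_signal, 110)
  expect_equal(rec$mean_signal_excl, 10)
  expect_equal(score_nuclei(rec)$S, 2)
  # nuclei too small for the removal are refused
  tiny <- matrix(0L, 7, 7); tiny[2:6, 2:6] <- 1L
  rtiny <- extract_nuclei(tiny, matrix(50, 7, 7), matrix(10, 7, 7))
  expect_error(score_nuclei(rtiny), class = "nucleus_too_small")
})

test_that("S grows monotonically with planted dot contrast", {
  lbl <- matrix(0L, 15, 15); lbl[3:13, 3:13] <- 1L
  s_of <- vapply(c(1, 3, 6, 12), function(ct) {
    sig <- matrix(10, 15, 15); sig[8, 8] <- 10 + ct
    score_nuclei(extract_nuclei(lbl, matrix(50, 15, 15), sig))$S
  }, numeric(1))
  expect_true(all(diff(s_of) > 0))
})

test_that("percentile dot calling cuts exactly at the theta quantile", {
  rec <- data.frame(frame = 1L, S = sample(1:100))
  out <- suppressWarnings(call_dots(rec))
  expect_equal(sum(out$is_dot), 2L)          # top 2 of 100 distinct scores
  expect_setequal(rec$S[out$is_dot], c(99, 100))
  expect_equal(unique(out$threshold_value),
               unname(quantile(rec$S, 0.98)))
  # identical scores: threshold equals the common value, everything called
  same <- data.frame(frame = 1L, S = rep(0.4, 60))
  os <- call_dots(same)
  expect_true(all(os$is_dot))
  expect_equal(attr(os, "degenerate_frames"), 1L)
  # thresholds are per time point
  two <- data.frame(frame = rep(1:2, each = 100), S = c(1:100, 1001:1100))
  ot <- suppressWarnings(call_dots(two))
  expect_equal(length(unique(ot$threshold_value)), 2L)
  expect_equal(sum(ot$is_dot), 4L)
  expect_warning(call_dots(data.frame(frame = 1L, S = runif(10))),
                 "unstable")
})

test_that("the boundary score matches exhaustive hand enumeration", {
  h <- toy_half_calls()
  expect_equal(boundary_score(h$dv, h$is_dot, 0.15), 3.00)
  expect_equal(boundary_score(h$dv, h$is_dot, 0.50), 3 - 0.02 * 7)
  # no dots: score is -gamma * (count dorsal), never positive
  expect_equal(boundary_score(h$dv, rep(FALSE, 10), c(0.15, 0.5)),
               c(-0.02 * 3, -0.02 * 10))
  # all dots: score equals the dorsal count, maximal at 1
  all_s <- boundary_score(h$dv, rep(TRUE, 10), h$dv)
  expect_equal(all_s, 1:10)
  # adding one dot dorsal of x0 adds exactly 1; a non-dot subtracts gamma
  base <- boundary_score(h$dv, h$is_dot, 0.3)
  expect_equal(boundary_score(c(h$dv, 0.12), c(h$is_dot, TRUE), 0.3), base + 1)
  expect_equal(boundary_score(c(h$dv, 0.12), c(h$is_dot, FALSE), 0.3),
               base - 0.02)
})

test_that("boundary detection takes the argmax, averaged over halves", {
  h <- toy_half_calls()
  calls <- rbind(h, within(h, { dv <- -dv; label <- label + 10L }))
  b <- find_boundary(calls)
  expect_equal(b$left_boundary, 0.15)
  expect_equal(b$right_boundary, 0.15)
  expect_equal(b$width, 0.15)
  expect_length(b$empty_halves, 0L)
  # width is always the mean of the two halves
  h2 <- within(h, dv <- -dv)
  h2$is_dot <- rep(c(TRUE, FALSE), c(5, 5))
  b2 <- find_boundary(rbind(h, within(h2, label <- label + 10L)))
  expect_equal(b2$width, (0.15 + 0.25) / 2)
  # a half without any dot contributes boundary 0 and is flagged
  none <- within(h, is_dot <- FALSE)
  b3 <- find_boundary(rbind(h, within(none, { dv <- -dv; label <- label + 10L })))
  expect_equal(b3$left_boundary, 0)
  expect_equal(b3$empty_halves, "left")
  expect_error(find_boundary(h), class = "empty_half")  # one-sided input
})

test_that("gamma limits select the most ventral dot or the dorsal run", {
  h <- data.frame(label = 1:10, dv = seq(0.05, 0.50, by = 0.05),
                  is_dot = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                             FALSE, TRUE, FALSE))
  calls <- rbind(h, within(h, { dv <- -dv; label <- label + 10L }))
  expect_equal(find_boundary(calls, gamma = 0)$width, 0.45)
  expect_equal(find_boundary(calls, gamma = 0.999)$width, 0.15)
})

test_that("z-slices collapse to one dot decision per nucleus", {
  # nucleus 2 is called in one slice only; it must count as dot-positive
  calls <- data.frame(label = rep(1:3, each = 2), z = rep(1:2, 3),
                      dv = rep(c(0.1, 0.2, 0.3), each = 2),
                      is_dot = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  left <- data.frame(label = 4L, z = 1L, dv = -0.1, is_dot = TRUE)
  b <- find_boundary(rbind(calls, left))
  expect_equal(b$right_boundary, 0.2)
})

test_that("the reported width is insensitive to the assumed midline", {
  # symmetric synthetic embryo as a call table: nuclei every 0.02 around the
  # circumference, dots wherever |dv| <= 0.27
  pos <- seq(-0.99, 0.99, by = 0.02)
  spacing <- 0.02
  widths <- vapply(-3:3, function(k) {
    dv <- pos - k * spacing
    dv <- dv - 2 * round(dv / 2)
    calls <- data.frame(label = seq_along(pos), dv = dv,
                        is_dot = abs(pos) <= 0.27)
    find_boundary(calls)$width
  }, numeric(1))
  expect_lt(max(widths) - min(widths), spacing)
})

test_that("width summaries aggregate time points and embryos", {
  calls <- function(f, w) {
    pos <- seq(0.025, 0.975, by = 0.05)
    h <- data.frame(frame = f, label = seq_along(pos), dv = pos,
                    is_dot = pos <= w)
    rbind(h, within(h, { dv <- -dv; label <- label + 100L }))
  }
  wt <- width_time_course(rbind(calls(1, 0.21), calls(2, 0.31)))
  expect_equal(wt$boundaries$width, c(0.175, 0.275))
  expect_equal(wt$mean_width, 0.225)
  expect_equal(wt$sd_width, sd(c(0.175, 0.275)))
  flat <- width_time_course(rbind(calls(1, 0.21), calls(2, 0.21)))
  expect_equal(flat$sd_width, 0)
  ens <- ensemble_widths(list(wt, flat))
  expect_equal(ens$per_embryo$mean_width, c(0.225, 0.175))
  expect_equal(ens$mean, mean(c(0.225, 0.175)))
})

test_that("planted dots are recovered through the full MS2 chain", {
  cfg <- small_config(n_z = 4L, dot_probability = 1, rng_seed = 11L)
  ser <- generate_ms2_stack(cfg, n_frames = 3L)
  out <- analyze_ms2_series(ser, min_size = SMALL_MIN_SIZE)
  gt <- ser$ground_truth
  in_domain <- gt$nuclei[abs(gt$nuclei$dv) <= 0.27, ]
  called_any <- unique(out$calls$label[out$calls$is_dot])
  rec1 <- out$calls[!duplicated(out$calls$label), ]
  called <- rec1[rec1$label %in% called_any, ]
  m <- match_ground_truth(called, in_domain)
  # every called nucleus is a genuinely planted (in-domain) one...
  expect_gte(mean(m$matched), 0.9)
  # ...and, although the fixed percentile budget caps per-frame recall when
  # every in-domain nucleus carries a dot, the time course accumulates a
  # substantial share of the planted nuclei
  expect_gte(length(unique(m$gt_index[m$matched])) / nrow(in_domain), 0.4)
})
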