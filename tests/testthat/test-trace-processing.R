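test_that("dF/F0 maps constant traces to zero and is gain-invariant", {
  x <- 3 + kernel_train(c(10, 40, 70), peak = 1, frame_interval = 0.5,
                        duration = 100)
  ts <- trace_set(rbind(rep(5, 200), x, 3 * x), frame_interval = 0.5)
  norm <- normalize_dff(ts)
  expect_equal(norm$values[1, ], rep(0, 200), ignore_attr = TRUE)
  expect_equal(norm$values[2, ], norm$values[3, ], ignore_attr = TRUE)
  # additive offsets change dF/F0 (ratio normalization is not shift-proof)
  ts2 <- trace_set(rbind(x, x + 2), frame_interval = 0.5)
  n2 <- normalize_dff(ts2)
  expect_gt(max(abs(n2$values[1, ] - n2$values[2, ])), 0.01)
})

test_that("dF/F0 matches a brute-force window mean on a square pulse", {
  dt <- 1
  c0 <- 2
  x <- rep(c0, 120)
  x[50:54] <- 2 * c0  # 5 s pulse, much shorter than the 30 s window
  ts <- trace_set(matrix(x, 1), frame_interval = dt)
  norm <- normalize_dff(ts, window_half_width = 30)
  i <- 52  # mid-pulse frame
  f0 <- mean(x[(i - 30):(i + 30)])  # brute-force centered window mean
  expect_equal(unname(norm$values[1, i]), (2 * c0 - f0) / f0,
               tolerance = 1e-12)
  # edge truncation: first frame uses only the forward half-window
  f0_edge <- mean(x[1:31])
  expect_equal(unname(norm$values[1, 1]), (c0 - f0_edge) / f0_edge,
               tolerance = 1e-12)
})

test_that("cells with non-positive baseline are flagged and excluded", {
  ts <- trace_set(rbind(c(rep(1, 50), rep(-2, 50)), runif(100) + 1),
                  frame_interval = 1)
  expect_warning(norm <- normalize_dff(ts), "flagged")
  expect_true(norm$flagged[1])
  expect_false(norm$flagged[2])
  expect_true(all(is.na(norm$values[1, ])))
})

test_that("event detection finds each transient once at 50% amplitude", {
  dt <- 0.5
  times <- seq(5, 185, by = 20)  # 10 well-separated transients
  x <- kernel_train(times, peak = 0.5, frame_interval = dt, duration = 200)
  ev <- detect_events(norm_set(matrix(x, 1), dt))
  expect_length(ev$times[[1]], 10L)
  peak_offset <- 0.3 * 2 / (2 - 0.3) * log(2 / 0.3)  # kernel peak delay
  expect_true(all(abs(ev$times[[1]] - (times + peak_offset)) <= 2 * dt))
  expect_true(ev$active[1])
  # the same train at 10% peak stays below the 20% threshold
  ev_low <- detect_events(norm_set(matrix(0.2 * x, 1), dt))
  expect_length(ev_low$times[[1]], 0L)
  expect_false(ev_low$active[1])
  # a flat trace has no events
  ev0 <- detect_events(norm_set(matrix(0, 1, 100), dt))
  expect_length(ev0$times[[1]], 0L)
})

test_that("event counts never increase with the threshold", {
  set.seed(42)
  dt <- 0.5
  x <- kernel_train(sort(runif(12, 0, 190)), peak = 0.6,
                    frame_interval = dt, duration = 200) +
    rnorm(400, 0, 0.03)
  ns <- norm_set(matrix(x, 1), dt)
  counts <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.8),
                   function(th) length(detect_events(ns,
                     threshold_frac = th)$times[[1]]), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("nearby maxima are merged keeping the larger peak", {
  dt <- 0.5
  x <- numeric(100)
  x[30] <- 0.4; x[32] <- 0.6  # two maxima 1 s apart
  ev <- detect_events(norm_set(matrix(x, 1), dt), min_separation = 2)
  expect_equal(ev$times[[1]], 31 * dt)
})

test_that("the pipeline recovers truth event counts exactly at zero noise", {
  # star coupling from one pacemaker: all events >> min_separation apart
  adj <- matrix(0L, 6, 6)
  adj[1, 2:6] <- 1L; adj[2:6, 1] <- 1L
  dyn <- dynamics_spec(pacemaker_rate = 40, rate_jitter_cv = 0.1,
                       transmission_prob = 0.7, noise_sd = 0,
                       drift_amplitude = 0, duration = 280)
  rec <- simulate_recording(adj, dyn, seed = 31, pacemakers = 1L)
  ev <- detect_events(normalize_dff(rec$traces))
  expect_identical(unname(lengths(ev$times)), lengths(rec$truth_events))
})

test_that("rectify_smooth conditions signals as specified", {
  dt <- 0.01
  expect_equal(rectify_smooth(rep(0, 500), dt), rep(0, 500))
  out <- rectify_smooth(rep(2, 500), dt)  # DC passes the low-pass
  expect_equal(out, rep(2, 500), tolerance = 1e-6)
  # a 5 Hz unit sine through the high-pass variant: mean |sin| = 2/pi
  tt <- seq(0, 20 - dt, by = dt)
  s <- sin(2 * pi * 5 * tt)
  out <- rectify_smooth(s, dt, mode = "high")
  expect_equal(mean(out), 2 / pi, tolerance = 0.05 * 2 / pi)
  expect_error(rectify_smooth(s, frame_interval = 1, smooth_window = 0.5),
               "smooth_window")
  expect_error(rectify_smooth(s, dt, cutoff = 100), "Nyquist")
})

test_that("ROI extraction recovers rendered cells and their traces", {
  skip_if_not_installed("EBImage")
  set.seed(8)
  n <- 5
  pos <- cbind(c(10, 10, 30, 30, 20), c(10, 34, 10, 34, 22))
  vals <- t(vapply(seq_len(n), function(i)
    1 + kernel_train(sort(runif(6, 0, 110)), peak = 2,
                     frame_interval = 1, duration = 120),
    numeric(120)))
  ts <- trace_set(vals, frame_interval = 1)
  st <- render_stack(ts, positions = pos, radii = 3, dim = c(44, 44))
  got <- extract_rois_and_traces(st, frame_interval = 1, min_area = 4)
  expect_equal(nrow(got$values), n)
  # match each recovered ROI to its nearest truth cell
  for (j in seq_len(n)) {
    d <- sqrt((pos[, 1] - got$roi_centroids[j, 1])^2 +
                (pos[, 2] - got$roi_centroids[j, 2])^2)
    i <- which.min(d)
    expect_lt(d[i], 2)
    expect_gt(cor(got$values[j, ], vals[i, ]), 0.99)
  }
  # a constant stack has zero SD everywhere: no ROIs
  expect_warning(empty <- extract_rois_and_traces(array(1, c(16, 16, 4)),
                                                  frame_interval = 1),
                 "no ROI")
  expect_equal(nrow(empty$values), 0)
})

test_that("label-image ROI import reproduces mean traces", {
  st <- array(0, c(8, 8, 4))
  st[2:3, 2:3, ] <- rep(1:4, each = 4)
  labels <- matrix(0L, 8, 8)
  labels[2:3, 2:3] <- 1L
  ts <- rois_from_labels(st, labels, frame_interval = 0.5)
  expect_equal(unname(ts$values[1, ]), as.numeric(1:4))
})

test_that("trace CSV round-trips", {
  ts <- trace_set(matrix(rnorm(30), 3), frame_interval = 0.5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(ts, p)
  back <- read_traces_csv(p)
  expect_equal(back$values, ts$values, tolerance = 1e-12)
  expect_equal(back$frame_interval, 0.5)
})
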