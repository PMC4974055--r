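dyn0 <- function(...) {
  dynamics_spec(noise_sd = 0, drift_amplitude = 0, ...)
}

test_that("a jitter-free 50 mHz pacemaker fires exactly 3 times in 60 s", {
  # first event at a random phase within one 20 s period, so the count
  # over 60 s is exactly 3 for every phase
  ad <- matrix(0, 2, 2)
  for (s in 1:10) {
    rec <- simulate_recording(ad, dyn0(pacemaker_fraction = 0.5,
                                       pacemaker_rate = 50,
                                       rate_jitter_cv = 0, duration = 60),
                              seed = s)
    expect_equal(sum(rec$pacemaker_mask), 1L)
    ev <- rec$truth_events[[which(rec$pacemaker_mask)]]
    expect_length(ev, 3L)
    expect_true(all(diff(ev) == 20))
  }
})

test_that("all truth events lie inside the recording", {
  net <- generate_network(40, "small_world", k = 4, seed = 2)
  rec <- simulate_recording(net, dynamics_spec(duration = 120), seed = 2)
  ev <- unlist(rec$truth_events)
  expect_true(all(ev >= 0 & ev < 120))
  expect_true(all(vapply(rec$truth_events,
                         function(x) !is.unsorted(x, strictly = TRUE),
                         logical(1))))
})

test_that("identical specs and seed give a bit-identical recording", {
  net <- generate_network(30, "small_world", k = 4, seed = 4)
  a <- simulate_recording(net, dynamics_spec(duration = 100), seed = 11)
  b <- simulate_recording(net, dynamics_spec(duration = 100), seed = 11)
  expect_identical(a$traces$values, b$traces$values)
  expect_identical(a$truth_events, b$truth_events)
  c <- simulate_recording(net, dynamics_spec(duration = 100), seed = 12)
  expect_false(identical(a$traces$values, c$traces$values))
})

test_that("decoupling from onset 0 silences all non-pacemaker cells", {
  net <- generate_network(30, "small_world", k = 4, seed = 6)
  rec <- simulate_recording(net, dyn0(),
                            perturbation("decouple_all", onset = 0),
                            seed = 6)
  followers <- which(!rec$pacemaker_mask)
  expect_true(all(lengths(rec$truth_events[followers]) == 0L))
  expect_true(all(lengths(rec$truth_events[which(rec$pacemaker_mask)]) > 0L))
})

test_that("doubling the pacemaker rate halves inter-event intervals", {
  ad <- matrix(0, 2, 2)
  dyn <- dyn0(pacemaker_fraction = 0.5, pacemaker_rate = 50,
              rate_jitter_cv = 0.2, duration = 600)
  base <- simulate_recording(ad, dyn, seed = 3)
  fast <- simulate_recording(ad, dyn,
                             perturbation("scale_rate", 2, onset = 0),
                             seed = 3)
  i <- which(base$pacemaker_mask)
  r <- mean(diff(base$truth_events[[i]])) /
    mean(diff(fast$truth_events[[i]]))
  expect_gt(r, 1.8)
  expect_lt(r, 2.2)
})

test_that("deleting edges keeps pacemaker trains untouched", {
  net <- generate_network(40, "small_world", k = 6, seed = 9)
  dyn <- dynamics_spec(duration = 150)
  base <- simulate_recording(net, dyn, seed = 9)
  del <- simulate_recording(net, dyn,
                            perturbation("delete_edge_fraction", 0.8,
                                         onset = 0), seed = 9)
  pm <- which(base$pacemaker_mask)
  expect_identical(base$truth_events[pm], del$truth_events[pm])
  expect_lt(sum(lengths(del$truth_events)), sum(lengths(base$truth_events)))
})

test_that("follower event counts grow with transmission probability", {
  net <- generate_network(30, "small_world", k = 4, seed = 5)
  mean_follower_events <- function(p) {
    counts <- vapply(1:6, function(s) {
      rec <- simulate_recording(net, dyn0(transmission_prob = p,
                                          duration = 200), seed = s)
      mean(lengths(rec$truth_events[!rec$pacemaker_mask]))
    }, numeric(1))
    mean(counts)
  }
  m <- vapply(c(0.2, 0.5, 0.9), mean_follower_events, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("tonic Poisson events appear only after onset", {
  ad <- matrix(0, 3, 3)
  rec <- simulate_recording(ad, dyn0(pacemaker_fraction = 0),
                            perturbation("add_tonic_rate", 200,
                                         onset = 100), seed = 7)
  ev <- unlist(rec$truth_events)
  expect_gt(length(ev), 0)
  expect_true(all(ev >= 100))
})

test_that("explicit pacemaker indices override the random draw", {
  net <- generate_network(10, "empty")
  rec <- simulate_recording(net, dyn0(), seed = 1, pacemakers = c(2L, 7L))
  expect_identical(which(rec$pacemaker_mask), c(2L, 7L))
})

test_that("rendered stacks reflect the traces", {
  ts <- trace_set(matrix(2, 1, 5), frame_interval = 0.5)
  st <- render_stack(ts, positions = cbind(10, 10), radii = 3,
                     dim = c(24, 24))
  for (f in 2:5) expect_identical(st[, , f], st[, , 1])  # constant trace

  st0 <- render_stack(trace_set(matrix(0, 0, 5), 0.5,
                                roi_ids = character(0)),
                      positions = matrix(0, 0, 2), dim = c(8, 8),
                      background = 0.3)
  expect_true(all(st0 == 0.3))  # no cells: pure background

  # footprint-mean intensity tracks the input trace
  x <- 1 + kernel_train(c(2, 10, 18), peak = 1, frame_interval = 0.5,
                        duration = 25)
  ts <- trace_set(matrix(x, 1), frame_interval = 0.5)
  st <- render_stack(ts, positions = cbind(12, 12), radii = 4,
                     dim = c(25, 25))
  inside <- (row(st[, , 1]) - 13)^2 + (col(st[, , 1]) - 13)^2 <= 16
  tr <- apply(st, 3, function(fr) mean(fr[inside]))
  expect_gt(cor(tr, x), 0.99)

  expect_error(render_stack(ts, positions = cbind(40, 5), dim = c(25, 25)),
               "bounds")
  ts2 <- trace_set(matrix(1, 2, 5), frame_interval = 0.5)
  expect_warning(render_stack(ts2, positions = rbind(c(5, 5), c(5, 5)),
                              dim = c(16, 16)), "overlapping")
})
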