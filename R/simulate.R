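#' Dynamics parameters for the recording simulator
#'
#' Defaults emulate the rhythmic calcium activity of cultured respiratory
#' networks: roughly a third of cells are autonomously rhythmic pacemakers
#' firing in the tens-of-mHz range, activity spreads to coupled neighbours
#' with high probability and sub-second delay, and transients follow
#' stereotyped sub-second-rise / seconds-decay kinetics on a slowly
#' drifting, mildly noisy baseline.
#'
#' @param pacemaker_fraction fraction of cells that fire autonomously;
#'   default 0.31 (about a third of cells keep rhythmic calcium activity
#'   when synaptic transmission is blocked)
#' @param pacemaker_rate mean autonomous event rate, mHz (default 50)
#' @param rate_jitter_cv coefficient of variation of pacemaker inter-event
#'   intervals (0 = perfectly periodic)
#' @param transmission_prob probability that a pacemaker event elicits an
#'   event in each coupled neighbour
#' @param transmission_delay mean conduction delay, s
#' @param delay_jitter SD of the conduction delay, s
#' @param kernel_rise,kernel_decay transient kinetics, s (see [ca_kernel()])
#' @param amplitude transient peak amplitude, intensity units
#' @param baseline resting fluorescence intensity
#' @param noise_sd SD of additive Gaussian imaging noise, intensity units
#' @param drift_amplitude amplitude of a slow sinusoidal baseline drift
#'   (period = recording duration, random phase per cell), intensity units
#' @param frame_interval imaging frame interval, s (0.1-2 s regime)
#' @param duration recording length, s
#' @return list of class `dynamics_spec`
#' @export
dynamics_spec <- function(pacemaker_fraction = 0.31,
                          pacemaker_rate = 50,
                          rate_jitter_cv = 0.2,
                          transmission_prob = 0.8,
                          transmission_delay = 0.2,
                          delay_jitter = 0.05,
                          kernel_rise = 0.3,
                          kernel_decay = 2,
                          amplitude = 0.5,
                          baseline = 1,
                          noise_sd = 0.02,
                          drift_amplitude = 0.05,
                          frame_interval = 0.5,
                          duration = 300) {
  d <- as.list(environment())
  with(d, {
    stopifnot(pacemaker_fraction >= 0, pacemaker_fraction <= 1,
              pacemaker_rate >= 0, rate_jitter_cv >= 0,
              transmission_prob >= 0, transmission_prob <= 1,
              transmission_delay >= 0, delay_jitter >= 0,
              kernel_rise > 0, kernel_decay > kernel_rise,
              baseline > 0, noise_sd >= 0, frame_interval > 0,
              duration > 0)
  })
  if (d$duration / d$frame_interval < 2)
    stop("duration must cover at least 2 frames")
  structure(d, class = "dynamics_spec")
}

#' Perturbation scenario for the simulator
#'
#' Emulates the pharmacological manipulations used on cultured respiratory
#' networks: `decouple_all` removes all event transmission from `onset`
#' onward (synaptic block, TTX-like); `delete_edge_fraction` permanently
#' removes a random fraction `magnitude` of coupling edges from `onset`
#' (gap-junction block-like); `scale_rate` multiplies the pacemaker rate
#' by `magnitude` from `onset` (opioid- or potassium-like rate changes);
#' `add_tonic_rate` adds independent Poisson events at `magnitude` mHz to
#' every cell from `onset`.
#'
#' @param mode one of `"decouple_all"`, `"delete_edge_fraction"`,
#'   `"scale_rate"`, `"add_tonic_rate"`
#' @param magnitude mode-dependent scalar (fraction in `[0,1]` for
#'   `delete_edge_fraction`, positive multiplier for `scale_rate`,
#'   rate in mHz for `add_tonic_rate`; unused for `decouple_all`)
#' @param onset time the perturbation starts, s
#' @return list of class `perturbation`
#' @export
perturbation <- function(mode = c("decouple_all", "delete_edge_fraction",
                                  "scale_rate", "add_tonic_rate"),
                         magnitude = 1, onset = 0) {
  mode <- match.arg(mode)
  if (onset < 0) stop("onset must be non-negative")
  if (mode == "delete_edge_fraction" && (magnitude < 0 || magnitude > 1))
    stop("delete_edge_fraction magnitude must lie in [0, 1]")
  if (mode == "scale_rate" && magnitude <= 0)
    stop("scale_rate magnitude must be positive")
  if (mode == "add_tonic_rate" && magnitude < 0)
    stop("add_tonic_rate magnitude must be non-negative")
  structure(list(mode = mode, magnitude = magnitude, onset = onset),
            class = "perturbation")
}

# Quasi-periodic event train on [0, duration): first event at a random
# phase uniform on [0, period) -- independent oscillators carry no common
# phase reference, so uncoupled pacemakers must not be synchronized at
# recording onset -- then gamma-distributed intervals with mean 1/rate
# and CV = cv (degenerate to the exact period when cv = 0). rate_fun maps
# a time to the instantaneous mean rate (Hz), so rate-scaling
# perturbations apply from their onset. Note the event count over a
# duration D is phase-invariant when cv = 0: exactly ceiling((D - phi) /
# period) with phi < period, e.g. always 3 events in 60 s at 50 mHz.
pacemaker_train <- function(rate_fun, cv, duration) {
  r0 <- rate_fun(0)
  if (r0 <= 0) return(numeric(0))
  tt <- numeric(0)
  t <- runif(1, 0, 1 / r0)
  repeat {
    r <- rate_fun(t)
    if (r <= 0 || t >= duration) break
    tt <- c(tt, t)
    m <- 1 / r
    iv <- if (cv == 0) m else rgamma(1L, shape = 1 / cv^2, scale = m * cv^2)
    t <- t + iv
  }
  tt
}

#' Simulate a calcium imaging recording with known ground truth
#'
#' Pacemaker cells emit quasi-periodic events; every event is transmitted
#' once (single hop, no cascading re-propagation) to each coupled
#' neighbour with probability `transmission_prob` after a jittered delay.
#' Fluorescence traces are built as baseline + amplitude x sum of
#' unit-peak transient kernels at the event times + slow sinusoidal drift
#' + Gaussian noise, sampled at the frame interval. Single-hop
#' transmission keeps ground-truth correlation structure local to the
#' coupling edges, which is what makes edge-recovery benchmarks against
#' `truth_graph` well defined.
#'
#' @param net a [generate_network()] result (or a 0/1 adjacency matrix)
#' @param dynamics a [dynamics_spec()]
#' @param perturbations list of [perturbation()] objects
#' @param seed RNG seed; identical specs and seed give an identical
#'   recording (per-cell sub-seeds are derived from this seed, so pacemaker
#'   trains are reproducible cell by cell)
#' @param pacemakers optional integer vector of cell indices to use as
#'   pacemakers, overriding the random draw implied by
#'   `pacemaker_fraction`
#' @return object of class `sim_recording`: list with `traces` (a
#'   [trace_set()]), `truth_graph` (the coupling adjacency), `pacemaker_mask`
#'   (logical per cell), `truth_events` (list of event-time vectors, s),
#'   plus the specs used
#' @export
simulate_recording <- function(net, dynamics = dynamics_spec(),
                               perturbations = list(), seed = 1,
                               pacemakers = NULL) {
  if (is.matrix(net))
    net <- list(adjacency = (net != 0) * 1L, n_cells = nrow(net))
  if (inherits(perturbations, "perturbation"))
    perturbations <- list(perturbations)
  adj <- net$adjacency
  n <- nrow(adj)
  dyn <- dynamics
  n_frames <- floor(dyn$duration / dyn$frame_interval)
  if (n_frames < 2L) stop("duration must cover at least 2 frames")
  for (p in perturbations)
    if (p$onset > dyn$duration) stop("perturbation onset beyond recording")

  pmode <- vapply(perturbations, `[[`, "", "mode")
  pert <- function(mode) {
    i <- match(mode, pmode)
    if (is.na(i)) NULL else perturbations[[i]]
  }

  set.seed(seed)
  pacemaker_mask <- rep(FALSE, n)
  if (!is.null(pacemakers)) {
    stopifnot(all(pacemakers >= 1L), all(pacemakers <= n))
    pacemaker_mask[pacemakers] <- TRUE
  } else {
    n_pm <- round(dyn$pacemaker_fraction * n)
    if (n_pm > 0L) pacemaker_mask[sample.int(n, n_pm)] <- TRUE
  }
  cell_seed <- sample.int(.Machine$integer.max, n)

  # edge deletion set drawn once, applied from onset onward
  del <- pert("delete_edge_fraction")
  edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  deleted <- matrix(FALSE, n, n)
  if (!is.null(del) && nrow(edges) > 0L) {
    nd <- round(del$magnitude * nrow(edges))
    if (nd > 0L) {
      di <- edges[sample.int(nrow(edges), nd), , drop = FALSE]
      deleted[di] <- TRUE
      deleted[di[, 2:1, drop = FALSE]] <- TRUE
    }
  }

  sc <- pert("scale_rate")
  base_rate <- dyn$pacemaker_rate / 1000  # mHz -> Hz
  rate_fun <- function(t) {
    r <- base_rate
    if (!is.null(sc) && t >= sc$onset) r <- r * sc$magnitude
    r
  }

  events <- vector("list", n)
  for (i in seq_len(n)) {
    events[[i]] <- numeric(0)
    if (pacemaker_mask[i]) {
      set.seed(cell_seed[i])
      events[[i]] <- pacemaker_train(rate_fun, dyn$rate_jitter_cv,
                                     dyn$duration)
    }
  }

  # single-hop transmission of pacemaker events along surviving edges;
  # propagate from a snapshot of the autonomous trains so received events
  # never re-propagate (no cascading). Pacemakers are autonomous
  # oscillators: their own event trains are not altered by incoming
  # transmission, so only non-pacemaker neighbours are driven.
  autonomous <- events
  dec <- pert("decouple_all")
  set.seed(cell_seed[1L] %% 1000003L + seed)
  for (i in which(pacemaker_mask)) {
    nb <- which(adj[i, ] == 1L & !pacemaker_mask)
    for (te in autonomous[[i]]) {
      if (!is.null(dec) && te >= dec$onset) next
      for (j in nb) {
        if (!is.null(del) && te >= del$onset && deleted[i, j]) next
        if (runif(1) < dyn$transmission_prob) {
          tj <- te + abs(rnorm(1, dyn$transmission_delay, dyn$delay_jitter))
          if (tj < dyn$duration) events[[j]] <- c(events[[j]], tj)
        }
      }
    }
  }

  ton <- pert("add_tonic_rate")
  if (!is.null(ton) && ton$magnitude > 0) {
    span <- dyn$duration - ton$onset
    for (i in seq_len(n)) {
      nev <- rpois(1L, ton$magnitude / 1000 * span)
      if (nev > 0L)
        events[[i]] <- c(events[[i]], ton$onset + sort(runif(nev, 0, span)))
    }
  }
  events <- lapply(events, function(e) unique(sort(e)))

  tt <- (seq_len(n_frames) - 1L) * dyn$frame_interval
  vals <- matrix(0, n, n_frames)
  support <- 8 * dyn$kernel_decay  # kernel negligible beyond this
  for (i in seq_len(n)) {
    x <- rep(dyn$baseline, n_frames)
    for (te in events[[i]]) {
      i0 <- max(1L, floor(te / dyn$frame_interval) + 1L)
      i1 <- min(n_frames, ceiling((te + support) / dyn$frame_interval) + 1L)
      if (i0 <= i1) {
        idx <- i0:i1
        x[idx] <- x[idx] + dyn$amplitude *
          ca_kernel(tt[idx] - te, dyn$kernel_rise, dyn$kernel_decay)
      }
    }
    if (dyn$drift_amplitude > 0)
      x <- x + dyn$drift_amplitude *
        sin(2 * pi * tt / dyn$duration + runif(1, 0, 2 * pi))
    if (dyn$noise_sd > 0)
      x <- x + rnorm(n_frames, 0, dyn$noise_sd)
    vals[i, ] <- x
  }

  structure(list(
    traces = trace_set(vals, dyn$frame_interval),
    truth_graph = adj,
    pacemaker_mask = pacemaker_mask,
    truth_events = events,
    dynamics = dyn,
    perturbations = perturbations,
    network = if (inherits(net, "cell_network")) net else NULL,
    seed = seed), class = "sim_recording")
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf(paste0("<sim_recording> %d cells (%d pacemakers), %g s at ",
                     "%g s/frame, %d truth events, seed %s\n"),
              nrow(x$traces$values), sum(x$pacemaker_mask),
              x$dynamics$duration, x$dynamics$frame_interval,
              sum(lengths(x$truth_events)), format(x$seed)))
  invisible(x)
}

#' Render a simulated recording as an image stack
#'
#' Each frame is `background` plus, for every cell, a 2-D Gaussian
#' footprint (SD = radius / 2, unit peak) scaled by that cell's trace
#' value in that frame. The result can be written with
#' [write_stack_tiff()] and fed to [extract_rois_and_traces()].
#'
#' @param rec a [simulate_recording()] result, or a [trace_set()]
#' @param positions n_cells x 2 matrix of (row, col) pixel centers, 0-based
#' @param radii cell radius in pixels (scalar or per cell)
#' @param dim image size `c(height, width)` in pixels
#' @param background constant background intensity
#' @return numeric array height x width x frames
#' @export
render_stack <- function(rec, positions, radii = 3,
                         dim = c(64L, 64L), background = 0) {
  ts <- if (inherits(rec, "sim_recording")) rec$traces else rec
  vals <- ts$values
  n <- nrow(vals)
  positions <- matrix(positions, ncol = 2L)
  radii <- rep_len(radii, max(n, 1L))
  if (n > 0L) {
    stopifnot(nrow(positions) == n)
    if (any(positions[, 1L] < 0 | positions[, 1L] > dim[1L] - 1 |
            positions[, 2L] < 0 | positions[, 2L] > dim[2L] - 1))
      stop("cell positions must lie within the image bounds")
    if (anyDuplicated(positions))
      warning("overlapping identical cell positions")
  }
  nf <- ncol(vals)
  stack <- array(background, c(dim[1L], dim[2L], nf))
  rr <- matrix(seq_len(dim[1L]) - 1L, dim[1L], dim[2L])
  cc <- matrix(seq_len(dim[2L]) - 1L, dim[1L], dim[2L], byrow = TRUE)
  for (i in seq_len(n)) {
    s <- radii[i] / 2
    fp <- exp(-((rr - positions[i, 1L])^2 + (cc - positions[i, 2L])^2) /
                (2 * s^2))
    for (f in seq_len(nf))
      stack[, , f] <- stack[, , f] + vals[i, f] * fp
  }
  stack
}

#' Write simulation ground truth as JSON
#'
#' Stores the coupling edge list, the pacemaker mask and the per-cell
#' event times of a simulated recording in a plain JSON file.
#'
#' @param rec a [simulate_recording()] result
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_truth_json <- function(rec, path) {
  adj <- rec$truth_graph
  e <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  jsonlite::write_json(list(
    n_cells = nrow(adj),
    edges = unname(apply(e, 1L, function(r) as.integer(r), simplify = FALSE)),
    pacemaker = which(rec$pacemaker_mask),
    event_times_s = rec$truth_events,
    seed = rec$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
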