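#' Fit a functional network to a calcium recording
#'
#' The package's central estimator. Runs the full inference chain on a
#' set of fluorescence traces: sliding-window dF/F0 normalization,
#' calcium transient event detection, pairwise Pearson correlation, the
#' scrambled-trace (circular time-shift) null cut-off, functional graph
#' construction over active cells, small-world metrics against
#' degree-preserving randomized networks, and per-cell frequency
#' statistics.
#'
#' @param traces a [trace_set()] (raw intensities) or a
#'   [normalize_dff()] result (used as-is)
#' @param window_half_width dF/F0 baseline half-window, s (default 30)
#' @param threshold_frac event threshold, minimum dF/F0 increase above
#'   baseline (default 0.2)
#' @param min_separation minimum event spacing, s (default 2)
#' @param n_scrambles scramble realizations for the null cut-off
#'   (default 100)
#' @param n_random randomized networks for metric normalization
#'   (default 100)
#' @param seed RNG seed covering both randomized stages
#' @param gamma_form `"ratio"` (default) or `"product"`, see
#'   [normalize_metrics()]
#' @param cutoff optional fixed correlation cut-off; skips the scramble
#'   stage when given
#' @return object of class `fnet`: list with `traces`, `norm`, `events`,
#'   `corr` (with cut-off filled in), `graph`, `summary`
#'   (a `network_summary`), `freq` (a `frequency_report`), `params`, `call`
#' @seealso [summary.fnet()], [plot.fnet()], [simulate.fnet()]
#' @examples
#' net <- generate_network(30, "small_world", k = 4, rewire_p = 0.1,
#'                         seed = 7)
#' rec <- simulate_recording(net, dynamics_spec(duration = 200), seed = 7)
#' fit <- fnet(rec$traces, n_scrambles = 20, n_random = 20, seed = 7)
#' summary(fit)
#' @export
fnet <- function(traces, window_half_width = 30, threshold_frac = 0.20,
                 min_separation = 2, n_scrambles = 100, n_random = 100,
                 seed = 1, gamma_form = c("ratio", "product"),
                 cutoff = NULL) {
  gamma_form <- match.arg(gamma_form)
  cl <- match.call()
  norm <- if (inherits(traces, "norm_trace_set")) traces
          else normalize_dff(traces, window_half_width)
  events <- detect_events(norm, threshold_frac = threshold_frac,
                          min_separation = min_separation)
  corr <- correlation_matrix(norm)
  corr$cutoff <- if (!is.null(cutoff)) as.numeric(cutoff)
                 else as.numeric(scrambled_cutoff(norm,
                                                  n_scrambles = n_scrambles,
                                                  seed = seed))
  corr$n_scrambles <- if (is.null(cutoff)) n_scrambles else NA_integer_
  corr$seed <- seed
  graph <- build_graph(corr, events, centroids = norm$roi_centroids)
  summ <- normalize_metrics(graph, n_random = n_random, seed = seed,
                            gamma_form = gamma_form)
  freq <- frequency_and_cv(events)
  structure(list(traces = traces, norm = norm, events = events,
                 corr = corr, graph = graph, summary = summ, freq = freq,
                 params = list(window_half_width = window_half_width,
                               threshold_frac = threshold_frac,
                               min_separation = min_separation,
                               n_scrambles = n_scrambles,
                               n_random = n_random, seed = seed,
                               gamma_form = gamma_form),
                 call = cl),
            class = "fnet")
}

#' @export
print.fnet <- function(x, ...) {
  cat("Functional network fit\n")
  cat(sprintf("  %d ROI(s) x %d frames at %g s/frame\n",
              nrow(x$norm$values), ncol(x$norm$values),
              x$norm$frame_interval))
  cat(sprintf("  cutoff r >= %.3f; %d active cell(s); %d edge(s)\n",
              x$corr$cutoff, sum(x$events$active),
              x$summary$correlating_pairs))
  invisible(x)
}

#' Summarize a functional network fit
#'
#' @param object an [fnet()] fit
#' @param ... unused
#' @return the fit's `network_summary`, printed together with population
#'   frequency statistics
#' @export
summary.fnet <- function(object, ...) {
  print(object$summary)
  cat(sprintf(paste0("  population mean frequency: %.1f mHz; ",
                     "%d regularly spiking cell(s)\n"),
              object$freq$population_freq_mhz,
              length(object$freq$regular_cells)))
  invisible(object$summary)
}

#' Network summary metrics of a fit
#'
#' @param object an [fnet()] fit
#' @param ... unused
#' @return named numeric vector of the estimated network parameters
#' @export
coef.fnet <- function(object, ...) {
  s <- object$summary
  c(correlating_pairs = s$correlating_pairs,
    active_cells = s$active_cells,
    correlations_per_active_cell = s$correlations_per_active_cell,
    connectivity = s$connectivity,
    lambda = s$lambda, sigma = s$sigma, gamma = s$gamma,
    cutoff = object$corr$cutoff)
}

#' Plot a functional network fit
#'
#' Spatial edge map of the inferred graph (see
#' [plot.functional_graph()]).
#'
#' @param x an [fnet()] fit
#' @param ... passed on to [plot.functional_graph()]
#' @return `x`, invisibly
#' @export
plot.fnet <- function(x, ...) {
  plot(x$graph, ...)
  invisible(x)
}

#' Simulate recordings from a fitted functional network
#'
#' Parametric-bootstrap-style generator: uses the inferred adjacency as
#' the coupling graph and the fitted cells' activity scale to produce new
#' synthetic recordings via [simulate_recording()].
#'
#' @param object an [fnet()] fit
#' @param nsim number of recordings
#' @param seed base RNG seed (recording `i` uses `seed + i - 1`)
#' @param dynamics a [dynamics_spec()]; defaults to the package defaults
#'   with the fit's frame interval and duration
#' @param ... unused
#' @return list of `sim_recording` objects (length `nsim`)
#' @export
simulate.fnet <- function(object, nsim = 1, seed = 1,
                          dynamics = NULL, ...) {
  adj <- matrix(0L, igraph::vcount(object$graph$graph),
                igraph::vcount(object$graph$graph))
  el <- igraph::as_edgelist(object$graph$graph, names = FALSE)
  if (nrow(el) > 0L) { adj[el] <- 1L; adj[el[, 2:1]] <- 1L }
  if (is.null(dynamics))
    dynamics <- dynamics_spec(
      frame_interval = object$norm$frame_interval,
      duration = ncol(object$norm$values) * object$norm$frame_interval)
  lapply(seq_len(nsim), function(i)
    simulate_recording(adj, dynamics, seed = seed + i - 1L))
}
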