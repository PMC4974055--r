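#' Analyze a recording end to end and write all artifacts
#'
#' Orchestrates simulate/load -> normalize -> detect events -> correlate
#' -> threshold -> graph metrics -> frequency report, writing every
#' output plus a machine-readable provenance record. Reruns with the
#' same configuration produce byte-identical outputs.
#'
#' The configuration is a named list (or path to a JSON file) with:
#' \describe{
#'   \item{input}{one of: `list(traces_csv = path)`,
#'     `list(stack_tiff = path, frame_interval = s)`, or
#'     `list(simulate = list(network = <args for [generate_network()]>,
#'     dynamics = <args for [dynamics_spec()]>,
#'     perturbations = <list of [perturbation()] args>, seed = int))`}
#'   \item{params}{optional overrides for [fnet()] arguments
#'     (`window_half_width`, `threshold_frac`, `min_separation`,
#'     `n_scrambles`, `n_random`, `seed`, `gamma_form`)}
#'   \item{output_dir}{directory for artifacts (created if needed);
#'     omit to skip writing}
#' }
#'
#' Artifacts written to `output_dir`: `normalized_traces.csv`,
#' `events.csv`, `correlation_matrix.csv`, `edges.csv`, `summary.csv`
#' (one row), `frequency.csv`, `provenance.json` (config, seeds, package
#' version), and `graph.graphml` when `graphml = TRUE`.
#'
#' @param config named list or path to a JSON config
#' @param graphml also write a GraphML export (default FALSE)
#' @return the [fnet()] fit, with the artifact paths in
#'   `$artifacts` and the resolved config in `$config`
#' @export
analyze_recording <- function(config, graphml = FALSE) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$input))
  inp <- config$input
  rec <- NULL
  traces <- if (!is.null(inp$traces_csv)) {
    read_traces_csv(inp$traces_csv)
  } else if (!is.null(inp$stack_tiff)) {
    if (is.null(inp$frame_interval))
      stop("stack input requires input$frame_interval")
    extract_rois_and_traces(read_stack_tiff(inp$stack_tiff),
                            inp$frame_interval)
  } else if (!is.null(inp$simulate)) {
    sim <- inp$simulate
    net <- do.call(generate_network, as.list(sim$network))
    dyn <- do.call(dynamics_spec, as.list(sim$dynamics %||% list()))
    perts <- lapply(sim$perturbations %||% list(),
                    function(p) do.call(perturbation, as.list(p)))
    rec <- simulate_recording(net, dyn, perts, seed = sim$seed %||% 1L,
                              pacemakers = sim$pacemakers)
    rec$traces
  } else stop("config$input must name traces_csv, stack_tiff or simulate")

  params <- as.list(config$params %||% list())
  fit <- do.call(fnet, c(list(traces = traces), params))
  fit$recording <- rec
  fit$config <- config

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out, f)
    write_traces_csv(fit$norm, p("normalized_traces.csv"))
    write_events_csv(fit$events, p("events.csv"))
    write.csv(fit$corr$matrix, p("correlation_matrix.csv"))
    write_edges_csv(fit$graph, p("edges.csv"))
    write.csv(as.data.frame(fit$summary), p("summary.csv"),
              row.names = FALSE)
    write.csv(fit$freq$cells, p("frequency.csv"), row.names = FALSE)
    if (graphml) write_graphml(fit$graph, p("graph.graphml"))
    if (!is.null(rec)) write_truth_json(rec, p("truth.json"))
    jsonlite::write_json(list(
      config = config,
      params = fit$params,
      cutoff = fit$corr$cutoff,
      package_version = as.character(utils::packageVersion("respnet")),
      r_version = paste(R.version$major, R.version$minor, sep = ".")),
      p("provenance.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    fit$artifacts <- vapply(c("normalized_traces.csv", "events.csv",
                              "correlation_matrix.csv", "edges.csv",
                              "summary.csv", "frequency.csv",
                              "provenance.json"), p, character(1))
  }
  message(sprintf(
    "analyze_recording: %d cells, %d active, cutoff %.3f, %d pairs",
    nrow(fit$norm$values), sum(fit$events$active), fit$corr$cutoff,
    fit$summary$correlating_pairs))
  fit
}

#' Aggregate network summaries across recordings
#'
#' Reads one-row `summary.csv` files (or takes their data frames) and
#' reports per-parameter mean and sample SD (n - 1 denominator) across
#' recordings, in the conventional mean +/- SD report layout.
#'
#' @param summaries character vector of `summary.csv` paths, or a list of
#'   data frames / `network_summary` objects
#' @return data frame with columns `parameter`, `mean`, `sd`, `n`
#' @export
report_summaries <- function(summaries) {
  if (length(summaries) == 0L) stop("no summaries to aggregate")
  dfs <- lapply(summaries, function(s) {
    if (is.character(s)) read.csv(s)
    else if (inherits(s, "network_summary")) as.data.frame(s)
    else as.data.frame(s)
  })
  cols <- names(dfs[[1L]])
  for (d in dfs)
    if (!identical(names(d), cols))
      stop("summaries have mixed schemas")
  mat <- do.call(rbind, dfs)
  data.frame(parameter = cols,
             mean = vapply(mat, mean, numeric(1)),
             sd = vapply(mat, function(x)
               if (length(x) > 1L) sd(x) else 0, numeric(1)),
             n = nrow(mat), row.names = NULL)
}
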