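#' Pairwise Pearson correlation matrix of normalized traces
#'
#' Linear similarity (Pearson correlation) between every unordered pair
#' of dF/F0 traces. Constant traces and cells flagged during
#' normalization have no defined correlation; their rows/columns are set
#' to `NA` with a warning and they are excluded from all downstream
#' pair counts.
#'
#' @param norm a [normalize_dff()] result (any `trace_set` works)
#' @return object of class `correlation_result`: list with `matrix`
#'   (symmetric, unit diagonal for valid cells), `valid` (logical per
#'   cell), `cutoff` (`NA` until [scrambled_cutoff()] is run), `n_scrambles`,
#'   `seed`
#' @export
correlation_matrix <- function(norm) {
  stopifnot(inherits(norm, "trace_set"))
  vals <- norm$values
  if (nrow(vals) < 2L) stop("need at least 2 cells")
  if (ncol(vals) < 3L) stop("need at least 3 frames")
  valid <- apply(vals, 1L, function(x) !anyNA(x) && sd(x) > 0)
  if (!is.null(norm$flagged)) valid <- valid & !norm$flagged
  if (any(!valid))
    warning(sum(!valid), " constant or flagged cell(s) have undefined ",
            "correlations")
  m <- matrix(NA_real_, nrow(vals), nrow(vals),
              dimnames = list(norm$roi_ids, norm$roi_ids))
  if (sum(valid) >= 2L)
    m[valid, valid] <- cor(t(vals[valid, , drop = FALSE]))
  diag(m)[valid] <- 1
  structure(list(matrix = m, valid = valid, cutoff = NA_real_,
                 n_scrambles = NA_integer_, seed = NA_integer_),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d cell(s) (%d valid), cutoff %s\n",
              nrow(x$matrix), sum(x$valid),
              if (is.na(x$cutoff)) "not set" else format(x$cutoff,
                                                         digits = 3)))
  invisible(x)
}

#' Correlation cut-off from scrambled (circularly time-shifted) traces
#'
#' Builds the null distribution of correlations expected in the absence
#' of coordinated activity: in each scramble realization every trace is
#' independently translated in time by a uniformly random circular shift
#' (wrap-around), which preserves each trace's marginal distribution and
#' autocorrelation while destroying cross-cell alignment. The 99th
#' percentile (linear interpolation) of the pooled off-diagonal
#' correlations is recorded per realization, and the cut-off is the mean
#' of those percentiles across realizations.
#'
#' @param norm a [normalize_dff()] result
#' @param n_scrambles number of scramble realizations (default 100)
#' @param seed RNG seed; identical inputs and seed give an identical
#'   cut-off
#' @param percentile percentile of the null distribution (default 0.99)
#' @return the scalar cut-off; attributes `percentiles` (per realization)
#' @export
scrambled_cutoff <- function(norm, n_scrambles = 100, seed = 1,
                             percentile = 0.99) {
  stopifnot(inherits(norm, "trace_set"), n_scrambles >= 1)
  vals <- norm$values
  valid <- apply(vals, 1L, function(x) !anyNA(x) && sd(x) > 0)
  if (!is.null(norm$flagged)) valid <- valid & !norm$flagged
  vals <- vals[valid, , drop = FALSE]
  n <- nrow(vals); nf <- ncol(vals)
  if (n < 3L) stop("scrambled cut-off needs at least 3 valid cells")
  set.seed(seed)
  ut <- upper.tri(matrix(0, n, n))
  q <- vapply(seq_len(n_scrambles), function(r) {
    off <- sample.int(nf - 1L, n, replace = TRUE)
    shifted <- vals
    for (i in seq_len(n)) {
      o <- off[i]
      shifted[i, ] <- vals[i, c((nf - o + 1L):nf, 1L:(nf - o))]
    }
    cm <- cor(t(shifted))
    as.numeric(quantile(cm[ut], percentile, names = FALSE, type = 7))
  }, numeric(1))
  structure(mean(q), percentiles = q, n_scrambles = n_scrambles,
            seed = seed)
}

#' Build the functional graph from thresholded correlations
#'
#' Converts the correlation matrix to an adjacency over *active* cells
#' (cells with at least one detected event): an undirected edge joins two
#' active cells whenever their correlation meets or exceeds the cut-off
#' (signed r, not absolute: anti-correlated pairs are not edges). Edge
#' weights keep the correlation coefficient for visualization.
#'
#' @param corr a [correlation_matrix()] result
#' @param events a [detect_events()] result, or a logical active mask;
#'   `NULL` treats every valid cell as active
#' @param cutoff correlation cut-off (typically from [scrambled_cutoff()]);
#'   if missing, `corr$cutoff` is used
#' @param centroids optional per-cell pixel coordinates for plotting
#' @return object of class `functional_graph`: list with `graph` (weighted
#'   igraph over active cells), `cutoff`, `active` (logical over all
#'   cells), `centroids`
#' @export
build_graph <- function(corr, events = NULL, cutoff = corr$cutoff,
                        centroids = NULL) {
  stopifnot(inherits(corr, "correlation_result"))
  if (is.na(cutoff)) stop("no cut-off available; run scrambled_cutoff()")
  n <- nrow(corr$matrix)
  active <- if (is.null(events)) rep(TRUE, n)
            else if (is.logical(events)) events
            else events$active
  stopifnot(length(active) == n)
  active <- active & corr$valid
  m <- corr$matrix[active, active, drop = FALSE]
  a <- !is.na(m) & m >= cutoff
  diag(a) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::E(g)$weight <- m[igraph::as_edgelist(g, names = FALSE)]
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    stopifnot(nrow(centroids) == n)
  }
  structure(list(graph = g, cutoff = as.numeric(cutoff), active = active,
                 centroids = if (is.null(centroids)) NULL
                             else centroids[active, , drop = FALSE]),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf(paste0("<functional_graph> %d active cell(s), %d edge(s) ",
                     "at cutoff r >= %.3f\n"),
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$cutoff))
  invisible(x)
}

#' Write the edge list of a functional graph to CSV
#'
#' @param fg a [build_graph()] result
#' @param path output CSV path (columns `cell_a`, `cell_b`, `r`)
#' @return `path`, invisibly
#' @export
write_edges_csv <- function(fg, path) {
  el <- igraph::as_edgelist(fg$graph)
  df <- data.frame(cell_a = el[, 1L], cell_b = el[, 2L],
                   r = if (igraph::ecount(fg$graph) > 0)
                         igraph::E(fg$graph)$weight else numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a functional graph to GraphML
#'
#' @param fg a [build_graph()] result
#' @param path output .graphml path
#' @return `path`, invisibly
#' @export
write_graphml <- function(fg, path) {
  igraph::write_graph(fg$graph, path, format = "graphml")
  invisible(path)
}

#' Plot a functional graph as a spatial edge map
#'
#' Draws a line between every pair of connected cells, colored by the
#' correlation coefficient (warmer = more strongly correlated), on top of
#' an optional background image (typically the SD-over-time image).
#'
#' @param x a [build_graph()] result
#' @param background optional matrix shown underneath (e.g. SD image)
#' @param ... passed to [graphics::plot()]
#' @return `x`, invisibly
#' @export
plot.functional_graph <- function(x, background = NULL, ...) {
  g <- x$graph
  xy <- if (!is.null(x$centroids)) x$centroids[, 2:1, drop = FALSE]
        else igraph::layout_with_fr(g)
  op <- par(mar = c(2, 2, 2, 4)); on.exit(par(op))
  if (!is.null(background)) {
    graphics::image(t(background)[, nrow(background):1],
                    col = grDevices::gray.colors(64), axes = FALSE)
    xy <- cbind(xy[, 1L] / (ncol(background) - 1L),
                1 - xy[, 2L] / (nrow(background) - 1L))
  } else {
    plot(xy, type = "n", xlab = "", ylab = "", ...)
  }
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    wt <- igraph::E(g)$weight
    pal <- colorRampPalette(c("blue", "cyan", "yellow", "red"))(64)
    ci <- pmax(1L, pmin(64L, ceiling((wt - x$cutoff) /
                                       max(1e-9, 1 - x$cutoff) * 64)))
    segments(xy[el[, 1L], 1L], xy[el[, 1L], 2L],
             xy[el[, 2L], 1L], xy[el[, 2L], 2L], col = pal[ci])
  }
  points(xy, pch = 16, cex = 0.6)
  invisible(x)
}
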