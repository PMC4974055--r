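#' Generate a ground-truth coupling network
#'
#' Builds the cell-to-cell coupling graph used by [simulate_recording()].
#' Topologies mirror the structures reported for respiratory circuits:
#' locally clustered cells interconnected through a few hub-like links
#' (small-world), plus reference topologies for calibration.
#'
#' @param n_cells number of cells (>= 2)
#' @param topology one of `"ring_lattice"`, `"small_world"`, `"random"`,
#'   `"planted_clusters"`, `"empty"`
#' @param k target mean degree; for the ring lattice and small-world
#'   topologies `k` must be even (each node is wired to `k/2` neighbours on
#'   each side); must satisfy `k < n_cells`
#' @param rewire_p Watts-Strogatz rewiring probability in `[0, 1]`
#'   (small_world only; `rewire_p = 0` reproduces the ring lattice exactly)
#' @param n_clusters number of planted clusters (planted_clusters only)
#' @param inter_cluster_edges exact number of bridge edges placed across
#'   the cluster partition (planted_clusters only)
#' @param seed RNG seed; the same seed always yields the same graph
#' @return object of class `cell_network`: list with `graph` (igraph),
#'   `adjacency` (0/1 matrix), `membership` (cluster labels or NULL),
#'   plus the generating parameters
#' @export
generate_network <- function(n_cells,
                             topology = c("small_world", "ring_lattice",
                                          "random", "planted_clusters",
                                          "empty"),
                             k = 6, rewire_p = 0.1,
                             n_clusters = 2, inter_cluster_edges = 1,
                             seed = 1) {
  topology <- match.arg(topology)
  if (n_cells < 2L) stop("n_cells must be at least 2")
  if (rewire_p < 0 || rewire_p > 1) stop("rewire_p must lie in [0, 1]")
  if (topology != "empty" && k >= n_cells)
    stop("mean degree k must be smaller than n_cells")
  set.seed(seed)
  membership <- NULL
  adj <- matrix(0L, n_cells, n_cells)

  ring_edges <- function(n, k) {
    if (k %% 2 != 0) stop("ring lattice requires an even k")
    do.call(rbind, lapply(seq_len(k / 2), function(d) {
      cbind(seq_len(n), (seq_len(n) - 1L + d) %% n + 1L)
    }))
  }

  edges <- switch(topology,
    empty = matrix(integer(), 0L, 2L),
    ring_lattice = ring_edges(n_cells, k),
    small_world = {
      e <- ring_edges(n_cells, k)
      # Watts-Strogatz: each lattice edge is rewired with probability
      # rewire_p by moving its far endpoint to a uniformly chosen
      # non-neighbour (self-loops and duplicate edges refused).
      amat <- matrix(FALSE, n_cells, n_cells)
      amat[e] <- TRUE; amat[e[, 2:1]] <- TRUE
      for (i in seq_len(nrow(e))) {
        if (runif(1) < rewire_p) {
          u <- e[i, 1L]
          cand <- which(!amat[u, ] & seq_len(n_cells) != u)
          if (length(cand) > 0L) {
            v_new <- if (length(cand) == 1L) cand else sample(cand, 1L)
            v_old <- e[i, 2L]
            amat[u, v_old] <- amat[v_old, u] <- FALSE
            amat[u, v_new] <- amat[v_new, u] <- TRUE
            e[i, 2L] <- v_new
          }
        }
      }
      e
    },
    random = {
      m <- round(n_cells * k / 2)
      all_pairs <- which(upper.tri(adj), arr.ind = TRUE)
      if (m > nrow(all_pairs)) stop("k too large for a simple graph")
      all_pairs[sample.int(nrow(all_pairs), m), , drop = FALSE]
    },
    planted_clusters = {
      if (n_clusters < 1L || n_clusters > n_cells)
        stop("n_clusters must lie in [1, n_cells]")
      membership <- sort(rep_len(seq_len(n_clusters), n_cells))
      within <- do.call(rbind, lapply(seq_len(n_clusters), function(cl) {
        idx <- which(membership == cl)
        nc <- length(idx)
        if (nc < 2L) return(matrix(integer(), 0L, 2L))
        pairs <- t(combn(idx, 2L))
        m <- min(round(nc * min(k, nc - 1L) / 2), nrow(pairs))
        pairs[sample.int(nrow(pairs), m), , drop = FALSE]
      }))
      cross_pairs <- which(outer(membership, membership, "!=") &
                             upper.tri(adj), arr.ind = TRUE)
      if (inter_cluster_edges > nrow(cross_pairs))
        stop("inter_cluster_edges exceeds the number of cross-cluster pairs")
      bridges <- cross_pairs[sample.int(nrow(cross_pairs),
                                        inter_cluster_edges), ,
                             drop = FALSE]
      rbind(within, bridges)
    }
  )

  if (nrow(edges) > 0L) {
    adj[edges] <- 1L
    adj[edges[, 2:1, drop = FALSE]] <- 1L
  }
  diag(adj) <- 0L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, adjacency = adj, membership = membership,
                 n_cells = n_cells, topology = topology, k = k,
                 rewire_p = rewire_p, seed = seed),
            class = "cell_network")
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf("<cell_network> %s, %d cells, %d edges (seed %s)\n",
              x$topology, x$n_cells, igraph::ecount(x$graph),
              format(x$seed)))
  invisible(x)
}
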