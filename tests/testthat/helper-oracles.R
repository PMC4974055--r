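# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths and igraph.

# two-pass direct-formula Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

pearson_matrix_oracle <- function(vals) {
  n <- nrow(vals)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- pearson_oracle(vals[i, ], vals[j, ])
  m
}

# local clustering by direct triangle counting; degree < 2 contributes 0
clustering_oracle <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- sum(adj[nb, nb]) / 2
    cc[i] <- links / (k * (k - 1) / 2)
  }
  mean(cc)
}

# all-pairs shortest paths by Floyd-Warshall; mean over connected pairs
path_length_oracle <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  dv <- d[upper.tri(d)]
  mean(dv[is.finite(dv)])
}

adjacency_of <- function(fg) {
  g <- if (inherits(fg, "functional_graph")) fg$graph else fg
  as.matrix(igraph::as_adjacency_matrix(g))
}

# build a normalized trace set directly from a value matrix (bypasses
# normalize_dff) for tests that specify dF/F0 values explicitly
norm_set <- function(values, frame_interval) {
  structure(list(values = as.matrix(values),
                 frame_interval = frame_interval,
                 roi_ids = paste0("cell_", seq_len(nrow(values))),
                 roi_centroids = NULL,
                 flagged = logical(nrow(values))),
            class = c("norm_trace_set", "trace_set"))
}

# kernel transient train as a dF/F0 trace with a given peak value
kernel_train <- function(event_times, peak, frame_interval, duration,
                         rise = 0.3, decay = 2) {
  tt <- seq(0, duration - frame_interval, by = frame_interval)
  x <- numeric(length(tt))
  for (te in event_times) x <- x + peak * ca_kernel(tt - te, rise, decay)
  x
}

# recovered-vs-truth edge agreement over all unordered pairs
edge_f1 <- function(fit, rec) {
  n <- nrow(rec$truth_graph)
  act <- which(fit$events$active & fit$corr$valid)
  ra <- matrix(FALSE, n, n)
  el <- igraph::as_edgelist(fit$graph$graph, names = FALSE)
  if (nrow(el) > 0) {
    ia <- act[el[, 1]]; ib <- act[el[, 2]]
    ra[cbind(ia, ib)] <- TRUE
    ra[cbind(ib, ia)] <- TRUE
  }
  ta <- rec$truth_graph == 1
  ut <- upper.tri(ta)
  tp <- sum(ra[ut] & ta[ut])
  fp <- sum(ra[ut] & !ta[ut])
  fn <- sum(!ra[ut] & ta[ut])
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall,
       tp = tp, fp = fp, fn = fn)
}
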