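#' Per-cell event frequency and regularity
#'
#' Frequency is `(n_events - 1) / (t_last - t_first)` within the epoch,
#' in mHz (0 when a cell has fewer than 2 events; the `(n-1)/span` form
#' avoids the edge bias of `n/duration`). Regularity is the coefficient
#' of variation of the inter-event intervals, `100 * sd / mean` (percent;
#' `NA` below 3 events). Cells with CV at or below
#' `regularity_threshold` are reported as regularly spiking.
#'
#' @param events a [detect_events()] result (or a list of event-time
#'   vectors)
#' @param epoch optional `c(start, end)` in seconds; only events inside
#'   are used (default: whole recording)
#' @param regularity_threshold CV threshold (percent) for calling a cell
#'   regular (default 50)
#' @return object of class `frequency_report`: data frame `cells`
#'   (cell_id, n_events, freq_mhz, cv_pct, regular), `population_freq_mhz`
#'   (mean over cells with >= 2 events), `regular_cells`
#' @export
frequency_and_cv <- function(events, epoch = NULL,
                             regularity_threshold = 50) {
  times <- if (inherits(events, "event_series")) events$times else events
  ids <- names(times) %||% paste0("cell_", seq_along(times))
  if (!is.null(epoch)) {
    stopifnot(length(epoch) == 2L, epoch[2L] > epoch[1L])
    times <- lapply(times, function(tt) tt[tt >= epoch[1L] & tt < epoch[2L]])
  }
  n <- lengths(times)
  freq <- vapply(times, function(tt) {
    if (length(tt) < 2L) return(0)
    1000 * (length(tt) - 1L) / (max(tt) - min(tt))
  }, numeric(1))
  cv <- vapply(times, function(tt) {
    if (length(tt) < 3L) return(NA_real_)
    iv <- diff(sort(tt))
    100 * sd(iv) / mean(iv)
  }, numeric(1))
  cells <- data.frame(cell_id = ids, n_events = as.integer(n),
                      freq_mhz = unname(freq), cv_pct = unname(cv),
                      regular = !is.na(cv) & cv <= regularity_threshold)
  structure(list(
    cells = cells,
    population_freq_mhz = if (any(freq > 0)) mean(freq[freq > 0])
                          else 0,
    regular_cells = cells$cell_id[cells$regular],
    epoch = epoch,
    regularity_threshold = regularity_threshold),
    class = "frequency_report")
}

#' @export
print.frequency_report <- function(x, ...) {
  cat(sprintf(paste0("<frequency_report> %d cell(s), population mean ",
                     "%.1f mHz, %d regular (CV <= %g%%)\n"),
              nrow(x$cells), x$population_freq_mhz,
              length(x$regular_cells), x$regularity_threshold))
  invisible(x)
}

#' Detect bursts in a rectified-smoothed population trace
#'
#' Intended for the output of [rectify_smooth()] on an integrated nerve
#' or population signal. Samples at or above `threshold` times the signal
#' maximum are grouped into bursts; above-threshold groups separated by
#' less than `min_burst_gap` seconds are merged. Each burst is stamped at
#' its peak.
#'
#' @param x processed 1-D signal
#' @param frame_interval sampling interval, s
#' @param threshold burst threshold as a fraction of the signal maximum
#'   (default 0.5)
#' @param min_burst_gap minimum below-threshold gap separating bursts, s
#'   (default 2)
#' @return list with `times` (burst peak times, s), `rate_per_min`,
#'   `cv_pct` (CV of inter-burst intervals, `NA` below 3 bursts)
#' @export
detect_bursts <- function(x, frame_interval, threshold = 0.5,
                          min_burst_gap = 2) {
  stopifnot(is.numeric(x), frame_interval > 0,
            threshold > 0, threshold <= 1)
  dur <- length(x) * frame_interval
  mx <- max(x)
  if (mx <= 0)
    return(list(times = numeric(0), rate_per_min = 0, cv_pct = NA_real_))
  above <- x >= threshold * mx
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) > 1L) {
    gap_frames <- max(1L, round(min_burst_gap / frame_interval))
    merged <- seg[1L, , drop = FALSE]
    for (i in 2L:nrow(seg)) {
      if (seg[i, 1L] - merged[nrow(merged), 2L] < gap_frames)
        merged[nrow(merged), 2L] <- seg[i, 2L]
      else merged <- rbind(merged, seg[i, ])
    }
    seg <- merged
  }
  times <- apply(seg, 1L, function(s) {
    idx <- s[1L]:s[2L]
    (idx[which.max(x[idx])] - 1L) * frame_interval
  })
  iv <- diff(times)
  list(times = as.numeric(times),
       rate_per_min = length(times) / dur * 60,
       cv_pct = if (length(iv) >= 2L) 100 * sd(iv) / mean(iv)
                else NA_real_)
}

#' Compare event statistics across epochs
#'
#' Computes per-cell frequencies in each epoch and the paired change
#' relative to the first (reference) epoch, plus population means. No
#' hypothesis testing is performed; this is a descriptive comparison
#' (e.g. control vs. drug vs. washout).
#'
#' @param events a [detect_events()] result (or list of event-time
#'   vectors)
#' @param epochs data frame with columns `start`, `end` (s) and optional
#'   `label`; epochs must not overlap and must have positive duration
#' @return object of class `epoch_comparison`: data frames `per_cell`
#'   (cell_id, epoch, freq_mhz, delta_mhz vs first epoch) and `population`
#'   (epoch, mean_freq_mhz, n_active)
#' @export
compare_epochs <- function(events, epochs) {
  epochs <- as.data.frame(epochs)
  stopifnot(nrow(epochs) >= 2L,
            all(c("start", "end") %in% names(epochs)))
  if (any(epochs$end <= epochs$start))
    stop("every epoch must have positive duration")
  so <- epochs[order(epochs$start), ]
  if (nrow(so) > 1L && any(so$start[-1L] < so$end[-nrow(so)] - 1e-9))
    warning("epochs overlap; frequencies are still reported per epoch")
  if (is.null(epochs$label))
    epochs$label <- paste0("epoch_", seq_len(nrow(epochs)))
  reports <- lapply(seq_len(nrow(epochs)), function(i)
    frequency_and_cv(events, epoch = c(epochs$start[i], epochs$end[i])))
  ref <- reports[[1L]]$cells$freq_mhz
  per_cell <- do.call(rbind, lapply(seq_along(reports), function(i) {
    ci <- reports[[i]]$cells
    data.frame(cell_id = ci$cell_id, epoch = epochs$label[i],
               freq_mhz = ci$freq_mhz, cv_pct = ci$cv_pct,
               delta_mhz = ci$freq_mhz - ref)
  }))
  population <- do.call(rbind, lapply(seq_along(reports), function(i) {
    ci <- reports[[i]]$cells
    data.frame(epoch = epochs$label[i],
               mean_freq_mhz = reports[[i]]$population_freq_mhz,
               n_active = sum(ci$n_events > 0L))
  }))
  structure(list(per_cell = per_cell, population = population,
                 epochs = epochs), class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat("<epoch_comparison>\n")
  print(x$population, row.names = FALSE)
  invisible(x)
}
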