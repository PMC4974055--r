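#' Sliding-window dF/F0 normalization
#'
#' Each trace is normalized individually: the baseline `F0(t)` is the mean
#' intensity within +/- `window_half_width` seconds of frame `t` (the
#' window is centered, includes the frame itself, and is truncated at the
#' recording edges), and the normalized value is
#' `(F(t) - F0(t)) / F0(t)`. A constant trace therefore maps to all zeros,
#' and the result is invariant under per-trace multiplicative gain.
#'
#' Cells whose baseline is not strictly positive at every frame cannot be
#' ratio-normalized; they are flagged, their rows set to `NA`, and they
#' are excluded from downstream correlation with a warning.
#'
#' @param traces a [trace_set()]
#' @param window_half_width baseline half-window, s (default 30: F0 is the
#'   average intensity over the 30 s before and after each time point)
#' @return a `norm_trace_set` (inherits `trace_set`) with dF/F0 values and
#'   a logical attribute-field `flagged` marking excluded cells
#' @export
normalize_dff <- function(traces, window_half_width = 30) {
  stopifnot(inherits(traces, "trace_set"), window_half_width > 0)
  w <- max(1L, round(window_half_width / traces$frame_interval))
  vals <- traces$values
  out <- vals
  flagged <- logical(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    f0 <- running_mean(vals[i, ], w)
    if (any(f0 <= 0)) {
      flagged[i] <- TRUE
      out[i, ] <- NA_real_
    } else {
      out[i, ] <- (vals[i, ] - f0) / f0
    }
  }
  if (any(flagged))
    warning(sum(flagged), " cell(s) with non-positive baseline flagged ",
            "and excluded: ", paste(traces$roi_ids[flagged], collapse = ", "))
  structure(list(values = out, frame_interval = traces$frame_interval,
                 roi_ids = traces$roi_ids,
                 roi_centroids = traces$roi_centroids,
                 flagged = flagged,
                 window_half_width = window_half_width),
            class = c("norm_trace_set", "trace_set"))
}

#' Detect calcium transient events
#'
#' Events are local maxima of the dF/F0 trace whose prominence above a
#' running baseline reaches `threshold_frac` (default 0.20, i.e. a minimum
#' 20% increase above baseline). The running baseline is the 10th
#' percentile of the normalized trace over a sliding window (default
#' 60 s), which tracks slow residual drift without following the
#' transients themselves. Maxima closer together than `min_separation`
#' are merged, keeping the larger peak. A cell is *active* if it has at
#' least one event.
#'
#' @param norm a [normalize_dff()] result
#' @param threshold_frac minimum dF/F0 increase above baseline (default 0.2)
#' @param min_separation minimum event spacing, s (default 2, shorter than
#'   the slowest transient decay)
#' @param baseline_window full width of the running-percentile baseline
#'   window, s (default 60)
#' @param baseline_quantile percentile used for the running baseline
#'   (default 0.1)
#' @return object of class `event_series`: list with `times` (per-cell
#'   numeric vectors of event times, s, strictly increasing), `active`
#'   (logical), `frame_interval`, `duration`
#' @export
detect_events <- function(norm, threshold_frac = 0.20, min_separation = 2,
                          baseline_window = 60, baseline_quantile = 0.1) {
  stopifnot(inherits(norm, "trace_set"), threshold_frac >= 0)
  dt <- norm$frame_interval
  vals <- norm$values
  nf <- ncol(vals)
  wb <- max(1L, round(baseline_window / 2 / dt))
  times <- vector("list", nrow(vals))
  names(times) <- norm$roi_ids
  for (i in seq_len(nrow(vals))) {
    x <- vals[i, ]
    if (anyNA(x)) { times[[i]] <- numeric(0); next }
    b <- running_quantile(x, wb, baseline_quantile)
    # local maxima (left-inclusive so plateau starts count once)
    is_pk <- c(FALSE, x[2:(nf - 1L)] >= x[1:(nf - 2L)] &
                 x[2:(nf - 1L)] > x[3:nf], FALSE)
    pk <- which(is_pk & (x - b) >= threshold_frac)
    if (length(pk) > 1L) {
      # greedy merge: keep the larger of any pair closer than min_separation
      keep <- integer(0)
      for (j in pk[order(x[pk], decreasing = TRUE)]) {
        if (!any(abs(j - keep) * dt < min_separation)) keep <- c(keep, j)
      }
      pk <- sort(keep)
    }
    times[[i]] <- (pk - 1L) * dt
  }
  structure(list(times = times,
                 active = lengths(times) > 0L,
                 frame_interval = dt,
                 duration = nf * dt),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d cell(s), %d active, %d events over %g s\n",
              length(x$times), sum(x$active), sum(lengths(x$times)),
              x$duration))
  invisible(x)
}

#' Write an event table to CSV
#'
#' @param events an [detect_events()] result
#' @param path output CSV path (columns `cell_id`, `event_time_s`)
#' @return `path`, invisibly
#' @export
write_events_csv <- function(events, path) {
  ids <- names(events$times) %||% as.character(seq_along(events$times))
  df <- data.frame(
    cell_id = rep(ids, lengths(events$times)),
    event_time_s = unlist(events$times, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Filter, rectify and smooth a population or nerve trace
#'
#' Standard conditioning of an integrated nerve/population signal before
#' burst detection: a 2nd-order Butterworth filter at `cutoff` Hz
#' (zero-phase, applied forward and backward), full-wave rectification,
#' then a centered moving average of width `smooth_window` seconds.
#'
#' The default is a 0.06 Hz low-pass, the printed setting of the original
#' nerve-recording workflow. Note that a 0.06 Hz *low*-pass attenuates
#' respiratory burst rhythms (~0.05-0.13 Hz); `mode = "high"` applies the
#' same corner as a high-pass (baseline removal), which is the reading
#' consistent with subsequent burst detection. Both are exposed.
#'
#' @param x numeric vector, uniformly sampled
#' @param frame_interval sampling interval, s
#' @param cutoff filter corner frequency, Hz (default 0.06); must be below
#'   the Nyquist frequency
#' @param mode `"low"` (default, as printed) or `"high"`
#' @param smooth_window moving-average width, s (default 1); must be at
#'   least one sample
#' @return processed signal, same length as `x`
#' @export
rectify_smooth <- function(x, frame_interval, cutoff = 0.06,
                           mode = c("low", "high"), smooth_window = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(x), frame_interval > 0, cutoff > 0)
  if (smooth_window < frame_interval)
    stop("smooth_window must be at least one sample (frame_interval)")
  nyq <- 1 / (2 * frame_interval)
  if (cutoff >= nyq)
    stop("cutoff must be below the Nyquist frequency ", nyq, " Hz")
  bf <- signal::butter(2, cutoff / nyq, type = mode)
  # filtfilt zero-pads, which leaves a large edge transient at corners
  # far below the signal band; filtering the mean-removed signal and
  # restoring the DC component through the filter's exact DC gain (1 for
  # low-pass, 0 for high-pass) avoids it
  m <- mean(x)
  y <- as.numeric(signal::filtfilt(bf, x - m))
  if (mode == "low") y <- y + m
  y <- abs(y)
  w <- max(1L, round(smooth_window / 2 / frame_interval))
  running_mean(y, w)
}

#' Extract ROIs and traces from an image stack
#'
#' Cells are located on the per-pixel standard deviation of fluorescence
#' over time: active cells flicker, so they stand out in the SD image.
#' The SD image is Gaussian-smoothed, thresholded automatically (Otsu's
#' histogram method), and connected components with area within
#' `[min_area, max_area]` pixels become ROIs. Each ROI's trace is the mean
#' intensity over its pixels in every frame.
#'
#' Requires the `EBImage` package (Bioconductor) for smoothing and
#' connected-component labelling.
#'
#' @param stack numeric array height x width x frames (see
#'   [read_stack_tiff()])
#' @param frame_interval frame interval, s
#' @param min_area,max_area admissible ROI area, pixels
#' @param smooth_sigma Gaussian smoothing SD for the SD image, pixels
#'   (0 disables smoothing)
#' @return a [trace_set()] with ROI centroids ((row, col), 0-based); empty
#'   (0 ROIs) with a warning when nothing is found
#' @export
extract_rois_and_traces <- function(stack, frame_interval,
                                    min_area = 4, max_area = Inf,
                                    smooth_sigma = 1) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3L] >= 2L)
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("extract_rois_and_traces requires the EBImage package")
  h <- dim(stack)[1L]; w <- dim(stack)[2L]; nf <- dim(stack)[3L]
  flat <- matrix(stack, h * w, nf)
  mu <- rowMeans(flat)
  sdimg <- matrix(sqrt(pmax(rowMeans(flat^2) - mu^2, 0) * nf / (nf - 1L)),
                  h, w)
  if (max(sdimg) <= 0)
    return(empty_roi_set(frame_interval))
  img <- sdimg / max(sdimg)
  if (smooth_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = smooth_sigma))
  img <- pmin(pmax(img, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(img))
  labels <- as.matrix(EBImage::bwlabel(EBImage::Image(img > thr)))
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0L)
    return(empty_roi_set(frame_interval))
  vals <- matrix(0, length(keep), nf)
  centroids <- matrix(0, length(keep), 2L)
  for (j in seq_along(keep)) {
    px <- which(labels == keep[j])
    vals[j, ] <- colMeans(flat[px, , drop = FALSE])
    centroids[j, ] <- c(mean((px - 1L) %% h), mean((px - 1L) %/% h))
  }
  trace_set(vals, frame_interval,
            roi_ids = paste0("roi_", seq_along(keep)),
            roi_centroids = centroids)
}

empty_roi_set <- function(frame_interval) {
  warning("no ROI found; returning an empty trace set")
  trace_set(matrix(numeric(0), 0L, 2L), frame_interval,
            roi_ids = character(0))
}

#' Extract traces using an externally curated ROI label image
#'
#' Reproduces manually curated segmentations: `labels` assigns each pixel
#' an ROI id (0 = background), e.g. read from a label-image TIFF.
#'
#' @param stack numeric array height x width x frames
#' @param labels integer matrix, same height/width as `stack`
#' @param frame_interval frame interval, s
#' @return a [trace_set()]
#' @export
rois_from_labels <- function(stack, labels, frame_interval) {
  stopifnot(length(dim(stack)) == 3L,
            all(dim(labels) == dim(stack)[1:2]))
  labels <- round(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) return(empty_roi_set(frame_interval))
  h <- dim(stack)[1L]; nf <- dim(stack)[3L]
  flat <- matrix(stack, h * dim(stack)[2L], nf)
  vals <- t(vapply(ids, function(id)
    colMeans(flat[which(labels == id), , drop = FALSE]), numeric(nf)))
  centroids <- t(vapply(ids, function(id) {
    px <- which(labels == id)
    c(mean((px - 1L) %% h), mean((px - 1L) %/% h))
  }, numeric(2)))
  trace_set(vals, frame_interval, roi_ids = paste0("roi_", ids),
            roi_centroids = centroids)
}
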