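#' Construct a trace set
#'
#' The central container of the pipeline: one fluorescence intensity trace
#' per ROI (cell), sampled on a uniform frame grid. Frame `i` (0-based) is
#' at time `i * frame_interval` seconds.
#'
#' @param values numeric matrix, cells (rows) x frames (columns)
#' @param frame_interval frame interval in seconds; the supported imaging
#'   regime is 0.1-2 s per frame, values outside it are accepted with a
#'   warning
#' @param roi_ids character labels, one per row
#' @param roi_centroids optional matrix of pixel coordinates (row, col),
#'   0-based, one row per ROI
#' @return object of class `trace_set`
#' @export
trace_set <- function(values, frame_interval,
                      roi_ids = NULL, roi_centroids = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("a trace set needs at least 2 frames")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive number of seconds")
  if (nrow(values) > 0L && !all(is.finite(values)))
    stop("trace values must be finite")
  if (frame_interval < 0.1 || frame_interval > 2)
    warning("frame_interval ", frame_interval,
            " s is outside the usual 0.1-2 s imaging range")
  if (is.null(roi_ids)) roi_ids <- paste0("cell_", seq_len(nrow(values)))
  if (length(roi_ids) != nrow(values))
    stop("roi_ids length must match the number of rows")
  rownames(values) <- roi_ids
  if (!is.null(roi_centroids)) {
    roi_centroids <- as.matrix(roi_centroids)
    stopifnot(nrow(roi_centroids) == nrow(values), ncol(roi_centroids) == 2L)
  }
  structure(list(values = values, frame_interval = frame_interval,
                 roi_ids = roi_ids, roi_centroids = roi_centroids),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<%s> %d ROI(s) x %d frames, frame interval %g s (%.1f s)\n",
              class(x)[1L], nrow(x$values), ncol(x$values),
              x$frame_interval, ncol(x$values) * x$frame_interval))
  invisible(x)
}

#' @export
dim.trace_set <- function(x) dim(x$values)

#' Frame time stamps of a trace set
#' @param x a `trace_set`
#' @return numeric vector of frame times in seconds (first frame at 0)
#' @export
frame_times <- function(x) (seq_len(ncol(x$values)) - 1L) * x$frame_interval

#' Read a trace table from CSV
#'
#' Expected layout: first column `time_s` (uniform grid starting at 0),
#' one further column per ROI.
#'
#' @param path CSV file path
#' @return a [trace_set()]
#' @export
read_traces_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "time_s")
    stop("trace CSV must have a first column named time_s")
  tt <- df[[1L]]
  dt <- diff(tt)
  if (length(dt) < 1L || any(abs(dt - dt[1L]) > 1e-6 * max(dt[1L], 1)))
    stop("time_s must be a uniform grid")
  vals <- t(as.matrix(df[, -1L, drop = FALSE]))
  trace_set(vals, frame_interval = dt[1L], roi_ids = names(df)[-1L])
}

#' Write a trace set to CSV
#'
#' Inverse of [read_traces_csv()]: first column `time_s`, one column per ROI.
#'
#' @param x a `trace_set`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_traces_csv <- function(x, path) {
  df <- data.frame(time_s = frame_times(x), check.names = FALSE)
  for (i in seq_len(nrow(x$values))) df[[x$roi_ids[i]]] <- x$values[i, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a single-channel TIFF stack as an array
#'
#' @param path TIFF file with one grayscale image per frame
#' @return numeric array height x width x frames
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L]  # ignore extra channels
    f
  })
  array(unlist(frames), dim = c(dim(frames[[1L]]), length(frames)))
}

#' Write an image stack to a single-channel TIFF
#'
#' Values are rescaled to the unit interval (the TIFF writer's range);
#' downstream trace extraction is invariant to this global affine rescale.
#'
#' @param stack numeric array height x width x frames
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3L)
  lo <- min(stack); hi <- max(stack)
  sc <- if (hi > lo) (stack - lo) / (hi - lo) else stack * 0
  tiff::writeTIFF(lapply(seq_len(dim(sc)[3L]), function(i) sc[, , i]),
                  path, bits.per.sample = 16L)
  invisible(path)
}
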