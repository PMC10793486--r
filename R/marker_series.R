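#' Construct a marker series
#'
#' Holds synchronously sampled 3D positions of the hand and shoulder markers
#' together with per-frame tracking quality (reprojection error in pixels and
#' number of cameras that saw the marker) and a validity mask. Positions are
#' in meters; time is uniformly spaced at `frame_rate`.
#'
#' @param time Frame times (s), uniformly spaced.
#' @param hand,shoulder n x 3 matrices of marker positions (m).
#' @param reprojection_error Per-frame reprojection error (pixels).
#' @param n_cameras Per-frame camera count.
#' @param valid Optional logical validity mask (default all `TRUE`).
#' @param frame_rate Sampling rate (Hz); inferred from `time` if missing.
#' @return A `marker_series` object (a list with matrix fields).
#' @export
marker_series <- function(time, hand, shoulder,
                          reprojection_error = rep(0, length(time)),
                          n_cameras = rep(2L, length(time)),
                          valid = rep(TRUE, length(time)),
                          frame_rate = NULL) {
  n <- length(time)
  hand <- as_xyz(hand, n, "hand")
  shoulder <- as_xyz(shoulder, n, "shoulder")
  dt <- diff(time)
  if (n > 1 && (max(dt) - min(dt)) > 1e-9) {
    stop("time must be uniformly spaced (within 1e-9 s)")
  }
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(dt)
  bad <- valid & (!is.finite(rowSums(hand)) | !is.finite(rowSums(shoulder)))
  if (any(bad)) stop("non-finite positions at frames marked valid")
  structure(list(
    time = as.numeric(time),
    hand = hand,
    shoulder = shoulder,
    reprojection_error = as.numeric(reprojection_error),
    n_cameras = as.integer(n_cameras),
    valid = as.logical(valid),
    interpolated = rep(FALSE, n),
    frame_rate = frame_rate
  ), class = "marker_series")
}

as_xyz <- function(m, n, what) {
  m <- as.matrix(m)
  if (nrow(m) != n || ncol(m) != 3) {
    stop(what, " must be an n x 3 matrix matching length(time)")
  }
  colnames(m) <- c("x", "y", "z")
  m
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("marker_series: %d frames at %.4g Hz (%.1f s), %d%% valid\n",
              length(x$time), x$frame_rate, diff(range(x$time)),
              round(100 * mean(x$valid))))
  invisible(x)
}

n_frames <- function(series) length(series$time)

#' Write / read a marker series as tidy CSV
#'
#' Columns: time, hand_x/y/z, shoulder_x/y/z, reprojection_error, n_cameras,
#' valid, interpolated. The frame rate is recovered from the time column.
#'
#' @param series A [marker_series()].
#' @param path File path.
#' @return `write_marker_csv` returns `path` invisibly; `read_marker_csv`
#'   returns a `marker_series`.
#' @export
write_marker_csv <- function(series, path) {
  df <- data.frame(
    time = series$time,
    hand_x = series$hand[, 1], hand_y = series$hand[, 2],
    hand_z = series$hand[, 3],
    shoulder_x = series$shoulder[, 1], shoulder_y = series$shoulder[, 2],
    shoulder_z = series$shoulder[, 3],
    reprojection_error = series$reprojection_error,
    n_cameras = series$n_cameras,
    valid = series$valid,
    interpolated = series$interpolated
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- marker_series(
    time = df$time,
    hand = cbind(df$hand_x, df$hand_y, df$hand_z),
    shoulder = cbind(df$shoulder_x, df$shoulder_y, df$shoulder_z),
    reprojection_error = df$reprojection_error,
    n_cameras = df$n_cameras,
    valid = df$valid
  )
  out$interpolated <- df$interpolated
  out
}

# Runs of TRUE in a logical vector as a two-column matrix [start, end]
# (inclusive frame indices).
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
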