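#' Lead-lag window specification for trajectory samples
#'
#' A kinematic sample centered at spike time `t0` spans the window
#' `[t0 - lead_ms, t0 + lag_ms]`. Velocity trajectories are taken on a 40 Hz
#' grid (25 ms spacing) that is left-aligned within the window and excludes
#' the right endpoint, so a window of duration `d` ms contributes `d / 25`
#' time points and `3 * d / 25` x-y-z velocity terms. The canonical
#' `[-100, +300]` ms window therefore yields 16 time points and 48 velocity
#' terms. `lead_ms` may be negative, which places the whole window after the
#' spike sample (e.g. `lead_lag(-100, 150)` is the brief `[+100, +150]` ms
#' window of the velocity and short-kinematics models, 2 time points).
#'
#' @param lead_ms Time (ms) the window extends before the spike sample;
#'   negative values shift the window start after the spike sample.
#' @param lag_ms Time (ms) the window extends after the spike sample.
#' @param dt_ms Trajectory grid spacing in ms (default 25, i.e. 40 Hz).
#' @return A `lead_lag` object with fields `lead_ms`, `lag_ms`, `dt_ms`.
#' @examples
#' spec <- lead_lag(100, 300)
#' n_traj_points(spec)  # 16
#' @export
lead_lag <- function(lead_ms, lag_ms, dt_ms = 25) {
  duration <- lead_ms + lag_ms
  if (duration <= 0) stop("lead_ms + lag_ms must be positive")
  if (duration %% dt_ms != 0) {
    stop("window duration (", duration, " ms) must be a multiple of dt_ms (",
         dt_ms, " ms)")
  }
  structure(list(lead_ms = lead_ms, lag_ms = lag_ms, dt_ms = dt_ms),
            class = "lead_lag")
}

#' @export
print.lead_lag <- function(x, ...) {
  cat(sprintf("lead-lag window [%+d, %+d] ms, %d points at %d ms\n",
              -x$lead_ms, x$lag_ms, n_traj_points(x), x$dt_ms))
  invisible(x)
}

#' Number of trajectory time points in a lead-lag window
#' @param spec A [lead_lag()] object.
#' @return Integer count of 40 Hz grid points.
#' @export
n_traj_points <- function(spec) {
  as.integer((spec$lead_ms + spec$lag_ms) / spec$dt_ms)
}

#' Trajectory grid offsets relative to the sample center, in seconds
#' @param spec A [lead_lag()] object.
#' @return Numeric vector of offsets (s), left-aligned, right endpoint excluded.
#' @export
traj_offsets <- function(spec) {
  n <- n_traj_points(spec)
  (-spec$lead_ms + spec$dt_ms * (seq_len(n) - 1)) / 1000
}

#' Default lead-lag sweep
#'
#' Seventeen windows of 300-500 ms duration spanning all-lead to all-lag in
#' 50 ms offsets; the exact membership is configurable, this is the default
#' grid used for the sweep analysis.
#'
#' @return A list of [lead_lag()] objects.
#' @export
default_leadlag_sweep <- function() {
  grid <- list()
  for (dur in c(300, 400, 500)) {
    for (lead in seq(dur, 0, by = -50)) {
      grid[[length(grid) + 1L]] <- lead_lag(lead, dur - lead)
    }
  }
  # 7 + 9 + 11 = 27 candidates; keep a 17-member subset spanning the range:
  # all 300 ms (7), the odd-index 400 ms (5) and 500 ms (5) windows.
  keep <- c(seq_len(7), 7 + seq(1, 9, by = 2), 16 + seq(1, 11, by = 2)[1:5])
  grid[keep]
}

leadlag_label <- function(spec) {
  sprintf("[%+d,%+d]ms", -spec$lead_ms, spec$lag_ms)
}
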