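#' Extract paired kinematic/spike samples from reach segments
#'
#' Sample centers `t0` are placed every `step_ms` within each reach segment
#' such that the full kinematic window `[t0 - lead, t0 + lag]` fits inside
#' the segment. Each sample holds the hand velocity trajectory on the 40 Hz
#' grid (x-y-z interleaved per time point), the mean shoulder-referenced hand
#' position over the same grid, the per-unit spike count in the 10 ms bin
#' containing `t0`, and the per-unit binary firing states of that bin
#' (coincident, `S0`) and the preceding bin (leading, `S1`). Spike bins are
#' anchored at session time 0; the response bin is the bin containing `t0`.
#'
#' @param series A cleaned, smoothed [marker_series()].
#' @param velocity Velocity matrix from [hand_velocity()].
#' @param spike_times List of per-unit spike-time vectors (s).
#' @param segments Segments from [segment_reaches()] (after
#'   [assign_reach_sets()] if reach-set labels are needed downstream).
#' @param spec A [lead_lag()] window.
#' @param step_ms Spacing of sample centers in ms (default 30).
#' @param bin Spike sampling bin width in s (default 0.010).
#' @param session_span Session span for spike binning; defaults to
#'   `c(0, max(series$time) + 1/frame_rate)`.
#' @return A `kinematic_sample_set`: list with matrices `V` (samples x
#'   3*n_traj_points), `P` (samples x 3), `counts`, `S0`, `S1` (samples x
#'   units), vectors `t0`, `segment`, `reach_set`, and the `spec`.
#' @export
extract_samples <- function(series, velocity, spike_times, segments, spec,
                            step_ms = 30, bin = 0.010, session_span = NULL) {
  stopifnot(inherits(spec, "lead_lag"))
  if (is.null(session_span)) {
    session_span <- c(0, max(series$time) + 1 / series$frame_rate)
  }
  bc <- bin_spike_counts(spike_times, session_span, bin)
  states <- (bc$counts > 0L) + 0L
  n_units <- length(spike_times)

  lead_s <- spec$lead_ms / 1000
  lag_s <- spec$lag_ms / 1000
  step_s <- step_ms / 1000
  offs <- traj_offsets(spec)

  t0_all <- numeric(0); seg_all <- integer(0); set_all <- character(0)
  for (k in seq_len(nrow(segments))) {
    a <- segments$start_t[k]
    b <- segments$stop_t[k]
    lo <- a + max(lead_s, 0)
    hi <- b - max(lag_s, 0)
    if (hi < lo - 1e-9) next
    t0 <- seq(lo, hi + 1e-9, by = step_s)
    t0_all <- c(t0_all, t0)
    seg_all <- c(seg_all, rep(k, length(t0)))
    set_all <- c(set_all, rep(segments$set_label[k], length(t0)))
  }
  p <- n_traj_points(spec)
  if (length(t0_all) == 0) {
    return(empty_sample_set(spec, p, n_units))
  }
  # spike responses are read from the 10 ms bin containing t0; a preceding
  # bin must exist for the leading states S1
  ib <- floor((t0_all - session_span[1]) / bin + 1e-9) + 1L
  keep <- ib >= 2L & ib <= ncol(states)
  t0_all <- t0_all[keep]; seg_all <- seg_all[keep]; set_all <- set_all[keep]
  ib <- ib[keep]
  if (length(t0_all) == 0) return(empty_sample_set(spec, p, n_units))

  kd <- kinematic_design(series, velocity, t0_all, spec)
  V <- kd$V; P <- kd$P

  structure(list(
    V = V, P = P,
    counts = t(bc$counts[, ib, drop = FALSE]),
    S0 = t(states[, ib, drop = FALSE]),
    S1 = t(states[, ib - 1L, drop = FALSE]),
    t0 = t0_all, segment = seg_all, reach_set = set_all,
    spec = spec
  ), class = "kinematic_sample_set")
}

# Velocity-trajectory and mean-position design blocks for arbitrary sample
# centers. Velocities and shoulder-referenced positions are linearly
# interpolated from the (valid frames of the) marker series at the 40 Hz
# grid times of the window; shared by extract_samples() and the spike
# simulator so the generative and fitted designs have identical layout.
kinematic_design <- function(series, velocity, t0, spec) {
  p <- n_traj_points(spec)
  offs <- traj_offsets(spec)
  rel <- series$hand - series$shoulder
  ok <- series$valid & is.finite(velocity[, 1])
  ns <- length(t0)
  V <- matrix(NA_real_, ns, 3 * p)
  P <- matrix(NA_real_, ns, 3)
  tim <- outer(t0, offs, `+`)
  for (j in 1:3) {
    vj <- stats::approx(series$time[ok], velocity[ok, j], xout = tim,
                        rule = 2)$y
    V[, seq(j, 3 * p, by = 3)] <- matrix(vj, ns, p)
    pj <- stats::approx(series$time[ok], rel[ok, j], xout = tim, rule = 2)$y
    P[, j] <- rowMeans(matrix(pj, ns, p))
  }
  colnames(V) <- paste0("v", rep(c("x", "y", "z"), p), "_t",
                        rep(seq_len(p), each = 3))
  colnames(P) <- c("px", "py", "pz")
  list(V = V, P = P)
}

empty_sample_set <- function(spec, p, n_units) {
  structure(list(
    V = matrix(numeric(0), 0, 3 * p), P = matrix(numeric(0), 0, 3),
    counts = matrix(integer(0), 0, n_units),
    S0 = matrix(integer(0), 0, n_units), S1 = matrix(integer(0), 0, n_units),
    t0 = numeric(0), segment = integer(0), reach_set = character(0),
    spec = spec
  ), class = "kinematic_sample_set")
}

#' @export
print.kinematic_sample_set <- function(x, ...) {
  cat(sprintf(
    "kinematic_sample_set: %d samples x %d velocity terms (%s), %d units\n",
    nrow(x$V), ncol(x$V), leadlag_label(x$spec), ncol(x$counts)))
  invisible(x)
}

n_samples <- function(samples) nrow(samples$V)

# Subset a sample set by row index, preserving structure.
subset_samples <- function(samples, idx) {
  out <- samples
  for (f in c("V", "P", "counts", "S0", "S1")) {
    out[[f]] <- samples[[f]][idx, , drop = FALSE]
  }
  for (f in c("t0", "segment", "reach_set")) out[[f]] <- samples[[f]][idx]
  out
}
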