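#' Clean marker tracking using reprojection error and camera count
#'
#' Frames with reprojection error above `err_thresh` pixels or fewer than
#' `min_cams` cameras are invalidated. Remaining valid runs strictly shorter
#' than 50 ms are also invalidated (brief islands of good tracking inside bad
#' stretches are untrustworthy); invalid gaps strictly shorter than 200 ms
#' that are flanked by valid data are then filled by linear interpolation and
#' marked as interpolated. Runs of exactly 50 ms are kept and gaps of exactly
#' 200 ms are not filled.
#'
#' @param series A [marker_series()].
#' @param err_thresh Reprojection error threshold in pixels (default 20; 35
#'   is an appropriate alternative for noisier camera setups).
#' @param min_cams Minimum number of cameras tracking the marker (default 2).
#' @param min_run_s,max_gap_s Run/gap duration rules in seconds.
#' @return A cleaned `marker_series` with updated `valid` and `interpolated`.
#' @export
clean_tracking <- function(series, err_thresh = 20, min_cams = 2,
                           min_run_s = 0.050, max_gap_s = 0.200) {
  stopifnot(inherits(series, "marker_series"))
  if (err_thresh <= 0) stop("err_thresh must be positive")
  if (min_cams < 2) stop("min_cams must be at least 2")
  dt <- 1 / series$frame_rate
  valid <- series$valid &
    series$reprojection_error <= err_thresh &
    series$n_cameras >= min_cams

  # drop valid runs strictly shorter than min_run_s
  runs <- logical_runs(valid)
  if (nrow(runs) > 0) {
    len_s <- (runs[, "end"] - runs[, "start"] + 1L) * dt
    for (k in which(len_s < min_run_s - 1e-12)) {
      valid[runs[k, "start"]:runs[k, "end"]] <- FALSE
    }
  }

  interpolated <- series$interpolated
  # fill interior invalid gaps strictly shorter than max_gap_s
  gaps <- logical_runs(!valid)
  n <- n_frames(series)
  for (k in seq_len(nrow(gaps))) {
    a <- gaps[k, "start"]; b <- gaps[k, "end"]
    if (a == 1L || b == n) next           # not flanked on both sides
    if ((b - a + 1L) * dt >= max_gap_s - 1e-12) next
    idx <- a:b
    w <- (series$time[idx] - series$time[a - 1L]) /
      (series$time[b + 1L] - series$time[a - 1L])
    for (f in c("hand", "shoulder")) {
      series[[f]][idx, ] <- (1 - w) %o% series[[f]][a - 1L, ] +
        w %o% series[[f]][b + 1L, ]
    }
    valid[idx] <- TRUE
    interpolated[idx] <- TRUE
  }

  if (!any(valid)) warning("cleaning left no valid frames")
  series$valid <- valid
  series$interpolated <- interpolated
  series
}

#' Savitzky-Golay smoothing of marker positions
#'
#' Applies a 3rd-order Savitzky-Golay filter with a 70 ms window to each
#' coordinate of each marker, independently within each valid run. The window
#' length in frames is `round(0.070 * frame_rate)` forced odd (rounded up).
#' Run boundaries are handled by the filter's polynomial-fit truncation (no
#' wrap-around); valid runs shorter than the window are left unsmoothed with
#' a warning. An order-3 filter reproduces cubic polynomials exactly.
#'
#' @param series A [marker_series()], ideally after [clean_tracking()].
#' @param window_s Filter window length in seconds (default 0.070).
#' @param order Polynomial order (default 3).
#' @return The smoothed `marker_series`.
#' @export
smooth_series <- function(series, window_s = 0.070, order = 3) {
  stopifnot(inherits(series, "marker_series"))
  wl <- round(window_s * series$frame_rate)
  if (wl %% 2 == 0) wl <- wl + 1L
  if (wl < 5) stop("smoothing window must be at least 5 frames")
  runs <- logical_runs(series$valid)
  short <- 0L
  for (k in seq_len(nrow(runs))) {
    idx <- runs[k, "start"]:runs[k, "end"]
    if (length(idx) < wl) { short <- short + 1L; next }
    for (f in c("hand", "shoulder")) {
      for (j in 1:3) {
        series[[f]][idx, j] <- signal::sgolayfilt(series[[f]][idx, j],
                                                  p = order, n = wl)
      }
    }
  }
  if (short > 0) {
    warning(short, " valid run(s) shorter than the filter window were left unsmoothed")
  }
  series
}

#' Shoulder-referenced hand velocity
#'
#' Subtracts the shoulder marker from the hand marker to isolate hand
#' movement from postural changes, then differentiates by central differences
#' (one-sided at the ends of each valid run). Invalid frames propagate as NA.
#'
#' @param series A smoothed [marker_series()].
#' @return n x 3 velocity matrix (m/s) with NA outside valid runs.
#' @export
hand_velocity <- function(series) {
  stopifnot(inherits(series, "marker_series"))
  rel <- series$hand - series$shoulder
  v <- matrix(NA_real_, n_frames(series), 3,
              dimnames = list(NULL, c("x", "y", "z")))
  fr <- series$frame_rate
  runs <- logical_runs(series$valid)
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, "start"]; b <- runs[k, "end"]
    if (b - a < 1L) next
    idx <- a:b
    seg <- rel[idx, , drop = FALSE]
    m <- nrow(seg)
    dv <- matrix(0, m, 3)
    if (m > 2) dv[2:(m - 1), ] <- (seg[3:m, ] - seg[1:(m - 2), ]) * fr / 2
    dv[1, ] <- (seg[2, ] - seg[1, ]) * fr
    dv[m, ] <- (seg[m, ] - seg[m - 1, ]) * fr
    v[idx, ] <- dv
  }
  v
}

#' Segment reaches from hand kinematics
#'
#' Reaches are identified as local maxima of the (shoulder-referenced) hand
#' y-position whose prominence exceeds `min_peak_prominence`; each candidate
#' extends backward and forward from its peak to the nearest frames where the
#' hand speed falls below `speed_thresh`. Overlapping candidates are merged,
#' keeping the highest peak. Segments are half-open frame intervals
#' `[start_idx, stop_idx)`.
#'
#' @param series A cleaned, smoothed [marker_series()].
#' @param velocity Optional velocity matrix from [hand_velocity()]
#'   (recomputed if missing).
#' @param speed_thresh Speed threshold (m/s) marking movement onset/offset
#'   (default 0.05).
#' @param min_peak_prominence Minimum y-peak prominence in meters
#'   (default 0.02).
#' @return A data.frame with columns `start_idx`, `stop_idx`, `peak_idx`,
#'   `start_t`, `stop_t`, `set_label` (initially "unassigned"); zero rows if
#'   no peaks are found.
#' @export
segment_reaches <- function(series, velocity = NULL, speed_thresh = 0.05,
                            min_peak_prominence = 0.02) {
  stopifnot(inherits(series, "marker_series"))
  if (is.null(velocity)) velocity <- hand_velocity(series)
  y <- series$hand[, 2] - series$shoulder[, 2]
  y[!series$valid] <- NA
  speed <- sqrt(rowSums(velocity^2))
  n <- n_frames(series)

  yy <- y
  yy[is.na(yy)] <- min(yy, na.rm = TRUE)  # NA frames can't host a peak
  peaks <- peak_prominences(yy, min_peak_prominence)
  empty <- data.frame(start_idx = integer(), stop_idx = integer(),
                      peak_idx = integer(), start_t = numeric(),
                      stop_t = numeric(), set_label = character())
  if (nrow(peaks) == 0) return(empty)

  # movement mask with brief still gaps closed: a reach decelerates through
  # the speed threshold around the y-peak (hold between extension and
  # retraction), so the extension and retraction bouts are bridged when the
  # still stretch between them is shorter than max_still_s
  fast <- is.finite(speed) & speed >= speed_thresh
  gaps <- logical_runs(!fast)
  max_still <- round(0.4 * series$frame_rate)
  for (k in seq_len(nrow(gaps))) {
    a <- gaps[k, "start"]; b <- gaps[k, "end"]
    if (a > 1L && b < n && (b - a + 1L) <= max_still) fast[a:b] <- TRUE
  }
  runs <- logical_runs(fast)
  if (nrow(runs) == 0) return(empty)
  # each prominent y-peak must sit inside a movement run
  segs <- lapply(seq_len(nrow(peaks)), function(k) {
    p <- peaks$index[k]
    r <- which(runs[, "start"] <= p & runs[, "end"] >= p)
    if (!length(r)) return(NULL)  # peak without movement: not a reach
    c(start = unname(runs[r, "start"]), stop = unname(runs[r, "end"]) + 1L,
      peak = p)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs)) return(empty)
  segs <- segs[order(segs[, "start"]), , drop = FALSE]

  # merge overlapping candidates, keeping the highest peak
  merged <- list(segs[1, ])
  for (k in seq_len(nrow(segs))[-1]) {
    last <- merged[[length(merged)]]
    cur <- segs[k, ]
    if (cur["start"] < last["stop"]) {
      keep_peak <- if (yy[cur["peak"]] > yy[last["peak"]]) cur["peak"] else last["peak"]
      merged[[length(merged)]] <- c(start = unname(last["start"]),
                                    stop = unname(max(last["stop"], cur["stop"])),
                                    peak = unname(keep_peak))
    } else {
      merged[[length(merged) + 1L]] <- cur
    }
  }
  m <- do.call(rbind, merged)
  data.frame(
    start_idx = as.integer(m[, "start"]),
    stop_idx = as.integer(m[, "stop"]),
    peak_idx = as.integer(m[, "peak"]),
    start_t = series$time[m[, "start"]],
    stop_t = series$time[pmin(m[, "stop"], n)],
    set_label = "unassigned"
  )
}

#' Randomly assign reach segments to two sets
#'
#' A uniformly random half of the segments (floor/ceil split for odd counts)
#' is labeled `reachSet1` and the rest `reachSet2`. Deterministic under
#' `seed`. With fewer than two segments all stay unassigned with a warning.
#'
#' @param segments Data frame from [segment_reaches()].
#' @param seed Integer seed.
#' @return The segments with `set_label` filled in.
#' @export
assign_reach_sets <- function(segments, seed) {
  n <- nrow(segments)
  if (n < 2) {
    warning("fewer than 2 segments; all left unassigned")
    return(segments)
  }
  set1 <- local_seed(seed, sample.int(n, n %/% 2))
  segments$set_label <- "reachSet2"
  segments$set_label[set1] <- "reachSet1"
  segments
}

# Local maxima of y whose topographic prominence reaches min_prom: walking
# outward from a candidate peak, a side is "based" once the terrain drops to
# y[peak] - min_prom before any strictly higher sample is met (array edges
# count as bases). Prominence >= min_prom iff both sides are based, which
# permits early exit and keeps the scan fast on long, wandering series.
peak_prominences <- function(y, min_prom) {
  n <- length(y)
  empty <- data.frame(index = integer(), height = numeric())
  if (n < 3) return(empty)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(cand)) return(empty)
  based <- function(i, step) {
    floor_y <- y[i] - min_prom
    j <- i + step
    while (j >= 1L && j <= n) {
      if (y[j] > y[i]) return(FALSE)
      if (y[j] <= floor_y) return(TRUE)
      j <- j + step
    }
    TRUE
  }
  ok <- vapply(cand, function(i) based(i, -1L) && based(i, 1L), logical(1))
  data.frame(index = cand[ok], height = y[cand[ok]])
}

# Evaluate expr with a temporary RNG state seeded at `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
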