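#' Integrate a preferred velocity trajectory into a pathlet
#'
#' Treats the fitted velocity coefficients `k` as instantaneous 3D velocities
#' on the trajectory grid and integrates them in time (rectangle rule,
#' step `dt`) to obtain the unit's preferred hand path. Integration runs
#' forward from the sample center `t0` for lag-side grid points and backward
#' for lead-side points, so the path passes through the origin at `t0`. Only
#' the velocity coefficients contribute; position coefficients are not
#' integrated.
#'
#' @param k Velocity coefficient vector, x-y-z interleaved per time point
#'   (length `3 * n_traj_points(spec)`).
#' @param spec The [lead_lag()] window the coefficients were fitted with.
#' @return A `pathlet`: list with `positions` ((n_points + 1) x 3, origin at
#'   the `t0` anchor), `times` (s, relative to `t0`), `lead_part`/`lag_part`
#'   (row index ranges), `spec`.
#' @export
integrate_pathlet <- function(k, spec) {
  p <- n_traj_points(spec)
  if (length(k) != 3 * p) {
    stop("k has length ", length(k), "; expected ", 3 * p, " for ",
         leadlag_label(spec))
  }
  V <- matrix(k, ncol = 3, byrow = TRUE)      # one 3-vector per grid point
  dt <- spec$dt_ms / 1000
  g <- traj_offsets(spec)                     # grid times rel. t0
  lead_idx <- which(g < 0)
  lag_idx <- which(g >= 0)

  # forward from t0: position after consuming each lag velocity
  fwd <- if (length(lag_idx)) apply(V[lag_idx, , drop = FALSE] * dt, 2,
                                    cumsum) else NULL
  if (!is.null(fwd) && length(lag_idx) == 1) fwd <- matrix(fwd, 1, 3)
  # backward from t0: position before each lead velocity (reverse cumsum)
  bwd <- if (length(lead_idx)) {
    b <- apply(V[rev(lead_idx), , drop = FALSE] * dt, 2, cumsum)
    if (length(lead_idx) == 1) b <- matrix(b, 1, 3)
    -b[rev(seq_len(nrow(b))), , drop = FALSE]
  } else NULL

  positions <- rbind(bwd, c(0, 0, 0), fwd)
  colnames(positions) <- c("x", "y", "z")
  times <- c(g[lead_idx], if (length(lag_idx)) c(0, g[lag_idx] + dt) else 0)
  structure(list(
    positions = positions,
    times = times,
    lead_part = seq_along(lead_idx),
    lag_part = length(lead_idx) + 1 + seq_along(lag_idx),
    spec = spec
  ), class = "pathlet")
}

#' @export
print.pathlet <- function(x, ...) {
  cat(sprintf("pathlet (%s): %d positions, extent %.3g\n",
              leadlag_label(x$spec), nrow(x$positions),
              max(abs(x$positions))))
  invisible(x)
}

#' Pearson correlation between two pathlets
#'
#' Correlates the flattened position sequences (x, y, z concatenated,
#' excluding the fixed origin anchor). Invariant to positive rescaling of
#' either pathlet. With `on = "coefficients"` the raw velocity coefficient
#' vectors are correlated instead.
#'
#' @param p1,p2 [integrate_pathlet()] results with identical specs (or, for
#'   `on = "coefficients"`, raw coefficient vectors of equal length).
#' @param on `"positions"` (default) or `"coefficients"`.
#' @return List with `r` and `defined` (`FALSE` for a zero-variance pathlet).
#' @export
pathlet_correlation <- function(p1, p2, on = c("positions", "coefficients")) {
  on <- match.arg(on)
  if (on == "positions") {
    stopifnot(inherits(p1, "pathlet"), inherits(p2, "pathlet"))
    if (!identical(unclass(p1$spec), unclass(p2$spec))) {
      stop("pathlets must share the same lead-lag spec")
    }
    anchor <- length(p1$lead_part) + 1L
    a <- as.numeric(p1$positions[-anchor, ])
    b <- as.numeric(p2$positions[-anchor, ])
  } else {
    a <- as.numeric(if (inherits(p1, "pathlet")) stop("pass raw k") else p1)
    b <- as.numeric(p2)
    if (length(a) != length(b)) stop("coefficient vectors differ in length")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, defined = FALSE))
  }
  list(r = stats::cor(a, b), defined = TRUE)
}

#' Pairwise pathlet correlation matrix for a population
#'
#' @param k_list List of velocity coefficient vectors (one per unit).
#' @param spec Shared [lead_lag()] window.
#' @return Symmetric matrix of pairwise Pearson correlations (`NA` where
#'   undefined), diagonal 1.
#' @export
pathlet_correlation_matrix <- function(k_list, spec) {
  paths <- lapply(k_list, integrate_pathlet, spec = spec)
  n <- length(paths)
  R <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      R[i, j] <- R[j, i] <- pathlet_correlation(paths[[i]], paths[[j]])$r
    }
  }
  R
}

#' Export a pathlet as tidy CSV
#' @param pathlet An [integrate_pathlet()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pathlet_csv <- function(pathlet, path) {
  df <- data.frame(t = pathlet$times,
                   pathlet$positions,
                   part = c(rep("lead", length(pathlet$lead_part)), "anchor",
                            rep("lag", length(pathlet$lag_part))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
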