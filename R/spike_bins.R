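#' Bin spike trains into a units x bins count matrix
#'
#' Bins are half-open `[start, start + bin)` anchored at `session_span[1]`
#' (normally session time 0); a spike exactly on a boundary is assigned to
#' the later bin.
#'
#' @param spike_times List of numeric spike-time vectors (s), one per unit.
#' @param session_span Length-2 numeric, `[t_start, t_end)` of the session.
#' @param bin Bin width in seconds (default 0.010).
#' @return List with `counts` (units x bins integer matrix) and
#'   `bin_start_times`.
#' @export
bin_spike_counts <- function(spike_times, session_span, bin = 0.010) {
  if (bin <= 0) stop("bin must be positive")
  t0 <- session_span[1]; t1 <- session_span[2]
  n_bins <- ceiling((t1 - t0) / bin - 1e-9)
  grid_end <- t0 + n_bins * bin   # bins tile [t0, grid_end) >= [t0, t1)
  n_units <- length(spike_times)
  counts <- matrix(0L, n_units, n_bins)
  for (u in seq_len(n_units)) {
    st <- spike_times[[u]]
    if (length(st) == 0) next
    bad <- st < t0 | st >= grid_end
    if (any(bad)) {
      stop(sprintf("unit %d has %d spike(s) outside the session span [%g, %g)",
                   u, sum(bad), t0, t1))
    }
    # the 1e-9 nudge keeps boundary spikes in the later bin when
    # floating-point division lands infinitesimally below the boundary
    ib <- floor((st - t0) / bin + 1e-9) + 1L
    tab <- tabulate(ib, nbins = n_bins)
    counts[u, ] <- tab
  }
  list(counts = counts, bin_start_times = t0 + bin * (seq_len(n_bins) - 1L),
       bin = bin)
}

#' Binarize spike trains into 10 ms firing states
#'
#' A bin's state is 1 if at least one spike fell in it, 0 otherwise; spike
#' counts are deliberately not preserved. This binary matrix is the substrate
#' of the confluent mutual information network.
#'
#' @inheritParams bin_spike_counts
#' @return A `binary_spike_matrix`: list with `states` (units x bins, 0/1),
#'   `bin_start_times`, `bin`.
#' @export
binarize <- function(spike_times, session_span, bin = 0.010) {
  b <- bin_spike_counts(spike_times, session_span, bin)
  structure(list(states = (b$counts > 0L) + 0L,
                 bin_start_times = b$bin_start_times,
                 bin = b$bin),
            class = "binary_spike_matrix")
}

#' @export
print.binary_spike_matrix <- function(x, ...) {
  cat(sprintf("binary_spike_matrix: %d units x %d bins of %g ms\n",
              nrow(x$states), ncol(x$states), 1000 * x$bin))
  invisible(x)
}

#' Epoch mask over spike bins
#'
#' Marks the bins whose full `[start, start + bin)` extent lies inside any of
#' the given epochs.
#'
#' @param bsm A [binarize()] result (or anything with `bin_start_times` and
#'   `bin`).
#' @param epochs Data frame with `start_t`, `stop_t` columns (s).
#' @return Logical vector over bins.
#' @export
epoch_bin_mask <- function(bsm, epochs) {
  starts <- bsm$bin_start_times
  ends <- starts + bsm$bin
  mask <- rep(FALSE, length(starts))
  for (k in seq_len(nrow(epochs))) {
    mask <- mask | (starts >= epochs$start_t[k] - 1e-9 &
                    ends <= epochs$stop_t[k] + 1e-9)
  }
  mask
}
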