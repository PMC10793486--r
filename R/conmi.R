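#' Confluent mutual information between two binary spike trains
#'
#' Directed pairwise statistic: the mutual information (bits) between the
#' source unit's firing state `j(t)` and the target's confluent state
#' `i_hat(t) = i(t) OR i(t + 1)`, estimated by the plug-in (empirical
#' frequency) estimator over the 2 x 2 joint table. Only bins `t` for which
#' both `t` and `t + 1` lie inside the analyzed epoch contribute, so the
#' statistic never straddles context boundaries. A degenerate marginal
#' (all-0 or all-1 source or confluent target) gives exactly 0 bits.
#'
#' @param source,target Equal-length 0/1 vectors of per-bin firing states.
#' @param epoch_mask Optional logical vector (same length) selecting in-epoch
#'   bins; default all.
#' @return conMI in bits (non-negative scalar).
#' @export
conmi_pair <- function(source, target, epoch_mask = NULL) {
  n <- length(source)
  if (length(target) != n) stop("source and target must have equal length")
  if (is.null(epoch_mask)) epoch_mask <- rep(TRUE, n)
  use <- which(epoch_mask[-n] & epoch_mask[-1])
  if (length(use) < 2) stop("need at least 2 usable bins after epoch masking")
  x <- source[use]
  y <- pmax(target[use], target[use + 1L])  # confluent state
  mi_2x2(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
}

# Plug-in MI (bits) of a 2x2 table given the four cell counts.
mi_2x2 <- function(n11, n10, n01, n00) {
  cells <- as.numeric(c(n11, n10, n01, n00))  # avoid integer overflow
  n11 <- cells[1]; n10 <- cells[2]; n01 <- cells[3]; n00 <- cells[4]
  m <- n11 + n10 + n01 + n00
  px <- c(n11 + n10, n11 + n10, n01 + n00, n01 + n00)  # source marginal
  py <- c(n11 + n01, n10 + n00, n11 + n01, n10 + n00)  # target marginal
  pos <- cells > 0
  sum(cells[pos] / m * log2(cells[pos] * m / (px[pos] * py[pos])))
}

#' Compute a directed functional network of conMI weights
#'
#' Evaluates [conmi_pair()] for every ordered pair of units over the bins
#' selected by `epoch_mask`, fully vectorized through joint-count matrix
#' products. Targets are rows and sources columns; the diagonal is stored as
#' 0 and excluded from all downstream averages.
#'
#' @param bsm A [binarize()] result.
#' @param epoch_mask Logical vector over bins selecting the context; default
#'   all bins.
#' @param context Label, e.g. `"reachFN1"`, `"reachFN2"`, `"spontaneousFN"`.
#' @param min_bins Minimum number of usable bins (default 1000).
#' @return A `functional_network`: list with `W` (units x units, bits),
#'   `context`, `n_bins_used`.
#' @export
compute_fn <- function(bsm, epoch_mask = NULL, context = "FN",
                       min_bins = 1000) {
  states <- bsm$states
  nb <- ncol(states)
  if (is.null(epoch_mask)) epoch_mask <- rep(TRUE, nb)
  use <- which(epoch_mask[-nb] & epoch_mask[-1])
  if (length(use) < min_bins) {
    stop("only ", length(use), " usable bins in context '", context,
         "'; need at least ", min_bins, " - provide more data or lower min_bins")
  }
  S <- states[, use, drop = FALSE]                        # source j(t)
  Ihat <- pmax(S, states[, use + 1L, drop = FALSE])       # target i(t_hat)
  m <- length(use)
  n11 <- Ihat %*% t(S)                                    # [i, j]
  ri <- rowSums(Ihat)     # i_hat = 1 counts (per target)
  cj <- rowSums(S)        # j = 1 counts (per source)
  n10 <- outer(ri, cj, function(a, b) a) - n11            # i_hat=1, j=0
  n01 <- matrix(cj, nrow(S), nrow(S), byrow = TRUE) - n11 # i_hat=0, j=1
  n00 <- m - n11 - n10 - n01

  term <- function(nxy, px, py) {
    out <- nxy / m * log2(nxy * m / (px * py))
    out[nxy == 0] <- 0
    out
  }
  pi1 <- matrix(ri, nrow(S), nrow(S))          # target marginal (rows)
  pj1 <- matrix(cj, nrow(S), nrow(S), byrow = TRUE)
  W <- term(n11, pi1, pj1) + term(n10, pi1, m - pj1) +
    term(n01, m - pi1, pj1) + term(n00, m - pi1, m - pj1)
  W[!is.finite(W)] <- 0   # degenerate marginals
  diag(W) <- 0
  W[W < 0] <- 0           # clip tiny negative rounding residue
  ids <- paste0("unit_", seq_len(nrow(S)))
  dimnames(W) <- list(target = ids, source = ids)
  structure(list(W = W, context = context, n_bins_used = m),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("functional_network '%s': %d units, %d bins, mean weight %.4g bits\n",
              x$context, nrow(x$W), x$n_bins_used,
              mean(x$W[row(x$W) != col(x$W)])))
  invisible(x)
}

#' Mean incoming edge weight per target unit
#' @param fn A [compute_fn()] result or a raw weight matrix.
#' @return Numeric vector: row mean of `W` excluding the diagonal.
#' @export
in_weight <- function(fn) {
  W <- if (inherits(fn, "functional_network")) fn$W else fn
  (rowSums(W) - diag(W)) / (ncol(W) - 1)
}

#' Functional weight versus inter-electrode distance profile
#'
#' Averages edge weights within distance bins; pairs recorded on the same
#' electrode (distance 0) are reported separately.
#'
#' @param fn A [compute_fn()] result.
#' @param unit_coords units x 2 matrix of electrode coordinates; units with
#'   missing coordinates are skipped with a warning.
#' @param n_bins Number of distance bins (default 10).
#' @return Data frame with `distance` (bin midpoint; 0 for same-electrode),
#'   `mean_weight`, `n_pairs`.
#' @export
fn_distance_profile <- function(fn, unit_coords, n_bins = 10) {
  W <- fn$W
  unit_coords <- as.matrix(unit_coords)
  ok <- stats::complete.cases(unit_coords)
  if (!all(ok)) {
    warning(sum(!ok), " unit(s) missing coordinates; skipped")
  }
  idx <- which(ok)
  if (length(idx) < 2) stop("need at least 2 units with coordinates")
  D <- as.matrix(stats::dist(unit_coords[idx, , drop = FALSE]))
  Wd <- W[idx, idx]
  off <- row(D) != col(D)
  d <- D[off]; w <- Wd[off]
  same <- d < 1e-12
  out <- data.frame(distance = 0, mean_weight = mean(w[same]),
                    n_pairs = sum(same))
  if (any(!same)) {
    dd <- d[!same]; ww <- w[!same]
    if (length(unique(dd)) == 1) {
      out <- rbind(out, data.frame(distance = dd[1], mean_weight = mean(ww),
                                   n_pairs = length(ww)))
    } else {
      br <- seq(min(dd), max(dd), length.out = n_bins + 1)
      bin <- cut(dd, br, include.lowest = TRUE)
      mids <- (br[-1] + br[-length(br)]) / 2
      agg <- tapply(ww, bin, mean)
      cnt <- tapply(ww, bin, length)
      keep <- !is.na(agg)
      out <- rbind(out, data.frame(distance = mids[keep],
                                   mean_weight = as.numeric(agg[keep]),
                                   n_pairs = as.integer(cnt[keep])))
    }
  }
  out[out$n_pairs > 0, , drop = FALSE]
}

#' Write a functional network as CSV with a JSON metadata sidecar
#'
#' @param fn A [compute_fn()] result.
#' @param path CSV path (square matrix, unit ids as header and row names);
#'   metadata goes to `<path>.json` and an edge list to `<path>_edges.csv`.
#' @return `path`, invisibly.
#' @export
write_fn_csv <- function(fn, path) {
  utils::write.csv(fn$W, path, row.names = TRUE)
  meta <- list(context = fn$context, n_bins_used = fn$n_bins_used,
               n_units = nrow(fn$W))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  off <- which(row(fn$W) != col(fn$W), arr.ind = TRUE)
  edges <- data.frame(source = colnames(fn$W)[off[, 2]],
                      target = rownames(fn$W)[off[, 1]],
                      weight_bits = fn$W[off])
  utils::write.csv(edges, sub("\\.csv$", "_edges.csv", path),
                   row.names = FALSE)
  invisible(path)
}
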