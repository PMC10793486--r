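#' Select the strongest N% of functional network edges
#'
#' Off-diagonal edges are ranked by weight descending and the top
#' `round(fraction * E)` taken; ties at the cut are broken by (source,
#' target) lexicographic order so the selection is deterministic.
#'
#' @param fn A [compute_fn()] network or weight matrix.
#' @param fraction Fraction of off-diagonal edges, in (0, 1].
#' @param selection `"strongest"` (default) or `"random"` (uniform matched
#'   size; requires `seed`).
#' @param seed Seed for `selection = "random"`.
#' @return An `edge_set`: data frame with `source`, `target`, `weight`
#'   columns (integer unit indices) and attributes `fraction`, `selection`.
#' @export
select_strong_edges <- function(fn, fraction, selection = c("strongest",
                                                            "random"),
                                seed = NULL) {
  selection <- match.arg(selection)
  W <- if (inherits(fn, "functional_network")) fn$W else fn
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  off <- which(row(W) != col(W), arr.ind = TRUE)
  w <- W[off]
  n_take <- round(fraction * nrow(off))
  src <- off[, 2]; tgt <- off[, 1]
  idx <- if (selection == "strongest") {
    order(-w, src, tgt)[seq_len(n_take)]
  } else {
    if (is.null(seed)) stop("random selection requires a seed")
    local_seed(seed, sample.int(length(w), n_take))
  }
  out <- data.frame(source = src[idx], target = tgt[idx], weight = w[idx])
  attr(out, "fraction") <- fraction
  attr(out, "selection") <- selection
  class(out) <- c("edge_set", "data.frame")
  out
}

#' Permute edge weights within a functional group
#'
#' The multiset of weights on the group's edges is randomly permuted over
#' those same (source, target) positions; everything outside the group is
#' untouched. Tests the models' reliance on the precise pairing of input
#' activity and edge weight.
#'
#' @param fn A [compute_fn()] network or weight matrix.
#' @param group An [select_strong_edges()] edge set.
#' @param seed Integer seed.
#' @return A weight matrix of the same shape.
#' @export
permute_weights <- function(fn, group, seed) {
  W <- if (inherits(fn, "functional_network")) fn$W else fn
  pos <- cbind(group$target, group$source)
  perm <- local_seed(seed, sample.int(nrow(pos)))
  W[pos] <- group$weight[perm]
  W
}

#' Permute the target units of a functional group's edges
#'
#' Each group edge keeps its (source, weight) pair but is reassigned to a new
#' target drawn uniformly among units other than the source and the original
#' target. Because the network is dense, the reassignment is realized as a
#' within-column swap: the weight previously at the destination moves into
#' the vacated position, so the matrix stays single-valued, the global weight
#' multiset is conserved exactly, and each source's out-edge weight multiset
#' is preserved. A destination already settled by an earlier reassignment in
#' the same shuffle is rejected and redrawn (bounded retries, then error).
#'
#' @inheritParams permute_weights
#' @param max_tries Redraw budget per edge (default `50 * n_units`).
#' @return A weight matrix of the same shape.
#' @export
permute_targets <- function(fn, group, seed, max_tries = NULL) {
  W <- if (inherits(fn, "functional_network")) fn$W else fn
  n <- nrow(W)
  if (is.null(max_tries)) max_tries <- 50L * n
  settled <- matrix(FALSE, n, n)   # positions fixed by a completed move
  # current position (row) of each group edge, updated as swaps displace them
  cur_t <- group$target
  src <- group$source
  orig_t <- group$target
  local_seed(seed, {
    ord <- sample.int(length(src))
    for (e in ord) {
      s <- src[e]
      forbidden <- c(s, orig_t[e])
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("could not resolve target permutation collisions; ",
               "group too constrained")
        }
        t_new <- sample.int(n, 1L)
        if (t_new %in% forbidden) next
        if (settled[t_new, s]) next
        break
      }
      t_old <- cur_t[e]
      # swap within column s; the displaced weight takes the vacated slot
      tmp <- W[t_new, s]
      W[t_new, s] <- W[t_old, s]
      W[t_old, s] <- tmp
      displaced <- which(cur_t == t_new & src == s)
      displaced <- displaced[displaced != e]
      if (length(displaced)) cur_t[displaced] <- t_old
      cur_t[e] <- t_new
      settled[t_new, s] <- TRUE
    }
  })
  W
}

#' AUC loss from a functional network manipulation
#'
#' Recomputes the network features from a manipulated network (or drops them
#' entirely for `removal`), predicts on the TRAINING samples with the
#' original, un-retrained coefficients, and reports the percent loss
#' normalized by the above-chance headroom:
#' `100 * (AUC_intact - AUC_perm) / (AUC_intact - 0.5)`, so 100% means all
#' predictive power above chance is lost. Retraining is deliberately avoided
#' since it would re-optimize coefficients and mask the manipulation.
#'
#' @param fit A `kin_plus_FN` [run_splits()] fit (with recorded splits).
#' @param samples The sample set the fit was built from.
#' @param W_perm Manipulated weight matrix (single network), a list of two
#'   (cross-paired), or `NULL` with `mode = "removal"`.
#' @param mode `"permuted"` (default) or `"removal"`.
#' @param split Which recorded split's training rows to evaluate on
#'   (default 1); `"all"` uses every sample.
#' @return List with `loss_pct`, `raw_diff`, `auc_intact`, `auc_perm`,
#'   `excluded` (`TRUE` when `auc_intact <= 0.5`, with a warning).
#' @export
auc_loss <- function(fit, samples, W_perm = NULL,
                     mode = c("permuted", "removal"), split = 1) {
  mode <- match.arg(mode)
  if (fit$family != "kin_plus_FN") stop("fit must be a kin_plus_FN model")
  rows <- if (identical(split, "all")) seq_len(n_samples(samples)) else
    fit$splits[[split]]
  sub <- subset_samples(samples, rows)
  y <- sub$counts[, fit$target_unit]

  if (is.null(fit$F_intact)) {
    stop("fit does not record its intact network features; refit with ",
         "run_splits() on a kin_plus_FN design")
  }
  intact <- fit$F_intact[rows, , drop = FALSE]
  Xkin <- cbind(sub$V, sub$P)
  co <- fit$fit$coefficients
  kin_idx <- c(fit$layout$velocity, fit$layout$position)
  net_idx <- fit$layout$network
  eta_kin <- fit$fit$intercept + drop(Xkin %*% co[kin_idx])
  auc_intact <- auc_score(eta_kin + drop(intact %*% co[net_idx]), y)

  if (mode == "removal") {
    auc_perm <- auc_score(eta_kin, y)
  } else {
    if (is.null(W_perm)) stop("W_perm required unless mode = 'removal'")
    FF <- if (is.list(W_perm) && !is.matrix(W_perm)) {
      network_features(sub, target_unit = fit$target_unit, fn_pair = W_perm)
    } else {
      network_features(sub, fn = W_perm, target_unit = fit$target_unit)
    }
    auc_perm <- auc_score(eta_kin + drop(FF %*% co[net_idx]), y)
  }
  excluded <- !is.na(auc_intact) && auc_intact <= 0.5
  if (excluded) {
    warning("intact AUC <= 0.5 for unit ", fit$target_unit,
            "; loss undefined, unit excluded")
    return(list(loss_pct = NA_real_, raw_diff = auc_intact - auc_perm,
                auc_intact = auc_intact, auc_perm = auc_perm,
                excluded = TRUE))
  }
  list(loss_pct = 100 * (auc_intact - auc_perm) / (auc_intact - 0.5),
       raw_diff = auc_intact - auc_perm,
       auc_intact = auc_intact, auc_perm = auc_perm, excluded = FALSE)
}

#' Strong-edge permutation experiment over a functional network
#'
#' For each functional group size (fraction of edges) and each shuffle:
#' permute the strongest-N% group, an independently drawn random group of
#' matched size, and compare both with complete removal of the network
#' features. Mean AUC loss across units is compared between strongest and
#' random groups by a one-sided sign test across shuffles, and removal is
#' compared against the strongest-group permutation the same way.
#'
#' @param fits List of `kin_plus_FN` [run_splits()] fits (one per analyzed
#'   unit, built with `attach_intact_features`).
#' @param samples The common sample set.
#' @param fn_pair List of the two cross-paired networks.
#' @param fractions Functional group sizes, e.g. `c(0.1, 0.2, 0.5)`.
#' @param mode `"weights"` or `"targets"`.
#' @param n_shuffles Number of shuffles per fraction (>= 2).
#' @param seed Master seed.
#' @param p_thresh Sign-test threshold (default 0.01).
#' @return List with `losses` (tidy data frame: fraction, shuffle, group,
#'   unit, loss_pct), `summary` (per fraction: mean losses and sign-test
#'   p-values), `removal` (per-unit removal loss).
#' @export
permutation_experiment <- function(fits, samples, fn_pair, fractions,
                                   mode = c("weights", "targets"),
                                   n_shuffles = 50, seed = 1,
                                   p_thresh = 0.01) {
  mode <- match.arg(mode)
  if (n_shuffles < 2) stop("n_shuffles must be at least 2")
  permute <- if (mode == "weights") permute_weights else permute_targets

  removal <- vapply(fits, function(f) {
    auc_loss(f, samples, mode = "removal")$loss_pct
  }, numeric(1))

  rows <- list()
  summaries <- list()
  for (fi in seq_along(fractions)) {
    fr <- fractions[fi]
    strong_groups <- lapply(fn_pair, select_strong_edges, fraction = fr)
    mean_strong <- numeric(n_shuffles)
    mean_random <- numeric(n_shuffles)
    for (sh in seq_len(n_shuffles)) {
      sd_base <- seed + 7919L * fi + 104729L * sh
      W_s <- lapply(1:2, function(k) {
        permute(fn_pair[[k]], strong_groups[[k]], seed = sd_base + k)
      })
      rand_groups <- lapply(1:2, function(k) {
        select_strong_edges(fn_pair[[k]], fr, selection = "random",
                            seed = sd_base + 10L + k)
      })
      W_r <- lapply(1:2, function(k) {
        permute(fn_pair[[k]], rand_groups[[k]], seed = sd_base + 20L + k)
      })
      loss_s <- vapply(fits, function(f) {
        auc_loss(f, samples, W_s)$loss_pct
      }, numeric(1))
      loss_r <- vapply(fits, function(f) {
        auc_loss(f, samples, W_r)$loss_pct
      }, numeric(1))
      mean_strong[sh] <- mean(loss_s, na.rm = TRUE)
      mean_random[sh] <- mean(loss_r, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fr, shuffle = sh,
        group = rep(c("strongest", "random"), each = length(fits)),
        unit = rep(vapply(fits, `[[`, numeric(1), "target_unit"), 2),
        loss_pct = c(loss_s, loss_r))
    }
    p_sr <- sign_test(mean_strong - mean_random, side = "greater")$p_value
    p_rem <- sign_test(mean(removal, na.rm = TRUE) - mean_strong,
                       side = "greater")$p_value
    summaries[[fi]] <- data.frame(
      fraction = fr, mode = mode,
      mean_loss_strongest = mean(mean_strong),
      mean_loss_random = mean(mean_random),
      mean_loss_removal = mean(removal, na.rm = TRUE),
      p_strong_gt_random = p_sr,
      strong_gt_random = p_sr < p_thresh,
      p_removal_gt_strong = p_rem,
      removal_gt_strong = p_rem < p_thresh)
  }
  list(losses = do.call(rbind, rows),
       summary = do.call(rbind, summaries),
       removal = removal, mode = mode, n_shuffles = n_shuffles)
}
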