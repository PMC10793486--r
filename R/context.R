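#' Cross-context generalization test for one unit
#'
#' Model A is the standard `kin_plus_FN` model: trained and tested on reach
#' samples with cross-paired reach-network features. Model B is trained on
#' the same samples but with network features computed from the spontaneous
#' network, then tested with the reach-network features substituted in --
#' asking whether functional interactions measured during spontaneous
#' behavior remain informative during reaching. Both use identical split
#' sequences so their per-split AUCs are paired.
#'
#' @param samples Reach sample set from [extract_samples()].
#' @param target_unit Target unit index.
#' @param fn_spont The spontaneous-context network.
#' @param fn_reach_pair List of the two reach networks (cross-pairing).
#' @param alpha,n_splits,train_frac,seed Passed to [run_splits()].
#' @return List with `fit_reach` (model A), `fit_crosstest` (model B),
#'   `auc_reach`, `auc_crosstest`, `delta` (mean AUC A - mean AUC B).
#' @export
crosstest_spont_fn <- function(samples, target_unit, fn_spont, fn_reach_pair,
                               alpha = 1e-6, n_splits = 100,
                               train_frac = 0.8, seed = 1) {
  des_reach <- build_design(samples, "kin_plus_FN", target_unit,
                            fn_pair = fn_reach_pair)
  des_spont <- build_design(samples, "kin_plus_FN", target_unit,
                            fn = fn_spont)
  fit_a <- run_splits(des_reach, alpha = alpha, n_splits = n_splits,
                      train_frac = train_frac, seed = seed)
  fit_b <- run_splits(des_spont, alpha = alpha, n_splits = n_splits,
                      train_frac = train_frac, seed = seed,
                      design_test = des_reach)
  a <- mean(fit_a$auc_per_split, na.rm = TRUE)
  b <- mean(fit_b$auc_per_split, na.rm = TRUE)
  list(fit_reach = fit_a, fit_crosstest = fit_b,
       auc_reach = a, auc_crosstest = b, delta = a - b)
}

#' Classify units into context-specific and context-invariant groups
#'
#' Sorts the per-unit generalization deficits (AUC of the reach-network
#' model minus the cross-tested spontaneous-network model) in descending
#' order, takes first differences, median-filters them with an odd window,
#' and finds the first index at which the filtered derivative magnitude
#' falls below `kink_frac` of its maximum -- the "kink" where the sorted
#' curve flattens. Units ranked strictly before that index are labeled
#' context-specific. The rule depends only on the derivative, so adding a
#' constant to every delta never changes the labels. Flat deltas (zero
#' maximum derivative) yield zero context-specific units, flagged
#' degenerate.
#'
#' @param deltas Per-unit AUC differences.
#' @param filter_window Odd median-filter window (default 5; 1 disables
#'   filtering).
#' @param kink_frac Threshold as a fraction of the maximum filtered
#'   derivative (default 0.075).
#' @return A `context_groups` list: `labels` (per unit, in input order),
#'   `delta`, `order` (descending), `threshold_index` (rank of the kink in
#'   sorted order; units before it are context-specific), `n_specific`,
#'   `degenerate`.
#' @export
classify_context_groups <- function(deltas, filter_window = 5,
                                    kink_frac = 0.075) {
  n <- length(deltas)
  if (n < 10) stop("need at least 10 units to classify")
  if (filter_window %% 2 == 0) stop("filter_window must be odd")
  ord <- order(deltas, decreasing = TRUE)
  srt <- deltas[ord]
  d <- srt[-n] - srt[-1]               # derivative magnitude (>= 0)
  f <- if (filter_window > 1) {
    as.numeric(stats::runmed(d, filter_window, endrule = "median"))
  } else d
  mx <- max(f)
  labels <- rep("context_invariant", n)
  if (mx <= 0) {
    res <- list(labels = labels, delta = deltas, order = ord,
                threshold_index = 1L, n_specific = 0L, degenerate = TRUE)
    class(res) <- "context_groups"
    return(res)
  }
  below <- which(f < kink_frac * mx)
  thr <- if (length(below)) below[1] else n
  if (thr > 1) labels[ord[seq_len(thr - 1L)]] <- "context_specific"
  res <- list(labels = labels, delta = deltas, order = ord,
              threshold_index = as.integer(thr),
              n_specific = as.integer(thr - 1L), degenerate = FALSE)
  class(res) <- "context_groups"
  res
}

#' @export
print.context_groups <- function(x, ...) {
  cat(sprintf("context groups: %d specific / %d invariant%s\n",
              x$n_specific, length(x$labels) - x$n_specific,
              if (x$degenerate) " [degenerate: flat deltas]" else ""))
  invisible(x)
}

#' Edge-weight change distributions between contexts, by functional group
#'
#' Edge-wise differences `W_reach - W_spont` are split into within-group
#' edge sets -- context-specific (both endpoints specific),
#' context-invariant (both invariant) and the full network -- and the three
#' distributions are compared pairwise with two-sided median tests.
#'
#' @param fn_reach,fn_spont Networks (or weight matrices) on the same units.
#' @param labels Per-unit labels from [classify_context_groups()] (the
#'   `labels` field or the object itself).
#' @return List with `differences` (named list of numeric vectors) and
#'   `tests` (data frame of pairwise median tests). Groups with fewer than
#'   2 edges are excluded.
#' @export
edge_change_distributions <- function(fn_reach, fn_spont, labels) {
  Wr <- if (inherits(fn_reach, "functional_network")) fn_reach$W else fn_reach
  Ws <- if (inherits(fn_spont, "functional_network")) fn_spont$W else fn_spont
  if (inherits(labels, "context_groups")) labels <- labels$labels
  n <- nrow(Wr)
  if (length(labels) != n) stop("labels must cover all units")
  D <- Wr - Ws
  off <- row(D) != col(D)
  spec <- labels == "context_specific"
  sets <- list(
    context_specific = D[off & outer(spec, spec, `&`)],
    context_invariant = D[off & outer(!spec, !spec, `&`)],
    full = D[off]
  )
  sets <- sets[lengths(sets) >= 2]
  tests <- NULL
  nm <- names(sets)
  if (length(sets) >= 2) {
    pairs <- utils::combn(seq_along(sets), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      mt <- median_test(list(sets[[i1]], sets[[i2]]))
      data.frame(group1 = nm[i1], group2 = nm[i2],
                 median1 = stats::median(sets[[i1]]),
                 median2 = stats::median(sets[[i2]]),
                 statistic = mt$statistic, p_value = mt$p_value,
                 degenerate = mt$degenerate)
    }))
  }
  list(differences = sets, tests = tests)
}

#' Compare tuning and pathlet correlations across context groups
#'
#' Median tests of (a) full-kinematics AUC distributions and (b)
#' within-group pairwise pathlet correlations across the context-specific,
#' context-invariant and full populations.
#'
#' @param auc_kin Per-unit mean full-kinematics AUC.
#' @param labels Per-unit labels (or a `context_groups` object).
#' @param pathlet_corrs Symmetric pairwise pathlet correlation matrix
#'   ([pathlet_correlation_matrix()]).
#' @return List of data frames `auc_tests` and `pathlet_tests`.
#' @export
group_tuning_comparisons <- function(auc_kin, labels, pathlet_corrs) {
  if (inherits(labels, "context_groups")) labels <- labels$labels
  spec <- labels == "context_specific"
  auc_groups <- list(context_specific = auc_kin[spec],
                     context_invariant = auc_kin[!spec],
                     full = auc_kin)
  off <- upper.tri(pathlet_corrs)
  corr_groups <- list(
    context_specific = pathlet_corrs[off & outer(spec, spec, `&`)],
    context_invariant = pathlet_corrs[off & outer(!spec, !spec, `&`)],
    full = pathlet_corrs[off]
  )
  run_tests <- function(groups) {
    groups <- lapply(groups, function(g) g[is.finite(g)])
    groups <- groups[lengths(groups) >= 2]
    nm <- names(groups)
    if (length(groups) < 2) return(NULL)
    pairs <- utils::combn(seq_along(groups), 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      mt <- median_test(list(groups[[i1]], groups[[i2]]))
      data.frame(group1 = nm[i1], group2 = nm[i2],
                 median1 = stats::median(groups[[i1]]),
                 median2 = stats::median(groups[[i2]]),
                 p_value = mt$p_value, degenerate = mt$degenerate)
    }))
  }
  list(auc_tests = run_tests(auc_groups),
       pathlet_tests = run_tests(corr_groups))
}

#' Modulation and firing-rate-ratio controls with AUC matching
#'
#' Controls that group differences are not mere excitability differences:
#' `modulation` is the normalized absolute rate change around reach onset
#' (|mean rate over [0, +250] ms - mean rate over [-250, 0] ms| / their sum,
#' rates averaged over reaches first); `rate_ratio` is the mean reach-epoch
#' rate over the mean spontaneous-epoch rate (flagged undefined for units
#' silent in either context). The AUC-matched invariant subset keeps only
#' invariant units whose full-kinematics AUC exceeds the lowest AUC in the
#' context-specific group; group comparisons use two-sided median tests.
#'
#' @param spike_times List of per-unit spike-time vectors (s).
#' @param reach_onsets Reach onset times (s).
#' @param epochs Data frame with `start_t`, `stop_t`, `label` in
#'   {"reach", "spontaneous"}.
#' @param labels Per-unit context labels (or `context_groups`).
#' @param auc_kin Per-unit full-kinematics AUC (for AUC matching).
#' @param window_s Half-window around onset for modulation (default 0.250).
#' @return List with `metrics` (per-unit data frame), `matched_invariant`
#'   (logical), `tests` (modulation and ratio median tests, specific vs
#'   AUC-matched invariant).
#' @export
control_metrics <- function(spike_times, reach_onsets, epochs, labels,
                            auc_kin, window_s = 0.250) {
  if (inherits(labels, "context_groups")) labels <- labels$labels
  n_units <- length(spike_times)
  reach_ep <- epochs[epochs$label == "reach", , drop = FALSE]
  spont_ep <- epochs[epochs$label == "spontaneous", , drop = FALSE]
  t_reach <- sum(reach_ep$stop_t - reach_ep$start_t)
  t_spont <- sum(spont_ep$stop_t - spont_ep$start_t)

  count_in <- function(st, a, b) sum(st >= a & st < b)
  metrics <- do.call(rbind, lapply(seq_len(n_units), function(u) {
    st <- spike_times[[u]]
    pre <- mean(vapply(reach_onsets, function(o) {
      count_in(st, o - window_s, o) / window_s
    }, numeric(1)))
    post <- mean(vapply(reach_onsets, function(o) {
      count_in(st, o, o + window_s) / window_s
    }, numeric(1)))
    modulation <- if (pre + post == 0) 0 else abs(post - pre) / (post + pre)
    n_r <- sum(vapply(seq_len(nrow(reach_ep)), function(k) {
      count_in(st, reach_ep$start_t[k], reach_ep$stop_t[k])
    }, numeric(1)))
    n_s <- sum(vapply(seq_len(nrow(spont_ep)), function(k) {
      count_in(st, spont_ep$start_t[k], spont_ep$stop_t[k])
    }, numeric(1)))
    rate_r <- n_r / t_reach
    rate_s <- n_s / t_spont
    data.frame(unit = u, label = labels[u], modulation = modulation,
               rate_reach = rate_r, rate_spont = rate_s,
               rate_ratio = if (n_s == 0 || n_r == 0) NA_real_ else
                 rate_r / rate_s,
               ratio_defined = n_s > 0 && n_r > 0)
  }))

  spec <- labels == "context_specific"
  matched <- rep(FALSE, n_units)
  if (any(spec)) {
    matched <- !spec & auc_kin > min(auc_kin[spec])
  }
  test_for <- function(col) {
    a <- metrics[[col]][spec]
    b <- metrics[[col]][matched]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    mt <- median_test(list(a, b))
    data.frame(metric = col, median_specific = stats::median(a),
               median_matched_invariant = stats::median(b),
               p_value = mt$p_value, degenerate = mt$degenerate)
  }
  list(metrics = metrics, matched_invariant = matched,
       tests = rbind(test_for("modulation"), test_for("rate_ratio")))
}
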