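#' Fit and evaluate an encoding model over resampled train/test splits
#'
#' Each split independently redraws a random `train_frac`/(1 - `train_frac`)
#' partition of the samples (partitions are independent across splits), fits
#' the penalized GLM on the training portion and computes the ROC AUC of the
#' predicted intensity against the binarized response on the held-out
#' portion. A final fit on all samples provides the reported coefficients
#' (preferred velocity trajectory `k`, position coefficients `c`, network
#' scaling terms `beta0`/`beta1`).
#'
#' @param design A [build_design()] result.
#' @param alpha Ridge penalty weight; defaults to 0.05 for pure kinematics
#'   families and 1e-6 for `kin_plus_FN`.
#' @param n_splits Number of train/test splits (default 500).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed; the split sequence is deterministic under it.
#' @param design_test Optional second design whose rows replace the held-out
#'   rows at prediction time (used for cross-context generalization tests:
#'   train with one network's features, test with another's).
#' @param family GLM family, see [fit_glm_ridge()].
#' @param keep_split_coefs If `TRUE`, store the per-split coefficient matrix
#'   (needed for split-stability analyses of pathlets).
#' @return An `encoding_fit`: list with `auc_per_split`, `fit` (full-data
#'   [fit_glm_ridge()]), `coef` (named pieces: `gamma`, `k`, `c`, `beta`),
#'   `layout`, `family`, `spec`, `target_unit`, `alpha`, `splits` (list of
#'   train indices), and optionally `split_coefs`.
#' @export
run_splits <- function(design, alpha = NULL, n_splits = 500, train_frac = 0.8,
                       seed = 1, design_test = NULL, family = "poisson",
                       keep_split_coefs = FALSE) {
  if (n_splits < 1) stop("n_splits must be at least 1")
  X <- design$X; y <- design$y
  n <- nrow(X)
  n_train <- floor(train_frac * n)
  if (n_train < ncol(X) + 1 || n_train >= n) {
    stop("too few samples (", n, ") for a ", train_frac, " train split")
  }
  if (is.null(alpha)) {
    alpha <- default_alpha(design$family)
  }
  Xt <- if (is.null(design_test)) X else design_test$X

  aucs <- numeric(n_splits)
  train_sets <- vector("list", n_splits)
  coefs <- if (keep_split_coefs) matrix(NA_real_, n_splits, ncol(X)) else NULL
  local_seed(seed, {
    for (s in seq_len(n_splits)) {
      tr <- sample.int(n, n_train)
      train_sets[[s]] <- tr
      fit <- fit_glm_ridge(X[tr, , drop = FALSE], y[tr], alpha,
                           family = family)
      pred <- predict(fit, Xt[-tr, , drop = FALSE])
      aucs[s] <- auc_score(pred, y[-tr])
      if (keep_split_coefs) coefs[s, ] <- fit$coefficients
    }
  })
  full <- fit_glm_ridge(X, y, alpha, family = family)
  out <- list(
    auc_per_split = aucs,
    fit = full,
    coef = split_coef(full, design$layout),
    layout = design$layout,
    family = design$family,
    spec = design$spec,
    target_unit = design$target_unit,
    alpha = alpha,
    train_frac = train_frac,
    seed = seed,
    splits = train_sets
  )
  if (keep_split_coefs) out$split_coefs <- coefs
  if (!is.null(design$layout$network)) {
    out$F_intact <- X[, design$layout$network, drop = FALSE]
  }
  structure(out, class = "encoding_fit")
}

default_alpha <- function(family) {
  if (identical(family, "kin_plus_FN")) 1e-6 else 0.05
}

split_coef <- function(fit, layout) {
  co <- fit$coefficients
  out <- list(gamma = fit$intercept, k = co[layout$velocity])
  out$c <- if (!is.null(layout$position)) co[layout$position] else NULL
  out$beta <- if (!is.null(layout$network)) co[layout$network] else NULL
  out
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("encoding_fit (%s, %s): mean AUC %.3f over %d splits\n",
              x$family, leadlag_label(x$spec), mean(x$auc_per_split,
                                                    na.rm = TRUE),
              length(x$auc_per_split)))
  invisible(x)
}

#' Shuffle controls that break the kinematics-spike relationship
#'
#' `total` permutes the kinematic blocks (velocity trajectory and mean
#' position jointly) across samples while leaving spikes in place, breaking
#' all kinematic tuning; `trajectory` permutes only the velocity trajectories
#' so the position-spike pairing is preserved.
#'
#' @param samples A [extract_samples()] result.
#' @param mode `"total"` or `"trajectory"`.
#' @param seed Integer seed.
#' @return A permuted copy of `samples`.
#' @export
shuffle_control <- function(samples, mode = c("total", "trajectory"), seed) {
  mode <- match.arg(mode)
  n <- n_samples(samples)
  if (n < 2) stop("need at least 2 samples to shuffle")
  perm <- local_seed(seed, sample.int(n))
  out <- samples
  out$V <- samples$V[perm, , drop = FALSE]
  if (mode == "total") out$P <- samples$P[perm, , drop = FALSE]
  out
}

#' Paired significance of tuning via one-sided sign test
#'
#' Tests whether per-split AUCs of the real model exceed those of a paired
#' shuffled model, with Bonferroni correction across the tested population.
#'
#' @param auc_real,auc_shuffled Paired per-split AUC vectors.
#' @param n_comparisons Bonferroni family size (number of units tested).
#' @param p_thresh Significance threshold after correction (default 0.01).
#' @return List with `p_value` (corrected, capped at 1), `p_raw`,
#'   `significant`.
#' @export
tuning_test <- function(auc_real, auc_shuffled, n_comparisons = 1,
                        p_thresh = 0.01) {
  if (length(auc_real) != length(auc_shuffled)) {
    stop("paired AUC vectors must have equal length")
  }
  st <- sign_test(auc_real - auc_shuffled, side = "greater")
  p <- min(1, st$p_value * n_comparisons)
  list(p_value = p, p_raw = st$p_value, significant = p < p_thresh)
}

#' Sweep lead-lag windows and identify the best and non-inferior set
#'
#' Takes per-unit mean AUCs for each candidate window, reports population
#' mean +/- sem per window, selects the best window by mean AUC, and flags
#' windows whose per-unit AUCs are not significantly below the best one
#' (one-sided sign test with Bonferroni correction, retained at corrected
#' p > 0.05).
#'
#' @param auc_by_spec Matrix of per-unit mean AUCs: units x specs (the same
#'   unit set for every spec), or a list of equal-length vectors.
#' @param specs List of [lead_lag()] objects matching the columns.
#' @return List with `table` (data frame: label, mean, sem, non_inferior,
#'   p_vs_best), `best` (index), `best_spec`.
#' @export
leadlag_sweep <- function(auc_by_spec, specs) {
  if (is.list(auc_by_spec) && !is.matrix(auc_by_spec)) {
    n <- unique(lengths(auc_by_spec))
    if (length(n) != 1) stop("unit sets differ across specs")
    auc_by_spec <- do.call(cbind, auc_by_spec)
  }
  if (length(specs) != ncol(auc_by_spec)) {
    stop("specs must match the columns of auc_by_spec")
  }
  if (length(specs) < 2) stop("need at least 2 specs to sweep")
  mu <- colMeans(auc_by_spec)
  sem <- apply(auc_by_spec, 2, stats::sd) / sqrt(nrow(auc_by_spec))
  best <- unname(which.max(mu))
  k <- length(specs)
  pv <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    if (j == best) { pv[j] <- 1; next }
    d <- auc_by_spec[, best] - auc_by_spec[, j]
    pv[j] <- min(1, sign_test(d, side = "greater")$p_value * (k - 1))
  }
  data.frame(
    label = vapply(specs, leadlag_label, character(1)),
    mean_auc = mu, sem_auc = sem,
    p_vs_best = pv, non_inferior = pv > 0.05
  ) -> tab
  list(table = tab, best = best, best_spec = specs[[best]])
}

#' Correlation of model performance and improvement with FN in-weight
#'
#' Pearson correlations of (a) per-unit mean full-kinematics AUC and (b) the
#' per-unit improvement from adding network features, against the unit's
#' mean incoming edge weight. Interpretive bands: |r| < 0.2 uncorrelated,
#' 0.2-0.5 weak-moderate, > 0.5 strong.
#'
#' @param auc_kin Per-unit mean AUC of the full kinematics model.
#' @param auc_fn Per-unit mean AUC of the kin_plus_FN model (or `NULL` to
#'   skip the improvement correlation).
#' @param fn A [compute_fn()] network (or weight matrix).
#' @return Data frame with rows `auc_vs_inweight` and (if available)
#'   `improvement_vs_inweight`: `r`, `band`, `defined`.
#' @export
inweight_correlates <- function(auc_kin, auc_fn = NULL, fn) {
  iw <- in_weight(fn)
  if (length(auc_kin) != length(iw)) {
    stop("auc_kin must have one value per unit in the network")
  }
  if (length(iw) < 3) stop("need at least 3 units")
  row1 <- pearson_row("auc_vs_inweight", auc_kin, iw)
  if (is.null(auc_fn)) return(row1)
  rbind(row1, pearson_row("improvement_vs_inweight", auc_fn - auc_kin, iw))
}

pearson_row <- function(name, x, y) {
  r <- pearson_cor(x, y)
  data.frame(comparison = name, r = r$r, band = r$band,
             defined = r$defined, stringsAsFactors = FALSE)
}

#' Serialize an encoding fit to JSON plus a per-split AUC CSV
#'
#' Writes the fitted coefficients (intercept and named blocks), the model
#' family, lead-lag window, penalty, seed and split settings as JSON, and
#' the per-split AUC sequence as a one-column CSV next to it.
#'
#' @param fit A [run_splits()] result.
#' @param path JSON output path; the AUC CSV goes to `<path>_aucs.csv`.
#' @return `path`, invisibly.
#' @export
write_encoding_fit <- function(fit, path) {
  stopifnot(inherits(fit, "encoding_fit"))
  meta <- list(
    family = fit$family,
    lead_ms = fit$spec$lead_ms, lag_ms = fit$spec$lag_ms,
    target_unit = fit$target_unit,
    alpha = fit$alpha, train_frac = fit$train_frac, seed = fit$seed,
    n_splits = length(fit$auc_per_split),
    mean_auc = mean(fit$auc_per_split, na.rm = TRUE),
    coefficients = list(gamma = fit$coef$gamma, k = fit$coef$k,
                        c = fit$coef$c, beta = fit$coef$beta)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  utils::write.csv(data.frame(auc = fit$auc_per_split),
                   sub("\\.json$", "", path) |> paste0("_aucs.csv"),
                   row.names = FALSE)
  invisible(path)
}
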