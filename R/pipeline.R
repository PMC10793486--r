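#' Default run configuration
#'
#' All pipeline parameters with their canonical defaults: 10 ms spike bins,
#' 30 ms sample step, 40 Hz trajectory grid, the `[-100, +300]` ms window,
#' 80/20 train/test splits resampled 500 times, ridge penalties 0.05
#' (kinematics families) and 1e-6 (network models), 7.5% kink rule with a
#' window-5 median filter. The configuration round-trips losslessly through
#' YAML.
#'
#' @param ... Overrides of any default field.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(...) {
  cfg <- list(
    profile = "small",
    seed = 1,
    frame_rate = 150,
    err_thresh_px = 20,
    min_cams = 2,
    speed_thresh = 0.05,
    min_peak_prominence = 0.02,
    lead_ms = 100,
    lag_ms = 300,
    step_ms = 30,
    bin_s = 0.010,
    alpha_kinematics = 0.05,
    alpha_network = 1e-6,
    n_splits = 500,
    train_frac = 0.8,
    fractions = c(0.1, 0.2, 0.5),
    n_shuffles = 50,
    filter_window = 5,
    kink_frac = 0.075,
    min_fn_bins = 1000,
    max_units = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Stages, in dependency order: simulate -> preprocess (clean, smooth,
#' velocity, reach segmentation, reach-set assignment) -> functional
#' networks (reachFN1/2 and spontaneousFN) -> encoding fits
#' (full kinematics and kinematics + network for every unit) -> strong-edge
#' permutations -> context-group classification -> report tables. Each
#' stage writes CSV/JSON artifacts into `out_dir` and a manifest with file
#' hashes and seeds; a rerun with an identical configuration reproduces
#' identical artifacts.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return The manifest (invisibly a list), with artifacts on disk.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- lead_lag(cfg$lead_ms, cfg$lag_ms)

  session <- make_default_session(cfg$profile, seed = cfg$seed,
                                  frame_rate = cfg$frame_rate)
  write_session(session, file.path(out_dir, "session"))

  series <- clean_tracking(session$series, cfg$err_thresh_px, cfg$min_cams)
  series <- smooth_series(series)
  velocity <- hand_velocity(series)
  segments <- segment_reaches(series, velocity, cfg$speed_thresh,
                              cfg$min_peak_prominence)
  if (nrow(segments) < 2) stop("preprocessing found fewer than 2 reaches")
  segments <- assign_reach_sets(segments, seed = cfg$seed + 10L)
  utils::write.csv(segments, file.path(out_dir, "segments.csv"),
                   row.names = FALSE)

  bsm <- binarize(session$spike_times, session$session_span, cfg$bin_s)
  seg_ep <- function(labels) {
    data.frame(start_t = segments$start_t[segments$set_label %in% labels],
               stop_t = segments$stop_t[segments$set_label %in% labels])
  }
  reach_mask1 <- epoch_bin_mask(bsm, seg_ep("reachSet1"))
  reach_mask2 <- epoch_bin_mask(bsm, seg_ep("reachSet2"))
  spont_mask <- !epoch_bin_mask(bsm, seg_ep(c("reachSet1", "reachSet2")))
  fn1 <- compute_fn(bsm, reach_mask1, "reachFN1", min_bins = cfg$min_fn_bins)
  fn2 <- compute_fn(bsm, reach_mask2, "reachFN2", min_bins = cfg$min_fn_bins)
  fns <- compute_fn(bsm, spont_mask, "spontaneousFN",
                    min_bins = cfg$min_fn_bins)
  write_fn_csv(fn1, file.path(out_dir, "reachFN1.csv"))
  write_fn_csv(fn2, file.path(out_dir, "reachFN2.csv"))
  write_fn_csv(fns, file.path(out_dir, "spontaneousFN.csv"))

  samples <- extract_samples(series, velocity, session$spike_times,
                             segments, spec, step_ms = cfg$step_ms,
                             bin = cfg$bin_s,
                             session_span = session$session_span)
  n_units <- length(session$spike_times)
  units <- seq_len(if (is.null(cfg$max_units)) n_units else
    min(cfg$max_units, n_units))

  fit_rows <- list()
  deltas <- numeric(length(units))
  k_list <- vector("list", length(units))
  auc_kin <- numeric(length(units))
  fn_fits <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[i]
    des_kin <- build_design(samples, "full_kinematics", u)
    fit_kin <- run_splits(des_kin, alpha = cfg$alpha_kinematics,
                          n_splits = cfg$n_splits,
                          train_frac = cfg$train_frac,
                          seed = cfg$seed + 100L + u)
    ct <- crosstest_spont_fn(samples, u, fns, list(fn1, fn2),
                             alpha = cfg$alpha_network,
                             n_splits = cfg$n_splits,
                             train_frac = cfg$train_frac,
                             seed = cfg$seed + 100L + u)
    auc_kin[i] <- mean(fit_kin$auc_per_split, na.rm = TRUE)
    deltas[i] <- ct$delta
    k_list[[i]] <- fit_kin$coef$k
    fn_fits[[i]] <- ct$fit_reach
    fit_rows[[i]] <- data.frame(
      unit = u, auc_full_kinematics = auc_kin[i],
      auc_kin_plus_fn = ct$auc_reach,
      auc_spont_crosstest = ct$auc_crosstest, delta = ct$delta)
  }
  fits_df <- do.call(rbind, fit_rows)
  utils::write.csv(fits_df, file.path(out_dir, "encoding_fits.csv"),
                   row.names = FALSE)

  perm <- permutation_experiment(fn_fits, samples, list(fn1, fn2),
                                 fractions = cfg$fractions,
                                 n_shuffles = cfg$n_shuffles,
                                 seed = cfg$seed + 500L)
  utils::write.csv(perm$summary, file.path(out_dir, "permutation_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(perm$losses, file.path(out_dir, "permutation_losses.csv"),
                   row.names = FALSE)

  groups <- classify_context_groups(deltas, cfg$filter_window, cfg$kink_frac)
  labels_df <- data.frame(unit = units, label = groups$labels,
                          delta = deltas)
  utils::write.csv(labels_df, file.path(out_dir, "context_labels.csv"),
                   row.names = FALSE)
  edge_changes <- edge_change_distributions(
    subfn(fn1, units), subfn(fns, units), groups$labels)
  if (!is.null(edge_changes$tests)) {
    utils::write.csv(edge_changes$tests,
                     file.path(out_dir, "edge_change_tests.csv"),
                     row.names = FALSE)
  }
  pc <- pathlet_correlation_matrix(k_list, spec)
  utils::write.csv(pc, file.path(out_dir, "pathlet_correlations.csv"),
                   row.names = FALSE)
  iw <- inweight_correlates(auc_kin, fits_df$auc_kin_plus_fn,
                            subfn(fn1, units))
  utils::write.csv(iw, file.path(out_dir, "inweight_correlations.csv"),
                   row.names = FALSE)

  write_config(cfg, file.path(out_dir, "config.yaml"))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = cfg$seed,
    files = as.list(stats::setNames(
      as.character(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

subfn <- function(fn, units) {
  fn$W <- fn$W[units, units, drop = FALSE]
  fn
}

#' Summary tables from a completed pipeline run
#'
#' Reads the artifacts of [run_pipeline()] back into a named list of data
#' frames (encoding fits, permutation summary, context labels, edge-change
#' tests, in-weight correlations). Missing stages are listed rather than
#' raising an error.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List with `tables` (data frames) and `missing` (character vector
#'   of absent artifacts).
#' @export
report <- function(run_dir) {
  wanted <- c(encoding_fits = "encoding_fits.csv",
              permutation_summary = "permutation_summary.csv",
              context_labels = "context_labels.csv",
              edge_change_tests = "edge_change_tests.csv",
              inweight_correlations = "inweight_correlations.csv",
              pathlet_correlations = "pathlet_correlations.csv",
              segments = "segments.csv")
  tables <- list()
  missing <- character(0)
  for (nm in names(wanted)) {
    f <- file.path(run_dir, wanted[[nm]])
    if (file.exists(f)) {
      tables[[nm]] <- utils::read.csv(f)
    } else {
      missing <- c(missing, wanted[[nm]])
    }
  }
  list(tables = tables, missing = missing)
}
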