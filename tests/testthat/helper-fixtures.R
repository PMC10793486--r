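# Shared fixture builders. Everything is generated in code at test time.

# A minimal uniform marker series with constant shoulder and scriptable
# hand coordinates.
toy_series <- function(n = 100, frame_rate = 200, hand = NULL,
                       err = rep(0, n), cams = rep(3L, n)) {
  time <- (seq_len(n) - 1) / frame_rate
  if (is.null(hand)) hand <- matrix(0, n, 3)
  marker_series(time, hand, matrix(0, n, 3),
                reprojection_error = err, n_cameras = cams,
                frame_rate = frame_rate)
}

# Brute-force plug-in mutual information of a 2x2 table (independent oracle
# for conMI: direct double loop over the outcome alphabet).
mi_table_oracle <- function(n11, n10, n01, n00) {
  tab <- matrix(c(n11, n01, n10, n00), 2, 2,
                dimnames = list(src = c(1, 0), tgt = c(1, 0)))
  m <- sum(tab)
  p <- tab / m
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
      }
    }
  }
  unname(total)
}

# Brute-force AUC by looping over all (positive, negative) pairs.
auc_pairwise_oracle <- function(scores, labels) {
  pos <- which(labels >= 1); neg <- which(labels < 1)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# Memoized mid-scale synthetic study used by the acceptance tests; built
# once per test run.
.study_cache <- new.env(parent = emptyenv())
acceptance_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  ses <- make_default_session("paperlike", seed = 11, n_units = 100,
                              n_reaches = 60, mean_gap_s = 10)
  s <- smooth_series(clean_tracking(ses$series))
  v <- hand_velocity(s)
  segs <- assign_reach_sets(segment_reaches(s, v), seed = 103)
  spec <- lead_lag(100, 300)
  samp <- extract_samples(s, v, ses$spike_times, segs, spec,
                          session_span = ses$session_span)
  bsm <- binarize(ses$spike_times, ses$session_span)
  seg_ep <- function(lbl) {
    data.frame(start_t = segs$start_t[segs$set_label %in% lbl],
               stop_t = segs$stop_t[segs$set_label %in% lbl])
  }
  fn1 <- compute_fn(bsm, epoch_bin_mask(bsm, seg_ep("reachSet1")),
                    "reachFN1")
  fn2 <- compute_fn(bsm, epoch_bin_mask(bsm, seg_ep("reachSet2")),
                    "reachFN2")
  fns <- compute_fn(bsm, !epoch_bin_mask(bsm, seg_ep(c("reachSet1",
                                                       "reachSet2"))),
                    "spontaneousFN")
  rates <- vapply(ses$spike_times, length, numeric(1)) /
    diff(ses$session_span)
  .study_cache$study <- list(ses = ses, series = s, velocity = v,
                             segments = segs, spec = spec, samples = samp,
                             bsm = bsm, fn1 = fn1, fn2 = fn2, fns = fns,
                             rates = rates)
  .study_cache$study
}

# Memoized per-unit model fits on the acceptance study (the expensive part,
# shared by several acceptance criteria).
acceptance_fits <- function() {
  if (!is.null(.study_cache$fits)) return(.study_cache$fits)
  st <- acceptance_study()
  n_units <- length(st$ses$spike_times)
  rows <- vector("list", n_units)
  fn_fits <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    dk <- build_design(st$samples, "full_kinematics", u)
    dn <- build_design(st$samples, "kin_plus_FN", u,
                       fn_pair = list(st$fn1, st$fn2))
    fit_kin <- fit_glm_ridge(dk$X, dk$y, 0.05)
    fk6 <- run_splits(dk, alpha = 1e-6, n_splits = 25, seed = 5 + u)
    fnr <- run_splits(dn, alpha = 1e-6, n_splits = 25, seed = 5 + u)
    ct <- crosstest_spont_fn(st$samples, u, st$fns, list(st$fn1, st$fn2),
                             n_splits = 40, seed = 5 + u)
    k_idx <- seq_len(3 * n_traj_points(st$spec))
    r <- pathlet_correlation(
      integrate_pathlet(fit_kin$coefficients[k_idx], st$spec),
      integrate_pathlet(st$ses$truth$K[u, ], st$spec))$r
    rows[[u]] <- c(gain = mean(fnr$auc_per_split) - mean(fk6$auc_per_split),
                   r_path = r,
                   delta = ct$delta,
                   auc_fn = mean(fnr$auc_per_split))
    fn_fits[[u]] <- fnr
  }
  .study_cache$fits <- list(stats = do.call(rbind, rows), fn_fits = fn_fits)
  .study_cache$fits
}
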