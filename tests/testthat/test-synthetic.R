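test_that("kinematics generation is deterministic and rejects bad inputs", {
  a <- generate_kinematics(2, seed = 5, mean_gap_s = 5)
  b <- generate_kinematics(2, seed = 5, mean_gap_s = 5)
  expect_identical(a$series$hand, b$series$hand)
  expect_identical(a$epochs, b$epochs)
  c2 <- generate_kinematics(2, seed = 6, mean_gap_s = 5)
  expect_false(identical(a$series$hand, c2$series$hand))
  expect_error(generate_kinematics(0, seed = 1), "n_reaches")
  expect_error(generate_kinematics(2, frame_rate = 50, seed = 1),
               "frame_rate")
  expect_error(generate_kinematics(2, mean_gap_s = -1, seed = 1),
               "mean_gap_s")
})

test_that("epochs are ordered, non-overlapping and cover the session", {
  kin <- generate_kinematics(4, seed = 8, mean_gap_s = 6)
  ep <- kin$epochs
  expect_true(all(diff(ep$start_t) > 0))
  expect_true(all(ep$stop_t[-nrow(ep)] <= ep$start_t[-1] + 1e-9))
  expect_equal(ep$start_t[1], 0)
  expect_equal(sum(ep$label == "reach"), 4)
})

test_that("a noise-free single extension has the minimum-jerk speed peak", {
  kin <- generate_kinematics(1, seed = 9, noise_sd = 0, mean_gap_s = 5)
  ep <- kin$epochs[kin$epochs$label == "reach", ]
  v <- hand_velocity(kin$series)
  speed <- sqrt(rowSums(v^2))
  tt <- kin$series$time
  # find the first extension: from movement onset to the first speed
  # minimum after the peak; minimum-jerk speed is symmetric about its peak
  infl <- which(tt >= ep$start_t & tt <= ep$stop_t)
  pk <- infl[which.max(speed[infl])]
  # locate the flanking sub-threshold crossings of the first movement piece
  lo <- pk; while (lo > 1 && speed[lo - 1] > 0.05) lo <- lo - 1
  hi <- pk; while (hi < length(tt) && speed[hi + 1] > 0.05) hi <- hi + 1
  mid <- (tt[lo] + tt[hi]) / 2
  expect_lt(abs(tt[pk] - mid), 0.06)  # peak near the midpoint
})

test_that("dropout bursts flag the expected binomial fraction of frames", {
  kin <- generate_kinematics(5, seed = 13, frame_rate = 150,
                             mean_gap_s = 13.5, dropout_fraction = 0.1)
  n <- length(kin$series$time)
  expect_gt(n, 9000)
  flagged <- kin$series$reprojection_error > 20 | kin$series$n_cameras < 2
  expect_equal(sum(flagged) / n, 0.1, tolerance = 0.1)  # 10% +/- 1 pt
  # flagged frames come in bursts, not isolated singletons
  r <- rle(as.numeric(flagged))
  expect_gt(mean(r$lengths[r$values == 1]), 2)
})

test_that("ground truth populations satisfy their structural invariants", {
  tr <- ground_truth_population(40, seed = 3)
  expect_equal(diag(tr$B_reach), rep(0, 40))
  expect_equal(diag(tr$B_spont), rep(0, 40))
  free <- !tr$mask
  expect_equal(tr$B_reach[free, free], tr$B_spont[free, free])
  # masked rows are reach-only
  expect_true(all(tr$B_spont[tr$mask, ] == 0))
  rates <- exp(tr$gamma) / 0.010
  expect_true(all(rates >= 0.5 & rates <= 50))
  expect_equal(sum(tr$mask), 8)  # 20% of 40
})

test_that("doubling the trajectory coefficients doubles the velocity drive", {
  tr <- ground_truth_population(3, seed = 4)
  set.seed(1)
  V <- matrix(rnorm(10 * 48, sd = 0.02), 10, 48)  # small: below the clip
  P <- matrix(0, 10, 3)
  base <- log_intensity(tr, V, P, s_prev = rep(0, 3))
  tr2 <- tr
  tr2$K <- 2 * tr$K
  doubled <- log_intensity(tr2, V, P, s_prev = rep(0, 3))
  drive1 <- sweep(base, 2, tr$gamma, `-`)
  drive2 <- sweep(doubled, 2, tr$gamma, `-`)
  expect_equal(drive2, 2 * drive1, tolerance = 1e-12)
})

test_that("homogeneous Poisson spiking reproduces its rate", {
  kin <- generate_kinematics(2, seed = 15, mean_gap_s = 30)
  tr <- ground_truth_population(4, seed = 15, tuning_sd = 1e-6,
                                pos_coef_sd = 0, frac_specific = 0,
                                frac_uncoupled = 1, rate_range = c(10, 10.1))
  tr$gamma[] <- log(0.1)
  sp <- generate_spikes(kin, kin$epochs, tr, seed = 77)
  mean_counts <- colMeans(sp$counts)
  expect_equal(mean_counts, rep(0.1, 4), tolerance = 0.05)
  # determinism
  sp2 <- generate_spikes(kin, kin$epochs, tr, seed = 77)
  expect_identical(sp$spike_times, sp2$spike_times)
  sp3 <- generate_spikes(kin, kin$epochs, tr, seed = 78)
  expect_false(identical(sp$spike_times, sp3$spike_times))
})

test_that("positive coupling raises the conditional spike probability", {
  kin <- generate_kinematics(2, seed = 16, mean_gap_s = 40)
  tr <- ground_truth_population(2, seed = 16, tuning_sd = 1e-6,
                                pos_coef_sd = 0, frac_specific = 0,
                                frac_uncoupled = 1, rate_range = c(5, 5.1))
  tr$B_reach[1, 2] <- tr$B_spont[1, 2] <- 1.5
  tr$gamma[] <- log(0.05)
  sp <- generate_spikes(kin, kin$epochs, tr, seed = 3)
  s1 <- sp$counts[, 1] > 0
  s2prev <- c(FALSE, sp$counts[-nrow(sp$counts), 2] > 0)
  p_cond <- mean(s1[s2prev])
  p_marg <- mean(s1)
  expect_gt(p_cond, p_marg * 2)
})

test_that("the stability cap aborts runaway intensities with a diagnostic", {
  kin <- generate_kinematics(1, seed = 17, mean_gap_s = 5)
  tr <- ground_truth_population(2, seed = 17)
  tr$gamma[] <- log(0.45)  # 45 spikes/s baseline: legal, but unstable
  tr$B_reach[1, 2] <- tr$B_spont[1, 2] <- 1.0
  expect_error(generate_spikes(kin, kin$epochs, tr, seed = 1),
               "stability cap")
})

test_that("default sessions honor their profile contracts", {
  ses <- make_default_session("small", seed = 2)
  expect_equal(length(ses$spike_times), 20)
  expect_equal(sum(ses$epochs$label == "reach"), 20)
  # invariants: ordered epochs, spikes inside the span
  expect_true(all(diff(ses$epochs$start_t) > 0))
  for (st in ses$spike_times) {
    if (length(st)) {
      expect_true(all(st >= ses$session_span[1] &
                        st <= ses$session_span[2] + 0.01))
    }
  }
  ses2 <- make_default_session("small", seed = 2)
  expect_identical(ses$spike_times, ses2$spike_times)
  ses3 <- make_default_session("small", seed = 3)
  expect_false(identical(ses$spike_times, ses3$spike_times))
  expect_error(make_default_session("huge"), "arg")
})

test_that("sessions export to plain-text files and record parameters", {
  ses <- make_default_session("small", seed = 4, n_units = 5, n_reaches = 3,
                              mean_gap_s = 4)
  dir <- tempfile()
  write_session(ses, dir)
  expect_true(file.exists(file.path(dir, "kinematics.csv")))
  expect_true(file.exists(file.path(dir, "epochs.csv")))
  expect_length(list.files(file.path(dir, "spikes")), 5)
  params <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(params$seed, 4)
  expect_equal(params$n_units, 5)
  unlink(dir, recursive = TRUE)
})

test_that("reach and spontaneous conMI differ most among the planted group", {
  ses <- make_default_session("small", seed = 6, n_units = 24,
                              n_reaches = 25, mean_gap_s = 7)
  bsm <- binarize(ses$spike_times, ses$session_span)
  rmask <- epoch_bin_mask(bsm, ses$epochs[ses$epochs$label == "reach", ])
  fn_r <- compute_fn(bsm, rmask, "reach", min_bins = 500)
  fn_s <- compute_fn(bsm, !rmask, "spont")
  D <- abs(fn_r$W - fn_s$W)
  off <- row(D) != col(D)
  m <- ses$truth$mask
  masked_pairs <- off & outer(m, m, `&`)
  free_pairs <- off & outer(!m, !m, `&`)
  expect_gt(median(D[masked_pairs]), 2 * median(D[free_pairs]))
})

test_that("planted couplings rank above non-edges in estimated networks", {
  ses <- make_default_session("small", seed = 6, n_units = 24,
                              n_reaches = 25, mean_gap_s = 7)
  bsm <- binarize(ses$spike_times, ses$session_span)
  rmask <- epoch_bin_mask(bsm, ses$epochs[ses$epochs$label == "reach", ])
  fn_r <- compute_fn(bsm, rmask, "reach", min_bins = 500)
  fn_s <- compute_fn(bsm, !rmask, "spont")
  off <- row(fn_r$W) != col(fn_r$W)
  # spontaneous context: many bins, invariant couplings cleanly detected
  auc_s <- auc_score(fn_s$W[off], ses$truth$B_spont[off] > 0)
  expect_gt(auc_s, 0.8)
  # reach context: fewer bins and shared drive, but edges still rank high
  auc_r <- auc_score(fn_r$W[off], ses$truth$B_reach[off] > 0)
  expect_gt(auc_r, 0.6)
})

test_that("lead-lag sweep and shuffle control run end to end on a session", {
  ses <- make_default_session("small", seed = 9, n_units = 6, n_reaches = 15,
                              mean_gap_s = 6)
  s <- smooth_series(clean_tracking(ses$series))
  v <- hand_velocity(s)
  segs <- assign_reach_sets(segment_reaches(s, v), seed = 2)
  specs <- default_leadlag_sweep()
  u <- which.max(ses$truth$tuning)  # the most strongly tuned unit
  aucs <- sapply(specs, function(sp) {
    samp <- extract_samples(s, v, ses$spike_times, segs, sp,
                            session_span = ses$session_span)
    f <- run_splits(build_design(samp, "full_kinematics", u),
                    n_splits = 3, seed = 11)
    mean(f$auc_per_split)
  })
  expect_length(aucs, 17)
  expect_true(all(is.finite(aucs)))
  # shuffling kinematics against spikes destroys the tuning
  samp <- extract_samples(s, v, ses$spike_times, segs, lead_lag(100, 300),
                          session_span = ses$session_span)
  real <- run_splits(build_design(samp, "full_kinematics", u),
                     n_splits = 12, seed = 12)
  shuf <- run_splits(build_design(shuffle_control(samp, "total", seed = 3),
                                  "full_kinematics", u),
                     n_splits = 12, seed = 12)
  expect_gt(mean(real$auc_per_split), mean(shuf$auc_per_split))
  expect_lt(abs(mean(shuf$auc_per_split) - 0.5), 0.08)
})
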