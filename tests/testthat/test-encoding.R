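make_samples <- function(n = 700, n_units = 4, spec = lead_lag(100, 300),
                         seed = 1) {
  set.seed(seed)
  p <- n_traj_points(spec)
  structure(list(
    V = matrix(rnorm(n * 3 * p, sd = 0.1), n, 3 * p),
    P = matrix(rnorm(n * 3, sd = 0.02), n, 3),
    counts = matrix(rpois(n * n_units, 0.1), n, n_units),
    S0 = matrix(rbinom(n * n_units, 1, 0.2), n, n_units),
    S1 = matrix(rbinom(n * n_units, 1, 0.2), n, n_units),
    t0 = seq_len(n) * 0.03, segment = rep(1L, n),
    reach_set = rep(c("reachSet1", "reachSet2"), length.out = n),
    spec = spec
  ), class = "kinematic_sample_set")
}

toy_fn <- function(W, context = "toy") {
  structure(list(W = W, context = context, n_bins_used = 1000),
            class = "functional_network")
}

test_that("design matrices have the documented column structure", {
  samp <- make_samples()
  expect_equal(ncol(build_design(samp, "trajectory", 1)$X), 48)
  expect_equal(ncol(build_design(samp, "full_kinematics", 1)$X), 51)
  W <- matrix(0.1, 4, 4); diag(W) <- 0
  d <- build_design(samp, "kin_plus_FN", 1, fn = toy_fn(W))
  expect_equal(ncol(d$X), 53)
  expect_equal(d$layout$network, 52:53)
  brief <- make_samples(spec = lead_lag(-100, 150))
  expect_equal(ncol(build_design(brief, "velocity", 1)$X), 6)
  expect_equal(ncol(build_design(brief, "short_kinematics", 1)$X), 9)
  # brief families reject full-window samples
  expect_error(build_design(samp, "velocity", 1), "brief")
})

test_that("network features are the in-weighted sums of source states", {
  samp <- make_samples(n = 5, n_units = 3)
  W <- matrix(c(0, 0.2, 0.3,
                0.1, 0, 0.4,
                0.5, 0.6, 0), 3, 3, byrow = TRUE)
  FF <- network_features(samp, toy_fn(W), target_unit = 1)
  manual_F0 <- samp$S0[, 2] * 0.2 + samp$S0[, 3] * 0.3
  manual_F1 <- samp$S1[, 2] * 0.2 + samp$S1[, 3] * 0.4  # row 1 weights
  expect_equal(unname(FF[, "F0"]), manual_F0)
  expect_equal(unname(FF[, "F1"]),
               samp$S1[, 2] * 0.2 + samp$S1[, 3] * 0.3)
  # all-zero source states give zero features
  samp0 <- samp; samp0$S0[] <- 0L; samp0$S1[] <- 0L
  expect_true(all(network_features(samp0, toy_fn(W), 1) == 0))
  expect_error(network_features(samp, toy_fn(W), 9), "unknown target")
})

test_that("cross-pairing swaps the reach networks between sample sets", {
  samp <- make_samples(n = 6, n_units = 2)
  W1 <- matrix(c(0, 1, 1, 0), 2, 2)
  W2 <- matrix(c(0, 3, 3, 0), 2, 2)
  FF <- network_features(samp, target_unit = 1,
                         fn_pair = list(toy_fn(W1), toy_fn(W2)))
  set1 <- samp$reach_set == "reachSet1"
  expect_equal(unname(FF[set1, "F0"]), 3 * samp$S0[set1, 2])
  expect_equal(unname(FF[!set1, "F0"]), 1 * samp$S0[!set1, 2])
})

test_that("noiseless Poisson responses are recovered at vanishing penalty", {
  set.seed(2)
  X <- matrix(rnorm(2000 * 5), 2000, 5)
  beta <- c(0.5, -0.3, 0.2, 0.1, -0.4)
  y <- exp(-2 + X %*% beta)   # noiseless conditional intensity
  fit <- fit_glm_ridge(X, y, alpha = 1e-10)
  expect_lt(max(abs(fit$coefficients - beta) / abs(beta)), 0.01)
  expect_lt(abs(fit$intercept - (-2)), 0.01)
})

test_that("ridge shrinks coefficients monotonically while tracking the mean", {
  set.seed(3)
  X <- matrix(rnorm(500 * 4), 500, 4)
  y <- rpois(500, exp(-1.5 + X %*% c(0.4, -0.2, 0.3, 0.1)))
  norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(a) {
    sqrt(sum(fit_glm_ridge(X, y, a)$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  big <- fit_glm_ridge(X, y, 1e4)
  expect_lt(abs(big$intercept - log(mean(y))), 0.05)
  expect_error(fit_glm_ridge(X, rep(0, 500), 0.05), "identically zero")
})

test_that("penalized likelihood at the optimum beats the zero vector", {
  set.seed(8)
  for (rep in 1:5) {
    X <- matrix(rnorm(300 * 6), 300, 6)
    y <- rpois(300, exp(-2 + X %*% rnorm(6, sd = 0.3)))
    if (all(y == 0)) next
    a <- runif(1, 0.01, 1)
    fit <- fit_glm_ridge(X, y, a)
    ll0 <- sum(y * 0 - exp(0))      # eta = 0 everywhere, beta = 0
    expect_gte(fit$penalized_loglik, ll0)
  }
})

test_that("AUC matches the brute-force pairwise comparison on random data", {
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_score(rep(1, 10), rbinom(10, 1, 0.5)), 0.5)
  ord <- c(rep(0, 5), rep(1, 5))
  expect_equal(auc_score(seq_len(10), ord), 1)
  expect_true(is.na(auc_score(1:5, rep(1, 5))))
  set.seed(4)
  for (rep in 1:30) {
    n <- sample(10:200, 1)
    scores <- sample(round(runif(n), 2))  # force some ties
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auc_score(scores, labels),
                 auc_pairwise_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("split resampling is seeded and honest about chance data", {
  samp <- make_samples(n = 700, seed = 5)
  d <- build_design(samp, "full_kinematics", 1)
  f1 <- run_splits(d, n_splits = 5, seed = 42)
  f2 <- run_splits(d, n_splits = 5, seed = 42)
  expect_identical(f1$auc_per_split, f2$auc_per_split)
  expect_false(identical(f1$auc_per_split,
                         run_splits(d, n_splits = 5, seed = 43)$auc_per_split))
  # perfectly separable toy data: every split reaches AUC 1
  X <- cbind(c(rep(0, 150), rep(1, 150)))
  dsep <- list(X = cbind(X, X, X), y = c(rep(0, 150), rep(3, 150)),
               layout = list(velocity = 1:3), family = "trajectory",
               spec = lead_lag(100, 300), target_unit = 1)
  fs <- run_splits(dsep, alpha = 1e-4, n_splits = 10, seed = 1)
  expect_true(all(fs$auc_per_split == 1))
})

test_that("null spikes give chance-level held-out AUC", {
  set.seed(6)
  samp <- make_samples(n = 2000, seed = 6)
  samp$counts[, 1] <- rbinom(2000, 1, 0.1)  # independent of kinematics
  d <- build_design(samp, "full_kinematics", 1)
  f <- run_splits(d, n_splits = 10, seed = 9)
  expect_lt(abs(mean(f$auc_per_split) - 0.5), 0.03)
})

test_that("shuffle controls permute exactly the advertised blocks", {
  samp <- make_samples(n = 50)
  tot <- shuffle_control(samp, "total", seed = 3)
  expect_equal(sort(as.numeric(tot$V)), sort(as.numeric(samp$V)))
  expect_equal(sort(as.numeric(tot$P)), sort(as.numeric(samp$P)))
  expect_identical(tot$counts, samp$counts)        # spikes fixed
  traj <- shuffle_control(samp, "trajectory", seed = 3)
  expect_identical(traj$P, samp$P)                 # position-spike intact
  expect_false(identical(traj$V, samp$V))
})

test_that("tuning test applies the one-sided sign test with Bonferroni", {
  res <- tuning_test(rep(1, 10), rep(0, 10), n_comparisons = 1)
  expect_equal(res$p_raw, 2^-10)
  res2 <- tuning_test(rep(1, 10), rep(0, 10), n_comparisons = 100)
  expect_equal(res2$p_value, min(1, 100 * 2^-10))
  expect_false(res2$significant)   # Bonferroni pushes it past 0.01
  res3 <- tuning_test(rep(1, 16), rep(0, 16), n_comparisons = 100)
  expect_true(res3$significant)
})

test_that("lead-lag sweep flags the dominant window and the tied case", {
  specs <- default_leadlag_sweep()
  expect_length(specs, 17)
  durs <- vapply(specs, function(s) s$lead_ms + s$lag_ms, numeric(1))
  expect_true(all(durs >= 300 & durs <= 500))
  set.seed(10)
  col <- 0.6 + rnorm(40, sd = 0.01)
  base <- cbind(col, col, col)
  # all specs fed identical data: everything non-inferior
  sw <- leadlag_sweep(base, list(lead_lag(100, 300), lead_lag(0, 300),
                                 lead_lag(200, 200)))
  expect_true(all(sw$table$non_inferior))
  # one strictly dominant spec is selected best
  set.seed(11)
  dom <- base + matrix(rnorm(120, sd = 0.005), 40, 3)
  dom[, 2] <- dom[, 2] + 0.1
  sw2 <- leadlag_sweep(dom, list(lead_lag(100, 300), lead_lag(0, 300),
                                 lead_lag(200, 200)))
  expect_equal(sw2$best, 2L)
  expect_false(sw2$table$non_inferior[1])
})

test_that("in-weight correlates flag degenerate uniform networks", {
  W <- matrix(0.2, 5, 5); diag(W) <- 0
  out <- inweight_correlates(runif(5, 0.5, 0.8), fn = W)
  expect_false(out$defined[1])
  # planted: tuning scales with in-weight
  set.seed(12)
  iw <- runif(40, 0, 0.4)
  W2 <- matrix(0, 40, 40)
  for (i in 1:40) W2[i, -i] <- iw[i]
  auc <- 0.55 + 0.5 * iw + rnorm(40, sd = 0.02)
  out2 <- inweight_correlates(auc, auc + 0.02 * iw / max(iw), W2)
  expect_gt(out2$r[1], 0.2)
})

test_that("encoding fits serialize to JSON with their AUC trace", {
  samp <- make_samples(n = 700, seed = 15)
  f <- run_splits(build_design(samp, "full_kinematics", 1),
                  n_splits = 3, seed = 2)
  path <- tempfile(fileext = ".json")
  write_encoding_fit(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$family, "full_kinematics")
  expect_length(back$coefficients$k, 48)
  aucs <- utils::read.csv(sub("\\.json$", "_aucs.csv", path))
  expect_equal(aucs$auc, f$auc_per_split)
  unlink(c(path, sub("\\.json$", "_aucs.csv", path)))
})
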