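toy_W <- function(n = 6, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(n * n, 0.01, 1), n, n)
  diag(W) <- 0
  W
}

test_that("strong-edge selection ranks, rounds and breaks ties deterministically", {
  W <- toy_W(10)
  all_edges <- select_strong_edges(W, 1)
  expect_equal(nrow(all_edges), 90)
  top <- select_strong_edges(W, 0.1)
  expect_equal(nrow(top), 9)
  off <- W[row(W) != col(W)]
  expect_gte(min(top$weight), sort(off, decreasing = TRUE)[9])
  expect_false(any(top$source == top$target))
  # ties straddling the cut: lexicographic (source, target) order decides
  Wt <- matrix(0, 4, 4)
  Wt[1, 2] <- Wt[2, 1] <- Wt[3, 1] <- 0.5  # three tied edges
  Wt[4, 1] <- 0.9
  sel <- select_strong_edges(Wt, round(2 / 12, 3))  # -> 2 edges
  expect_equal(nrow(sel), 2)
  expect_equal(sel$weight[1], 0.9)
  # among the tied 0.5s, the smallest (source, target) wins: source 1 -> t2
  expect_equal(sel$source[2], 1)
  expect_equal(sel$target[2], 2)
  expect_error(select_strong_edges(W, 0), "fraction")
})

test_that("weight permutation shuffles only the group and conserves weights", {
  W <- toy_W(8)
  grp <- select_strong_edges(W, 0.25)
  Wp <- permute_weights(W, grp, seed = 3)
  pos <- cbind(grp$target, grp$source)
  expect_equal(sort(Wp[pos]), sort(W[pos]))          # multiset preserved
  untouched <- matrix(TRUE, 8, 8)
  untouched[pos] <- FALSE
  expect_equal(Wp[untouched], W[untouched])
  expect_equal(sort(as.numeric(Wp)), sort(as.numeric(W)))
  # single-edge group: permutation is the identity
  one <- grp[1, , drop = FALSE]
  expect_identical(permute_weights(W, one, seed = 5), W)
})

test_that("target permutation preserves column multisets and forces the 2-edge swap", {
  # both group edges share source 1 in a 3-unit net: each must take the
  # other's target (the single valid derangement)
  W <- matrix(0, 3, 3)
  W[2, 1] <- 0.7; W[3, 1] <- 0.2; W[1, 2] <- 0.4; W[3, 2] <- 0.1
  grp <- data.frame(source = c(1, 1), target = c(2, 3),
                    weight = c(0.7, 0.2))
  Wp <- permute_targets(W, grp, seed = 1)
  expect_equal(Wp[2, 1], 0.2)
  expect_equal(Wp[3, 1], 0.7)
  expect_equal(Wp[1, 2], 0.4)  # non-group column untouched
  # general case: global multiset and per-source out-weight multisets hold
  W2 <- toy_W(9, seed = 4)
  grp2 <- select_strong_edges(W2, 0.2)
  Wp2 <- permute_targets(W2, grp2, seed = 9)
  expect_equal(sort(as.numeric(Wp2)), sort(as.numeric(W2)))
  for (s in 1:9) expect_equal(sort(Wp2[, s]), sort(W2[, s]))
  # group edges vacated their original targets
  moved <- Wp2[cbind(grp2$target, grp2$source)] != grp2$weight
  expect_true(all(moved | duplicated(round(grp2$weight, 12))))
})

test_that("AUC loss is zero for identity manipulations and honors removal", {
  set.seed(20)
  n <- 700
  samp <- structure(list(
    V = matrix(rnorm(n * 48, sd = 0.1), n, 48),
    P = matrix(rnorm(n * 3, sd = 0.02), n, 3),
    counts = matrix(rpois(n * 3, 0.15), n, 3),
    S0 = matrix(rbinom(n * 3, 1, 0.25), n, 3),
    S1 = matrix(rbinom(n * 3, 1, 0.25), n, 3),
    t0 = seq_len(n) * 0.03, segment = rep(1L, n),
    reach_set = rep(c("reachSet1", "reachSet2"), length.out = n),
    spec = lead_lag(100, 300)
  ), class = "kinematic_sample_set")
  # plant dependence of unit 1 on unit 2's leading state
  samp$counts[, 1] <- rpois(n, exp(-2.2 + 1.3 * samp$S1[, 2]))
  W <- matrix(0, 3, 3); W[1, 2] <- 0.3; W[1, 3] <- 0.05
  fn <- structure(list(W = W, context = "toy", n_bins_used = 1000),
                  class = "functional_network")
  des <- build_design(samp, "kin_plus_FN", 1, fn_pair = list(fn, fn))
  fit <- run_splits(des, alpha = 1e-6, n_splits = 4, seed = 2)
  same <- auc_loss(fit, samp, list(W, W))
  expect_equal(same$loss_pct, 0, tolerance = 1e-9)
  rem <- auc_loss(fit, samp, mode = "removal")
  expect_gt(rem$loss_pct, 0)
  # removal for a unit whose network coefficients are zero loses nothing
  fit0 <- fit
  fit0$fit$coefficients[fit0$layout$network] <- 0
  fit0$target_unit <- 1
  rem0 <- auc_loss(fit0, samp, mode = "removal")
  expect_equal(rem0$loss_pct, 0, tolerance = 1e-9)
})

test_that("permuting the informative strong edges costs more than random ones", {
  set.seed(33)
  n <- 900; n_units <- 8
  S0 <- matrix(rbinom(n * n_units, 1, 0.25), n, n_units)
  S1 <- matrix(rbinom(n * n_units, 1, 0.25), n, n_units)
  samp <- structure(list(
    V = matrix(rnorm(n * 48, sd = 0.1), n, 48),
    P = matrix(rnorm(n * 3, sd = 0.02), n, 3),
    counts = matrix(rpois(n * n_units, 0.1), n, n_units),
    S0 = S0, S1 = S1,
    t0 = seq_len(n) * 0.03, segment = rep(1L, n),
    reach_set = rep(c("reachSet1", "reachSet2"), length.out = n),
    spec = lead_lag(100, 300)
  ), class = "kinematic_sample_set")
  # unit 1 driven by units 2 and 3; W concentrates weight there
  samp$counts[, 1] <- rpois(n, exp(-2.5 + 1.5 * S1[, 2] + 1.2 * S1[, 3]))
  W <- matrix(runif(64, 0, 0.02), 8, 8); diag(W) <- 0
  W[1, 2] <- 0.5; W[1, 3] <- 0.4
  fn <- structure(list(W = W, context = "toy", n_bins_used = 1000),
                  class = "functional_network")
  des <- build_design(samp, "kin_plus_FN", 1, fn_pair = list(fn, fn))
  fit <- run_splits(des, alpha = 1e-6, n_splits = 4, seed = 7)
  out <- permutation_experiment(list(fit), samp, list(fn, fn),
                                fractions = 0.05, mode = "weights",
                                n_shuffles = 20, seed = 21)
  expect_true(out$summary$strong_gt_random)
  expect_lt(out$summary$p_strong_gt_random, 0.01)
  # removal bounds the permutation losses (up to Monte-Carlo error)
  expect_gte(out$summary$mean_loss_removal + 5,
             out$summary$mean_loss_strongest)
  # fraction 1: strongest and random groups coincide in expectation
  out1 <- permutation_experiment(list(fit), samp, list(fn, fn),
                                 fractions = 1, mode = "weights",
                                 n_shuffles = 6, seed = 22)
  expect_gt(out1$summary$p_strong_gt_random, 0.01)
})

test_that("target-unit permutation plugs into the experiment harness", {
  set.seed(44)
  n <- 700; n_units <- 6
  samp <- structure(list(
    V = matrix(rnorm(n * 48, sd = 0.1), n, 48),
    P = matrix(rnorm(n * 3, sd = 0.02), n, 3),
    counts = matrix(rpois(n * n_units, 0.1), n, n_units),
    S0 = matrix(rbinom(n * n_units, 1, 0.25), n, n_units),
    S1 = matrix(rbinom(n * n_units, 1, 0.25), n, n_units),
    t0 = seq_len(n) * 0.03, segment = rep(1L, n),
    reach_set = rep(c("reachSet1", "reachSet2"), length.out = n),
    spec = lead_lag(100, 300)
  ), class = "kinematic_sample_set")
  samp$counts[, 1] <- rpois(n, exp(-2.4 + 1.4 * samp$S1[, 2]))
  W <- matrix(runif(36, 0, 0.02), 6, 6); diag(W) <- 0
  W[1, 2] <- 0.5
  fn <- structure(list(W = W, context = "toy", n_bins_used = 1000),
                  class = "functional_network")
  fit <- run_splits(build_design(samp, "kin_plus_FN", 1,
                                 fn_pair = list(fn, fn)),
                    alpha = 1e-6, n_splits = 3, seed = 5)
  out <- permutation_experiment(list(fit), samp, list(fn, fn),
                                fractions = c(0.1, 0.3), mode = "targets",
                                n_shuffles = 5, seed = 31)
  expect_equal(nrow(out$summary), 2)
  expect_true(all(is.finite(out$losses$loss_pct)))
  expect_equal(out$summary$mode, c("targets", "targets"))
})
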