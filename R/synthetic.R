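#' Ground-truth population for the coupled spike simulator
#'
#' Draws baseline log-rates, preferred velocity trajectories (smooth random
#' 3D curves on the encoding grid), position coefficients and directed
#' log-linear coupling matrices for reach and spontaneous contexts. A
#' planted context-specific subgroup (`mask`) is interconnected by couplings
#' that exist only during reaching; a further subset of unmasked units
#' carries context-invariant couplings (identical in both contexts) and the
#' remainder is uncoupled. Coupling totals per target are heterogeneous
#' (log-uniform-ish ranges) so downstream network-feature gains vary across
#' the population, as they do in real recordings.
#'
#' @param n_units Number of units.
#' @param seed Integer seed.
#' @param spec [lead_lag()] window defining the layout of the true preferred
#'   trajectories (default `[-100, +300]` ms).
#' @param frac_specific Fraction of units in the context-specific subgroup
#'   (default 0.2).
#' @param frac_uncoupled Fraction of unmasked units with no incoming
#'   couplings (default 0.4).
#' @param rate_range Baseline firing-rate range under zero drive, spikes/s
#'   (default `c(2, 10)`); each unit's baseline is then clamped so its
#'   worst-case expected count per bin (full kinematic drive plus saturated
#'   coupling) stays below `stability_cap`.
#' @param tuning_sd Range of the per-unit standard deviation of the
#'   velocity log-drive during movement for uncoupled units (default
#'   `c(0.6, 0.9)`; a scalar gives every unit the same strength).
#' @param tuning_coupled Tuning-strength range for context-invariant
#'   coupled units (default `c(0.4, 0.6)`): weak, so their conMI edges
#'   stand out over shared-drive co-modulation.
#' @param tuning_specific Tuning-strength range for the context-specific
#'   subgroup (default `c(0.75, 0.80)`): tuned above the invariant coupled
#'   pool, mirroring the empirical association between context specificity
#'   and kinematic tuning. The range is deliberately narrow: with the
#'   stability budget, tuning sets the group's firing rates, and a
#'   homogeneous group makes the planted coupling ladder -- not rate
#'   differences -- the dominant source of variation in cross-context
#'   generalization deficits.
#' @param v_scale Typical per-axis velocity scale (default 0.1 m/s) used
#'   in the tuning calibration.
#' @param pos_coef_sd Spread of the mean-position coefficients (default
#'   0.4, log-rate per meter).
#' @param n_in In-degree of each coupled target (default 2).
#' @param b_tot_specific,b_tot_invariant Ranges of summed incoming coupling
#'   per target for masked / coupled-unmasked units.
#' @param coup_cap Coupling-drive saturation the simulator will apply
#'   (stored with the truth so simulation and stability budgeting agree);
#'   the kinematic-drive clip is derived per unit as 3.3x its tuning
#'   strength.
#' @param stability_cap Worst-case expected spikes per bin allowed per unit
#'   (default 0.90, just under the simulator's abort threshold).
#' @return A `ground_truth_population` list: `gamma`, `K` (units x 3p), `C`
#'   (units x 3), `B_reach`, `B_spont`, `mask`, `coupled`, `spec`.
#' @export
ground_truth_population <- function(n_units, seed, spec = lead_lag(100, 300),
                                    frac_specific = 0.2,
                                    frac_uncoupled = 0.4,
                                    rate_range = c(2, 10),
                                    tuning_sd = c(0.6, 0.9),
                                    tuning_coupled = c(0.4, 0.6),
                                    tuning_specific = c(0.75, 0.80),
                                    v_scale = 0.1,
                                    pos_coef_sd = 0.4,
                                    n_in = 2L,
                                    b_tot_specific = c(2.25, 2.55),
                                    b_tot_invariant = c(1.8, 2.4),
                                    coup_cap = 1.2,
                                    stability_cap = 0.90) {
  p <- n_traj_points(spec)
  if (length(tuning_sd) == 1) tuning_sd <- rep(tuning_sd, 2)
  pick <- function(x, k) x[sample.int(length(x), k)]  # safe for length 1
  local_seed(seed, {
    gamma <- log(stats::runif(n_units, rate_range[1], rate_range[2]) * 0.010)

    mask <- rep(FALSE, n_units)
    mask[sample.int(n_units, round(frac_specific * n_units))] <- TRUE
    unmasked <- which(!mask)
    uncoupled <- pick(unmasked, round(frac_uncoupled * length(unmasked)))
    coupled_inv <- setdiff(unmasked, uncoupled)

    # heterogeneous tuning strength: per-unit sd of the velocity log-drive.
    # The context-specific subgroup is strongly tuned (as its real-data
    # counterpart is) -- its reach co-modulation is itself reach-specific.
    # Context-invariant coupled targets are weakly tuned so their conMI
    # edges stand out over shared-drive co-modulation, and a unit cannot be
    # both maximally driven and strongly coupled without saturating the
    # stability budget of a log-linear model. Uncoupled units sit in
    # between, with the highest stable firing rates.
    tuning <- stats::runif(n_units, tuning_sd[1], tuning_sd[2])
    tuning[coupled_inv] <- stats::runif(length(coupled_inv),
                                        tuning_coupled[1], tuning_coupled[2])
    tuning[mask] <- stats::runif(sum(mask), tuning_specific[1],
                                 tuning_specific[2])
    # smooth random preferred trajectories: 4 Gaussian bumps per axis
    g <- traj_offsets(spec)
    centers <- seq(min(g), max(g), length.out = 4)
    basis <- sapply(centers, function(c0) exp(-(g - c0)^2 / (2 * 0.15^2)))
    K <- matrix(0, n_units, 3 * p)
    # axis structure of the preferred trajectories: the context-specific
    # subgroup prefers extension (y) -- the movement dimension exercised
    # only during reaching -- while the rest of the population prefers
    # x/z components that occur during both reaching and spontaneous
    # movement, so its kinematic relationships generalize across contexts
    for (u in seq_len(n_units)) {
      cu <- matrix(stats::rnorm(12), 4, 3)
      axis_w <- if (mask[u]) c(0.15, 1, 0.15) else c(1, 0.05, 1)
      cu <- cu * matrix(axis_w, 4, 3, byrow = TRUE)
      curve <- basis %*% cu                      # p x 3 smooth curve
      kvec <- as.numeric(t(curve))               # x-y-z interleaved
      # calibrate so k . v has roughly sd `tuning[u]` during movement; the
      # factor 2.8 accounts for the strong temporal correlation of the
      # velocity samples across the window (smooth trajectories times a
      # smooth k add coherently, not like independent terms)
      kvec <- kvec * tuning[u] / (sqrt(sum(kvec^2)) * v_scale * 2.8)
      K[u, ] <- kvec
    }
    # position coefficients share the axis structure of the velocity
    # tuning: y-position is informative only during reaches, so unmasked
    # units keep their position tuning in the x-z plane
    C <- matrix(stats::rnorm(n_units * 3, sd = pos_coef_sd), n_units, 3)
    C[!mask, 2] <- 0.1 * C[!mask, 2]
    C[mask, c(1, 3)] <- 0.3 * C[mask, c(1, 3)]

    B_reach <- matrix(0, n_units, n_units)
    masked_idx <- which(mask)
    # the context-specific group is densely interconnected within itself
    # (reach-only couplings), twice the in-degree of invariant targets.
    # Coupling totals are stratified evenly across the group from weak to
    # strong, so the planted generalization deficits span a smooth ramp
    # rather than clumping (the spread of coupling strength is a study
    # condition, and even coverage makes every strength represented).
    # log-spaced ladder: the generalization deficit grows roughly
    # exponentially in the coupling total, so spacing the ladder on a log
    # scale makes the planted deficits roughly evenly spaced -- a smooth,
    # constant-slope sorted-deficit curve rather than a top-heavy one
    u <- seq(0, 1, length.out = max(1L, length(masked_idx)))
    R <- exp(4.8 * (b_tot_specific[2] - b_tot_specific[1]))
    b_ladder <- b_tot_specific[1] +
      (b_tot_specific[2] - b_tot_specific[1]) * log1p(u * (R - 1)) / log(R)
    b_ladder <- b_ladder[sample.int(length(b_ladder))]
    for (i in seq_along(masked_idx)) {
      u <- masked_idx[i]
      pool <- setdiff(masked_idx, u)
      deg <- min(2L * n_in, length(pool))
      if (deg == 0) next
      src <- pick(pool, deg)
      w <- stats::runif(deg, 0.5, 1)
      B_reach[u, src] <- b_ladder[i] * w / sum(w)
    }
    B_spont <- B_reach
    B_spont[masked_idx, ] <- 0                  # reach-only couplings
    # invariant couplings stay within the weakly tuned invariant pool, so
    # the same edges carry comparable activity (and conMI) in both contexts
    for (u in coupled_inv) {
      pool <- setdiff(coupled_inv, u)
      if (!length(pool)) next
      src <- pick(pool, min(n_in, length(pool)))
      b_tot <- stats::runif(1, b_tot_invariant[1], b_tot_invariant[2])
      w <- stats::runif(length(src), 0.5, 1)
      B_reach[u, src] <- B_spont[u, src] <- b_tot * w / sum(w)
    }
    # per-unit kinematic drive clip: 2.5 sd of the unit's own drive -- a
    # mild saturation of the rate map that bounds the worst case
    drive_cap <- 2.5 * tuning
    # per-unit stability budget: the worst-case expected count per bin,
    # exp(gamma + drive_cap + min(b_tot, coup_cap)), must stay below the
    # simulator's cap, so strongly tuned or strongly coupled targets get
    # lower baselines (the stability geometry of log-linear models)
    b_load <- pmin(pmax(rowSums(B_reach), rowSums(B_spont)), coup_cap)
    gamma <- pmin(gamma, log(stability_cap) - drive_cap - b_load)
    gamma <- pmax(gamma, log(0.5 * 0.010))   # stay above 0.5 spikes/s
    structure(list(gamma = gamma, K = K, C = C,
                   B_reach = B_reach, B_spont = B_spont,
                   mask = mask,
                   coupled = rowSums(B_reach) > 0 | rowSums(B_spont) > 0,
                   tuning = tuning,
                   spec = spec, drive_cap = drive_cap, coup_cap = coup_cap),
              class = "ground_truth_population")
  })
}

#' @export
print.ground_truth_population <- function(x, ...) {
  cat(sprintf(
    "ground_truth_population: %d units (%d context-specific, %d coupled)\n",
    length(x$gamma), sum(x$mask), sum(x$coupled)))
  invisible(x)
}

#' Generate reach-like 3D marker kinematics with tracking metadata
#'
#' Each reach event is composed of one to three minimum-jerk extension
#' cycles dominated by +y displacement (randomized 5-12 cm amplitudes,
#' direction jitter, brief holds and partial retractions between cycles, as
#' in repeated prey-capture attempts) ending in a full retraction. Events
#' ride on a slow low-pass Gaussian wander (spectral content well below
#' 5 Hz) that models quiet spontaneous movement; the shoulder drifts
#' independently and slowly. Per-frame quality
#' fields are populated, with dropout bursts (high reprojection error or a
#' single tracking camera) injected so that the expected number of flagged
#' frames is `dropout_fraction` of all frames (binomial count, laid out in
#' short bursts).
#'
#' @param n_reaches Number of reach events (>= 1).
#' @param frame_rate Camera rate in Hz (>= 100).
#' @param noise_sd Additive white marker noise (m, default 0.001).
#' @param seed Integer seed.
#' @param mean_gap_s Mean spontaneous gap between reaches (s, default 12).
#' @param dropout_fraction Expected fraction of flagged frames (default
#'   0.02).
#' @return List with `series` (the observed, noisy [marker_series()]),
#'   `series_clean` (the noise-free kinematics that drive the spike
#'   simulator) and `epochs` (data frame: `start_t`, `stop_t`, `label` in
#'   {"reach", "spontaneous"}).
#' @export
generate_kinematics <- function(n_reaches, frame_rate = 150,
                                noise_sd = 0.0002, seed = 1,
                                mean_gap_s = 12, dropout_fraction = 0.02) {
  if (n_reaches < 1) stop("n_reaches must be at least 1")
  if (frame_rate < 100) stop("frame_rate must be at least 100 Hz")
  if (mean_gap_s <= 0) stop("mean_gap_s must be positive")
  local_seed(seed, {
    minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    # A reach event is 1-3 extension cycles (prey pursuit often needs
    # repeated attempts): extend, hold briefly, partially retract,
    # re-extend, ..., then fully retract. Each piece is a minimum-jerk
    # transition of the displacement along the event's direction.
    make_event <- function() {
      n_cyc <- sample.int(3, 1, prob = c(0.20, 0.40, 0.40))
      pieces <- list()  # (duration, from, to)
      cur <- 0
      for (cc in seq_len(n_cyc)) {
        a <- stats::runif(1, 0.05, 0.12)
        pieces[[length(pieces) + 1L]] <- c(stats::runif(1, 0.40, 0.60),
                                           cur, a)
        pieces[[length(pieces) + 1L]] <- c(stats::runif(1, 0.10, 0.20), a, a)
        cur <- a
        if (cc < n_cyc) {
          cur <- a * stats::runif(1, 0.2, 0.6)
          pieces[[length(pieces) + 1L]] <- c(stats::runif(1, 0.28, 0.42),
                                             a, cur)
        }
      }
      pieces[[length(pieces) + 1L]] <- c(stats::runif(1, 0.45, 0.65), cur, 0)
      do.call(rbind, pieces)
    }
    events <- lapply(seq_len(n_reaches), function(r) make_event())
    reach_dur <- vapply(events, function(e) sum(e[, 1]), numeric(1))
    gaps <- stats::runif(n_reaches + 1, 0.6, 1.4) * mean_gap_s
    dirs <- cbind(stats::rnorm(n_reaches, 0, 0.45), 1,
                  stats::rnorm(n_reaches, 0, 0.45))
    dirs <- dirs / sqrt(rowSums(dirs^2))

    starts <- cumsum(gaps)[seq_len(n_reaches)] +
      c(0, cumsum(reach_dur))[seq_len(n_reaches)]
    duration <- starts[n_reaches] + reach_dur[n_reaches] +
      gaps[n_reaches + 1]
    dt <- 1 / frame_rate
    time <- seq(0, duration, by = dt)
    nf <- length(time)

    disp <- matrix(0, nf, 3)
    for (r in seq_len(n_reaches)) {
      ev <- events[[r]]
      piece_start <- starts[r] + c(0, cumsum(ev[, 1]))[seq_len(nrow(ev))]
      s <- numeric(nf)
      for (k in seq_len(nrow(ev))) {
        ph <- time >= piece_start[k] & time < piece_start[k] + ev[k, 1]
        tau <- (time[ph] - piece_start[k]) / ev[k, 1]
        s[ph] <- ev[k, 2] + (ev[k, 3] - ev[k, 2]) * minjerk(tau)
      }
      disp <- disp + outer(s, dirs[r, ])
    }

    # spontaneous movement bouts: out-and-back minimum-jerk displacements
    # confined to the x-z plane (no y extension, so they are not reaches),
    # scattered through the inter-reach gaps. Spontaneous behavior in the
    # home enclosure is movement-rich, and these bouts give the spontaneous
    # context genuine kinematic drive.
    reach_windows <- cbind(starts, starts + reach_dur)
    t_bout <- 2
    while (t_bout < duration - 2) {
      t_bout <- t_bout + stats::runif(1, 2, 6)
      d_out <- stats::runif(1, 0.30, 0.50)
      d_back <- stats::runif(1, 0.30, 0.50)
      if (t_bout + d_out + d_back >= duration - 1) break
      in_reach <- any(t_bout < reach_windows[, 2] + 0.5 &
                      t_bout + d_out + d_back > reach_windows[, 1] - 0.5)
      if (in_reach) next
      amp <- stats::runif(1, 0.03, 0.08)
      dxz <- stats::rnorm(2)
      dir_b <- amp * c(dxz[1], 0, dxz[2]) / sqrt(sum(dxz^2))
      ph1 <- time >= t_bout & time < t_bout + d_out
      ph2 <- time >= t_bout + d_out & time < t_bout + d_out + d_back
      sb <- numeric(nf)
      sb[ph1] <- minjerk((time[ph1] - t_bout) / d_out)
      sb[ph2] <- 1 - minjerk((time[ph2] - t_bout - d_out) / d_back)
      disp <- disp + outer(sb, dir_b)
    }

    # low-pass Gaussian wander: white noise filtered well below 5 Hz, so
    # position AND velocity are smooth (an OU position would have white
    # velocity and masquerade as movement)
    lp_wander <- function(n, fc, sd_target) {
      x <- stats::rnorm(n)
      bf <- signal::butter(2, fc / (frame_rate / 2))
      y <- signal::filtfilt(bf, x)
      y * sd_target / stats::sd(y)
    }
    hand_wander <- sapply(1:3, function(j) lp_wander(nf, 0.8, 0.0025))
    shoulder <- sapply(1:3, function(j) lp_wander(nf, 0.3, 0.003))
    rest <- c(0, -0.02, 0)
    hand <- shoulder + matrix(rest, nf, 3, byrow = TRUE) + hand_wander + disp
    clean_hand <- hand; clean_shoulder <- shoulder
    if (noise_sd > 0) {
      hand <- hand + matrix(stats::rnorm(3 * nf, sd = noise_sd), nf, 3)
      shoulder <- shoulder + matrix(stats::rnorm(3 * nf, sd = noise_sd),
                                    nf, 3)
    }

    err <- stats::rexp(nf, rate = 1 / 3)
    cams <- rep(3L, nf)
    n_drop <- stats::rbinom(1, nf, dropout_fraction)
    if (n_drop > 0) {
      lens <- integer(0)
      while (sum(lens) < n_drop) lens <- c(lens, 1L + stats::rgeom(1, 1 / 5))
      extra <- sum(lens) - n_drop
      lens[length(lens)] <- lens[length(lens)] - extra
      lens <- lens[lens > 0]
      occupied <- rep(FALSE, nf)
      for (L in lens) {
        for (try in 1:200) {
          s0 <- sample.int(nf - L + 1L, 1L)
          idx <- s0:(s0 + L - 1L)
          if (!any(occupied[idx])) { occupied[idx] <- TRUE; break }
        }
      }
      err[occupied] <- stats::runif(sum(occupied), 30, 100)
      few_cam <- occupied & (stats::runif(nf) < 0.5)
      cams[few_cam] <- 1L
    }

    series <- marker_series(time, hand, shoulder,
                            reprojection_error = err, n_cameras = cams,
                            frame_rate = frame_rate)
    series_clean <- marker_series(time, clean_hand, clean_shoulder,
                                  frame_rate = frame_rate)
    stops <- starts + reach_dur
    bounds <- sort(c(0, starts, stops, max(time) + dt))
    epochs <- data.frame(start_t = bounds[-length(bounds)],
                         stop_t = bounds[-1])
    epochs$label <- ifelse(epochs$start_t %in% starts, "reach",
                           "spontaneous")
    epochs <- epochs[epochs$stop_t > epochs$start_t, ]
    rownames(epochs) <- NULL
    list(series = series, series_clean = series_clean, epochs = epochs)
  })
}

#' Per-bin log conditional intensity of the coupled point-process model
#'
#' `log lambda_i(t) = gamma_i + k_i . v(t) + c_i . p(t) + sum_j B[i, j]
#' s_j(t - 1)`, with the coupling matrix chosen by the bin's behavioral
#' context. The kinematic drive is clipped at `+/- drive_cap` to keep the
#' simulator in a physiological regime. Exposed so the rate map can be
#' probed directly.
#'
#' @param truth A [ground_truth_population()].
#' @param V,P Kinematic design blocks (rows are bins) in the truth's layout.
#' @param s_prev Binary firing-state vector of the previous bin.
#' @param context `"reach"` or `"spontaneous"`.
#' @param drive_cap Kinematic drive clip, scalar or per-unit (default: the
#'   truth's).
#' @param coup_cap Saturation of the summed coupling drive (default: the
#'   truth's, 1.2).
#' @return Matrix (bins x units) of log intensities per 10 ms bin.
#' @export
log_intensity <- function(truth, V, P, s_prev, context = "reach",
                          drive_cap = NULL, coup_cap = NULL) {
  if (is.null(drive_cap)) drive_cap <- truth$drive_cap %||% 3.0
  if (is.null(coup_cap)) coup_cap <- truth$coup_cap %||% 1.2
  drive <- clip_drive(V %*% t(truth$K) + P %*% t(truth$C), drive_cap)
  B <- if (context == "reach") truth$B_reach else truth$B_spont
  coup <- pmin(as.numeric(B %*% s_prev), coup_cap)
  sweep(drive, 2, truth$gamma + coup, `+`)
}

#' Simulate coupled spike trains driven by kinematics
#'
#' For each 10 ms bin the per-unit count is Poisson with intensity
#' `exp(gamma + k.v + c.p + B s(t-1))` where `B` is selected by the bin's
#' epoch context and `s(t-1)` is the binarized previous bin (couplings are
#' strictly causal; coincident-bin statistical dependence arises from shared
#' kinematic drive). Event times are placed uniformly within their bin.
#'
#' @param kin Result of [generate_kinematics()] (or a list with `series`).
#' @param epochs Epoch data frame (`start_t`, `stop_t`, `label`).
#' @param truth A [ground_truth_population()].
#' @param seed Integer seed.
#' @param bin Bin width (s, default 0.010).
#' @param cap Stability cap on the expected spikes per bin (default 0.95);
#'   exceeding it aborts with a diagnostic naming the offending units.
#' @param drive_cap Kinematic drive clip (default: the truth's).
#' @param coup_cap Saturation of the summed coupling drive per bin (default:
#'   the truth's), a stand-in for synaptic saturation that keeps the
#'   recurrent excitation stable at strong couplings.
#' @return List with `spike_times` (per-unit numeric vectors), `counts`
#'   (bins x units), `bin_start_times`, `session_span`.
#' @export
generate_spikes <- function(kin, epochs, truth, seed, bin = 0.010,
                            cap = 0.95, drive_cap = NULL, coup_cap = NULL) {
  if (is.null(drive_cap)) drive_cap <- truth$drive_cap %||% 3.0
  if (is.null(coup_cap)) coup_cap <- truth$coup_cap %||% 1.2
  # drive spiking from the noise-free kinematics when available: neural
  # activity follows the true limb state, not the camera measurement
  series <- kin$series_clean %||% kin$series
  if (min(epochs$start_t) < min(series$time) - 1e-9 ||
      max(epochs$stop_t) > max(series$time) + 1 / series$frame_rate + 1e-6) {
    stop("kinematics do not cover all epochs")
  }
  check_truth(truth)
  span <- c(0, max(series$time) + 1 / series$frame_rate)
  nb <- ceiling((span[2] - span[1]) / bin - 1e-9)
  centers <- span[1] + (seq_len(nb) - 0.5) * bin
  velocity <- hand_velocity(series)
  kd <- kinematic_design(series, velocity, centers, truth$spec)
  drive <- clip_drive(kd$V %*% t(truth$K) + kd$P %*% t(truth$C), drive_cap)
  base <- sweep(drive, 2, truth$gamma, `+`)       # bins x units

  reach_ep <- epochs[epochs$label == "reach", , drop = FALSE]
  is_reach <- rep(FALSE, nb)
  for (k in seq_len(nrow(reach_ep))) {
    is_reach <- is_reach | (centers >= reach_ep$start_t[k] &
                            centers < reach_ep$stop_t[k])
  }
  n_units <- length(truth$gamma)
  counts <- matrix(0L, nb, n_units)
  local_seed(seed, {
    s_prev <- integer(n_units)
    for (t in seq_len(nb)) {
      B <- if (is_reach[t]) truth$B_reach else truth$B_spont
      active <- which(s_prev > 0L)
      coup <- if (length(active)) {
        pmin(rowSums(B[, active, drop = FALSE]), coup_cap)
      } else 0
      lam <- exp(base[t, ] + coup)
      if (any(lam > cap)) {
        stop("expected spikes/bin exceeded the stability cap (", cap,
             ") at bin ", t, " for unit(s) ",
             paste(which(lam > cap), collapse = ", "))
      }
      ct <- stats::rpois(n_units, lam)
      counts[t, ] <- ct
      s_prev <- as.integer(ct > 0L)
    }
    spike_times <- lapply(seq_len(n_units), function(u) {
      cu <- counts[, u]
      nz <- which(cu > 0L)
      if (!length(nz)) return(numeric(0))
      starts <- span[1] + (nz - 1) * bin
      sort(rep(starts, cu[nz]) + stats::runif(sum(cu[nz])) * bin)
    })
    list(spike_times = spike_times, counts = counts,
         bin_start_times = span[1] + bin * (seq_len(nb) - 1L),
         session_span = span)
  })
}

# clip each unit's (column's) kinematic drive at +/- its own cap
clip_drive <- function(drive, cap) {
  capM <- matrix(cap, nrow(drive), ncol(drive), byrow = TRUE)
  pmin(pmax(drive, -capM), capM)
}

check_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth_population"))
  if (any(diag(truth$B_reach) != 0) || any(diag(truth$B_spont) != 0)) {
    stop("coupling matrices must have zero diagonal")
  }
  free <- !truth$mask
  if (any(truth$B_reach[free, free] != truth$B_spont[free, free])) {
    stop("context-invariant couplings must match across contexts")
  }
  rates <- exp(truth$gamma) / 0.010
  if (any(rates < 0.5 | rates > 50)) {
    stop("baseline rates must lie in [0.5, 50] spikes/s under zero drive")
  }
  invisible(TRUE)
}

#' Assemble a complete synthetic session
#'
#' Bundles kinematics, epochs, ground truth and simulated spikes under one
#' master seed (child seeds for each component are derived by fixed
#' offsets). Profiles: `"small"` (20 units, 20 reaches, short gaps) for fast
#' tests; `"paperlike"` (100 units, 100 reaches, about an hour of session)
#' mirroring the scale of a real recording at reduced unit count.
#'
#' @param profile `"small"` or `"paperlike"`.
#' @param seed Master integer seed.
#' @param ... Overrides passed to the generators: `n_units`, `n_reaches`,
#'   `mean_gap_s`, `frame_rate`, `noise_sd`, `dropout_fraction`, plus any
#'   [ground_truth_population()] argument.
#' @return A `synthetic_session`: list with `series`, `epochs`,
#'   `spike_times`, `truth`, `session_span`, `seed`, `params`.
#' @export
make_default_session <- function(profile = c("small", "paperlike"), seed = 1,
                                 ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    small = list(n_units = 20, n_reaches = 20, mean_gap_s = 6),
    paperlike = list(n_units = 100, n_reaches = 100, mean_gap_s = 34)
  )
  over <- list(...)
  params <- utils::modifyList(c(base, list(frame_rate = 150,
                                           noise_sd = 0.0002,
                                           dropout_fraction = 0.02)), over)
  truth_args <- params[names(params) %in%
                         names(formals(ground_truth_population))]
  truth <- do.call(ground_truth_population,
                   c(list(n_units = params$n_units, seed = seed + 1L),
                     truth_args[setdiff(names(truth_args), "n_units")]))
  kin <- generate_kinematics(params$n_reaches,
                             frame_rate = params$frame_rate,
                             noise_sd = params$noise_sd,
                             mean_gap_s = params$mean_gap_s,
                             dropout_fraction = params$dropout_fraction,
                             seed = seed + 2L)
  sp <- generate_spikes(kin, kin$epochs, truth, seed = seed + 3L)
  structure(list(series = kin$series, series_clean = kin$series_clean,
                 epochs = kin$epochs,
                 spike_times = sp$spike_times, truth = truth,
                 session_span = sp$session_span, seed = seed,
                 params = params, profile = profile),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "synthetic_session ('%s', seed %d): %d units, %d reaches, %.1f min\n",
    x$profile, x$seed, length(x$spike_times),
    sum(x$epochs$label == "reach"), diff(x$session_span) / 60))
  invisible(x)
}

#' Export a synthetic session as plain-text files
#'
#' Writes the kinematics CSV, per-unit spike-time CSVs, the epoch table and
#' a JSON sidecar of generation parameters into a directory.
#'
#' @param session A [make_default_session()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_marker_csv(session$series, file.path(dir, "kinematics.csv"))
  utils::write.csv(session$epochs, file.path(dir, "epochs.csv"),
                   row.names = FALSE)
  spdir <- file.path(dir, "spikes")
  dir.create(spdir, showWarnings = FALSE)
  for (u in seq_along(session$spike_times)) {
    utils::write.csv(data.frame(spike_time = session$spike_times[[u]]),
                     file.path(spdir, sprintf("unit_%03d.csv", u)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    c(session$params, list(seed = session$seed, profile = session$profile)),
    file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(dir)
}
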