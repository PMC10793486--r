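#' Network feature terms for a target unit
#'
#' Per-sample weighted sums of source-unit firing states, weights taken from
#' the incoming row of the functional network: `F0 = sum_j w_ji * s0_j`
#' (coincident bin) and `F1 = sum_j w_ji * s1_j` (leading bin), excluding the
#' target itself. When `fn_pair` is given, the cross-pairing rule applies:
#' samples from reachSet1 use the second network's weights and vice versa, so
#' network features never reuse the network estimated from their own reach
#' set.
#'
#' @param samples A [extract_samples()] result.
#' @param fn A single [compute_fn()] network, or `NULL` if `fn_pair` given.
#' @param target_unit Integer index of the target unit.
#' @param fn_pair Optional list of two networks `(reachFN1, reachFN2)` for
#'   cross-pairing.
#' @return Matrix with columns `F0`, `F1` (bits, one row per sample).
#' @export
network_features <- function(samples, fn = NULL, target_unit, fn_pair = NULL) {
  n_units <- ncol(samples$S0)
  if (target_unit < 1 || target_unit > n_units) {
    stop("unknown target unit: ", target_unit)
  }
  as_W <- function(x) if (inherits(x, "functional_network")) x$W else x
  feat_from <- function(W, rows) {
    w <- W[target_unit, ]
    w[target_unit] <- 0
    cbind(F0 = as.numeric(samples$S0[rows, , drop = FALSE] %*% w),
          F1 = as.numeric(samples$S1[rows, , drop = FALSE] %*% w))
  }
  ns <- n_samples(samples)
  if (!is.null(fn_pair)) {
    stopifnot(length(fn_pair) == 2)
    out <- matrix(NA_real_, ns, 2, dimnames = list(NULL, c("F0", "F1")))
    set1 <- samples$reach_set == "reachSet1"
    if (any(set1)) out[set1, ] <- feat_from(as_W(fn_pair[[2]]), which(set1))
    if (any(!set1)) out[!set1, ] <- feat_from(as_W(fn_pair[[1]]), which(!set1))
    return(out)
  }
  feat_from(as_W(fn), seq_len(ns))
}

#' Build a design matrix and response for one encoding model family
#'
#' Column order is fixed: velocity-trajectory terms (all families, x-y-z
#' interleaved per 40 Hz time point), then the three mean-position terms
#' (`short_kinematics`, `full_kinematics`, `kin_plus_FN`), then the
#' coincident and leading network features `F0`, `F1` (`kin_plus_FN` only).
#' The response is the target unit's spike count in the 10 ms sample window.
#' For the canonical `[-100, +300]` ms window, `full_kinematics` has
#' 48 + 3 = 51 columns and `kin_plus_FN` 53; the brief-window `velocity`
#' family has 6.
#'
#' @param samples A [extract_samples()] result (its lead-lag spec must match
#'   the family: the `velocity` and `short_kinematics` families expect the
#'   brief `[+100, +150]` ms window).
#' @param family One of `"velocity"`, `"short_kinematics"`, `"trajectory"`,
#'   `"full_kinematics"`, `"kin_plus_FN"`.
#' @param target_unit Target unit index (response column).
#' @param fn,fn_pair Functional network(s) for `kin_plus_FN`; see
#'   [network_features()].
#' @return List with `X` (design matrix), `y` (counts), `layout` (named
#'   column ranges), `family`, `spec`, `target_unit`.
#' @export
build_design <- function(samples, family = c("full_kinematics", "trajectory",
                                             "short_kinematics", "velocity",
                                             "kin_plus_FN"),
                         target_unit, fn = NULL, fn_pair = NULL) {
  family <- match.arg(family)
  brief <- family %in% c("velocity", "short_kinematics")
  dur <- samples$spec$lead_ms + samples$spec$lag_ms
  if (brief && dur > 100) {
    stop("family '", family, "' expects a brief trajectory window; samples ",
         "were extracted with ", leadlag_label(samples$spec))
  }
  X <- samples$V
  layout <- list(velocity = seq_len(ncol(X)))
  if (family %in% c("short_kinematics", "full_kinematics", "kin_plus_FN")) {
    layout$position <- ncol(X) + 1:3
    X <- cbind(X, samples$P)
  }
  if (family == "kin_plus_FN") {
    if (is.null(fn) && is.null(fn_pair)) {
      stop("kin_plus_FN requires fn or fn_pair")
    }
    FF <- network_features(samples, fn, target_unit, fn_pair)
    layout$network <- ncol(X) + 1:2
    X <- cbind(X, FF)
  }
  list(X = X, y = as.numeric(samples$counts[, target_unit]),
       layout = layout, family = family, spec = samples$spec,
       target_unit = target_unit)
}
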