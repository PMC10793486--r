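#' L2-penalized log-linear GLM fit by Newton iteration
#'
#' Maximizes the Poisson log-likelihood with log link (or Bernoulli with
#' logit link) minus `alpha * ||beta||^2`, with the intercept unpenalized.
#' The conditional spike intensity is `exp(gamma + k.v + c.p + b0 F0 + b1 F1)`
#' depending on which columns the design contains. Fitting uses damped
#' Newton steps (step-halving on objective decrease) and converges when the
#' step and gradient fall below `tol`.
#'
#' @param X Design matrix (no intercept column; one is added internally).
#' @param y Response: spike counts (Poisson) or 0/1 indicators (Bernoulli).
#' @param alpha Ridge penalty weight on the non-intercept coefficients
#'   (absolute scale: the penalty term is `alpha * sum(beta^2)`).
#' @param family `"poisson"` (default) or `"bernoulli"`.
#' @param max_iter,tol Newton iteration controls.
#' @return A `glm_ridge_fit`: list with `intercept`, `coefficients`,
#'   `penalized_loglik`, `loglik`, `n_iter`, `converged`, `family`, `alpha`.
#' @export
fit_glm_ridge <- function(X, y, alpha, family = c("poisson", "bernoulli"),
                          max_iter = 100L, tol = 1e-8) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (alpha <= 0) stop("alpha must be positive")
  if (n < 10 * (p + 1)) {
    warning("fewer than 10x more samples (", n, ") than columns (", p + 1,
            "); fit may be unstable")
  }
  if (family == "bernoulli") y <- as.numeric(y > 0)
  if (all(y == 0)) {
    stop("response is identically zero; the intercept is unbounded below")
  }
  if (family == "bernoulli" && all(y == 1)) {
    stop("response is identically one; the intercept diverges")
  }

  mu_fun <- if (family == "poisson") exp else function(eta) 1 / (1 + exp(-eta))
  ll_fun <- if (family == "poisson") {
    function(eta) sum(y * eta - exp(eta))
  } else {
    function(eta) sum(y * eta - log1p(exp(eta)))
  }
  var_fun <- if (family == "poisson") identity else function(mu) mu * (1 - mu)

  beta <- rep(0, p)
  b0 <- if (family == "poisson") log(mean(y)) else stats::qlogis(mean(y))
  pen <- function(beta) alpha * sum(beta^2)
  eta <- rep(b0, n)
  obj <- ll_fun(eta) - pen(beta)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- mu_fun(eta)
    if (any(!is.finite(mu)) || max(mu) > 1e8) {
      stop("intensity diverged during fitting (possible separation); ",
           "increase alpha or inspect the design")
    }
    g_b0 <- sum(y - mu)
    g_beta <- drop(crossprod(X, y - mu)) - 2 * alpha * beta
    w <- var_fun(mu)
    Xw <- X * w
    H <- rbind(
      c(sum(w), colSums(Xw)),
      cbind(colSums(Xw), crossprod(X, Xw) + diag(2 * alpha, p))
    )
    g <- c(g_b0, g_beta)
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-10 * max(diag(H)), p + 1), g)
    })
    # damped update
    scale <- 1
    repeat {
      b0_new <- b0 + scale * step[1]
      beta_new <- beta + scale * step[-1]
      eta_new <- b0_new + drop(X %*% beta_new)
      obj_new <- ll_fun(eta_new) - pen(beta_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      scale <- scale / 2
      if (scale < 1e-10) {
        stop("Newton step failed to improve the penalized likelihood")
      }
    }
    moved <- max(abs(c(b0_new - b0, beta_new - beta)))
    b0 <- b0_new; beta <- beta_new; eta <- eta_new; obj <- obj_new
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged && max(abs(c(g_b0, g_beta))) > sqrt(tol)) {
    stop("GLM failed to converge within ", max_iter, " iterations")
  }
  structure(list(intercept = b0, coefficients = beta,
                 penalized_loglik = obj, loglik = ll_fun(eta),
                 n_iter = iter, converged = TRUE, family = family,
                 alpha = alpha),
            class = "glm_ridge_fit")
}

#' Predicted conditional intensity of a fitted encoding model
#' @param object A [fit_glm_ridge()] fit.
#' @param X Design matrix (same columns as used to fit).
#' @param ... Unused.
#' @return Numeric vector of conditional intensities.
#' @export
predict.glm_ridge_fit <- function(object, X, ...) {
  eta <- object$intercept + drop(as.matrix(X) %*% object$coefficients)
  if (object$family == "poisson") exp(eta) else 1 / (1 + exp(-eta))
}

#' Area under the ROC curve for single-bin spike prediction
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' spike bin receives a higher predicted intensity than a randomly chosen
#' non-spike bin, with ties contributing 1/2. Ranges from 0.5 (no predictive
#' power) to 1.0 (perfect prediction).
#'
#' @param scores Predicted conditional intensities.
#' @param spikes Binary spike indicators (counts are binarized at >= 1).
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_score <- function(scores, spikes) {
  pos <- spikes >= 1
  n1 <- sum(pos); n0 <- length(pos) - n1
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
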