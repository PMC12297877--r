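#' Constant-velocity motion model for the box state
#'
#' The tracker's state is the 8-vector
#' `(cx, cy, a, h, v_cx, v_cy, v_a, v_h)`: box centre, aspect ratio, height,
#' and their per-frame velocities. The dynamics are constant-velocity,
#' `x[t+1] = F x[t]`, and the detector observes the first four components,
#' `z[t] = H x[t]`, so
#' `F = [[I4, dt*I4], [0, I4]]` and `H = [I4 | 0]`.
#'
#' Noise and initial uncertainty are isotropic: process noise
#' `Q = q_scale * I8`, observation noise `R = r_scale * I4`, and initial
#' state covariance `P0 = p0_scale * I8`. The defaults (`0.1`, `2.0`, `500`)
#' assume pixel-scale measurements from a detector with a couple of pixels
#' of localisation noise and express near-total ignorance of the initial
#' velocities.
#'
#' @param dt Time step in frames (default 1).
#' @param q_scale,r_scale,p0_scale Positive scalars multiplying the identity
#'   to form `Q`, `R` and `P0`.
#' @return A list of class `"motion_model"` with elements `F`, `H`, `Q`,
#'   `R`, `P0` and `dt`.
#' @export
motion_model <- function(dt = 1, q_scale = 0.1, r_scale = 2.0, p0_scale = 500) {
  if (!is.numeric(dt) || length(dt) != 1L || dt < 0) abort("dt must be a non-negative scalar")
  for (s in c(q_scale, r_scale, p0_scale)) {
    if (!is.numeric(s) || length(s) != 1L || s <= 0) {
      abort("q_scale, r_scale and p0_scale must be positive scalars")
    }
  }
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- dt
  H <- cbind(diag(4), matrix(0, 4, 4))
  structure(
    list(F = F, H = H,
         Q = q_scale * diag(8), R = r_scale * diag(4), P0 = p0_scale * diag(8),
         dt = dt),
    class = "motion_model"
  )
}

#' Scaled unscented-transform hyperparameters
#'
#' Controls the spread of the sigma points. `alpha` scales the spread around
#' the mean (small values keep points close), `beta` folds in prior
#' knowledge of the state distribution (2 is optimal for Gaussians), and
#' `kappa` is a secondary scaling term. The scaling constant is
#' `lambda_s = alpha^2 (n + kappa) - n` for state dimension `n`.
#'
#' @param alpha,beta,kappa Numeric scalars; `alpha` must be positive.
#' @return A list of class `"ukf_params"`.
#' @export
ukf_params <- function(alpha = 1e-3, beta = 2, kappa = 0) {
  if (alpha <= 0) abort("alpha must be positive")
  structure(list(alpha = alpha, beta = beta, kappa = kappa), class = "ukf_params")
}

new_track_state <- function(mean, cov) {
  structure(list(mean = as.numeric(mean), cov = cov), class = "track_state")
}

# Cholesky with escalating diagonal jitter: 1e-9 * 10^k up to 1e-3.
safe_chol <- function(m) {
  r <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(r)) return(r)
  jitter <- 1e-9
  while (jitter <= 1e-3) {
    r <- tryCatch(chol(m + jitter * diag(nrow(m))), error = function(e) NULL)
    if (!is.null(r)) return(r)
    jitter <- jitter * 10
  }
  abort(sprintf(
    "covariance is not positive definite even after 1e-3 jitter (min diagonal %.3g)",
    min(diag(m))))
}

symmetrize <- function(m) (m + t(m)) / 2

#' Sigma points of the scaled unscented transform
#'
#' Generates the `2n + 1` deterministic sample points whose weighted sample
#' mean and covariance reproduce the input state exactly: point 0 is the
#' mean, and points `i` / `i + n` sit symmetrically along the columns of the
#' scaled Cholesky factor `sqrt(n + lambda_s) * chol(P)`.
#'
#' @param state A `track_state` (list with `mean` and `cov`).
#' @param params A [ukf_params()] list.
#' @return A list with `points` (a `(2n+1) x n` matrix, one point per row),
#'   `wm` (mean weights, summing to 1) and `wc` (covariance weights).
#' @export
sigma_points <- function(state, params = ukf_params()) {
  n <- length(state$mean)
  lambda_s <- params$alpha^2 * (n + params$kappa) - n
  scale <- n + lambda_s
  L <- t(safe_chol(symmetrize(state$cov)))  # lower-triangular factor
  spread <- sqrt(scale) * L
  pts <- matrix(state$mean, nrow = 2 * n + 1, ncol = n, byrow = TRUE)
  for (i in seq_len(n)) {
    pts[1 + i, ]     <- pts[1 + i, ]     + spread[, i]
    pts[1 + n + i, ] <- pts[1 + n + i, ] - spread[, i]
  }
  wm <- c(lambda_s / scale, rep(1 / (2 * scale), 2 * n))
  wc <- wm
  wc[1] <- wc[1] + (1 - params$alpha^2 + params$beta)
  list(points = pts, wm = wm, wc = wc)
}

# Weighted mean/covariance of transformed sigma points.
unscented_moments <- function(pts, wm, wc, noise = NULL) {
  mean <- drop(crossprod(pts, wm))
  centred <- sweep(pts, 2, mean)
  cov <- crossprod(centred * wc, centred)
  if (!is.null(noise)) cov <- cov + noise
  list(mean = mean, cov = symmetrize(cov))
}

#' Initiate, predict and update a track state
#'
#' `ukf_initiate()` starts a track from its first measurement with zero
#' velocities and covariance `P0`. `ukf_predict()` propagates the sigma
#' points through the transition function and adds process noise `Q`;
#' `ukf_update()` folds in a new measurement via the unscented measurement
#' prediction and the standard Kalman gain. Because the shipped model is
#' linear, both coincide with the linear Kalman filter to numerical
#' precision; the unscented machinery is retained so a non-linear
#' transition can be substituted without touching the tracker.
#'
#' After every predict and update the covariance is re-symmetrised and the
#' aspect-ratio and height components of the mean are clamped to a floor of
#' `1e-3`, so the state always maps back to a valid box.
#'
#' @param z Numeric length-4 measurement `(cx, cy, a, h)`.
#' @param state A `track_state`.
#' @param model A [motion_model()].
#' @param params A [ukf_params()].
#' @return A `track_state` (list with `mean`, `cov`).
#' @export
ukf_initiate <- function(z, model = motion_model()) {
  z <- as.numeric(z)
  if (length(z) != 4L || any(!is.finite(z)) || z[3] <= 0 || z[4] <= 0) {
    abort("measurement must be a finite length-4 vector with positive aspect and height")
  }
  new_track_state(c(z, rep(0, 4)), model$P0)
}

clamp_state <- function(state, floor = 1e-3) {
  state$mean[3] <- max(state$mean[3], floor)
  state$mean[4] <- max(state$mean[4], floor)
  state
}

#' @rdname ukf_initiate
#' @export
ukf_predict <- function(state, model = motion_model(), params = ukf_params()) {
  sp <- sigma_points(state, params)
  propagated <- sp$points %*% t(model$F)
  mom <- unscented_moments(propagated, sp$wm, sp$wc, noise = model$Q)
  clamp_state(new_track_state(mom$mean, mom$cov))
}

# Unscented measurement prediction: predicted measurement z_hat, innovation
# covariance S = cov_zz + R, and state-measurement cross covariance.
ukf_measurement_prediction <- function(state, model, params = ukf_params()) {
  sp <- sigma_points(state, params)
  zs <- sp$points %*% t(model$H)
  z_hat <- drop(crossprod(zs, sp$wm))
  zc <- sweep(zs, 2, z_hat)
  xc <- sweep(sp$points, 2, state$mean)
  S <- symmetrize(crossprod(zc * sp$wc, zc) + model$R)
  cross <- crossprod(xc * sp$wc, zc)
  list(z_hat = z_hat, S = S, cross = cross)
}

#' @rdname ukf_initiate
#' @export
ukf_update <- function(state, z, model = motion_model(), params = ukf_params()) {
  z <- as.numeric(z)
  if (length(z) != 4L || any(!is.finite(z))) abort("measurement must be a finite length-4 vector")
  mp <- ukf_measurement_prediction(state, model, params)
  K <- t(solve(mp$S, t(mp$cross)))  # cross %*% S^-1
  mean <- state$mean + drop(K %*% (z - mp$z_hat))
  cov <- symmetrize(state$cov - K %*% mp$S %*% t(K))
  clamp_state(new_track_state(mean, cov))
}

#' Squared Mahalanobis gating distances
#'
#' For a track predicted to the current frame, returns
#' `d2_j = (z_j - z_hat)' S^-1 (z_j - z_hat)` for each candidate
#' measurement, where `z_hat` and the innovation covariance `S` come from
#' the unscented measurement prediction. Under the model, `d2` is
#' chi-squared with 4 degrees of freedom, which is what the association
#' gate thresholds against.
#'
#' @param state A predicted `track_state`.
#' @param Z A numeric matrix with one measurement `(cx, cy, a, h)` per row
#'   (or a single length-4 vector).
#' @inheritParams ukf_initiate
#' @return A numeric vector of non-negative squared distances, one per row
#'   of `Z`.
#' @export
gating_distance <- function(state, Z, model = motion_model(), params = ukf_params()) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != 4L) abort("measurements must have 4 columns (cx, cy, a, h)")
  if (nrow(Z) == 0L) return(numeric(0))
  mp <- ukf_measurement_prediction(state, model, params)
  resid <- sweep(Z, 2, mp$z_hat)
  # solve once against all residuals; quadratic form row-wise
  sol <- solve(mp$S, t(resid))
  pmax(colSums(t(resid) * sol), 0)
}
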