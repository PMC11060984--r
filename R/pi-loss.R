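# Composite physics-informed loss: data misfit + beta * equation-of-motion
# residual, with the parameter normalisation / sigmoid-constraint machinery
# and the time-derivative evaluation of network outputs.

#' Loss configuration
#'
#' @param beta weight of the ODE-residual penalty (dimensionless).  The
#'   verification setting is `1e-3`, proportional to `dt^2 / I`.
#' @param derivative_mode how the time derivatives of the predicted motion
#'   entering the residual are obtained.  `"finite_difference"` (default,
#'   used for training): central differences of the predicted trajectory
#'   over the trial grid, with the torque side averaged by the matching
#'   consistency stencil.  `"autodiff"`: exact first and second
#'   derivatives of the cell output with respect to the current-step time
#'   input, propagated in closed form; available for residual evaluation
#'   and supported in training, but note that when the excitation and
#'   history-motion inputs already determine the output, the time input
#'   is redundant and its partial derivatives are only weakly tied to the
#'   trajectory, which can leave the identified parameters unconstrained
#'   (see the methods vignette).
#' @param stats standardisation statistics from [standardization_stats()].
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(beta = 1e-3,
                        derivative_mode = c("finite_difference", "autodiff"),
                        stats = NULL) {
  stopifnot(beta >= 0)
  derivative_mode <- match.arg(derivative_mode)
  structure(list(beta = beta, derivative_mode = derivative_mode,
                 stats = stats), class = "loss_config")
}

#' Network input channels of a trial
#'
#' The sequence model receives the time stamp and the *delay-aligned*
#' excitations `u(t) = e(t - d)` rather than the raw sEMG: a muscle's
#' electrical activity influences the joint only one electromechanical
#' delay later, so aligning the channels to their mechanical effect puts
#' the causally relevant samples inside every training window.  (With raw
#' channels and a short history, the samples that actually drive the
#' current acceleration would lie before the window starts.)
#'
#' @param tr a [trial()].
#' @param model an [elbow_model()] supplying the delay.
#' @return Numeric matrix with columns `t`, `bi`, `tri`.
#' @export
network_inputs <- function(tr, model) {
  d <- model$activation$d
  cbind(t = tr$t,
        bi = excitation_from_emg(tr$emg[, "bi"], tr$t, d),
        tri = excitation_from_emg(tr$emg[, "tri"], tr$t, d))
}

#' Standardisation statistics of a training set
#'
#' Per-channel mean and standard deviation of the network inputs (time,
#' delay-aligned excitation channels) and the motion output, computed over
#' all training trials.
#'
#' @param trials list of [trial()] objects.
#' @param model an [elbow_model()] (for the delay alignment of
#'   [network_inputs()]).
#' @return List with `mu_x`, `sd_x` (length `n_in`), `mu_q`, `sd_q`.
#' @export
standardization_stats <- function(trials, model = elbow_model()) {
  X <- do.call(rbind, lapply(trials, network_inputs, model = model))
  q <- unlist(lapply(trials, `[[`, "q"))
  sd0 <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("constant channel cannot be standardized")
    s
  }
  list(mu_x = colMeans(X), sd_x = apply(X, 2, sd0),
       mu_q = mean(q), sd_q = sd0(q))
}

std_inputs <- function(tr, stats, model) {
  X <- network_inputs(tr, model)
  sweep(sweep(X, 2, stats$mu_x), 2, stats$sd_x, "/")
}
std_q <- function(q, stats) (q - stats$mu_q) / stats$sd_q
destd_q <- function(qs, stats) stats$mu_q + stats$sd_q * qs

#' Data-misfit loss
#'
#' Mean squared error between predicted and recorded motion over a batch.
#'
#' @param qhat,q equal-length numeric vectors.
#' @return Scalar mean squared error.
#' @export
data_loss <- function(qhat, q) {
  if (length(qhat) == 0) stop("empty batch")
  if (length(qhat) != length(q)) stop("prediction/target length mismatch")
  mean((qhat - q)^2)
}

#' Identified ODE parameters
#'
#' The four Hill-type parameters under identification with their
#' normalisation: the trainables are `bar = Gamma / Gamma0` so that all
#' parameters are order one regardless of units; physical values are
#' recovered as `bar * Gamma0`.
#'
#' @param Gamma0 named numeric vector of initialisation values with names
#'   `f0_Bi`, `l0_Bi`, `f0_Tri`, `l0_Tri` (N and m).
#' @param bar normalized trainable values (default all 1, i.e. start at
#'   `Gamma0`).
#' @return An object of class `identified_params`.
#' @export
identified_params <- function(Gamma0, bar = rep(1, length(Gamma0))) {
  need <- c("f0_Bi", "l0_Bi", "f0_Tri", "l0_Tri")
  if (!all(need %in% names(Gamma0)))
    stop("Gamma0 must supply f0_Bi, l0_Bi, f0_Tri and l0_Tri")
  stopifnot(all(Gamma0 > 0))
  Gamma0 <- Gamma0[need]
  bar <- stats::setNames(as.numeric(bar), need)
  structure(list(names = need, Gamma0 = Gamma0, bar = bar),
            class = "identified_params")
}

#' Physical values of identified parameters
#' @param p an [identified_params()].
#' @return Named numeric vector `bar * Gamma0`.
#' @export
param_values <- function(p) p$bar * p$Gamma0

#' @export
print.identified_params <- function(x, ...) {
  v <- param_values(x)
  cat("<identified_params>\n")
  for (nm in x$names)
    cat(sprintf("  %-7s = %10.4f  (bar = %.4f, init = %.4f)\n",
                nm, v[nm], x$bar[nm], x$Gamma0[nm]))
  invisible(x)
}

#' Sigmoid-constrained parameter values
#'
#' `Gamma_l = mean(anchors * sig(psi))`: each trainable `psi_r` gates one
#' literature anchor value through a sigmoid, keeping the identified
#' parameter inside the physiological envelope `(0, mean(anchors))`.
#'
#' @param psi numeric vector of trainables.
#' @param anchors positive literature values, same length as `psi`.
#' @return Scalar parameter value.
#' @export
constrained_params <- function(psi, anchors) {
  if (length(anchors) == 0) stop("at least one literature anchor is required")
  stopifnot(length(psi) == length(anchors))
  mean(anchors * sigm(psi))
}

#' Write identified parameters to JSON
#'
#' @param p an [identified_params()].
#' @param path output file.
#' @param truth optional named truth vector; adds percentage errors.
#' @export
write_identified_params <- function(p, path, truth = NULL) {
  v <- param_values(p)
  out <- list(names = p$names, value = as.list(v),
              bar = as.list(p$bar), Gamma0 = as.list(p$Gamma0))
  if (!is.null(truth))
    out$percent_error <- as.list(100 * (v - truth[p$names]) / truth[p$names])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- derivatives of the predicted trajectory --------------------------------

# closed-form first/second derivative of the current-step cell output with
# respect to the (standardized) current-step time input, vectorised over
# windows.  fwd is the output of seq_forward().
time_jet <- function(fwd, weights) {
  cc <- if (isTRUE(fwd$compiled)) .gru_last_cache_cpp(fwd$handle)
  else fwd$caches[[length(fwd$caches)]]
  Hp <- cc$Hp
  if (inherits(weights, "gru_weights")) {
    r <- cc$r; u <- cc$u; k <- cc$k; ht <- cc$ht
    er <- matrix(weights$W_xr[, 1], nrow(Hp), ncol(Hp), byrow = TRUE)
    eu <- matrix(weights$W_xu[, 1], nrow(Hp), ncol(Hp), byrow = TRUE)
    ec <- matrix(weights$W_xht[, 1], nrow(Hp), ncol(Hp), byrow = TRUE)
    r1 <- r * (1 - r) * er
    r2 <- r * (1 - r) * (1 - 2 * r) * er^2
    u1 <- u * (1 - u) * eu
    u2 <- u * (1 - u) * (1 - 2 * u) * eu^2
    pc1 <- r1 * k + ec
    pc2 <- r2 * k
    ht1 <- (1 - ht^2) * pc1
    ht2 <- -2 * ht * (1 - ht^2) * pc1^2 + (1 - ht^2) * pc2
    h1 <- u1 * Hp + ht1 - (u1 * ht + u * ht1)
    h2 <- u2 * Hp + ht2 - (u2 * ht + 2 * u1 * ht1 + u * ht2)
  } else {
    h <- cc$h
    e <- matrix(weights$W_xh[, 1], nrow(Hp), ncol(Hp), byrow = TRUE)
    h1 <- (1 - h^2) * e
    h2 <- -2 * h * (1 - h^2) * e^2
  }
  list(d1 = drop(h1 %*% t(weights$W_hq)),
       d2 = drop(h2 %*% t(weights$W_hq)))
}

#' Predicted motion and its time derivatives in physical units
#'
#' Evaluates the network over a set of teacher-forced windows and returns
#' the predicted trajectory with its first and second time derivatives, as
#' needed by the equation-of-motion residual.  In `"autodiff"` mode the
#' derivatives are exact derivatives of the cell output with respect to
#' the current-step time input, propagated in closed form and rescaled
#' from standardized to physical units by `sd_q/sd_t` and `sd_q/sd_t^2`.
#' In `"finite_difference"` mode they are central differences of the
#' predicted trajectory over the trial grid (endpoints are `NA`).
#'
#' @param weights [gru_weights()] or [rnn_weights()].
#' @param windows window set from [make_windows()] built from
#'   *standardized* inputs/motion.
#' @param cfg [loss_config()] carrying the standardisation statistics.
#' @param dt physical time step, s (needed in finite-difference mode).
#' @return List with vectors `q`, `qdot`, `qddot` (rad, rad/s, rad/s^2).
#' @export
predicted_derivatives <- function(weights, windows, cfg, dt = NULL) {
  st <- cfg$stats
  if (is.null(st)) stop("loss_config must carry standardization stats")
  fwd <- seq_forward(windows$Xs, windows$Qs, weights)
  qp <- destd_q(fwd$qhat, st)
  if (cfg$derivative_mode == "autodiff") {
    jet <- time_jet(fwd, weights)
    sd_t <- st$sd_x[1]
    list(q = qp, qdot = jet$d1 * st$sd_q / sd_t,
         qddot = jet$d2 * st$sd_q / sd_t^2)
  } else if (cfg$derivative_mode == "finite_difference") {
    if (is.null(dt)) stop("dt is required in finite-difference mode")
    n <- length(qp)
    qdot <- qddot <- rep(NA_real_, n)
    i <- 2:(n - 1)
    qdot[i] <- (qp[i + 1] - qp[i - 1]) / (2 * dt)
    qddot[i] <- (qp[i + 1] - 2 * qp[i] + qp[i - 1]) / dt^2
    list(q = qp, qdot = qdot, qddot = qddot)
  } else stop("unsupported derivative_mode")
}

# Finite-difference kinematics of a predicted trajectory: second-order
# velocities everywhere (one-sided at the ends) and interior central
# second differences.
fd_kinematics <- function(qp, dt) {
  N <- length(qp)
  i <- 2:(N - 1)
  qd <- numeric(N)
  qd[i] <- (qp[i + 1] - qp[i - 1]) / (2 * dt)
  qd[1] <- (-3 * qp[1] + 4 * qp[2] - qp[3]) / (2 * dt)
  qd[N] <- (3 * qp[N] - 4 * qp[N - 1] + qp[N - 2]) / (2 * dt)
  list(i = i, qd = qd, qdd = (qp[i + 1] - 2 * qp[i] + qp[i - 1]) / dt^2)
}

# Discretisation-consistent residual: the central second difference of the
# trajectory equals a triangular-kernel average of the instantaneous
# angular acceleration, which for torques that are piecewise linear
# between samples (noisy sEMG drives are) is exactly the (1, 4, 1)/6
# average of the nodal torques.  The residual therefore compares
# I * qdd_fd with the same average of E(q) + TMT, keeping the residual at
# the true trajectory at the discretisation error level instead of the
# torque-jitter level, and keeping parameter identification unbiased.
# Returns the residual series plus everything the adjoint needs.
residual_core <- function(qp, dt, a_bi, a_tri, Gamma, model) {
  kin <- fd_kinematics(qp, dt)
  i <- kin$i
  tt <- joint_torque_terms(qp, kin$qd, a_bi, a_tri, model, as.list(Gamma))
  phi <- tt$tau + gravity_torque(qp, model)
  phi_s <- (phi[i - 1] + 4 * phi[i] + phi[i + 1]) / 6
  list(r = model$I * kin$qdd - phi_s, i = i, kin = kin, tt = tt,
       phi_q = tt$dq + gravity_torque_dq(qp, model), phi_qd = tt$dqdot)
}

#' ODE-residual loss
#'
#' Mean squared equation-of-motion residual (N m) over a batch of windows:
#' the network's predicted trajectory and its finite-difference time
#' derivatives are pushed through the rigid-body/Hill-type torque balance
#' at the candidate parameters `Gamma`.  Activations come from the batch's
#' (noisy, scale-projected) sEMG at full physical scale.  The torque side
#' is averaged with the `(1, 4, 1)/6` stencil that makes the discrete
#' residual consistent with the central second difference (see the methods
#' vignette).
#'
#' @param batch a `pi_batch` from [pi_batch()].
#' @param weights network weights.
#' @param Gamma named vector of candidate parameter values (physical units).
#' @param model [elbow_model()].
#' @param cfg [loss_config()].
#' @return Scalar mean squared residual.
#' @export
residual_loss <- function(batch, weights, Gamma, model, cfg) {
  st <- cfg$stats
  Qs <- if (is.null(batch$Qs_clean)) batch$windows$Qs else batch$Qs_clean
  fwd <- seq_forward(batch$windows$Xs, Qs, weights)
  qp <- destd_q(fwd$qhat, st)
  if (cfg$derivative_mode == "autodiff") {
    der <- predicted_derivatives(weights, batch$windows, cfg, dt = batch$dt)
    r <- eom_residual(der$q, der$qdot, der$qddot,
                      batch$a_bi, batch$a_tri, Gamma, model)
  } else {
    r <- residual_core(qp, batch$dt, batch$a_bi, batch$a_tri, Gamma, model)$r
  }
  mean(r^2)
}

#' Composite physics-informed loss
#'
#' `J = J_data + beta * J_res`.
#'
#' @inheritParams residual_loss
#' @return Scalar loss, with components attached as attributes
#'   `J_data` and `J_res`.
#' @export
composite_loss <- function(batch, weights, Gamma, model, cfg) {
  fwd <- seq_forward(batch$windows$Xs, batch$windows$Qs, weights)
  jd <- data_loss(fwd$qhat, batch$target_std)
  jr <- if (cfg$beta > 0 || TRUE)
    residual_loss(batch, weights, Gamma, model, cfg) else 0
  structure(jd + cfg$beta * jr, J_data = jd, J_res = jr)
}

#' Training batch for the physics-informed loss
#'
#' Bundles one trial's teacher-forced windows (standardized units) with
#' the physical-scale quantities the residual needs: the time step and the
#' muscle activations at the predicted steps.  The data-misfit term uses
#' the noise-augmented history motions; the residual term uses the clean
#' histories, because the finite-difference stencil would amplify any
#' injected history noise by `1/dt^2` (the augmentation exists to harden
#' autoregressive rollout, not to perturb the physics).
#'
#' @param tr a [trial()] (at the training scale).
#' @param m history steps.
#' @param cfg [loss_config()] with standardisation statistics.
#' @param model [elbow_model()] (for the activation dynamics).
#' @param noise_sigma teacher-forcing noise sd in standardized units.
#' @param seed optional seed for the noise draw.
#' @return An object of class `pi_batch`.
#' @export
pi_batch <- function(tr, m, cfg, model, noise_sigma = 0, seed = NULL) {
  st <- cfg$stats
  X <- std_inputs(tr, st, model)
  qs <- std_q(tr$q, st)
  win <- make_windows(X, qs, m, noise_sigma = noise_sigma, seed = seed)
  Qs_clean <- if (noise_sigma > 0)
    make_windows(X, qs, m, noise_sigma = 0)$Qs else win$Qs
  d <- model$activation$d; A <- model$activation$A
  u_bi <- excitation_from_emg(tr$emg[, "bi"], tr$t, d)
  u_tri <- excitation_from_emg(tr$emg[, "tri"], tr$t, d)
  a_bi <- activation(u_bi, A)[win$steps]
  a_tri <- activation(u_tri, A)[win$steps]
  structure(list(windows = win, Qs_clean = Qs_clean,
                 target_std = win$target,
                 q_phys = tr$q[win$steps], t = tr$t[win$steps],
                 dt = tr$dt, a_bi = a_bi, a_tri = a_tri, m = m),
            class = "pi_batch")
}

# contiguous sub-batch of a pi_batch (keeps the FD stencil valid)
pi_batch_slice <- function(b, idx) {
  w <- b$windows
  structure(list(
    windows = list(Xs = lapply(w$Xs, function(M) M[idx, , drop = FALSE]),
                   Qs = lapply(w$Qs, function(M) M[idx, , drop = FALSE]),
                   target = w$target[idx], steps = w$steps[idx]),
    Qs_clean = lapply(b$Qs_clean, function(M) M[idx, , drop = FALSE]),
    target_std = b$target_std[idx], q_phys = b$q_phys[idx],
    t = b$t[idx], dt = b$dt,
    a_bi = b$a_bi[idx], a_tri = b$a_tri[idx], m = b$m),
    class = "pi_batch")
}
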