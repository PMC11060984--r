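# Rigid-tendon Hill-type muscle mechanics and single-DOF elbow forward dynamics.

#' Activation dynamics parameters
#'
#' Electromechanical delay and nonlinear shape factor linking surface EMG to
#' muscle activation.  The excitation is the EMG shifted by the delay
#' `d`, and activation is the exponential shaping
#' `a(u) = (exp(A u) - 1) / (exp(A) - 1)`.
#'
#' @param d electromechanical delay in seconds (`>= 0`).
#' @param A dimensionless shape factor (`!= 0`).  Positive values give a
#'   convex activation curve below the identity.
#' @return An object of class `activation_params`.
#' @export
activation_params <- function(d = 0.08, A = 0.2) {
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0)
  if (!is.numeric(A) || length(A) != 1L || A == 0)
    stop("shape factor A must be a nonzero scalar")
  structure(list(d = d, A = A), class = "activation_params")
}

#' Hill-type muscle-tendon parameters
#'
#' The constant vector characterising one homogenised muscle group:
#' optimal fibre length, maximum contraction velocity, maximum isometric
#' force, tendon slack length and initial pennation angle.
#'
#' @param l0M optimal muscle fibre length, m.
#' @param vmaxM maximum contraction velocity, m/s.
#' @param f0M maximum isometric force, N.
#' @param lsT tendon slack length, m (tendon is treated as rigid, so the
#'   tendon length is fixed at `lsT`).
#' @param theta0 initial pennation angle, rad, in `[0, pi/2)`.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(l0M, vmaxM, f0M, lsT, theta0 = 0) {
  vals <- c(l0M = l0M, vmaxM = vmaxM, f0M = f0M, lsT = lsT)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("muscle lengths, velocities and forces must be positive and finite")
  if (theta0 < 0 || theta0 >= pi / 2)
    stop("initial pennation angle must lie in [0, pi/2)")
  structure(list(l0M = l0M, vmaxM = vmaxM, f0M = f0M, lsT = lsT,
                 theta0 = theta0), class = "muscle_params")
}

#' Two-link elbow flexion-extension model
#'
#' A single degree-of-freedom rigid-body model of the elbow: the upper arm
#' link hangs fixed, the forearm link rotates about the elbow by the flexion
#' angle `q` (q = 0 is the straight, hanging arm; q = pi/2 is the horizontal
#' forearm), and the forearm mass is lumped at the wrist.  The biceps
#' (flexor) and triceps (extensor) muscle-tendon units attach at distances
#' `l1` (upper arm) and `l2` (forearm) from the joint; their path lengths
#' follow the law of cosines so the flexor shortens and the extensor
#' lengthens as `q` increases.
#'
#' Defaults are the verification-study values: 1 m links, 1 kg wrist mass,
#' biceps `l0 = 0.6` m, `f0 = 300` N, `lsT = 0.55` m, `vmax = 6` m/s;
#' triceps `l0 = 0.4` m, `f0 = 300` N, `lsT = 0.33` m, `vmax = 4` m/s;
#' zero pennation for both; activation delay 0.08 s and shape factor 0.2.
#'
#' Derived quantities: moment of inertia `I = m_fa * lfa^2` (point mass at
#' the wrist) and gravity torque `E(q) = -m_fa * g * lfa * sin(q)`, which
#' is restoring towards the hanging position.
#'
#' @param lua,lfa upper-arm and forearm link lengths, m.
#' @param m_fa lumped wrist mass, kg.
#' @param g gravitational acceleration, m/s^2.
#' @param l1_bi,l2_bi,l1_tri,l2_tri muscle attachment distances, m.
#' @param biceps,triceps [muscle_params()] for the two muscle groups.
#' @param activation [activation_params()] shared by both groups.
#' @param passive logical; include the passive-elastic fibre force.
#' @return An object of class `elbow_model`.
#' @export
elbow_model <- function(lua = 1.0, lfa = 1.0, m_fa = 1.0, g = 9.81,
                        l1_bi = 0.3, l2_bi = 0.8,
                        l1_tri = 0.2, l2_tri = 0.7,
                        biceps = muscle_params(0.6, 6, 300, 0.55, 0),
                        triceps = muscle_params(0.4, 4, 300, 0.33, 0),
                        activation = activation_params(),
                        passive = TRUE) {
  stopifnot(lua > 0, lfa > 0, m_fa > 0, g > 0,
            l1_bi > 0, l2_bi > 0, l1_tri > 0, l2_tri > 0,
            inherits(biceps, "muscle_params"),
            inherits(triceps, "muscle_params"),
            inherits(activation, "activation_params"))
  structure(list(lua = lua, lfa = lfa, m_fa = m_fa, g = g,
                 l1_bi = l1_bi, l2_bi = l2_bi,
                 l1_tri = l1_tri, l2_tri = l2_tri,
                 biceps = biceps, triceps = triceps,
                 activation = activation, passive = isTRUE(passive),
                 I = m_fa * lfa^2),
            class = "elbow_model")
}

#' Joint state
#' @param q elbow flexion angle, rad.
#' @param qdot angular velocity, rad/s.
#' @return An object of class `joint_state`.
#' @export
joint_state <- function(q, qdot) {
  stopifnot(is.finite(q), is.finite(qdot))
  structure(list(q = q, qdot = qdot), class = "joint_state")
}

# gravity torque and its derivative (restoring toward the hanging arm)
gravity_torque <- function(q, model) -model$m_fa * model$g * model$lfa * sin(q)
gravity_torque_dq <- function(q, model) -model$m_fa * model$g * model$lfa * cos(q)

#' Neural excitation from surface EMG
#'
#' Applies the electromechanical delay `u(t) = e(t - d)` by linear
#' interpolation on the uniform time grid; times earlier than the first
#' sample are padded with the first value.
#'
#' @param e sEMG series (dimensionless).
#' @param t uniform time grid, s.
#' @param d delay, s.
#' @return The excitation series on the same grid.
#' @export
excitation_from_emg <- function(e, t, d) {
  stopifnot(length(e) == length(t), d >= 0)
  if (d > (t[length(t)] - t[1])) stop("delay exceeds trial span")
  if (d == 0) return(e)
  stats::approx(t, e, xout = t - d, rule = 2)$y
}

#' Muscle activation from excitation
#'
#' `a(u) = (exp(A u) - 1) / (exp(A) - 1)` with the excitation clipped to
#' `[0, 1]` beforehand, so additive measurement noise cannot drive the
#' activation outside its physiological range.
#'
#' @param u excitation series.
#' @param A nonzero shape factor.
#' @return Activation series in `[0, 1]`.
#' @export
activation <- function(u, A) {
  if (A == 0) stop("shape factor A must be nonzero")
  u <- pmin(pmax(u, 0), 1)
  (exp(A * u) - 1) / (exp(A) - 1)
}

# ---- Hill curves (rigid-tendon fallback forms) -------------------------------
# Active force-length: Gaussian about the optimal length.
fl_gamma <- 0.45
force_length <- function(ltilde) exp(-(ltilde - 1)^2 / fl_gamma)
force_length_d <- function(ltilde)
  force_length(ltilde) * (-2 * (ltilde - 1) / fl_gamma)

# Force-velocity: zero beyond maximal shortening, concentric hyperbola for
# -1 < v <= 0, and an eccentric hyperbola capped at 1.4 with a C1 join at 0.
fv_ecc_cap <- 1.4
fv_ecc_b <- 0.08   # chosen so the eccentric slope at v = 0 matches the concentric slope 5
force_velocity <- function(vtilde) {
  out <- numeric(length(vtilde))
  con <- vtilde > -1 & vtilde <= 0
  ecc <- vtilde > 0
  out[con] <- (1 + vtilde[con]) / (1 - 4 * vtilde[con])
  out[ecc] <- (fv_ecc_cap * vtilde[ecc] + fv_ecc_b) / (vtilde[ecc] + fv_ecc_b)
  out
}
force_velocity_d <- function(vtilde) {
  out <- numeric(length(vtilde))
  con <- vtilde > -1 & vtilde <= 0
  ecc <- vtilde > 0
  out[con] <- 5 / (1 - 4 * vtilde[con])^2
  out[ecc] <- fv_ecc_b * (fv_ecc_cap - 1) / (vtilde[ecc] + fv_ecc_b)^2
  out
}

# Passive-elastic fibre force, engaged above the optimal length.
force_passive <- function(ltilde) {
  f <- (exp(10 * (ltilde - 1)) - 1) / (exp(5) - 1)
  pmax(f, 0)
}
force_passive_d <- function(ltilde)
  (ltilde > 1) * 10 * exp(10 * pmin(ltilde - 1, 30)) / (exp(5) - 1)

# ---- Muscle path geometry ----------------------------------------------------

# Smooth (uncheckd-range) path geometry used internally by the torque and
# residual evaluations, so that optimisation iterates remain well defined.
# sign = +1: flexor, path angle at the elbow is (pi - q); sign = -1: extensor,
# mirrored so the path lengthens with flexion.
mt_geom <- function(q, l1, l2, sign) {
  lMT <- sqrt(l1^2 + l2^2 + 2 * sign * l1 * l2 * cos(q))
  D <- -sign * l1 * l2 * sin(q) / lMT        # d lMT / d q
  list(lMT = lMT, D = D, R = -D)
}

#' Muscle-tendon path length and moment arm
#'
#' Law-of-cosines path between attachment points `l1` (upper arm) and `l2`
#' (forearm).  The flexor (`sign = +1`) spans the elbow with interior angle
#' `pi - q`, so it is longest with the arm straight and shortens under
#' flexion; the extensor (`sign = -1`) uses the mirrored convention.  The
#' moment arm is the tendon-excursion derivative `R = -d lMT / d q`, positive
#' for the flexor and negative for the extensor on `(0, pi)`.
#'
#' @param q joint angle, rad, in the anatomical range `(0, pi)`.
#' @param l1,l2 attachment distances, m.
#' @param sign `+1` for a flexor, `-1` for an extensor.
#' @return A list with elements `lMT` (path length, m) and `R` (moment arm, m).
#' @export
mt_length_and_moment_arm <- function(q, l1, l2, sign = 1) {
  stopifnot(l1 > 0, l2 > 0, sign %in% c(-1, 1))
  if (any(q <= 0 | q >= pi)) stop("joint angle out of anatomical range")
  g <- mt_geom(q, l1, l2, sign)
  list(lMT = g$lMT, R = g$R)
}

#' Fibre kinematics under the rigid-tendon assumption
#'
#' With a rigid tendon the fibre length follows directly from the path
#' length: `lM cos(theta) = lMT - lsT`, and the pennation angle preserves
#' the constant muscle thickness `lM sin(theta) = l0M sin(theta0)`.
#'
#' @param lMT muscle-tendon path length, m.
#' @param qdot joint angular velocity, rad/s.
#' @param R moment arm, m (`R = -d lMT/d q`).
#' @param kappa [muscle_params()].
#' @return List with normalised fibre length `ltilde`, normalised fibre
#'   velocity `vtilde` and pennation angle `theta`.
#' @export
fiber_state <- function(lMT, qdot, R, kappa) {
  if (any(lMT <= kappa$lsT * (1 - 1e-9)))
    stop("muscle-tendon shorter than tendon slack length")
  s <- lMT - kappa$lsT
  w <- kappa$l0M * sin(kappa$theta0)
  lM <- sqrt(s^2 + w^2)
  costh <- s / lM
  # d lM/dt = cos(theta) * d lMT/dt, with d lMT/dt = -R * qdot
  vM <- costh * (-R) * qdot
  list(ltilde = lM / kappa$l0M, vtilde = vM / kappa$vmaxM,
       theta = atan2(w, s))
}

#' Muscle-tendon force
#'
#' `FMT = f0M * (a * fl(ltilde) * fv(vtilde) + fp(ltilde)) * cos(theta)`.
#'
#' @param a activation in `[0, 1]`.
#' @param ltilde,vtilde normalised fibre length and velocity.
#' @param theta pennation angle, rad.
#' @param kappa [muscle_params()].
#' @param passive include the passive-elastic term.
#' @return Force along the tendon, N.
#' @export
mt_force <- function(a, ltilde, vtilde, theta, kappa, passive = TRUE) {
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  fp <- if (passive) force_passive(ltilde) else 0
  kappa$f0M * (a * force_length(ltilde) * force_velocity(vtilde) + fp) *
    cos(theta)
}

# Torque of one muscle group plus the analytic partials needed by the
# physics-informed residual: with respect to q, qdot, f0 and l0.
# All inputs may be vectors over time.
muscle_torque_terms <- function(q, qdot, a, l1, l2, sign, kappa, passive) {
  l0 <- kappa$l0M; vmax <- kappa$vmaxM; f0 <- kappa$f0M
  lsT <- kappa$lsT; th0 <- kappa$theta0
  L <- sqrt(l1^2 + l2^2 + 2 * sign * l1 * l2 * cos(q))
  D <- -sign * l1 * l2 * sin(q) / L
  dD <- -(sign * l1 * l2 * cos(q) + D^2) / L
  R <- -D; dR <- -dD
  s <- L - lsT
  w <- l0 * sin(th0)
  lM <- sqrt(s^2 + w^2)
  costh <- s / lM
  lt <- lM / l0
  vt <- costh * D * qdot / vmax
  fl <- force_length(lt); dfl <- force_length_d(lt)
  fv <- force_velocity(vt); dfv <- force_velocity_d(vt)
  fp <- if (passive) force_passive(lt) else 0
  dfp <- if (passive) force_passive_d(lt) else 0
  Fbar <- a * fl * fv + fp                 # normalised fibre force
  FMT <- f0 * Fbar * costh
  tau <- R * FMT

  dcosth_dq <- D * (1 - costh^2) / lM
  dlt_dq <- costh * D / l0
  dvt_dq <- (qdot / vmax) * (dcosth_dq * D + costh * dD)
  dF_dq <- f0 * ((a * dfl * fv + dfp) * dlt_dq + a * fl * dfv * dvt_dq) *
    costh + f0 * Fbar * dcosth_dq
  dtau_dq <- dR * FMT + R * dF_dq
  dtau_dqdot <- R * f0 * a * fl * dfv * (costh * D / vmax) * costh
  dtau_df0 <- tau / f0
  dlM_dl0 <- w * sin(th0) / lM
  dcosth_dl0 <- -costh * w * sin(th0) / lM^2
  dlt_dl0 <- (dlM_dl0 - lt) / l0
  dvt_dl0 <- (D * qdot / vmax) * dcosth_dl0
  dtau_dl0 <- R * f0 * (((a * dfl * fv + dfp) * dlt_dl0 +
                           a * fl * dfv * dvt_dl0) * costh +
                          Fbar * dcosth_dl0)
  list(tau = tau, dq = dtau_dq, dqdot = dtau_dqdot,
       df0 = dtau_df0, dl0 = dtau_dl0)
}

# torque only (no partials); the hot path of the forward integrator
muscle_torque_fast <- function(q, qdot, a, l1, l2, sign, kappa, passive) {
  L <- sqrt(l1^2 + l2^2 + 2 * sign * l1 * l2 * cos(q))
  D <- -sign * l1 * l2 * sin(q) / L
  s <- L - kappa$lsT
  w <- kappa$l0M * sin(kappa$theta0)
  lM <- sqrt(s^2 + w^2)
  costh <- s / lM
  lt <- lM / kappa$l0M
  vt <- costh * D * qdot / kappa$vmaxM
  fp <- if (passive) force_passive(lt) else 0
  -D * kappa$f0M * (a * force_length(lt) * force_velocity(vt) + fp) * costh
}

joint_torque_fast <- function(q, qdot, a_bi, a_tri, model) {
  muscle_torque_fast(q, qdot, a_bi, model$l1_bi, model$l2_bi, +1,
                     model$biceps, model$passive) +
    muscle_torque_fast(q, qdot, a_tri, model$l1_tri, model$l2_tri, -1,
                       model$triceps, model$passive)
}

# Total joint torque and partials for given activations and kinematics,
# optionally overriding the identified parameters {f0_Bi, l0_Bi, f0_Tri,
# l0_Tri} from Gamma.  Vectorised over time.
joint_torque_terms <- function(q, qdot, a_bi, a_tri, model, Gamma = NULL) {
  kb <- model$biceps; kt <- model$triceps
  if (!is.null(Gamma)) {
    kb$f0M <- Gamma[["f0_Bi"]]; kb$l0M <- Gamma[["l0_Bi"]]
    kt$f0M <- Gamma[["f0_Tri"]]; kt$l0M <- Gamma[["l0_Tri"]]
  }
  b <- muscle_torque_terms(q, qdot, a_bi, model$l1_bi, model$l2_bi, +1,
                           kb, model$passive)
  t_ <- muscle_torque_terms(q, qdot, a_tri, model$l1_tri, model$l2_tri, -1,
                            kt, model$passive)
  list(tau = b$tau + t_$tau,
       dq = b$dq + t_$dq, dqdot = b$dqdot + t_$dqdot,
       df0_bi = b$df0, dl0_bi = b$dl0,
       df0_tri = t_$df0, dl0_tri = t_$dl0)
}

#' Total muscle torque at the elbow
#'
#' `TMT = R_bi * FMT_bi + R_tri * FMT_tri`; the extensor moment arm is
#' negative, so flexion torque is positive.
#'
#' @param a_bi,a_tri activations of biceps and triceps in `[0, 1]`.
#' @param state a [joint_state()].
#' @param model an [elbow_model()].
#' @return Torque, N m.
#' @export
joint_torque <- function(a_bi, a_tri, state, model) {
  if (any(c(a_bi, a_tri) < 0 | c(a_bi, a_tri) > 1))
    stop("activation must lie in [0, 1]")
  joint_torque_terms(state$q, state$qdot, a_bi, a_tri, model)$tau
}

#' Forward-dynamics right-hand side
#'
#' The equation of motion `I qddot - TMT(a, q, qdot) - E(q) = 0` solved for
#' the accelerations: `qddot = (TMT + E(q)) / I` with `I = m_fa lfa^2` and
#' gravity torque `E(q) = -m_fa g lfa sin(q)`.
#'
#' @param t time, s.
#' @param state [joint_state()].
#' @param emg_pair named list or vector with elements `bi` and `tri` giving
#'   the *excitation-ready* sEMG values at time `t - d` resolution; here they
#'   are interpreted as already-delayed excitations (see
#'   [simulate_motion()] which performs the delay and interpolation).
#' @param model [elbow_model()].
#' @return A list `(qdot, qddot)`.
#' @export
forward_rhs <- function(t, state, emg_pair, model) {
  A <- model$activation$A
  a_bi <- activation(emg_pair[["bi"]], A)
  a_tri <- activation(emg_pair[["tri"]], A)
  tmt <- joint_torque_terms(state$q, state$qdot, a_bi, a_tri, model)$tau
  qddot <- (tmt + gravity_torque(state$q, model)) / model$I
  list(qdot = state$qdot, qddot = qddot)
}

#' Simulate elbow motion from sEMG
#'
#' Integrates the forward dynamics with an adaptive explicit Runge-Kutta
#' scheme (Dormand-Prince 4(5) via \pkg{deSolve}), sampling the dense output
#' on the trial grid.  sEMG between samples is linearly interpolated; the
#' electromechanical delay and activation shaping are applied inside the
#' right-hand side.
#'
#' @param emg matrix or data frame with columns `bi` and `tri` sampled on
#'   `t_grid`.
#' @param model [elbow_model()].
#' @param q0,qdot0 initial angle (rad) and velocity (rad/s).
#' @param t_grid uniform time grid, s.
#' @param atol,rtol integrator tolerances.
#' @return A [trial()] holding `t_grid`, the input sEMG and the solved angle.
#' @export
simulate_motion <- function(emg, model, q0 = pi / 6, qdot0 = 0, t_grid,
                            atol = 1e-7, rtol = 1e-7) {
  stopifnot(is.finite(q0), is.finite(qdot0))
  emg <- as.matrix(emg)
  stopifnot(nrow(emg) == length(t_grid), all(c("bi", "tri") %in% colnames(emg)))
  d <- model$activation$d
  e_bi <- stats::approxfun(t_grid, emg[, "bi"], rule = 2)
  e_tri <- stats::approxfun(t_grid, emg[, "tri"], rule = 2)
  A <- model$activation$A
  mgl <- model$m_fa * model$g * model$lfa
  rhs <- function(t, y, parms) {
    a_bi <- activation(e_bi(t - d), A)
    a_tri <- activation(e_tri(t - d), A)
    tmt <- joint_torque_fast(y[1], y[2], a_bi, a_tri, model)
    list(c(y[2], (tmt - mgl * sin(y[1])) / model$I))
  }
  sol <- deSolve::ode(y = c(q = q0, qdot = qdot0), times = t_grid,
                      func = rhs, parms = NULL, method = "ode45",
                      atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(t_grid))
    stop(sprintf("integrator failure at t = %.4f s", sol[nrow(sol), "time"]))
  trial(t = t_grid, emg = emg, q = sol[, "q"])
}

#' Equation-of-motion residual
#'
#' The residual `I qddot - E(q) - TMT(a, q, qdot; Gamma)` evaluated
#' pointwise; this is
#' the quantity penalised by the physics-informed loss.  `Gamma` supplies the
#' four identified parameters `f0_Bi`, `l0_Bi`, `f0_Tri`, `l0_Tri`; all other
#' muscle constants come from `model`.  The torque is evaluated as a smooth
#' extension of the anatomical geometry so the residual stays defined for
#' optimisation iterates that stray outside `(0, pi)`.
#'
#' @param q,qdot,qddot kinematic series (rad, rad/s, rad/s^2).
#' @param a_bi,a_tri activation series in `[0, 1]`.
#' @param Gamma named vector/list with `f0_Bi`, `l0_Bi`, `f0_Tri`, `l0_Tri`.
#' @param model [elbow_model()].
#' @return Residual series, N m.
#' @export
eom_residual <- function(q, qdot, qddot, a_bi, a_tri, Gamma, model) {
  Gamma <- as.list(Gamma)
  need <- c("f0_Bi", "l0_Bi", "f0_Tri", "l0_Tri")
  if (!all(need %in% names(Gamma)))
    stop("Gamma must supply f0_Bi, l0_Bi, f0_Tri, l0_Tri")
  tt <- joint_torque_terms(q, qdot, a_bi, a_tri, model, Gamma)
  model$I * qddot - gravity_torque(q, model) - tt$tau
}

# residual plus partials w.r.t. (q, qdot, qddot) and the four Gamma entries
eom_residual_terms <- function(q, qdot, qddot, a_bi, a_tri, Gamma, model) {
  tt <- joint_torque_terms(q, qdot, a_bi, a_tri, model, as.list(Gamma))
  list(r = model$I * qddot - gravity_torque(q, model) - tt$tau,
       dq = -gravity_torque_dq(q, model) - tt$dq,
       dqdot = -tt$dqdot,
       dqddot = model$I,
       df0_bi = -tt$df0_bi, dl0_bi = -tt$dl0_bi,
       df0_tri = -tt$df0_tri, dl0_tri = -tt$dl0_tri)
}
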