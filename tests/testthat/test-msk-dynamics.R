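# Activation dynamics, Hill-type forces, elbow geometry and forward dynamics.

test_that("excitation delay shifts the signal with first-sample padding", {
  t <- seq(0, 2, by = 0.01)
  e <- sin(2 * pi * t)
  u <- excitation_from_emg(e, t, d = 0.08)
  expect_equal(u[t >= 0.08], sin(2 * pi * (t[t >= 0.08] - 0.08)),
               tolerance = 1e-10)
  expect_equal(u[t < 0.08 - 1e-12], rep(e[1], sum(t < 0.08 - 1e-12)))
  expect_identical(excitation_from_emg(e, t, 0), e)
  expect_equal(excitation_from_emg(rep(0.7, length(t)), t, 0.31),
               rep(0.7, length(t)))
  expect_error(excitation_from_emg(e, t, 5), "delay exceeds trial span")
})

test_that("activation endpoints and shape match the exponential law", {
  expect_equal(activation(0, 0.2), 0)
  expect_equal(activation(1, 0.2), 1)
  expect_equal(activation(0.5, 0.2), (exp(0.1) - 1) / (exp(0.2) - 1),
               tolerance = 1e-12)
  # endpoint identities hold for any nonzero shape factor
  for (A in c(-3, -0.2, 0.2, 1, 5)) {
    expect_equal(activation(0, A), 0)
    expect_equal(activation(1, A), 1)
  }
  # A > 0: convex, below the identity on (0, 1); monotone in u
  u <- seq(0.05, 0.95, by = 0.05)
  a <- activation(u, 0.2)
  expect_true(all(a < u))
  expect_true(all(diff(a) > 0))
  expect_true(all(diff(diff(activation(seq(0, 1, 0.01), 0.2))) > 0))
  # clipping keeps out-of-range excitations physiological
  expect_equal(activation(c(-0.3, 1.4), 0.2), c(0, 1))
  expect_error(activation(0.5, 0), "nonzero")
})

test_that("muscle path length and moment arm follow the law of cosines", {
  g <- mt_length_and_moment_arm(pi / 2, 0.3, 0.8, sign = 1)
  expect_equal(g$lMT, sqrt(0.73), tolerance = 1e-12)
  expect_equal(abs(g$R), 0.3 * 0.8 / sqrt(0.73), tolerance = 1e-12)
  expect_true(g$R > 0)  # flexor
  ext <- mt_length_and_moment_arm(pi / 2, 0.3, 0.8, sign = -1)
  expect_true(ext$R < 0)  # extensor
  # extensor limit: shortest path and vanishing moment arm as q -> 0+
  e0 <- mt_length_and_moment_arm(1e-6, 0.3, 0.8, sign = -1)
  expect_equal(e0$lMT, 0.5, tolerance = 1e-6)
  expect_lt(abs(e0$R), 1e-5)
  expect_error(mt_length_and_moment_arm(-0.1, 0.3, 0.8), "anatomical range")
  expect_error(mt_length_and_moment_arm(3.2, 0.3, 0.8), "anatomical range")
})

test_that("moment arm equals the path-length derivative (finite differences)", {
  h <- 1e-5
  for (sgn in c(1, -1)) for (q in c(0.4, 1.1, 2.0)) {
    lp <- mt_length_and_moment_arm(q + h, 0.3, 0.8, sgn)$lMT
    lm <- mt_length_and_moment_arm(q - h, 0.3, 0.8, sgn)$lMT
    R <- mt_length_and_moment_arm(q, 0.3, 0.8, sgn)$R
    expect_equal(R, -(lp - lm) / (2 * h), tolerance = 1e-7)
  }
})

test_that("rigid-tendon fibre state matches the geometric relations", {
  kb <- muscle_params(0.6, 6, 300, 0.55, 0)
  fs <- fiber_state(1.15, 0, 0.1, kb)
  expect_equal(fs$ltilde, 1, tolerance = 1e-12)
  expect_equal(fs$theta, 0)
  expect_equal(fs$vtilde, 0)
  # pennation preserves thickness: lM sin(theta) = l0 sin(theta0)
  kp <- muscle_params(0.6, 6, 300, 0.55, 0.3)
  fsp <- fiber_state(1.0, 1.2, 0.2, kp)
  expect_equal(fsp$ltilde * kp$l0M * sin(fsp$theta), kp$l0M * sin(0.3),
               tolerance = 1e-12)
  expect_error(fiber_state(0.5, 0, 0.1, kb), "slack length")
})

test_that("muscle-tendon force combines active, passive and pennation terms", {
  kb <- muscle_params(0.6, 6, 300, 0.55, 0)
  # maximum isometric conditions
  expect_equal(mt_force(1, 1, 0, 0, kb, passive = FALSE), 300)
  expect_equal(mt_force(0, 1, 0, 0, kb, passive = FALSE), 0)
  # pennation scales by cos(theta)
  expect_equal(mt_force(1, 1, 0, 0.4, kb, passive = FALSE),
               300 * cos(0.4), tolerance = 1e-12)
  expect_error(mt_force(1.2, 1, 0, 0, kb), "activation")
})

test_that("joint torque has the antagonist sign structure", {
  m <- elbow_model(passive = FALSE)
  st <- joint_state(1.0, 0)
  expect_equal(joint_torque(0, 0, st, m), 0)
  # increasing biceps activation increases flexion torque
  taus <- vapply(c(0.2, 0.5, 0.9), function(a) joint_torque(a, 0, st, m),
                 numeric(1))
  expect_true(all(diff(taus) > 0))
  expect_lt(joint_torque(0, 0.5, st, m), 0)
  # antagonist balance: scale triceps activation to cancel the biceps torque
  tb <- joint_torque(0.5, 0, st, m)
  tt <- joint_torque(0, 1, st, m)
  expect_equal(joint_torque(0.5, -tb / tt, st, m), 0, tolerance = 1e-10)
})

test_that("torque is linear in each maximum isometric force", {
  m <- elbow_model()
  G <- truth_gamma
  tau1 <- mrpinn:::joint_torque_terms(1.1, 0.7, 0.6, 0.3, m, as.list(G))$tau
  G2 <- G; G2["f0_Bi"] <- G["f0_Bi"] * 1.1
  tau2 <- mrpinn:::joint_torque_terms(1.1, 0.7, 0.6, 0.3, m, as.list(G2))$tau
  G3 <- G; G3["f0_Bi"] <- G["f0_Bi"] * 1.2
  tau3 <- mrpinn:::joint_torque_terms(1.1, 0.7, 0.6, 0.3, m, as.list(G3))$tau
  expect_equal(tau3 - tau2, tau2 - tau1, tolerance = 1e-10)
})

test_that("analytic torque partials match finite differences", {
  m <- elbow_model(biceps = muscle_params(0.6, 6, 300, 0.55, 0.2))
  set.seed(4)
  q <- runif(6, 0.3, 2.2); qd <- runif(6, -3, 3)
  ab <- runif(6); at <- runif(6)
  G <- list(f0_Bi = 310, l0_Bi = 0.57, f0_Tri = 280, l0_Tri = 0.43)
  tt <- mrpinn:::joint_torque_terms(q, qd, ab, at, m, G)
  h <- 1e-6
  num <- (mrpinn:::joint_torque_terms(q + h, qd, ab, at, m, G)$tau -
            mrpinn:::joint_torque_terms(q - h, qd, ab, at, m, G)$tau) / (2 * h)
  expect_equal(tt$dq, num, tolerance = 1e-6)
  num <- (mrpinn:::joint_torque_terms(q, qd + h, ab, at, m, G)$tau -
            mrpinn:::joint_torque_terms(q, qd - h, ab, at, m, G)$tau) / (2 * h)
  expect_equal(tt$dqdot, num, tolerance = 1e-6)
  for (nm in c("f0_Bi", "l0_Bi", "f0_Tri", "l0_Tri")) {
    Gp <- G; Gp[[nm]] <- G[[nm]] + h
    Gm <- G; Gm[[nm]] <- G[[nm]] - h
    num <- (mrpinn:::joint_torque_terms(q, qd, ab, at, m, Gp)$tau -
              mrpinn:::joint_torque_terms(q, qd, ab, at, m, Gm)$tau) / (2 * h)
    key <- c(f0_Bi = "df0_bi", l0_Bi = "dl0_bi",
             f0_Tri = "df0_tri", l0_Tri = "dl0_tri")[[nm]]
    expect_equal(tt[[key]], num, tolerance = 1e-5)
  }
})

test_that("the passive system is a point-mass pendulum", {
  m <- elbow_model(passive = FALSE)
  expect_equal(m$I, 1.0)
  # at the stable hanging equilibrium nothing moves
  rhs <- forward_rhs(0, joint_state(0, 0), c(bi = 0, tri = 0), m)
  expect_equal(rhs$qddot, 0, tolerance = 1e-12)
  # small oscillations about the equilibrium: period 2*pi*sqrt(lfa/g)
  amp <- 5 * pi / 180
  tg <- seq(0, 6, by = 0.002)
  tr <- simulate_motion(cbind(bi = rep(0, length(tg)),
                              tri = rep(0, length(tg))),
                        m, q0 = amp, qdot0 = 0, t_grid = tg)
  # period from successive downward zero crossings
  s <- sign(tr$q)
  crossings <- tr$t[which(diff(s) < 0)]
  period <- diff(crossings)[1] * 1  # first full period between crossings
  expect_equal(period, 2 * pi * sqrt(1 / 9.81), tolerance = 0.5e-2 * 2)
})

test_that("simulated motion is integrator-tolerance converged", {
  spec <- synth_spec(n = 150, duration = 3)
  emg <- synth_emg(1, spec)
  m <- elbow_model()
  q1 <- simulate_motion(emg, m, t_grid = spec$t, atol = 1e-9, rtol = 1e-9)$q
  q2 <- simulate_motion(emg, m, t_grid = spec$t, atol = 5e-10, rtol = 5e-10)$q
  expect_lt(max(abs(q1 - q2)), 1e-6)
  expect_equal(q1[1], pi / 6)
})

test_that("the residual is identically zero with the integrator's own derivatives", {
  # qdot from the solved state and qddot from the right-hand side must
  # cancel exactly inside the residual: the simulator and the residual
  # share one torque balance
  m <- elbow_model()
  spec <- synth_spec(n = 100, duration = 2)
  tr <- simulate_motion(synth_emg(1, spec), m, t_grid = spec$t)
  act <- trial_activations(tr, m)
  for (i in c(10, 20, 60)) {
    qd <- c(0.7, -1.2, 0)[match(i, c(10, 20, 60))]
    a_b <- act$a_bi[i]; a_t <- act$a_tri[i]
    tau <- joint_torque(a_b, a_t, joint_state(tr$q[i], qd), m)
    qdd <- (tau + mrpinn:::gravity_torque(tr$q[i], m)) / m$I
    r <- eom_residual(tr$q[i], qd, qdd, a_b, a_t, truth_gamma, m)
    expect_equal(r, 0, tolerance = 1e-12)
  }
})

test_that("finite-difference residual on the true trajectory shrinks under refinement", {
  m <- elbow_model()
  resid_sup <- function(n) {
    spec <- synth_spec(n = n, duration = 4)
    tr <- simulate_motion(synth_emg(2, spec), m, t_grid = spec$t,
                          atol = 1e-10, rtol = 1e-10)
    act <- trial_activations(tr, m)
    i <- 2:(n - 1)
    qd <- (tr$q[i + 1] - tr$q[i - 1]) / (2 * tr$dt)
    qdd <- (tr$q[i + 1] - 2 * tr$q[i] + tr$q[i - 1]) / tr$dt^2
    max(abs(eom_residual(tr$q[i], qd, qdd, act$a_bi[i], act$a_tri[i],
                         truth_gamma, m)))
  }
  r1 <- resid_sup(200)
  r2 <- resid_sup(400)
  # the drive is interpolated between samples, so the pointwise residual
  # carries O(dt) kink errors; it must still shrink and stay small on the
  # ~10 N m torque scale, and the stencil-consistent residual is an order
  # of magnitude smaller
  expect_lt(r2, r1 / 1.7)
  expect_lt(r1, 0.5)
  spec <- synth_spec(n = 400, duration = 4)
  tr <- simulate_motion(synth_emg(2, spec), m, t_grid = spec$t,
                        atol = 1e-10, rtol = 1e-10)
  act <- trial_activations(tr, m)
  rs <- mrpinn:::residual_core(tr$q, tr$dt, act$a_bi, act$a_tri,
                               truth_gamma, m)$r
  expect_lt(max(abs(rs)), r2 / 2)
  # zero dynamics: no torques, no acceleration -> zero residual
  m0 <- elbow_model(passive = FALSE)
  expect_equal(eom_residual(0, 0, 0, 0, 0, truth_gamma, m0), 0)
})

test_that("residual responds monotonically to force perturbations", {
  tr <- small_trial()
  m <- elbow_model()
  act <- trial_activations(tr, m)
  n <- tr$n; i <- 2:(n - 1)
  qd <- (tr$q[i + 1] - tr$q[i - 1]) / (2 * tr$dt)
  qdd <- (tr$q[i + 1] - 2 * tr$q[i] + tr$q[i - 1]) / tr$dt^2
  rs <- sapply(c(1, 1.05, 1.1), function(f) {
    G <- truth_gamma; G["f0_Bi"] <- G["f0_Bi"] * f
    mean(eom_residual(tr$q[i], qd, qdd, act$a_bi[i], act$a_tri[i], G, m))
  })
  expect_true(all(diff(rs) < 0))  # more flexor force -> more negative residual
  expect_equal(diff(rs)[1], diff(rs)[2], tolerance = 1e-8)  # linear in f0
})
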