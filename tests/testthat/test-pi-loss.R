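# Composite physics-informed loss, parameter machinery and derivative modes.

make_cfg <- function(tr, beta = 1e-3,
                     mode = "finite_difference") {
  loss_config(beta = beta, derivative_mode = mode,
              stats = standardization_stats(list(tr)))
}

test_that("data loss is the batch mean squared error", {
  expect_equal(data_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(data_loss(rep(2, 10), rep(0, 10)), 4)
  expect_error(data_loss(numeric(0), numeric(0)), "empty")
  # equals the trial MSE metric when the batch is one full trial
  set.seed(1)
  q <- rnorm(50); qh <- q + rnorm(50, sd = 0.1)
  expect_equal(data_loss(qh, q), mean((q - qh)^2))
})

test_that("normalized parameters recover physical values", {
  p <- identified_params(truth_gamma)
  expect_equal(param_values(p), truth_gamma)
  p$bar <- c(f0_Bi = 1.1, l0_Bi = 0.9, f0_Tri = 1, l0_Tri = 1.05)
  expect_equal(param_values(p)[["f0_Bi"]], 330)
  expect_error(identified_params(c(f0_Bi = 1)), "f0_Bi")
})

test_that("sigmoid-constrained parameters stay in the anchor envelope", {
  expect_equal(constrained_params(0, 600), 300)
  expect_equal(constrained_params(c(0, 0), c(100, 300)), 100)  # mean/2
  expect_equal(constrained_params(c(50, 50), c(100, 300)), 200,
               tolerance = 1e-10)  # saturated sigmoids -> mean of anchors
  expect_lt(constrained_params(c(8, -8), c(100, 300)), 200)
  expect_error(constrained_params(numeric(0), numeric(0)), "anchor")
})

test_that("autodiff time derivatives match numerical differentiation of the cell", {
  tr <- small_trial()
  cfg <- make_cfg(tr, mode = "autodiff")
  st <- cfg$stats
  for (wmaker in list(function() gru_weights(7, 3, seed = 2),
                      function() rnn_weights(7, 3, seed = 2))) {
    w <- wmaker()
    X <- mrpinn:::std_inputs(tr, st, elbow_model())
    qs <- mrpinn:::std_q(tr$q, st)
    win <- make_windows(X, qs, m = 2)
    der <- predicted_derivatives(w, win, cfg, dt = tr$dt)
    # numerical oracle: perturb the standardized current-step time input
    probe <- function(k, h) {
      Xs <- win$Xs
      Xs[[3]][k, 1] <- Xs[[3]][k, 1] + h
      mrpinn:::destd_q(mrpinn:::seq_forward(Xs, win$Qs, w)$qhat[k], st)
    }
    h <- 1e-4
    for (k in c(5, 60, 150)) {
      f0 <- mrpinn:::destd_q(mrpinn:::seq_forward(win$Xs, win$Qs, w)$qhat[k], st)
      sd_t <- unname(st$sd_x[1])
      d1 <- (probe(k, h) - probe(k, -h)) / (2 * h) / sd_t
      d2 <- (probe(k, h) - 2 * f0 + probe(k, -h)) / h^2 / sd_t^2
      expect_equal(der$qdot[k], d1, tolerance = 1e-5)
      expect_equal(der$qddot[k], d2, tolerance = 1e-3)
    }
  }
})

test_that("finite-difference derivatives recover smooth trajectories", {
  tr <- small_trial()
  cfg <- make_cfg(tr)
  # a weight draw is an arbitrary smooth map; its predictions over the
  # uniform grid must differentiate consistently with an analytic probe
  w <- gru_weights(6, 3, seed = 11)
  st <- cfg$stats
  win <- make_windows(mrpinn:::std_inputs(tr, st, elbow_model()),
                      mrpinn:::std_q(tr$q, st), m = 2)
  der <- predicted_derivatives(w, win, cfg, dt = tr$dt)
  n <- length(der$q)
  i <- 2:(n - 1)
  expect_equal(der$qdot[i], (der$q[i + 1] - der$q[i - 1]) / (2 * tr$dt))
  expect_true(all(is.na(der$qdot[c(1, n)])))
  expect_error(predicted_derivatives(w, win, cfg), "dt is required")
})

test_that("composite loss dominates the data term and collapses at beta = 0", {
  tr <- small_noisy_trial()
  m <- elbow_model()
  cfg0 <- make_cfg(tr, beta = 0)
  cfg <- make_cfg(tr, beta = 1e-3)
  w <- gru_weights(10, 3, seed = 3)
  b <- pi_batch(tr, m = 2, cfg = cfg, model = m)
  G <- truth_gamma
  J0 <- composite_loss(b, w, G, m, cfg0)
  J <- composite_loss(b, w, G, m, cfg)
  fwd <- mrpinn:::seq_forward(b$windows$Xs, b$windows$Qs, w)
  expect_equal(as.numeric(J0), data_loss(fwd$qhat, b$target_std))
  expect_gte(as.numeric(J), as.numeric(J0))
  expect_equal(attr(J, "J_data"), as.numeric(J0))
  # quadratic form: doubling all residuals quadruples J_res
  r <- c(1, -2, 3); expect_equal(mean((2 * r)^2), 4 * mean(r^2))
})

test_that("loss gradients match central finite differences in both modes", {
  tr <- small_noisy_trial()
  m <- elbow_model()
  for (mode in c("finite_difference", "autodiff")) {
    cfg <- make_cfg(tr, beta = 1e-3, mode = mode)
    w <- gru_weights(6, 3, seed = 8)
    p <- identified_params(truth_gamma * c(1.1, 0.9, 0.95, 1.08))
    b <- pi_batch(tr, m = 2, cfg = cfg, model = m)
    lg <- mrpinn:::pi_loss_grad(b, w, p, m, cfg)
    lossf <- function(w2, p2)
      as.numeric(composite_loss(b, w2, param_values(p2), m, cfg))
    expect_equal(lg$J, lossf(w, p), tolerance = 1e-12)
    h <- 1e-6
    set.seed(42)
    for (nm in c("W_hr", "W_xht", "W_hq", "b_ht", "W_qu", "W_xr")) {
      idx <- sample(length(w[[nm]]), 1)
      wp <- w; wp[[nm]][idx] <- wp[[nm]][idx] + h
      wm <- w; wm[[nm]][idx] <- wm[[nm]][idx] - h
      num <- (lossf(wp, p) - lossf(wm, p)) / (2 * h)
      expect_equal(lg$g[[nm]][idx], num, tolerance = 1e-5)
    }
    for (j in 1:4) {
      pp <- p; pp$bar[j] <- pp$bar[j] + h
      pm <- p; pm$bar[j] <- pm$bar[j] - h
      num <- (lossf(w, pp) - lossf(w, pm)) / (2 * h)
      expect_equal(unname(lg$gbar[j]), num, tolerance = 1e-5)
    }
  }
  # Gamma enters only through the residual: beta = 0 kills its gradient
  cfg0 <- make_cfg(tr, beta = 0)
  b0 <- pi_batch(tr, m = 2, cfg = cfg0, model = m)
  w <- gru_weights(6, 3, seed = 8)
  p <- identified_params(truth_gamma)
  lg0 <- mrpinn:::pi_loss_grad(b0, w, p, m, cfg0)
  expect_equal(unname(lg0$gbar), rep(0, 4))
})

test_that("residual loss on the true trajectory shrinks under refinement", {
  m <- elbow_model()
  jres_truth <- function(n) {
    spec <- synth_spec(n = n, duration = 4)
    tr <- simulate_motion(synth_emg(2, spec), m, t_grid = spec$t,
                          atol = 1e-9, rtol = 1e-9)
    act <- trial_activations(tr, m)
    r <- mrpinn:::residual_core(tr$q, tr$dt, act$a_bi, act$a_tri,
                                truth_gamma, m)$r
    mean(r^2)
  }
  j1 <- jres_truth(150)
  j2 <- jres_truth(300)
  expect_lt(j2, j1 / 5)     # ~O(dt^4) decay of the mean square
  expect_lt(j1, 2e-2)       # small on the ~100 (N m)^2 squared-torque scale
})

test_that("residual-only identification recovers the true parameters", {
  # network replaced by the true trajectory; minimise J_res over Gamma.
  # The identification floor is the O(dt^2) stencil error, so the test
  # uses a fine grid (dt = 5 ms) where the floor sits below 0.1%.
  m <- elbow_model()
  spec <- synth_spec(n = 800, duration = 4)
  tr <- simulate_motion(synth_emg(2, spec), m, t_grid = spec$t,
                        atol = 1e-9, rtol = 1e-9)
  act <- trial_activations(tr, m)
  obj <- function(bar) {
    G <- truth_gamma * bar
    mean(mrpinn:::residual_core(tr$q, tr$dt, act$a_bi, act$a_tri, G, m)$r^2)
  }
  fit <- optim(c(1.08, 0.94, 0.92, 1.06), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  expect_true(all(abs(fit$par - 1) < 1e-3))  # each parameter within 0.1%
  expect_lt(obj(fit$par), obj(rep(1, 4)))    # a genuine interior optimum
})
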