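# Shared fixture builders.  Everything is generated in code; heavier
# objects are cached per session.

fixture_env <- new.env(parent = emptyenv())

# a small noiseless simulated trial (cheap: 4 s, 200 points)
small_trial <- function() {
  if (is.null(fixture_env$small_trial)) {
    spec <- synth_spec(n = 200, duration = 4)
    fixture_env$small_trial <- simulate_motion(
      synth_emg(2, spec), elbow_model(), t_grid = spec$t,
      atol = 1e-8, rtol = 1e-8)
  }
  fixture_env$small_trial
}

# a small noisy trial for loss/training tests
small_noisy_trial <- function() {
  if (is.null(fixture_env$small_noisy)) {
    spec <- synth_spec(n = 200, duration = 4)
    emg <- apply_noise(synth_emg(2, spec), noise_case(1), seed = 91)
    fixture_env$small_noisy <- simulate_motion(
      emg, elbow_model(), t_grid = spec$t, atol = 1e-8, rtol = 1e-8)
  }
  fixture_env$small_noisy
}

truth_gamma <- c(f0_Bi = 300, l0_Bi = 0.6, f0_Tri = 300, l0_Tri = 0.4)

# finite-difference activations/kinematics helper used by residual tests
trial_activations <- function(tr, model = elbow_model()) {
  d <- model$activation$d; A <- model$activation$A
  list(a_bi = activation(excitation_from_emg(tr$emg[, "bi"], tr$t, d), A),
       a_tri = activation(excitation_from_emg(tr$emg[, "tri"], tr$t, d), A))
}

# independent per-equation transcription of the GRU used by the
# acceptance oracle block (the module tests carry their own copy)
oracle_check_gru <- function(x, qhist, w) {
  sg <- function(z) 1 / (1 + exp(-z))
  m <- length(qhist); H <- length(w$b_r)
  h <- rep(0, H)
  for (s in seq_len(m + 1)) {
    xi <- x[s, ]
    hist <- s <= m
    pr <- w$W_hr %*% h + w$W_xr %*% xi + w$b_r
    pu <- w$W_hu %*% h + w$W_xu %*% xi + w$b_u
    pcq <- 0
    if (hist) {
      pr <- pr + w$W_qr * qhist[s]
      pu <- pu + w$W_qu * qhist[s]
      pcq <- w$W_qht * qhist[s]
    }
    r <- sg(pr); u <- sg(pu)
    ht <- tanh(r * (w$W_hht %*% h) + w$W_xht %*% xi + pcq + w$b_ht)
    h <- as.numeric(u * h + ht - u * ht + w$b_h)
  }
  as.numeric(w$W_hq %*% h + w$b_q)
}
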