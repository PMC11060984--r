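# Coarse-to-fine training: per-scale optimisation of the composite
# physics-informed loss with Adam, early stopping, weight and parameter
# transfer across scales, and rollout evaluation.
#
# Gradients are computed analytically: backpropagation through time for the
# recurrent cell, the banded adjoint of the central-difference derivative
# stencils for the residual term, and the closed-form torque partials of
# the musculoskeletal model for the identified parameters.

#' Training schedule
#'
#' @param scales ordered training scales ending at 0, e.g. `c(-2, -1, 0)`
#'   for 3-scale training.
#' @param epochs_per_scale epochs at each scale (one Adam step per training
#'   trial per epoch).
#' @param lr initial Adam learning rate.
#' @param lr_end learning rate reached (geometrically) by the final epoch
#'   of each scale; set equal to `lr` for a constant rate.
#' @param lr_gamma Adam learning rate of the normalized identified
#'   parameters (constant).  The four physical parameters are well
#'   conditioned, so they track the running optimum of the residual at a
#'   faster rate than the annealed network weights.
#' @param patience early-stopping patience (epochs without improvement of
#'   the training loss before stopping; best weights are restored).
#' @param min_delta minimum loss improvement that resets the patience.
#' @param m history steps of the recurrent cell.
#' @param noise_sigma teacher-forcing noise sd in standardized motion units.
#' @param batch_size windows per optimisation step; each trial's windows
#'   are split into contiguous chunks of this size (contiguity keeps the
#'   finite-difference residual stencil valid inside a chunk), and one
#'   Adam update is taken per chunk per epoch.
#' @param identify_scales scales at which the normalized parameters are
#'   updated (default: the full scale only).  The residual always enters
#'   the loss, but the torque balance holds for the *unprojected* signals,
#'   so the parameter read-out belongs to scale 0; updating the parameters
#'   against coarse-scale residuals would pull them toward the projected
#'   system's (different) optimum.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(scales = c(-2, -1, 0), epochs_per_scale = 1000,
                              lr = 1e-3, lr_end = 1e-4, lr_gamma = 5e-3,
                              patience = 100, min_delta = 1e-6, m = 2,
                              noise_sigma = 0.003, batch_size = 24,
                              identify_scales = 0) {
  stopifnot(epochs_per_scale > 0, lr > 0, lr_end > 0, lr_end <= lr,
            lr_gamma > 0, m >= 1, batch_size >= 8,
            all(diff(scales) > 0), scales[length(scales)] == 0)
  structure(list(scales = scales, epochs_per_scale = epochs_per_scale,
                 lr = lr, lr_end = lr_end, lr_gamma = lr_gamma,
                 patience = patience,
                 min_delta = min_delta, m = m, noise_sigma = noise_sigma,
                 batch_size = batch_size, identify_scales = identify_scales),
            class = "training_schedule")
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function(w) list(m = zero_like(w), v = zero_like(w), t = 0)

adam_step <- function(w, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  aw <- attributes(w)
  upd <- .adam_step_cpp(w, g[names(w)], st$m, st$v, st$t, lr, b1, b2, eps)
  w <- upd$w
  attributes(w) <- aw
  st$m <- upd$m
  st$v <- upd$v
  list(w = w, st = st)
}

# ---- loss + gradient for one trial batch ------------------------------------

# Returns J and its components together with gradients w.r.t. all network
# weights and the normalized parameters bar(Gamma).  The data term is
# evaluated on the (possibly noise-augmented) teacher-forcing windows, the
# residual term on the clean-history windows; gradients of the two passes
# are summed.
pi_loss_grad <- function(batch, weights, params, model, cfg) {
  if (cfg$derivative_mode == "autodiff") {
    if (!inherits(weights, "gru_weights"))
      stop("autodiff-mode training is implemented for the GRU cell; ",
           "use derivative_mode = 'finite_difference' for the RNN")
    return(pi_loss_grad_jet(batch, weights, params, model, cfg))
  }
  st <- cfg$stats
  win <- batch$windows
  fwd <- seq_forward(win$Xs, win$Qs, weights)
  qhat <- fwd$qhat
  N <- length(qhat)
  resid_data <- qhat - batch$target_std
  J_data <- mean(resid_data^2)
  d_qhat <- 2 * resid_data / N

  clean_pass <- !identical(batch$Qs_clean, win$Qs)
  fwd_c <- if (clean_pass) seq_forward(win$Xs, batch$Qs_clean, weights)
  else fwd

  Gamma <- param_values(params)
  qp <- destd_q(fwd_c$qhat, st)
  dt <- batch$dt
  rc <- residual_core(qp, dt, batch$a_bi, batch$a_tri, Gamma, model)
  i <- rc$i
  Nr <- N - 2L
  J_res <- mean(rc$r^2)
  wr <- 2 * rc$r / Nr                          # dJ_res / dr_k, interior k

  # adjoint of r = I * D2 q - W phi(q, D1 q):
  #   psi = W^T wr (the smoothing stencil spread back to nodes),
  #   g_q = I * D2^T wr - psi * dphi/dq - D1^T (psi * dphi/dqdot)
  psi <- numeric(N)
  psi[i] <- psi[i] + 4 * wr / 6
  psi[i - 1] <- psi[i - 1] + wr / 6
  psi[i + 1] <- psi[i + 1] + wr / 6

  gq <- numeric(N)
  invdt2 <- model$I / dt^2
  gq[i] <- gq[i] - 2 * wr * invdt2
  gq[i - 1] <- gq[i - 1] + wr * invdt2
  gq[i + 1] <- gq[i + 1] + wr * invdt2

  gq <- gq - psi * rc$phi_q
  v <- psi * rc$phi_qd
  inv2dt <- 1 / (2 * dt)
  gq[i + 1] <- gq[i + 1] - v[i] * inv2dt       # central D1 rows
  gq[i - 1] <- gq[i - 1] + v[i] * inv2dt
  gq[1:3] <- gq[1:3] - v[1] * c(-3, 4, -1) * inv2dt       # one-sided ends
  gq[N - 0:2] <- gq[N - 0:2] - v[N] * c(3, -4, 1) * inv2dt

  tt <- rc$tt
  gGamma <- -c(f0_Bi = sum(psi * tt$df0_bi),
               l0_Bi = sum(psi * tt$dl0_bi),
               f0_Tri = sum(psi * tt$df0_tri),
               l0_Tri = sum(psi * tt$dl0_tri))
  gbar <- cfg$beta * gGamma * params$Gamma0

  if (clean_pass) {
    g <- if (isTRUE(fwd$compiled) && isTRUE(fwd_c$compiled)) {
      .gru_seq_backward2_cpp(d_qhat, fwd$handle,
                             cfg$beta * st$sd_q * gq, fwd_c$handle,
                             weights, attr_std(weights))
    } else {
      g1 <- seq_backward(d_qhat, fwd, weights)
      g2 <- seq_backward(cfg$beta * st$sd_q * gq, fwd_c, weights)
      for (nm in names(g1)) g1[[nm]] <- g1[[nm]] + g2[[nm]]
      g1
    }
  } else {
    g <- seq_backward(d_qhat + cfg$beta * st$sd_q * gq, fwd, weights)
  }
  list(J = J_data + cfg$beta * J_res, J_data = J_data, J_res = J_res,
       g = g, gbar = gbar)
}

# Autodiff-mode loss and gradient: the residual is evaluated pointwise at
# every window from the closed-form first/second derivatives of the cell
# output with respect to the current-step time input, and the full reverse
# pass (including the jet adjoint) runs in compiled code.
pi_loss_grad_jet <- function(batch, weights, params, model, cfg) {
  st <- cfg$stats
  win <- batch$windows
  fwd <- seq_forward(win$Xs, win$Qs, weights)
  qhat <- fwd$qhat
  N <- length(qhat)
  resid_data <- qhat - batch$target_std
  J_data <- mean(resid_data^2)
  d_qhat <- 2 * resid_data / N

  jet <- .gru_jet_cpp(fwd$handle, weights, attr_std(weights))
  sd_t <- st$sd_x[1]
  c1 <- st$sd_q / sd_t
  c2 <- st$sd_q / sd_t^2
  qp <- destd_q(qhat, st)
  qdot <- jet$d1 * c1
  qddot <- jet$d2 * c2
  Gamma <- param_values(params)
  terms <- eom_residual_terms(qp, qdot, qddot, batch$a_bi, batch$a_tri,
                              Gamma, model)
  J_res <- mean(terms$r^2)
  wr <- 2 * terms$r / N
  b <- cfg$beta
  dq <- d_qhat + b * st$sd_q * wr * terms$dq
  d1 <- b * c1 * wr * terms$dqdot
  d2 <- b * c2 * wr * model$I
  g <- .gru_seq_backward_jet_cpp(dq, d1, d2, fwd$handle, weights,
                                 attr_std(weights))
  gbar <- b * c(f0_Bi = mean(2 * terms$r * terms$df0_bi),
                l0_Bi = mean(2 * terms$r * terms$dl0_bi),
                f0_Tri = mean(2 * terms$r * terms$df0_tri),
                l0_Tri = mean(2 * terms$r * terms$dl0_tri)) * params$Gamma0
  list(J = J_data + b * J_res, J_data = J_data, J_res = J_res,
       g = g, gbar = gbar)
}

# ---- per-scale training ------------------------------------------------------

#' Train at one scale
#'
#' Minimises the composite loss over one scale's trials with Adam (one
#' update per trial per epoch), teacher-forcing noise freshly drawn for
#' the scale, and early stopping with best-weights restoration.
#'
#' @param scale_trials list of [trial()] objects at this scale.
#' @param weights initial network weights (transferred from the coarser
#'   scale, or freshly initialised).
#' @param params an [identified_params()] carrying the current normalized
#'   parameter state.
#' @param schedule a [training_schedule()].
#' @param model [elbow_model()].
#' @param cfg [loss_config()] with standardisation statistics.
#' @param scale_tag integer scale label (for the record).
#' @param seed integer seed for the teacher-forcing noise.
#' @return List with `weights`, `params`, and the per-epoch `record`.
#' @export
train_at_scale <- function(scale_trials, weights, params, schedule, model,
                           cfg, scale_tag = 0L, seed = NULL,
                           lr_range = c(schedule$lr, schedule$lr_end)) {
  if (!is.null(seed)) set.seed(seed)
  trial_batches <- lapply(scale_trials, pi_batch, m = schedule$m, cfg = cfg,
                          model = model, noise_sigma = schedule$noise_sigma)
  batches <- list()
  for (b in trial_batches) {
    N <- length(b$target_std)
    n_chunks <- max(1L, round(N / schedule$batch_size))
    bounds <- round(seq(0L, N, length.out = n_chunks + 1L))
    for (ci in seq_len(n_chunks)) {
      idx <- (bounds[ci] + 1L):bounds[ci + 1L]
      batches[[length(batches) + 1L]] <-
        if (n_chunks == 1L) b else pi_batch_slice(b, idx)
    }
  }
  st_w <- adam_init(weights)
  identify <- is.null(schedule$identify_scales) ||
    scale_tag %in% schedule$identify_scales
  par_vec <- params$bar
  st_p <- list(m = par_vec * 0, v = par_vec * 0, t = 0)
  best <- list(loss = Inf, weights = weights, bar = par_vec)
  wait <- 0L
  rec <- vector("list", schedule$epochs_per_scale)
  ne <- schedule$epochs_per_scale
  decay <- if (ne > 1) (lr_range[2] / lr_range[1])^(1 / (ne - 1)) else 1
  for (ep in seq_len(schedule$epochs_per_scale)) {
    lr_ep <- lr_range[1] * decay^(ep - 1)
    Js <- Jd <- Jr <- 0
    for (b in batches) {
      params$bar <- par_vec
      lg <- pi_loss_grad(b, weights, params, model, cfg)
      if (!is.finite(lg$J))
        stop(sprintf("non-finite loss at scale %d epoch %d", scale_tag, ep))
      upd <- adam_step(weights, lg$g, st_w, lr_ep)
      weights <- upd$w; st_w <- upd$st
      st_p$t <- st_p$t + 1
      st_p$m <- 0.9 * st_p$m + 0.1 * lg$gbar
      st_p$v <- 0.999 * st_p$v + 0.001 * lg$gbar^2
      if (identify) {
        par_vec <- par_vec - schedule$lr_gamma *
          (st_p$m / (1 - 0.9^st_p$t)) /
          (sqrt(st_p$v / (1 - 0.999^st_p$t)) + 1e-8)
      }
      Js <- Js + lg$J; Jd <- Jd + lg$J_data; Jr <- Jr + lg$J_res
    }
    nb <- length(batches)
    rec[[ep]] <- c(epoch = ep, scale = scale_tag, loss = Js / nb,
                   j_data = Jd / nb, j_res = Jr / nb)
    if (Js / nb < best$loss - schedule$min_delta) {
      best <- list(loss = Js / nb, weights = weights, bar = par_vec)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= schedule$patience) break
    }
  }
  params$bar <- best$bar
  list(weights = best$weights, params = params,
       record = as.data.frame(do.call(rbind, rec[!vapply(rec, is.null, TRUE)])))
}

#' Sequential multi-resolution training
#'
#' Trains scale-by-scale from the coarsest to the full scale, transferring
#' all network weights and the normalized parameter trainables forward; the
#' final parameter read-out happens after full-scale training.
#'
#' @param mr_data an [build_mr_dataset()] result holding the training
#'   trials at every scale of the schedule.
#' @param schedule a [training_schedule()].
#' @param model [elbow_model()].
#' @param cfg [loss_config()]; if its `stats` are missing they are computed
#'   from the full-scale training trials.
#' @param weights initial network weights, e.g. [gru_weights()].
#' @param params an [identified_params()] giving the parameter
#'   initialisation.
#' @param seed integer seed controlling the teacher-forcing noise draws.
#' @return List with final `weights`, `params`, identified `Gamma`
#'   (physical units), and the concatenated per-epoch `record`.
#' @export
mr_train <- function(mr_data, schedule, model, cfg, weights, params,
                     seed = NULL) {
  stopifnot(inherits(mr_data, "mr_dataset"))
  missing_sc <- setdiff(as.character(schedule$scales), names(mr_data$scales))
  if (length(missing_sc))
    stop("dataset is missing scales: ", paste(missing_sc, collapse = ", "))
  if (is.null(cfg$stats))
    cfg$stats <- standardization_stats(mr_data$scales[["0"]], model)
  recs <- list()
  # coarse scales pre-shape the network at a gentle constant rate (the
  # geometric mean of the anneal range); the full scale then runs the
  # complete anneal, so the final training phase is identical across
  # depths and deeper ladders only change its starting point
  lr_mid <- sqrt(schedule$lr * schedule$lr_end)
  for (si in seq_along(schedule$scales)) {
    sc <- schedule$scales[si]
    rng <- if (sc == 0) c(schedule$lr, schedule$lr_end) else rep(lr_mid, 2)
    fit <- train_at_scale(mr_data$scales[[as.character(sc)]], weights, params,
                          schedule, model, cfg, scale_tag = sc,
                          seed = if (is.null(seed)) NULL else seed + 7L * sc,
                          lr_range = rng)
    weights <- fit$weights
    params <- fit$params
    recs[[as.character(sc)]] <- fit$record
  }
  list(weights = weights, params = params, Gamma = param_values(params),
       record = do.call(rbind, recs), cfg = cfg)
}

#' Rollout evaluation metrics
#'
#' Runs the trained network autoregressively on a full-scale test trial
#' (only the first `m` motion values are given as seed) and reports the
#' mean squared error, the coefficient of determination and the normalized
#' mean squared error `NMSE = (1 - R^2) / n`.
#'
#' @param weights trained network weights.
#' @param test_trial a [trial()] at full scale.
#' @param cfg [loss_config()] with the training standardisation stats.
#' @param m history steps.
#' @param model [elbow_model()] used for the delay alignment of the input
#'   channels.
#' @return List with `mse`, `r2`, `nmse` and the predicted series `q_hat`.
#' @export
evaluate <- function(weights, test_trial, cfg, m = 2, model = elbow_model()) {
  st <- cfg$stats
  X <- std_inputs(test_trial, st, model)
  qs <- std_q(test_trial$q, st)
  pred_std <- rollout(weights, X, qs[seq_len(m)])
  q_hat <- destd_q(pred_std, st)
  q <- test_trial$q
  n <- length(q)
  ss_res <- sum((q - q_hat)^2)
  ss_tot <- sum((q - mean(q))^2)
  if (ss_tot == 0) stop("test motion has zero variance; R2/NMSE undefined")
  list(mse = ss_res / n, r2 = 1 - ss_res / ss_tot, nmse = ss_res / ss_tot / n,
       q_hat = q_hat)
}
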