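# Recurrent cells with motion feedback: a vanilla RNN and a GRU whose
# hidden-state update is
#   h_i = u_i . h_{i-1} + htilde_i - u_i . htilde_i + b_h
# i.e. the textbook convex-combination update plus an extra additive bias
# b_h; `standard_gru = TRUE` drops the extra bias.
#
# Windows carry m history steps with measured motion (teacher forcing) and
# a current step without motion input.  The batched forward/backward pass
# used for training lives here as well; gradients are hand-derived
# backpropagation-through-time over the m + 1 steps of a window.

sigm <- function(x) 1 / (1 + exp(-x))

runif_mat <- function(nr, nc, s) matrix(stats::runif(nr * nc, -s, s), nr, nc)

#' Initialise GRU weights
#'
#' All gate weight matrices for hidden width `H`, input width `n_in`
#' (time + sEMG channels) and the scalar motion-feedback input, drawn
#' uniformly from `[-1/sqrt(H), 1/sqrt(H)]`.
#'
#' @param H hidden width.
#' @param n_in input width (`1 + N_a`).
#' @param seed optional integer seed.
#' @param standard_gru drop the extra additive bias in the hidden-state
#'   update (textbook GRU) instead of keeping it verbatim.
#' @return An object of class `gru_weights`.
#' @export
gru_weights <- function(H, n_in, seed = NULL, standard_gru = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  s <- 1 / sqrt(H)
  w <- list(
    W_hr = runif_mat(H, H, s), W_xr = runif_mat(H, n_in, s),
    W_qr = runif_mat(H, 1, s),
    W_hu = runif_mat(H, H, s), W_xu = runif_mat(H, n_in, s),
    W_qu = runif_mat(H, 1, s),
    W_hht = runif_mat(H, H, s), W_xht = runif_mat(H, n_in, s),
    W_qht = runif_mat(H, 1, s),
    W_hq = runif_mat(1, H, s),
    b_r = numeric(H), b_u = numeric(H), b_ht = numeric(H),
    b_h = numeric(H), b_q = 0
  )
  structure(w, H = H, n_in = n_in, standard_gru = isTRUE(standard_gru),
            class = "gru_weights")
}

#' Initialise vanilla RNN weights
#'
#' @inheritParams gru_weights
#' @return An object of class `rnn_weights`.
#' @export
rnn_weights <- function(H, n_in, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- 1 / sqrt(H)
  w <- list(W_hh = runif_mat(H, H, s), W_xh = runif_mat(H, n_in, s),
            W_qh = runif_mat(H, 1, s), W_hq = runif_mat(1, H, s),
            b_h = numeric(H), b_q = 0)
  structure(w, H = H, n_in = n_in, class = "rnn_weights")
}

check_shapes <- function(w, n_in) {
  for (nm in names(w)) {
    d <- dim(w[[nm]])
    if (startsWith(nm, "W_x") && d[2] != n_in)
      stop(sprintf("shape mismatch in %s: expected %d input columns, got %d",
                   nm, n_in, d[2]))
  }
  invisible(TRUE)
}

# ---- batched cell evaluations ------------------------------------------------
# The GRU is evaluated in fused form: the reset, update and candidate
# pre-activations share two matrix products per step, one against the
# previous hidden state and one against the inputs (with the motion
# feedback appended as an extra input column at history steps).

attr_std <- function(w) isTRUE(attr(w, "standard_gru"))

# fused views of the GRU weights: Wh (3H x H), Wxq (3H x (n_in + 1)),
# fused gate bias (3H)
gru_fuse <- function(w) {
  Wh <- rbind(w$W_hr, w$W_hu, w$W_hht)
  Wxq <- cbind(rbind(w$W_xr, w$W_xu, w$W_xht),
               rbind(w$W_qr, w$W_qu, w$W_qht))
  list(Wh = Wh, tWh = t(Wh), tWxq = t(Wxq),
       bias = c(w$b_r, w$b_u, w$b_ht), H = attr(w, "H"),
       n_in = attr(w, "n_in"))
}

# Hp: N x H previous hidden state (NULL means zero); XQ: inputs with the
# motion column appended at history steps.  hist: logical, history step.
gru_cell_fwd <- function(Hp, XQ, fu, w, hist) {
  N <- nrow(XQ)
  H <- fu$H
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  tWxq <- if (hist) fu$tWxq else fu$tWxq[1:fu$n_in, , drop = FALSE]
  S <- XQ %*% tWxq + rep(fu$bias, each = N)
  Fh <- if (is.null(Hp)) NULL else Hp %*% fu$tWh
  if (is.null(Fh)) {
    r <- sigm(S[, i1, drop = FALSE]); u <- sigm(S[, i2, drop = FALSE])
    k <- matrix(0, N, H)
    ht <- tanh(S[, i3, drop = FALSE])
    h <- ht - u * ht
  } else {
    r <- sigm(Fh[, i1, drop = FALSE] + S[, i1, drop = FALSE])
    u <- sigm(Fh[, i2, drop = FALSE] + S[, i2, drop = FALSE])
    k <- Fh[, i3, drop = FALSE]
    ht <- tanh(r * k + S[, i3, drop = FALSE])
    h <- u * Hp + ht - u * ht
  }
  if (!attr_std(w)) h <- h + rep(w$b_h, each = N)
  list(h = h, cache = list(Hp = Hp, XQ = XQ, r = r, u = u, k = k, ht = ht,
                           hist = hist))
}

# backward step: dh is N x H; accumulates fused gradients into g and
# returns dHp
gru_cell_bwd <- function(dh, cache, fu, w, g) {
  Hp <- cache$Hp; XQ <- cache$XQ
  r <- cache$r; u <- cache$u; k <- cache$k; ht <- cache$ht
  if (!attr_std(w)) g$b_h <- g$b_h + colSums(dh)
  zeroH <- is.null(Hp)
  du <- if (zeroH) dh * (-ht) else dh * (Hp - ht)
  dht <- dh * (1 - u)
  dpre_c <- dht * (1 - ht^2)
  dk <- dpre_c * r
  dpre_r <- (dpre_c * k) * r * (1 - r)
  dpre_u <- du * u * (1 - u)
  dS <- cbind(dpre_r, dpre_u, dpre_c)
  if (cache$hist) {
    g$Wxq <- g$Wxq + crossprod(dS, XQ)
  } else {
    g$Wxq[, 1:fu$n_in] <- g$Wxq[, 1:fu$n_in, drop = FALSE] +
      crossprod(dS, XQ)
  }
  g$bias <- g$bias + colSums(dS)
  if (zeroH) return(list(dHp = NULL, g = g))
  dFh <- cbind(dpre_r, dpre_u, dk)
  g$Wh <- g$Wh + crossprod(dFh, Hp)
  list(dHp = dh * u + dFh %*% fu$Wh, g = g)
}

# scatter fused gradient blocks back onto the named weight list
gru_unfuse_grads <- function(g, w) {
  H <- attr(w, "H"); n_in <- attr(w, "n_in")
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H)
  out <- zero_like(w)
  out$W_hr <- g$Wh[i1, , drop = FALSE]
  out$W_hu <- g$Wh[i2, , drop = FALSE]
  out$W_hht <- g$Wh[i3, , drop = FALSE]
  xc <- 1:n_in
  out$W_xr <- g$Wxq[i1, xc, drop = FALSE]
  out$W_xu <- g$Wxq[i2, xc, drop = FALSE]
  out$W_xht <- g$Wxq[i3, xc, drop = FALSE]
  out$W_qr <- g$Wxq[i1, n_in + 1, drop = FALSE]
  out$W_qu <- g$Wxq[i2, n_in + 1, drop = FALSE]
  out$W_qht <- g$Wxq[i3, n_in + 1, drop = FALSE]
  out$b_r <- g$bias[i1]; out$b_u <- g$bias[i2]; out$b_ht <- g$bias[i3]
  out$b_h <- g$b_h
  out$W_hq <- g$W_hq; out$b_q <- g$b_q
  out
}

rnn_cell_fwd <- function(Hp, X, Q, w) {
  pre <- X %*% t(w$W_xh) + rep(w$b_h, each = nrow(X))
  if (!is.null(Hp)) pre <- pre + Hp %*% t(w$W_hh)
  if (!is.null(Q)) pre <- pre + Q %*% t(w$W_qh)
  h <- tanh(pre)
  list(h = h, cache = list(Hp = Hp, X = X, Q = Q, h = h))
}

rnn_cell_bwd <- function(dh, cache, w, g) {
  dpre <- dh * (1 - cache$h^2)
  g$W_xh <- g$W_xh + crossprod(dpre, cache$X)
  g$b_h <- g$b_h + colSums(dpre)
  if (!is.null(cache$Q)) g$W_qh <- g$W_qh + crossprod(dpre, cache$Q)
  if (is.null(cache$Hp)) return(list(dHp = NULL, g = g))
  g$W_hh <- g$W_hh + crossprod(dpre, cache$Hp)
  list(dHp = dpre %*% w$W_hh, g = g)
}

# Batched forward over windows.  Xs: list of m+1 matrices (N x n_in), the
# last being the current step; Qs: list of m matrices (N x 1).  Returns
# predictions and per-step caches.
seq_forward <- function(Xs, Qs, w, h_init = NULL) {
  m <- length(Qs)
  stopifnot(length(Xs) == m + 1L)
  if (inherits(w, "gru_weights") && is.null(h_init)) {
    out <- .gru_seq_forward_cpp(Xs, Qs, w, attr_std(w))
    return(list(qhat = out$qhat, h = out$h, handle = out$handle,
                compiled = TRUE))
  }
  Hp <- h_init   # NULL encodes the zero initial hidden state
  caches <- vector("list", m + 1L)
  if (inherits(w, "gru_weights")) {
    fu <- gru_fuse(w)
    for (s in seq_len(m + 1L)) {
      hist <- s <= m
      XQ <- if (hist) cbind(Xs[[s]], Qs[[s]]) else Xs[[s]]
      step <- gru_cell_fwd(Hp, XQ, fu, w, hist)
      Hp <- step$h
      caches[[s]] <- step$cache
    }
    attr(caches, "fuse") <- fu
  } else {
    for (s in seq_len(m + 1L)) {
      step <- rnn_cell_fwd(Hp, Xs[[s]], if (s <= m) Qs[[s]] else NULL, w)
      Hp <- step$h
      caches[[s]] <- step$cache
    }
  }
  qhat <- drop(Hp %*% t(w$W_hq)) + w$b_q
  list(qhat = qhat, h = Hp, caches = caches)
}

zero_like <- function(w) {
  g <- lapply(w, function(x) if (is.matrix(x)) array(0, dim(x)) else x * 0)
  attributes(g) <- attributes(w)
  g
}

# Backward pass: dqhat is the N-vector of loss gradients w.r.t. predictions.
seq_backward <- function(dqhat, fwd_out, w) {
  if (isTRUE(fwd_out$compiled)) {
    return(.gru_seq_backward_cpp(dqhat, fwd_out$handle, w, attr_std(w)))
  }
  h_last <- fwd_out$h
  dh <- matrix(dqhat, ncol = 1) %*% w$W_hq
  if (inherits(w, "gru_weights")) {
    fu <- attr(fwd_out$caches, "fuse")
    H <- attr(w, "H"); n_in <- attr(w, "n_in")
    g <- list(Wh = matrix(0, 3 * H, H), Wxq = matrix(0, 3 * H, n_in + 1),
              bias = numeric(3 * H), b_h = numeric(H),
              W_hq = crossprod(matrix(dqhat, ncol = 1), h_last),
              b_q = sum(dqhat))
    for (s in rev(seq_along(fwd_out$caches))) {
      step <- gru_cell_bwd(dh, fwd_out$caches[[s]], fu, w, g)
      dh <- step$dHp
      g <- step$g
      if (is.null(dh)) break
    }
    gru_unfuse_grads(g, w)
  } else {
    g <- zero_like(w)
    g$W_hq <- crossprod(matrix(dqhat, ncol = 1), h_last)
    g$b_q <- sum(dqhat)
    for (s in rev(seq_along(fwd_out$caches))) {
      step <- rnn_cell_bwd(dh, fwd_out$caches[[s]], w, g)
      dh <- step$dHp
      g <- step$g
      if (is.null(dh)) break
    }
    g
  }
}

# ---- user-facing single-window evaluations ----------------------------------

#' Evaluate a GRU on one teacher-forced window
#'
#' History steps receive the inputs and the measured motion; the current
#' step receives the inputs only; the prediction is a linear read-out of
#' the final hidden state.
#'
#' @param window list with `x`, an `(m+1) x n_in` matrix of inputs ordered
#'   oldest first (last row = current step), and `q`, the `m` history
#'   motion values.
#' @param weights a [gru_weights()].
#' @param h_init initial hidden state (default zero).
#' @return List with the prediction `q_hat` and final hidden state `h`.
#' @export
gru_forward <- function(window, weights, h_init = NULL) {
  stopifnot(inherits(weights, "gru_weights"))
  x <- as.matrix(window$x)
  m <- length(window$q)
  if (nrow(x) != m + 1L) stop("window must have one more input row than history motions")
  check_shapes(weights, ncol(x))
  Xs <- lapply(seq_len(m + 1L), function(s) x[s, , drop = FALSE])
  Qs <- lapply(seq_len(m), function(s) matrix(window$q[s], 1, 1))
  hi <- if (is.null(h_init)) NULL else matrix(h_init, nrow = 1)
  out <- seq_forward(Xs, Qs, weights, hi)
  list(q_hat = unname(out$qhat), h = drop(out$h))
}

#' Evaluate a vanilla RNN on one teacher-forced window
#' @inheritParams gru_forward
#' @param weights an [rnn_weights()].
#' @return List with `q_hat` and `h`.
#' @export
rnn_forward <- function(window, weights, h_init = NULL) {
  stopifnot(inherits(weights, "rnn_weights"))
  x <- as.matrix(window$x)
  m <- length(window$q)
  if (nrow(x) != m + 1L) stop("window must have one more input row than history motions")
  check_shapes(weights, ncol(x))
  Xs <- lapply(seq_len(m + 1L), function(s) x[s, , drop = FALSE])
  Qs <- lapply(seq_len(m), function(s) matrix(window$q[s], 1, 1))
  hi <- if (is.null(h_init)) NULL else matrix(h_init, nrow = 1)
  out <- seq_forward(Xs, Qs, weights, hi)
  list(q_hat = unname(out$qhat), h = drop(out$h))
}

# ---- windows -----------------------------------------------------------------

#' Teacher-forcing windows from a trial
#'
#' One window per predictable step (`n - m` windows).  Gaussian noise with
#' standard deviation `noise_sigma` is added independently to every history
#' motion value (the prediction targets stay clean), the stochastic
#' augmentation that prepares the network for autoregressive test mode.
#'
#' @param x `n x n_in` input matrix (time + sEMG channels), one row per step.
#' @param q motion series of length `n`.
#' @param m history steps (`m < n`).
#' @param noise_sigma history-motion noise standard deviation.
#' @param seed optional integer seed making the draw reproducible.
#' @return List with `Xs` (list of `m+1` input matrices, `N x n_in`),
#'   `Qs` (list of `m` noisy history-motion column matrices), `target`
#'   (length `N`), and `steps`, the trial indices being predicted.
#' @export
make_windows <- function(x, q, m, noise_sigma = 0, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(q) == n)
  if (m >= n) stop("history length m must be smaller than the trial length")
  if (!is.null(seed)) set.seed(seed)
  N <- n - m
  steps <- (m + 1L):n
  Xs <- lapply(0:m, function(off) x[steps - m + off, , drop = FALSE])
  Qs <- lapply(0:(m - 1L), function(off) {
    qh <- q[steps - m + off]
    if (noise_sigma > 0) qh <- qh + stats::rnorm(N, 0, noise_sigma)
    matrix(qh, ncol = 1)
  })
  list(Xs = Xs, Qs = Qs, target = q[steps], steps = steps)
}

#' Autoregressive rollout
#'
#' Test-mode prediction: the first `m` motion values are the given seed;
#' every later step is predicted from the inputs and the model's own
#' previous predictions.  The hidden state is re-initialised to zero for
#' every window, matching the training protocol.
#'
#' @param weights [gru_weights()] or [rnn_weights()].
#' @param x `n x n_in` input matrix.
#' @param q_seed first `m` motion values.
#' @return The predicted motion series of length `n` (seed values first).
#' @export
rollout <- function(weights, x, q_seed) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- length(q_seed)
  stopifnot(m >= 1, m < n)
  q <- numeric(n)
  q[seq_len(m)] <- q_seed
  fwd <- if (inherits(weights, "gru_weights")) gru_forward else rnn_forward
  for (i in (m + 1L):n) {
    win <- list(x = x[(i - m):i, , drop = FALSE], q = q[(i - m):(i - 1L)])
    q[i] <- fwd(win, weights)$q_hat
    if (!is.finite(q[i])) stop(sprintf("rollout diverged at step %d", i))
  }
  q
}
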