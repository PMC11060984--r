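# Recurrent cells, teacher-forcing windows, autoregressive rollout.

# Independent per-equation transcription of the GRU recurrence, written
# directly from the gate equations with plain loops: reset and update
# gates (with motion input at history steps, without at the current one),
# candidate state via the reset-gated Hadamard term, and the hidden-state
# update h = u.h_prev + htilde - u.htilde + b_h.
oracle_gru <- function(x, qhist, w, h0 = NULL) {
  sg <- function(z) 1 / (1 + exp(-z))
  m <- length(qhist)
  H <- length(w$b_r)
  h <- if (is.null(h0)) rep(0, H) else h0
  for (s in seq_len(m + 1)) {
    xi <- x[s, ]
    hist <- s <= m
    pr <- w$W_hr %*% h + w$W_xr %*% xi + w$b_r
    pu <- w$W_hu %*% h + w$W_xu %*% xi + w$b_u
    pc_q <- 0
    if (hist) {
      pr <- pr + w$W_qr * qhist[s]
      pu <- pu + w$W_qu * qhist[s]
      pc_q <- w$W_qht * qhist[s]
    }
    r <- sg(pr); u <- sg(pu)
    z <- r * (w$W_hht %*% h)
    ht <- tanh(z + w$W_xht %*% xi + pc_q + w$b_ht)
    h <- as.numeric(u * h + ht - u * ht + w$b_h)
  }
  list(q_hat = as.numeric(w$W_hq %*% h + w$b_q), h = h)
}

oracle_rnn <- function(x, qhist, w, h0 = NULL) {
  m <- length(qhist)
  h <- if (is.null(h0)) rep(0, length(w$b_h)) else h0
  for (s in seq_len(m + 1)) {
    pre <- w$W_hh %*% h + w$W_xh %*% x[s, ] + w$b_h
    if (s <= m) pre <- pre + w$W_qh * qhist[s]
    h <- as.numeric(tanh(pre))
  }
  list(q_hat = as.numeric(w$W_hq %*% h + w$b_q), h = h)
}

test_that("GRU forward matches the per-equation oracle on random draws", {
  set.seed(1)
  worst <- 0
  for (rep in 1:100) {
    H <- sample(2:5, 1); n_in <- sample(2:4, 1); m <- sample(1:3, 1)
    w <- gru_weights(H, n_in, seed = rep)
    # random biases too (constructors start them at zero)
    for (nm in c("b_r", "b_u", "b_ht", "b_h")) w[[nm]] <- rnorm(H, sd = 0.3)
    w$b_q <- rnorm(1)
    x <- matrix(rnorm((m + 1) * n_in), m + 1)
    qh <- rnorm(m)
    got <- gru_forward(list(x = x, q = qh), w)
    want <- oracle_gru(x, qh, w)
    worst <- max(worst, abs(got$q_hat - want$q_hat), max(abs(got$h - want$h)))
  }
  expect_lt(worst, 1e-12)
})

test_that("RNN forward matches the per-equation oracle on random draws", {
  set.seed(2)
  worst <- 0
  for (rep in 1:100) {
    H <- sample(2:5, 1); n_in <- sample(2:4, 1); m <- sample(1:3, 1)
    w <- rnn_weights(H, n_in, seed = 1000 + rep)
    w$b_h <- rnorm(H, sd = 0.3); w$b_q <- rnorm(1)
    x <- matrix(rnorm((m + 1) * n_in), m + 1)
    qh <- rnorm(m)
    got <- rnn_forward(list(x = x, q = qh), w)
    want <- oracle_rnn(x, qh, w)
    worst <- max(worst, abs(got$q_hat - want$q_hat), max(abs(got$h - want$h)))
  }
  expect_lt(worst, 1e-12)
})

test_that("zero-parameter cells behave as traced by hand", {
  w <- gru_weights(4, 3, seed = 1)
  for (nm in names(w)) w[[nm]] <- w[[nm]] * 0
  out <- gru_forward(list(x = matrix(1, 3, 3), q = c(0.5, 0.7)), w)
  # all gates sigma(0) = 0.5, htilde = 0, h = 0.5 * 0 + 0 - 0 + 0 = 0
  expect_equal(out$h, rep(0, 4))
  expect_equal(out$q_hat, 0)
  wr <- rnn_weights(4, 3, seed = 1)
  for (nm in names(wr)) wr[[nm]] <- wr[[nm]] * 0
  wr$b_q <- 0.3
  out <- rnn_forward(list(x = matrix(1, 3, 3), q = c(0.5, 0.7)), wr)
  expect_equal(out$q_hat, 0.3)  # h = tanh(0) = 0, so q_hat = b_q
})

test_that("scalar RNN step is hand-computable and tanh saturates", {
  w <- rnn_weights(1, 1, seed = 1)
  w$W_hh[] <- 1; w$W_xh[] <- 1; w$W_qh[] <- 1; w$W_hq[] <- 1
  out <- rnn_forward(list(x = matrix(c(0.5, 0.5), 2, 1), q = 0.5), w)
  h1 <- tanh(0.5 + 0.5)
  expect_equal(out$q_hat, tanh(h1 + 0.5), tolerance = 1e-12)
  big <- rnn_forward(list(x = matrix(c(50, 50), 2, 1), q = 50), w)
  expect_equal(abs(big$h), 1, tolerance = 1e-10)
})

test_that("the extra hidden-state bias is dropped under standard_gru", {
  w <- gru_weights(3, 2, seed = 5)
  w$b_h <- c(0.2, -0.1, 0.4)
  win <- list(x = matrix(rnorm(6), 3, 2), q = c(0.1, 0.2))
  full <- gru_forward(win, w)$q_hat
  ws <- gru_weights(3, 2, seed = 5, standard_gru = TRUE)
  ws$b_h <- w$b_h
  std <- gru_forward(win, ws)$q_hat
  expect_false(isTRUE(all.equal(full, std)))
})

test_that("hidden state stays bounded when the extra bias is zero", {
  set.seed(9)
  w <- gru_weights(6, 3, seed = 77)  # b_h is zero at init
  h <- NULL
  x <- matrix(rnorm(300), 100, 3)
  win <- list(x = x[1:3, ], q = rnorm(2))
  for (i in 1:50) {
    out <- gru_forward(win, w, h_init = h)
    h <- out$h
    expect_true(all(abs(h) <= 1 + 1e-12))
  }
})

test_that("window construction counts, noise and determinism", {
  x <- cbind(t = seq(0, 1, length.out = 500), e = rnorm(500))
  q <- sin(seq(0, 1, length.out = 500))
  win <- make_windows(x, q, m = 2)
  expect_equal(length(win$target), 498)
  expect_equal(length(win$Xs), 3)
  expect_equal(length(win$Qs), 2)
  expect_equal(win$steps, 3:500)
  # noiseless history equals the recorded motion
  expect_equal(drop(win$Qs[[1]]), q[1:498])
  expect_equal(win$target, q[3:500])
  # seeded noise is reproducible and has the requested scale
  w1 <- make_windows(x, q, 2, noise_sigma = 0.05, seed = 3)
  w2 <- make_windows(x, q, 2, noise_sigma = 0.05, seed = 3)
  expect_identical(w1, w2)
  expect_equal(sd(w1$Qs[[1]] - win$Qs[[1]]), 0.05, tolerance = 0.15)
  expect_error(make_windows(x, q, 500), "history length")
})

test_that("rollout feeds back its own predictions", {
  # a model trained to output a constant ignores its inputs
  w <- gru_weights(3, 2, seed = 4)
  for (nm in setdiff(names(w), "b_q")) w[[nm]] <- w[[nm]] * 0
  w$b_q <- 0.42
  x <- matrix(rnorm(40), 20, 2)
  pred <- rollout(w, x, q_seed = c(0, 0))
  expect_equal(pred[3:20], rep(0.42, 18))
  # with teacher data injected at every step, rollout equals per-window passes
  w2 <- gru_weights(4, 2, seed = 6)
  q <- cumsum(rnorm(20)) / 10
  manual <- vapply(3:20, function(i)
    gru_forward(list(x = x[(i - 2):i, ], q = q[(i - 2):(i - 1)]), w2)$q_hat,
    numeric(1))
  # rollout on a 3-step trial reduces to a single window prediction
  one <- rollout(w2, x[1:3, ], q_seed = q[1:2])
  expect_equal(one[3], manual[1], tolerance = 1e-12)
})
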