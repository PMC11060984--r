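# Daubechies-2 multi-resolution projection of uniformly sampled signals.
#
# The coarse-scale representation is a full-length reconstruction with the
# detail coefficients zeroed (a projection, not a decimation), so every
# scale of a trial keeps the same number of time steps.  The transform uses
# periodised boundary handling, under which the analysis/synthesis pair is
# an orthonormal map and the scale projection is an exact orthogonal
# projector: projections are idempotent, nest exactly across scales, and
# never increase signal energy.

# db2 scaling (synthesis) filter; the wavelet filter is its quadrature mirror.
db2_g <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
db2_h <- c(db2_g[4], -db2_g[3], db2_g[2], -db2_g[1])

# one periodised analysis step: x (even length) -> list(cA, cD), each n/2
dwt_step <- function(x) {
  n <- length(x)
  half <- n / 2L
  idx <- (outer(2L * (seq_len(half) - 1L), 0:3, "+") - 1L) %% n + 1L  # half x 4
  xm <- matrix(x[idx], nrow = half)
  list(cA = drop(xm %*% db2_g), cD = drop(xm %*% db2_h))
}

# inverse of dwt_step: coefficients -> signal of length 2 * length(cA)
idwt_step <- function(cA, cD) {
  half <- length(cA)
  n <- 2L * half
  x <- numeric(n)
  pos <- (outer(2L * (seq_len(half) - 1L), 0:3, "+") - 1L) %% n + 1L
  for (k in 1:4) {
    x[pos[, k]] <- x[pos[, k]] + db2_g[k] * cA + db2_h[k] * cD
  }
  x
}

# pad odd-length signals by repeating the last sample
even_pad <- function(x) if (length(x) %% 2L == 1L) c(x, x[length(x)]) else x

#' Project a signal onto a coarse wavelet scale
#'
#' Decomposes `j` levels with the Daubechies-2 discrete wavelet transform,
#' zeroes all detail coefficients and reconstructs to the original length.
#' `j = 0` is the identity.  Signals whose length is divisible by `2^j`
#' are projected exactly (orthogonal projector); odd intermediate lengths
#' are handled by repeating the final sample for that level.
#'
#' @param signal numeric vector.
#' @param j number of decomposition levels (`>= 0`).
#' @return The scale `[-j]` approximation, same length as `signal`.
#' @export
wavelet_project <- function(signal, j) {
  stopifnot(j >= 0, j == round(j))
  if (j == 0) return(signal)
  n0 <- length(signal)
  a <- signal
  lens <- integer(j)
  for (lev in seq_len(j)) {
    if (length(a) < 4L) stop("insufficient samples for requested scale")
    lens[lev] <- length(a)
    a <- dwt_step(even_pad(a))$cA
  }
  for (lev in rev(seq_len(j))) {
    a <- idwt_step(a, numeric(length(a)))[seq_len(lens[lev])]
  }
  a[seq_len(n0)]
}

#' Wavelet detail between adjacent scales
#'
#' `H_b f = P_b f - P_{b+1} f` (with `P_0` the identity), the component of
#' the signal living between scales `[-b]` and `[-(b+1)]`.  Summing the
#' details over `b = 0 .. J-1` with the deepest approximation reconstructs
#' the signal exactly.
#'
#' @param signal numeric vector.
#' @param b level (`>= 0`).
#' @return Detail series, same length as `signal`.
#' @export
wavelet_detail <- function(signal, b) {
  wavelet_project(signal, b) - wavelet_project(signal, b + 1)
}

#' Multi-resolution decomposition of one signal
#'
#' @param signal numeric vector (scale `[0]`).
#' @param J deepest scale.
#' @return An object of class `mr_signal` with the base signal, the
#'   approximations at scales `-1 .. -J` and the inter-scale details.
#' @export
mr_signal <- function(signal, J) {
  stopifnot(J >= 1)
  approx <- lapply(seq_len(J), function(j) wavelet_project(signal, j))
  details <- lapply(seq_len(J), function(b) {
    if (b == 1) signal - approx[[1]] else approx[[b - 1]] - approx[[b]]
  })
  names(approx) <- names(details) <- as.character(-seq_len(J))
  structure(list(base = signal, approximations = approx, details = details,
                 J = J), class = "mr_signal")
}

#' Build the nested multi-resolution training dataset
#'
#' Projects every sEMG channel and the joint angle of each trial onto the
#' scales `0, -1, ..., -J` independently; the time column is never
#' filtered.  The scale-`[-j]` dataset is the wavelet projection of the
#' scale-`[-j+1]` dataset, giving the nested ladder used for
#' coarse-to-fine training.
#'
#' @param trials list of [trial()] objects sharing the same time grid.
#' @param J deepest scale (`>= 0`).
#' @return An object of class `mr_dataset`: `x$scales[["-j"]]` is the list
#'   of projected trials at scale `[-j]`.
#' @export
build_mr_dataset <- function(trials, J) {
  stopifnot(J >= 0, length(trials) >= 1)
  n <- trials[[1]]$n
  dt <- trials[[1]]$dt
  for (tr in trials) {
    if (!inherits(tr, "msk_trial")) stop("trials must be msk_trial objects")
    if (tr$n != n || abs(tr$dt - dt) > 1e-9)
      stop("all trials must share the same length and time step")
  }
  scales <- lapply(0:J, function(j) {
    lapply(trials, function(tr) {
      emg <- apply(tr$emg, 2, wavelet_project, j = j)
      colnames(emg) <- colnames(tr$emg)
      trial(tr$t, emg, wavelet_project(tr$q, j))
    })
  })
  names(scales) <- as.character(-(0:J))
  structure(list(scales = scales, J = J), class = "mr_dataset")
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("<mr_dataset> J = %d, %d trial(s), scales: %s\n", x$J,
              length(x$scales[[1]]), paste(names(x$scales), collapse = " ")))
  invisible(x)
}
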