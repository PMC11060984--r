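# Trial container and delimited-text I/O.

#' A movement trial
#'
#' One recording: a uniform time grid, per-muscle sEMG channels and the
#' elbow flexion angle.
#'
#' @param t strictly increasing, uniformly spaced times, s.
#' @param emg numeric matrix (or data frame) of sEMG channels, one column
#'   per muscle; columns `bi` and `tri` for the elbow model.
#' @param q joint angle series, rad.
#' @return An object of class `msk_trial` with fields `t`, `emg`, `q`, `n`
#'   and the step `dt`.
#' @export
trial <- function(t, emg, q) {
  emg <- as.matrix(emg)
  n <- length(t)
  stopifnot(n >= 2L, nrow(emg) == n, length(q) == n)
  dts <- diff(t)
  if (any(dts <= 0)) stop("time grid must be strictly increasing")
  dt <- dts[1]
  if (max(abs(dts - dt)) > 1e-9 * max(abs(dt), 1))
    stop("time grid must be uniform")
  structure(list(t = as.numeric(t), emg = emg, q = as.numeric(q),
                 n = n, dt = dt), class = "msk_trial")
}

#' @export
print.msk_trial <- function(x, ...) {
  cat(sprintf("<msk_trial> n = %d, dt = %g s, span = [%g, %g] s, %d sEMG channel(s)\n",
              x$n, x$dt, x$t[1], x$t[x$n], ncol(x$emg)))
  invisible(x)
}

#' Read / write trial files
#'
#' Trials are exchanged as comma-separated text with a header row and
#' columns `time, emg_bi, emg_tri, q` in SI units.
#'
#' @param path file path.
#' @return `read_trial()` returns an `msk_trial`; `write_trial()` returns
#'   `path` invisibly.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "emg_bi", "emg_tri", "q")
  if (!all(need %in% names(df)))
    stop("trial file must have columns time, emg_bi, emg_tri, q")
  trial(df$time, cbind(bi = df$emg_bi, tri = df$emg_tri), df$q)
}

#' @rdname read_trial
#' @param x an `msk_trial`.
#' @export
write_trial <- function(x, path) {
  stopifnot(inherits(x, "msk_trial"))
  df <- data.frame(time = x$t, emg_bi = x$emg[, "bi"],
                   emg_tri = x$emg[, "tri"], q = x$q)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
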