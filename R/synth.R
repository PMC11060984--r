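# Synthetic verification data: sinusoidal sEMG trials, Gaussian noise cases,
# and forward-dynamics ground-truth motions.

#' Noise case for the verification study
#'
#' Zero-mean Gaussian noise added to the unit-maximum sEMG signals; the
#' three cases use standard deviations of 10, 15 and 20 percent of the
#' signal maximum.
#'
#' @param case_id 1, 2 or 3.
#' @return List with `case_id`, `mu = 0` and `sigma`.
#' @export
noise_case <- function(case_id) {
  sigmas <- c(`1` = 0.1, `2` = 0.15, `3` = 0.2)
  key <- as.character(case_id)
  if (!key %in% names(sigmas)) stop("unknown noise case id (must be 1, 2 or 3)")
  list(case_id = as.integer(case_id), mu = 0, sigma = unname(sigmas[key]))
}

#' Synthetic-trial specification
#'
#' The five verification trials are periodic sinusoidal sEMG pairs with
#' unit maximum amplitude and strictly increasing frequencies across
#' trials.  Defaults: 500 samples over 10 s (dt = 0.02 s), frequencies
#' 1-2 Hz, triceps at 0.2 amplitude lagging the biceps by 0.5 rad.  The
#' frequencies sit above the passive pendulum resonance (~0.5 Hz) and the
#' partially co-contracting antagonists keep the net joint torque at the
#' gravity scale, so the solved motions remain inside the anatomical
#' range for every trial and noise case; the phase lag decorrelates the
#' two muscles' torque contributions so both are identifiable.  See the
#' methods vignette for the reasoning behind these choices.
#'
#' @param n samples per trial.
#' @param duration trial length, s.
#' @param freqs per-trial frequencies, Hz.
#' @param amp_bi,amp_tri half-amplitudes of the two channels; channel k is
#'   `amp * (1 + sin(...))`, so the biceps default 0.5 gives maximum 1.
#' @param phase_tri triceps phase offset, rad.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n = 500, duration = 10,
                       freqs = c(1.0, 1.25, 1.5, 1.75, 2.0),
                       amp_bi = 0.5, amp_tri = 0.2, phase_tri = 0.5) {
  stopifnot(n > 1, duration > 0, all(freqs > 0), !is.unsorted(freqs),
            amp_bi > 0, amp_tri > 0)
  structure(list(n = n, duration = duration, freqs = freqs,
                 amp_bi = amp_bi, amp_tri = amp_tri, phase_tri = phase_tri,
                 t = (seq_len(n) - 1) * (duration / n)),
            class = "synth_spec")
}

#' Noiseless synthetic sEMG for one trial
#'
#' `e_bi(t) = amp_bi (1 + sin(2 pi f_k t))` and
#' `e_tri(t) = amp_tri (1 + sin(2 pi f_k t + phase_tri))`; with the
#' defaults both signals live in `[0, 1]` and the signal maximum is
#' exactly 1.  This waveform family is deliberately isolated here so it
#' can be swapped out wholesale.
#'
#' @param trial_k trial index 1..5 (selects the frequency).
#' @param spec [synth_spec()].
#' @return Matrix with columns `bi`, `tri` on the specification's time grid.
#' @export
synth_emg <- function(trial_k, spec = synth_spec()) {
  stopifnot(trial_k %in% seq_along(spec$freqs))
  f <- spec$freqs[trial_k]
  cbind(bi = spec$amp_bi * (1 + sin(2 * pi * f * spec$t)),
        tri = spec$amp_tri * (1 + sin(2 * pi * f * spec$t + spec$phase_tri)))
}

#' Add Gaussian measurement noise to sEMG channels
#'
#' i.i.d. `N(0, sigma^2)` per sample per channel.  No clipping is applied
#' here; excitation clipping happens downstream in [activation()].
#'
#' @param signals numeric matrix of sEMG channels.
#' @param case a [noise_case()] (or any list with `mu`, `sigma`).
#' @param seed integer seed for reproducibility, or `NULL` to use the
#'   current RNG state.
#' @return Matrix of the same shape.
#' @export
apply_noise <- function(signals, case, seed = NULL) {
  signals <- as.matrix(signals)
  if (!is.null(seed)) set.seed(seed)
  if (case$sigma == 0) return(signals)
  signals + matrix(stats::rnorm(length(signals), case$mu, case$sigma),
                   nrow = nrow(signals), dimnames = dimnames(signals))
}

#' Generate the five-trial verification set
#'
#' For each trial: draw the noisy sEMG, then solve the forward dynamics
#' from `q(0) = pi/6`, `qdot(0) = 0` with the noisy signals as input, so
#' the ground-truth motion satisfies the equation of motion for exactly
#' the inputs the learner will see.
#'
#' @param case a [noise_case()].
#' @param spec [synth_spec()].
#' @param model [elbow_model()].
#' @param seed integer seed controlling the noise draws.
#' @param q0,qdot0 initial conditions.
#' @return List of five [trial()] objects.
#' @export
generate_verification_set <- function(case = noise_case(1),
                                      spec = synth_spec(),
                                      model = elbow_model(),
                                      seed = 1L, q0 = pi / 6, qdot0 = 0) {
  set.seed(seed)
  lapply(seq_along(spec$freqs), function(k) {
    emg <- apply_noise(synth_emg(k, spec), case)
    simulate_motion(emg, model, q0 = q0, qdot0 = qdot0, t_grid = spec$t)
  })
}
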