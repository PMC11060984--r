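# End-to-end verification experiment: multi-seed, multi-depth training with
# aggregated metrics and parameter-identification summaries.

#' Experiment configuration
#'
#' @param trials list of five [trial()] objects (the verification set).
#' @param model [elbow_model()] providing geometry, activation dynamics and
#'   the nominal muscle constants (the identification truth in synthetic
#'   studies).
#' @param depths scale depths to compare; depth `d` trains on scales
#'   `[-(d-1)] .. [0]`.
#' @param seeds parameter-initialisation seeds.
#' @param train_idx,test_idx trial split.
#' @param epochs epochs per scale.
#' @param lr Adam learning rate.
#' @param m history steps.
#' @param hidden hidden width of the GRU.
#' @param beta residual penalty weight.
#' @param noise_sigma teacher-forcing noise sd (standardized units).
#' @param gamma0_spread relative half-width of the uniform draw of the
#'   parameter initialisation around the model's nominal values.
#' @param cell `"gru"` or `"rnn"`.
#' @return A validated config list of class `experiment_config`.
#' @export
experiment_config <- function(trials, model = elbow_model(),
                              depths = c(1, 2, 3), seeds = 1:5,
                              train_idx = c(1, 2, 4, 5), test_idx = 3,
                              epochs = 300, lr = 1e-3, m = 2, hidden = 50,
                              beta = 1e-3, noise_sigma = 0.003,
                              gamma0_spread = 0.2, cell = c("gru", "rnn")) {
  cell <- match.arg(cell)
  if (!length(trials) || !all(vapply(trials, inherits, TRUE, "msk_trial")))
    stop("config error: trials must be a non-empty list of msk_trial objects")
  idx <- c(train_idx, test_idx)
  if (any(idx < 1 | idx > length(trials)) || length(test_idx) != 1)
    stop("config error: invalid train/test split")
  if (any(depths < 1) || !length(seeds))
    stop("config error: depths must be >= 1 and seeds non-empty")
  stopifnot(epochs > 0, lr > 0, m >= 1, hidden >= 1, beta >= 0,
            gamma0_spread >= 0, gamma0_spread < 1)
  structure(list(trials = trials, model = model, depths = sort(depths),
                 seeds = seeds, train_idx = train_idx, test_idx = test_idx,
                 epochs = epochs, lr = lr, m = m, hidden = hidden,
                 beta = beta, noise_sigma = noise_sigma,
                 gamma0_spread = gamma0_spread, cell = cell),
            class = "experiment_config")
}

truth_params <- function(model) {
  c(f0_Bi = model$biceps$f0M, l0_Bi = model$biceps$l0M,
    f0_Tri = model$triceps$f0M, l0_Tri = model$triceps$l0M)
}

#' Run the verification experiment
#'
#' For every seed and every requested scale depth: build the wavelet
#' ladder of the training trials, run coarse-to-fine physics-informed
#' training, evaluate by autoregressive rollout on the held-out test
#' trial, and record the identified parameters.  Each seed controls the
#' network initialisation, the parameter-initialisation draw and the
#' teacher-forcing noise.
#'
#' @param config an [experiment_config()].
#' @return List of class `experiment_results` with the per-run data frame
#'   `runs`, aggregate tables from [report()], and the resolved config.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  model <- config$model
  truth <- truth_params(model)
  Jmax <- max(config$depths) - 1L
  mr_train_data <- build_mr_dataset(config$trials[config$train_idx], Jmax)
  test_trial <- config$trials[[config$test_idx]]
  cfg <- loss_config(beta = config$beta,
                     stats = standardization_stats(
                       mr_train_data$scales[["0"]], model))
  n_in <- 1L + ncol(test_trial$emg)
  rows <- list()
  for (s in config$seeds) {
    w0 <- if (config$cell == "gru")
      gru_weights(config$hidden, n_in, seed = s)
    else rnn_weights(config$hidden, n_in, seed = s)
    set.seed(s + 104729L)   # independent draw for the parameter init
    Gamma0 <- truth * stats::runif(4, 1 - config$gamma0_spread,
                                   1 + config$gamma0_spread)
    for (d in config$depths) {
      schedule <- training_schedule(scales = (-(d - 1L)):0L,
                                    epochs_per_scale = config$epochs,
                                    lr = config$lr, m = config$m,
                                    noise_sigma = config$noise_sigma)
      fit <- mr_train(mr_train_data, schedule, model, cfg, w0,
                      identified_params(Gamma0), seed = s)
      ev <- evaluate(fit$weights, test_trial, cfg, m = config$m,
                     model = model)
      Gam <- fit$Gamma
      perr <- 100 * (Gam - truth) / truth
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, depth = d, mse = ev$mse, r2 = ev$r2, nmse = ev$nmse,
        f0_Bi = Gam[["f0_Bi"]], l0_Bi = Gam[["l0_Bi"]],
        f0_Tri = Gam[["f0_Tri"]], l0_Tri = Gam[["l0_Tri"]],
        err_f0_Bi = perr[["f0_Bi"]], err_l0_Bi = perr[["l0_Bi"]],
        err_f0_Tri = perr[["f0_Tri"]], err_l0_Tri = perr[["l0_Tri"]])
    }
  }
  runs <- do.call(rbind, rows)
  structure(list(runs = runs, tables = report(runs), truth = truth,
                 config = config), class = "experiment_results")
}

#' Aggregate experiment tables
#'
#' Per-depth mean and standard deviation of the test metrics (with the
#' percentage change relative to 1-scale training when available) and the
#' per-parameter identification errors at the deepest training.
#'
#' @param runs per-run data frame as produced by [run_experiment()].
#' @return List with data frames `metrics` and `param_errors`.
#' @export
report <- function(runs) {
  if (!nrow(runs)) {
    return(list(metrics = data.frame(depth = integer(), mse_mean = numeric(),
                                     mse_sd = numeric(), r2_mean = numeric(),
                                     r2_sd = numeric(), nmse_mean = numeric()),
                param_errors = data.frame(parameter = character(),
                                          err_mean = numeric(),
                                          err_sd = numeric())))
  }
  ag <- function(col, f) tapply(runs[[col]], runs$depth, f)
  metrics <- data.frame(depth = as.integer(names(ag("mse", mean))),
                        mse_mean = as.numeric(ag("mse", mean)),
                        mse_sd = as.numeric(ag("mse", stats::sd)),
                        r2_mean = as.numeric(ag("r2", mean)),
                        r2_sd = as.numeric(ag("r2", stats::sd)),
                        nmse_mean = as.numeric(ag("nmse", mean)))
  if (1 %in% metrics$depth) {
    base <- metrics[metrics$depth == 1, ]
    metrics$mse_change_pct <- 100 * (metrics$mse_mean - base$mse_mean) /
      base$mse_mean
    metrics$r2_change_pct <- 100 * (metrics$r2_mean - base$r2_mean) /
      abs(base$r2_mean)
  }
  deepest <- runs[runs$depth == max(runs$depth), ]
  pe <- vapply(c("err_f0_Bi", "err_l0_Bi", "err_f0_Tri", "err_l0_Tri"),
               function(cn) c(mean(deepest[[cn]]), stats::sd(deepest[[cn]])),
               numeric(2))
  param_errors <- data.frame(parameter = sub("^err_", "", colnames(pe)),
                             err_mean = pe[1, ], err_sd = pe[2, ],
                             row.names = NULL)
  list(metrics = metrics, param_errors = param_errors)
}

#' Write experiment outputs
#'
#' Writes the per-run table, the aggregate tables and a self-describing
#' JSON summary (resolved settings, seeds, package version) to a
#' directory.
#'
#' @param results an `experiment_results` object.
#' @param dir output directory (created if needed).
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$runs, file.path(dir, "runs.csv"),
                   row.names = FALSE)
  utils::write.csv(results$tables$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(results$tables$param_errors,
                   file.path(dir, "param_errors.csv"), row.names = FALSE)
  cf <- results$config
  summary <- list(
    package_version = as.character(utils::packageVersion("mrpinn")),
    depths = cf$depths, seeds = cf$seeds, epochs = cf$epochs,
    lr = cf$lr, m = cf$m, hidden = cf$hidden, beta = cf$beta,
    noise_sigma = cf$noise_sigma, gamma0_spread = cf$gamma0_spread,
    cell = cf$cell, train_idx = cf$train_idx, test_idx = cf$test_idx,
    truth = as.list(results$truth))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
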