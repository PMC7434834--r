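#' Run the full heterogeneity experiment
#'
#' Orchestrates the whole pipeline: dataset generation, the heterogeneity
#' sweep, mental-simulation judgment, overfitting metrics, weight and PB-map
#' summaries, and simulated real-time interaction trials with flexibility
#' and generalization judgments.  Every stage's seed derives from
#' `seed`, so the bundle is reproducible from its arguments alone.
#'
#' @param spec an [sequence_spec()]; defaults to the desk-scale sequences
#'   (40-step cycles, 5 cycles).
#' @param config template [sctrnnpb_config()]; defaults to [desk_config()].
#' @param k_values heterogeneity conditions.
#' @param n_replicates replicates per condition (scalar or vector along
#'   `k_values`).
#' @param n_train,n_test sequences per behavior and split.
#' @param seed master seed.
#' @param n_trials interaction trials per model (alternating initial
#'   behavior).
#' @param trial_k k conditions that receive interaction trials (default:
#'   all; trials dominate runtime, so narrow this for quick looks).
#' @param switch_step,trial_length interaction-phase settings.
#' @param trial_jitter maximum absolute phase jitter (steps) drawn per
#'   trial.
#' @param map_resolution PB error-map grid nodes per axis (0 skips maps).
#' @return an object of class `"spb_experiment"`: list with the `dataset`,
#'   the `sweep`, `xi`, per-model `results` (data frame) and `maps`.
#' @export
run_experiment <- function(spec = sequence_spec(cycle_length = 40,
                                                n_cycles = 5),
                           config = desk_config(),
                           k_values = c(0.1, 1, 10, 100),
                           n_replicates = 4, n_train = 2, n_test = 2,
                           seed = 1, n_trials = 6, trial_k = k_values,
                           switch_step = 120, trial_length = 300,
                           trial_jitter = 3, map_resolution = 21) {
  if (length(k_values) == 0) stop_field("k_values", "must be non-empty")
  dataset <- build_dataset(spec, n_train = n_train, n_test = n_test,
                           seed = derive_seed(seed, 1))
  plan <- experiment_plan(k_values = k_values, n_replicates = n_replicates,
                          config = config, seed = derive_seed(seed, 2))
  sweep <- train_sweep(dataset, plan)
  xi <- success_threshold(dataset)
  maps <- list()
  rows <- list()
  for (id in names(sweep$fits)) {
    fit <- sweep$fits[[id]]
    mrow <- sweep$manifest[sweep$manifest$id == id, ]
    om <- overfitting_metrics(fit)
    ms <- judge_mental_simulation(fit, xi = xi)
    ws <- weight_distribution_stats(fit)
    area <- dist_pb <- NA_real_
    if (map_resolution >= 11) {
      ml <- pb_error_map(fit, "left", resolution = map_resolution)
      mr <- pb_error_map(fit, "right", resolution = map_resolution)
      maps[[id]] <- list(left = ml, right = mr)
      area <- mean(c(ml$area_fraction, mr$area_fraction))
      dist_pb <- pb_map_distance(ml, mr)
    }
    flex <- gener <- NA_real_
    if (mrow$k %in% trial_k && n_trials > 0) {
      res_f <- res_g <- logical(0)
      for (tr in seq_len(n_trials)) {
        b0 <- if (tr %% 2 == 1) "right" else "left"
        tseed <- derive_seed(seed, 50000 + 100 * match(id,
                                                       names(sweep$fits)) + tr)
        jit <- with_seed(tseed, sample.int(2L * trial_jitter + 1L, 1L) -
                           trial_jitter - 1L)
        env <- interaction_env(spec, initial_situation = b0,
                               switch_step = switch_step,
                               trial_length = trial_length, jitter = jit,
                               seed = tseed)
        trial <- interaction_trial(fit, env)
        res_f <- c(res_f, isTRUE(judge_flexibility(trial, fit, xi = xi)))
        res_g <- c(res_g, isTRUE(judge_generalization(trial, fit, xi = xi)))
      }
      flex <- mean(res_f)
      gener <- mean(res_g)
    }
    rows[[id]] <- data.frame(
      id = id, k = mrow$k, replicate = mrow$replicate,
      converged = mrow$converged,
      train_error = om$train_error, test_error = om$test_error,
      train_variance = om$train_variance, test_variance = om$test_variance,
      mental_sim_rate = ms$rate, flexibility_rate = flex,
      generalization_rate = gener, weight_sd = ws$sd,
      weight_frac_weak = ws$frac_weak, pb_area = area,
      pb_distance = dist_pb)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(dataset = dataset, sweep = sweep, xi = xi,
                 results = results, maps = maps, seed = seed),
            class = "spb_experiment")
}

#' Condition-level summary of an experiment
#'
#' Means and standard deviations per heterogeneity condition k of the
#' per-model metrics, over converged runs; failed or non-convergent runs are
#' counted separately.
#'
#' @param experiment an [run_experiment()] bundle (or its `results` data
#'   frame).
#' @return data frame, one row per k.
#' @export
summarize_experiment <- function(experiment) {
  res <- if (inherits(experiment, "spb_experiment")) experiment$results
         else experiment
  metrics <- c("train_error", "test_error", "train_variance",
               "test_variance", "mental_sim_rate", "flexibility_rate",
               "generalization_rate", "weight_sd", "weight_frac_weak",
               "pb_area", "pb_distance")
  out <- lapply(split(res, res$k), function(g) {
    conv <- g[g$converged, , drop = FALSE]
    row <- data.frame(k = g$k[1], n = nrow(g), n_converged = nrow(conv))
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(conv[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- if (nrow(conv) < 2) 0
                                 else sd(conv[[m]], na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, out)
  out[order(out$k), ]
}

#' @export
print.spb_experiment <- function(x, ...) {
  cat(sprintf("Heterogeneity experiment: %d models, xi = %.3f\n",
              nrow(x$results), x$xi))
  s <- summarize_experiment(x)
  cols <- c("k", "n_converged", "train_error_mean", "test_error_mean",
            "train_variance_mean", "mental_sim_rate_mean",
            "flexibility_rate_mean", "generalization_rate_mean")
  print(s[, intersect(cols, names(s))], row.names = FALSE, digits = 3)
  invisible(x)
}
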