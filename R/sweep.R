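#' Plan a heterogeneity sweep
#'
#' Describes the learning experiment: for each context-bias variance `k`,
#' train `n_replicates` networks (differing only in their parameter
#' initialization seed, hence in initial synaptic weights and context-bias
#' draws) on a shared dataset.
#'
#' @param k_values heterogeneity conditions (default `c(0.1, 1, 10, 100)`;
#'   values of 10 and above are the heterogeneous regime, 1 and below the
#'   homogeneous one).
#' @param n_replicates replicates per condition; a scalar or a vector
#'   recycled along `k_values`.
#' @param config template [sctrnnpb_config()] (its `k` is overridden per
#'   condition).
#' @param seed master seed from which every replicate's init seed derives.
#' @return an object of class `"spb_plan"`.
#' @export
experiment_plan <- function(k_values = c(0.1, 1, 10, 100), n_replicates = 8,
                            config = desk_config(), seed = 1) {
  if (length(k_values) == 0) stop_field("k_values", "must be non-empty")
  if (any(k_values < 0)) stop_field("k_values", "must be >= 0")
  if (any(n_replicates < 1)) stop_field("n_replicates", "must be >= 1")
  n_replicates <- rep_len(as.integer(n_replicates), length(k_values))
  structure(list(k_values = k_values, n_replicates = n_replicates,
                 config = config, seed = seed),
            class = "spb_plan")
}

#' Train a sweep of networks across heterogeneity conditions
#'
#' Trains every (k, replicate) cell of the plan on the same dataset.
#' Individual failures (e.g. divergence) are recorded and the sweep
#' continues.  A run is flagged as non-convergent when its mean squared
#' training error exceeds 10 times the median over the k = 10 runs (or over
#' all runs when k = 10 is not part of the plan) -- the operational reading
#' of "could not successfully learn".
#'
#' @param dataset an [build_dataset()] object.
#' @param plan an [experiment_plan()].
#' @param thin loss-trace thinning passed to [sctrnnpb()].
#' @return an object of class `"sctrnnpb_sweep"`: list with `fits` (named
#'   list of `"sctrnnpb"` fits), `manifest` (data frame with k, replicate,
#'   seed, final loss, training MSE, convergence flag) and the `plan`.
#' @export
train_sweep <- function(dataset, plan, thin = 100) {
  stopifnot(inherits(dataset, "spb_dataset"), inherits(plan, "spb_plan"))
  fits <- list()
  rows <- list()
  for (ki in seq_along(plan$k_values)) {
    k <- plan$k_values[ki]
    for (r in seq_len(plan$n_replicates[ki])) {
      id <- sprintf("k%s_r%d", format(k), r)
      init_seed <- derive_seed(plan$seed, 1000 * ki + r)
      cfg <- plan$config
      cfg$k <- k
      fit <- tryCatch(sctrnnpb(dataset, cfg, seed = init_seed, thin = thin),
                      error = function(e) e)
      ok <- inherits(fit, "sctrnnpb")
      mse <- NA_real_
      if (ok) {
        fits[[id]] <- fit
        mse <- overfitting_metrics(fit)$train_error
      }
      rows[[id]] <- data.frame(
        id = id, k = k, replicate = r, seed = init_seed,
        final_loss = if (ok) fit$final_loss else NA_real_,
        train_mse = mse, failed = !ok,
        error = if (ok) "" else conditionMessage(fit))
    }
  }
  manifest <- do.call(rbind, rows)
  ref <- manifest$train_mse[!manifest$failed &
                              abs(manifest$k - 10) < 1e-12]
  if (length(ref) == 0) ref <- manifest$train_mse[!manifest$failed]
  manifest$converged <- !manifest$failed &
    manifest$train_mse <= 10 * stats::median(ref)
  rownames(manifest) <- NULL
  structure(list(fits = fits, manifest = manifest, plan = plan,
                 dataset = dataset),
            class = "sctrnnpb_sweep")
}

#' @export
print.sctrnnpb_sweep <- function(x, ...) {
  cat(sprintf("S-CTRNNPB heterogeneity sweep: %d runs (%d converged)\n",
              nrow(x$manifest), sum(x$manifest$converged)))
  print(x$manifest[, c("id", "k", "replicate", "final_loss", "train_mse",
                       "converged")])
  invisible(x)
}

#' Fits of one heterogeneity condition
#'
#' @param sweep an `"sctrnnpb_sweep"`.
#' @param k condition value.
#' @param converged_only drop runs flagged non-convergent.
#' @return named list of fits.
#' @export
sweep_fits <- function(sweep, k, converged_only = TRUE) {
  m <- sweep$manifest
  keep <- !m$failed & abs(m$k - k) < 1e-12
  if (converged_only) keep <- keep & m$converged
  sweep$fits[m$id[keep]]
}
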