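# Shared fixtures.  The desk-scale experiment (the study conditions: 40-step
# cycles, 5 cycles, 2+2 sequences per behavior, 30 context neurons, 40,000
# epochs, k in {0.1, 1, 10, 100}) is trained once per test run and reused by
# every test that needs trained networks.

desk_spec <- function(...) {
  args <- utils::modifyList(list(cycle_length = 40, n_cycles = 5), list(...))
  do.call(sequence_spec, args)
}

desk_dataset <- function(seed = 1, ...) build_dataset(desk_spec(), n_train = 2,
                                                      n_test = 2, seed = seed,
                                                      ...)

# a tiny network + short random sequences for oracle-level tests
tiny_setup <- function(n_input = 3, n_context = 4, n_pb = 2, T_ = 5, S = 2,
                       seed = 42) {
  cfg <- sctrnnpb_config(n_input = n_input, n_context = n_context,
                         n_pb = n_pb, k = 1, n_epochs = 10)
  params <- init_network(cfg, n_sequences = S, seed = seed)
  seqs <- with_seed(seed + 1, lapply(seq_len(S), function(s)
    matrix(runif(T_ * n_input, -0.5, 0.5), T_, n_input)))
  u0 <- with_seed(seed + 2, matrix(runif(n_pb * S, -0.3, 0.3), n_pb, S))
  list(cfg = cfg, params = params, seqs = seqs, u0 = u0)
}

with_seed <- sctrnnpb:::with_seed

# all-zero-weight parameters: y = 0, v = 1 everywhere
zero_params <- function(n_input = 2, n_context = 3, n_pb = 2, tau = 4,
                        b_c = rep(0, n_context)) {
  structure(list(W_xc = matrix(0, n_context, n_input),
                 W_cc = matrix(0, n_context, n_context),
                 W_pc = matrix(0, n_context, n_pb),
                 W_cm = matrix(0, n_input, n_context),
                 W_cv = matrix(0, n_input, n_context),
                 b_c = b_c, b_m = rep(0, n_input), b_v = rep(0, n_input),
                 tau = rep(tau, n_context),
                 u0_pb = matrix(0, n_pb, 1)),
            class = "sctrnnpb_params")
}

# R-side reference of the windowed PB loss (closed-loop regeneration via
# forward_step), used as the independent oracle for the adaptation gradient
window_loss_R <- function(params, u_pb, u_anchor, x_anchor, obs, dims) {
  W <- nrow(obs) + 1
  state <- list(u_context = u_anchor, u_pb = u_pb)
  x <- x_anchor
  loss <- 0
  for (j in seq_len(W)) {
    state <- forward_step(params, state, x)
    if (j < W) {
      e <- obs[j, dims] - state$y[dims]
      v <- state$v[dims]
      loss <- loss + sum(0.5 * log(2 * pi * v) + e^2 / (2 * v))
    }
    x <- state$y
  }
  loss
}

# cached desk-scale experiment -----------------------------------------------
the <- new.env(parent = emptyenv())

desk_experiment <- function() {
  if (is.null(the$experiment)) {
    the$experiment <- run_experiment(
      spec = desk_spec(), config = desk_config(),
      k_values = c(0.1, 1, 10, 100), n_replicates = c(4, 2, 4, 2),
      n_train = 2, n_test = 2, seed = 1, n_trials = 6,
      trial_k = c(0.1, 10), map_resolution = 21)
  }
  the$experiment
}

# condition means over converged runs
condition_mean <- function(results, k, col) {
  g <- results[results$k == k & results$converged, col]
  mean(g, na.rm = TRUE)
}

# the best-converged fit of one condition (lowest training MSE)
best_fit <- function(sweep, k) {
  m <- sweep$manifest
  m <- m[!m$failed & m$converged & abs(m$k - k) < 1e-12, ]
  sweep$fits[[m$id[which.min(m$train_mse)]]]
}
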