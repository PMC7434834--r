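#' S-CTRNNPB model configuration
#'
#' Collects the architectural and optimization hyperparameters of the
#' network.  Full-scale defaults: 10 input/mean/variance neurons, 100 context
#' neurons with time constant 4, 2 parametric-bias (PB) neurons, learning
#' rate 1e-4, momentum 0.9, 300,000 training epochs, and real-time
#' adaptation with a sliding window of 10 steps and 50 PB updates per step.
#' `k` is the variance of the Gaussian from which the fixed context-neuron
#' biases (intrinsic excitabilities) are drawn; `bias_mean` shifts their
#' common mean (the mean-excitability control).
#'
#' @param n_input number of input neurons (= mean = variance neurons).
#' @param n_context number of context neurons.
#' @param n_pb number of PB neurons.
#' @param tau context time constant (>= 1; shared by all context neurons).
#' @param alpha learning rate of the momentum gradient descent.
#' @param eta momentum coefficient in `[0, 1)`.
#' @param bias_mean mean of the context-bias distribution.
#' @param k variance of the context-bias distribution (heterogeneity of
#'   intrinsic excitability); `k = 0` makes all context biases equal
#'   `bias_mean`.
#' @param n_epochs number of full-batch training updates.
#' @param window sliding-window length W for real-time PB adaptation.
#' @param pb_updates_per_step PB updates per interaction time step.
#' @return an object of class `"sctrnnpb_config"`.
#' @seealso [desk_config()] for the reduced-scale defaults used throughout
#'   the examples and tests.
#' @export
sctrnnpb_config <- function(n_input = 10, n_context = 100, n_pb = 2,
                            tau = 4, alpha = 1e-4, eta = 0.9,
                            bias_mean = 0, k = 10, n_epochs = 300000,
                            window = 10, pb_updates_per_step = 50) {
  check_scalar_num(n_input, "n_input", lower = 1)
  check_scalar_num(n_context, "n_context", lower = 1)
  check_scalar_num(n_pb, "n_pb", lower = 1)
  check_scalar_num(tau, "tau", lower = 1)
  check_scalar_num(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_scalar_num(eta, "eta", lower = 0, upper = 1 - 1e-12)
  check_scalar_num(bias_mean, "bias_mean")
  check_scalar_num(k, "k", lower = 0)
  check_scalar_num(n_epochs, "n_epochs", lower = 1)
  check_scalar_num(window, "window", lower = 2)
  check_scalar_num(pb_updates_per_step, "pb_updates_per_step", lower = 1)
  structure(list(n_input = as.integer(n_input),
                 n_context = as.integer(n_context),
                 n_pb = as.integer(n_pb), tau = tau, alpha = alpha,
                 eta = eta, bias_mean = bias_mean, k = k,
                 n_epochs = as.integer(n_epochs),
                 window = as.integer(window),
                 pb_updates_per_step = as.integer(pb_updates_per_step)),
            class = "sctrnnpb_config")
}

#' Reduced-scale configuration
#'
#' Convenience wrapper around [sctrnnpb_config()] with the desk-scale
#' defaults used by the examples and tests: 30 context neurons and 40,000
#' epochs (paired with 40-step cycles and 5 cycles per sequence on the data
#' side), preserving the time-scale ratio between sequence length and the
#' context time constant while keeping a full heterogeneity sweep within
#' minutes on one CPU.  The learning rate is lowered to 2e-6: the loss is an
#' unaveraged sum over sequences, steps and channels, so the stable step
#' size shrinks with the batch, and the full-scale rate makes the
#' variance pathway oscillate at this scale; the epoch count is doubled
#' relative to half the full-scale budget so that the homogeneous regime
#' trains long enough to overfit the sensory noise (see the methods
#' vignette).
#'
#' @param ... overrides passed to [sctrnnpb_config()].
#' @export
desk_config <- function(...) {
  args <- list(...)
  defaults <- list(n_context = 30, n_epochs = 40000, alpha = 2e-6)
  do.call(sctrnnpb_config, utils::modifyList(defaults, args))
}

#' @export
print.sctrnnpb_config <- function(x, ...) {
  cat(sprintf(
    "S-CTRNNPB config: %d inputs, %d context (tau %.3g), %d PB; k = %.3g, bias mean %.3g\n",
    x$n_input, x$n_context, x$tau, x$n_pb, x$k, x$bias_mean))
  cat(sprintf("  alpha %.3g, eta %.2g, %d epochs; window W = %d, %d PB updates/step\n",
              x$alpha, x$eta, x$n_epochs, x$window, x$pb_updates_per_step))
  invisible(x)
}

#' Initialize network parameters
#'
#' Synaptic weights are drawn uniformly on intervals set by the size of the
#' source layer: `[-1/sqrt(n_input), 1/sqrt(n_input)]` for input-to-context
#' weights and `[-1/sqrt(n_context), 1/sqrt(n_context)]` for recurrent,
#' PB-to-context and output weights.  Mean/variance biases are uniform on
#' `[-1, 1]`.  Context biases -- the intrinsic excitabilities -- are drawn
#' once from `N(bias_mean, k)` and are never updated afterwards.  PB internal
#' states start at 0 for every sequence.
#'
#' @param config an [sctrnnpb_config()].
#' @param n_sequences number of training sequences (one PB initial state
#'   each).
#' @param seed seed; the result is a pure function of `(config, n_sequences,
#'   seed)`.
#' @return an object of class `"sctrnnpb_params"`.
#' @export
init_network <- function(config, n_sequences = 1, seed = 1) {
  stopifnot(inherits(config, "sctrnnpb_config"))
  nc <- config$n_context; ni <- config$n_input; np <- config$n_pb
  bi <- 1 / sqrt(ni); bc <- 1 / sqrt(nc)
  with_seed(seed, {
    params <- list(
      W_xc = matrix(runif(nc * ni, -bi, bi), nc, ni),
      W_cc = matrix(runif(nc * nc, -bc, bc), nc, nc),
      W_pc = matrix(runif(nc * np, -bc, bc), nc, np),
      W_cm = matrix(runif(ni * nc, -bc, bc), ni, nc),
      W_cv = matrix(runif(ni * nc, -bc, bc), ni, nc),
      b_c = rnorm(nc, config$bias_mean, sqrt(config$k)),
      b_m = runif(ni, -1, 1),
      b_v = runif(ni, -1, 1),
      tau = rep(config$tau, nc),
      u0_pb = matrix(0, np, n_sequences))
    class(params) <- "sctrnnpb_params"
    params
  })
}

#' One forward step of the S-CTRNNPB dynamics
#'
#' Reference implementation of a single time step: PB internal states are
#' carried over unchanged, context internal states leak with time constant
#' tau while integrating input, recurrent, PB and bias drive, and the mean
#' and variance neurons read the *current* context outputs (`y = tanh`,
#' `v = exp`, with the variance internal state clamped to +-20 before
#' exponentiation).
#'
#' @param params an `"sctrnnpb_params"` object.
#' @param state list with elements `u_context` and `u_pb` (internal states at
#'   the previous step).
#' @param x input vector (length `n_input`).
#' @return a list with the updated `u_context`, `u_pb` and the outputs `c`,
#'   `p`, `y`, `v`.
#' @export
forward_step <- function(params, state, x) {
  if (!all(is.finite(x))) stop("non-finite input", call. = FALSE)
  invtau <- 1 / params$tau
  c_prev <- tanh(state$u_context)
  p <- tanh(state$u_pb)
  u <- invtau * (params$W_xc %*% x + params$W_cc %*% c_prev +
                   params$W_pc %*% p + params$b_c) +
    (1 - invtau) * state$u_context
  u <- drop(u)
  cc <- tanh(u)
  u_m <- drop(params$W_cm %*% cc + params$b_m)
  u_v <- pmax(pmin(drop(params$W_cv %*% cc + params$b_v), 20), -20)
  list(u_context = u, u_pb = state$u_pb, c = cc, p = tanh(state$u_pb),
       y = tanh(u_m), v = exp(u_v))
}

#' Per-dimension heteroscedastic Gaussian negative log-likelihood
#'
#' `ln(2 pi v)/2 + (target - y)^2 / (2 v)` -- the precision-weighted
#' prediction error of one step.  May be negative when `v < 1/(2 pi)`.
#'
#' @param y mean prediction vector.
#' @param v variance prediction vector (strictly positive).
#' @param target observed target vector.
#' @return vector of per-dimension losses.
#' @export
stepwise_nll <- function(y, v, target) {
  if (any(v <= 0)) stop("nonpositive variance", call. = FALSE)
  0.5 * log(2 * pi * v) + (target - y)^2 / (2 * v)
}

#' Total negative log-likelihood of one or more traces
#'
#' The plain sum -- no averaging -- over sequences, time steps and output
#' dimensions of the per-step losses.
#'
#' @param traces a single trace (from [run_open_loop()]) or a list of traces.
#' @return scalar total loss.
#' @export
sequence_nll <- function(traces) {
  if (inherits(traces, "sctrnnpb_trace")) traces <- list(traces)
  sum(vapply(traces, function(tr) sum(tr$loss), numeric(1)))
}

as_trace <- function(res, mode) {
  structure(list(y = res$y, v = res$v, context = res$context,
                 u_context = res$u_context, p = drop(res$p),
                 loss = res$loss, mode = mode),
            class = "sctrnnpb_trace")
}

#' @export
print.sctrnnpb_trace <- function(x, ...) {
  cat(sprintf("S-CTRNNPB %s trace: %d steps, %d output dims, %d context neurons\n",
              x$mode, nrow(x$y), ncol(x$y), ncol(x$context)))
  if (!is.null(x$loss))
    cat(sprintf("  total NLL %.4f\n", sum(x$loss)))
  invisible(x)
}

#' Teacher-forced (open-loop) pass over a sequence
#'
#' At step t the network receives the observed state at t and is scored
#' against the observed state at t+1, so a T-step sequence yields T-1
#' prediction steps.  Context internal states start at zero.
#'
#' @param params an `"sctrnnpb_params"` object.
#' @param u_pb PB internal-state vector for this sequence.
#' @param x sequence matrix (T x n_input, T >= 2).
#' @return an `"sctrnnpb_trace"` with per-step `y`, `v`, `context`,
#'   `u_context`, `loss` and the PB activity `p`.
#' @export
run_open_loop <- function(params, u_pb, x) {
  x <- unclass(x)
  if (!is.matrix(x) || nrow(x) < 2)
    stop("sequence must have at least 2 steps", call. = FALSE)
  as_trace(cpp_open_loop(unclass(params), u_pb, x), "open_loop")
}

#' Closed-loop (mental simulation) generation
#'
#' The network's own mean prediction is fed back as the next input; after the
#' initial state `x0` no external data are consumed.
#'
#' @param params an `"sctrnnpb_params"` object.
#' @param u_pb PB internal-state vector.
#' @param x0 initial input vector.
#' @param n_steps number of generated steps (>= 1).
#' @param u_init initial context internal states (default zero).
#' @return an `"sctrnnpb_trace"` (no loss: there is no target).
#' @export
run_closed_loop <- function(params, u_pb, x0, n_steps,
                            u_init = rep(0, length(params$b_c))) {
  check_scalar_num(n_steps, "n_steps", lower = 1)
  res <- cpp_closed_loop(unclass(params), u_pb, x0, as.integer(n_steps),
                         u_init)
  as_trace(res, "closed_loop")
}

#' Full-batch BPTT gradients
#'
#' Gradients of the summed negative log-likelihood with respect to all
#' synaptic weights, the mean/variance biases and each sequence's initial PB
#' internal state.  Context biases are excluded from the gradient by
#' construction (they parameterize fixed intrinsic excitability).
#'
#' @param params an `"sctrnnpb_params"` object.
#' @param sequences list of equally long T x n_input matrices.
#' @param u0_pb n_pb x S matrix of PB internal states (defaults to the ones
#'   stored in `params`).
#' @return a named list of gradient arrays with attribute `"loss"`.
#' @export
bptt_gradients <- function(params, sequences, u0_pb = params$u0_pb) {
  if (length(sequences) == 0) stop("empty dataset", call. = FALSE)
  Ts <- vapply(sequences, nrow, integer(1))
  if (length(unique(Ts)) != 1)
    stop("all sequences must have equal length", call. = FALSE)
  X <- array(unlist(lapply(sequences, unclass)),
             dim = c(Ts[1], ncol(sequences[[1]]), length(sequences)))
  res <- cpp_grads(unclass(params), u0_pb, X)
  loss <- res$loss
  res$loss <- NULL
  res$b_m <- drop(res$b_m)  # arma vectors come back as n x 1 matrices
  res$b_v <- drop(res$b_v)
  for (nm in names(res)) {
    if (!all(is.finite(res[[nm]])))
      stop(sprintf("non-finite gradient in parameter block '%s'", nm),
           call. = FALSE)
  }
  attr(res, "loss") <- loss
  res
}

#' Momentum gradient-descent update
#'
#' `delta(n) = -alpha * grad + eta * delta(n-1); theta(n) = theta(n-1) +
#' delta(n)`.  Only parameter blocks present in `grads` are touched, so
#' context biases and time constants pass through unchanged.
#'
#' @param params an `"sctrnnpb_params"` object.
#' @param grads gradient list (as from [bptt_gradients()]).
#' @param velocity previous update list (same shapes); defaults to zeros.
#' @param alpha learning rate.
#' @param eta momentum coefficient.
#' @return list with updated `params` and `velocity`.
#' @export
momentum_update <- function(params, grads, velocity = NULL, alpha, eta) {
  if (is.null(velocity)) velocity <- lapply(grads, function(g) g * 0)
  for (nm in names(grads)) {
    tgt <- if (nm == "u0_pb") params$u0_pb else params[[nm]]
    if (is.null(tgt) || !identical(length(tgt), length(grads[[nm]])))
      stop(sprintf("shape mismatch in parameter block '%s'", nm),
           call. = FALSE)
    velocity[[nm]] <- -alpha * grads[[nm]] + eta * velocity[[nm]]
    params[[nm]] <- params[[nm]] + velocity[[nm]]
  }
  list(params = params, velocity = velocity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
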