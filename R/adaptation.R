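#' Sliding-window parametric-bias adaptation (postdiction)
#'
#' One round of real-time intention inference: the W-step window ending at
#' the current step is regenerated closed-loop from its anchors (the context
#' internal state and mean proprioceptive prediction at the window start,
#' and the vision observation that opened the window) under the current PB
#' internal state; the precision-weighted prediction error of the regenerated
#' window against the buffered observations is backpropagated through time to
#' the PB state, which takes `iterations` momentum steps.  Only the buffer
#' and anchors are read -- never future observations.
#'
#' @param params an `"sctrnnpb_params"` object (weights stay untouched).
#' @param u_pb current PB internal state.
#' @param velocity current PB momentum velocity (persists across steps).
#' @param u_anchor context internal state at the window start (time t-W).
#' @param x_anchor input vector opening the window (mean proprioceptive
#'   prediction at t-W combined with the vision observation at t-W+1).
#' @param observations matrix of the W-1 observed input vectors at window
#'   steps 2..W (rows; full input dimension).
#' @param dims indices of the input dimensions entering the error (default:
#'   the vision channels, per the operative description of real-time
#'   adaptation; pass all dimensions for the all-dimension variant).
#' @param iterations number of momentum updates (default 50).
#' @param alpha,eta learning rate and momentum coefficient.
#' @return list with updated `u_pb`, `velocity`, the windowed loss under the
#'   final PB state (`loss`), and the network's prediction for the step
#'   after the window (`y_next`, `v_next`).
#' @export
adapt_pb_window <- function(params, u_pb, velocity, u_anchor, x_anchor,
                            observations, dims, iterations = 50,
                            alpha = 1e-4, eta = 0.9) {
  if (!is.matrix(observations) || nrow(observations) < 1)
    stop("empty observation buffer", call. = FALSE)
  check_scalar_num(iterations, "iterations", lower = 0)
  cpp_pb_adapt(unclass(params), u_pb, velocity, u_anchor, x_anchor,
               observations, as.integer(dims) - 1L, as.integer(iterations),
               alpha, eta)
}

#' Run one simulated real-time interaction trial
#'
#' The trained network interacts with a scripted environment for
#' `env$trial_length` steps.  At every step the robot's joints follow the
#' network's mean proprioceptive prediction (the command), the environment
#' returns a noisy vision observation of the scripted ball (flipping
#' behavior once at the switch step), and -- once W observations have
#' accumulated -- the PB internal state is re-inferred by
#' [adapt_pb_window()] with `pb_updates_per_step` iterations.  During the
#' first W steps the PB state is held at the trained state of
#' `initial_behavior` while the buffer fills.  Synaptic weights and biases
#' are bit-identical across the whole trial.
#'
#' @param fit a fitted `"sctrnnpb"`.
#' @param env an [interaction_env()] (fresh; stepped by this function).
#' @param initial_behavior behavior whose trained PB state seeds the trial
#'   (defaults to the environment's initial situation).
#' @param error_dims `"vision"` (default) or `"all"`: which channels enter
#'   the precision-weighted error driving PB updates.
#' @return an object of class `"spb_trial"`: per-step observations,
#'   commands, inputs, PB activity, windowed precision-weighted error
#'   (`NA` during warm-up), plus trial metadata.
#' @export
interaction_trial <- function(fit, env,
                              initial_behavior = env$initial_situation,
                              error_dims = c("vision", "all")) {
  stopifnot(inherits(fit, "sctrnnpb"), inherits(env, "spb_env"))
  error_dims <- match.arg(error_dims)
  params <- fit$params
  cfg <- fit$config
  W <- cfg$window
  TL <- env$trial_length
  train <- dataset_sequences(fit$dataset, "train", initial_behavior)
  roles <- seq_roles(train[[1]])
  ip <- proprio_idx(roles); iv <- vision_idx(roles)
  D <- length(roles)
  dims <- if (error_dims == "vision") iv else seq_len(D)

  u_pb <- behavior_pb(fit, initial_behavior)
  vel <- rep(0, length(u_pb))
  nc <- length(params$b_c)

  inputs <- matrix(NA_real_, TL, D)
  preds <- matrix(NA_real_, TL, D)
  obs_log <- matrix(NA_real_, TL, length(iv))
  cmd_log <- matrix(NA_real_, TL, length(ip))
  pb_log <- matrix(NA_real_, TL, length(u_pb))
  pwpe <- rep(NA_real_, TL)
  u_tf <- matrix(NA_real_, TL, nc)  # teacher-forced anchor states

  state <- list(u_context = rep(0, nc), u_pb = u_pb)
  command <- unclass(train[[1]])[1, ip]
  for (t in seq_len(TL)) {
    obs <- env_step(env, command)
    x_t <- numeric(D)
    x_t[ip] <- command
    x_t[iv] <- obs
    inputs[t, ] <- x_t
    obs_log[t, ] <- obs
    cmd_log[t, ] <- command

    if (t > W) {
      a <- t - W  # window start (anchor time)
      res <- adapt_pb_window(params, u_pb, vel,
                             u_anchor = u_tf[a, ],
                             x_anchor = inputs[a + 1, ],
                             observations = inputs[(a + 2):t, ,
                                                   drop = FALSE],
                             dims = dims,
                             iterations = cfg$pb_updates_per_step,
                             alpha = cfg$alpha, eta = cfg$eta)
      u_pb <- drop(res$u_pb)
      vel <- drop(res$velocity)
      pwpe[t] <- res$loss
      preds[t, ] <- drop(res$y_next)
    }

    # advance the teacher-forced anchor pass with the realized input
    state$u_pb <- u_pb
    state <- forward_step(params, state, x_t)
    u_tf[t, ] <- state$u_context
    if (t <= W) preds[t, ] <- state$y

    command <- preds[t, ip]
    pb_log[t, ] <- tanh(u_pb)
    if (!all(is.finite(u_pb)))
      stop(sprintf("non-finite PB state at step %d", t), call. = FALSE)
  }
  structure(list(observations = obs_log, commands = cmd_log,
                 inputs = inputs, predictions = preds, pb = pb_log,
                 pwpe = pwpe, u_pb_final = u_pb,
                 initial_behavior = initial_behavior,
                 post_behavior = setdiff(c("right", "left"),
                                         initial_behavior),
                 switch_step = env$switch_step, trial_length = TL,
                 window = W, error_dims = error_dims, roles = roles),
            class = "spb_trial")
}

#' @export
print.spb_trial <- function(x, ...) {
  cat(sprintf(
    "Interaction trial: %d steps, switch at %d (%s -> %s)\n",
    x$trial_length, x$switch_step, x$initial_behavior, x$post_behavior))
  cat(sprintf("  final PB activity: %s\n",
              paste(sprintf("%.3f", tanh(x$u_pb_final)), collapse = ", ")))
  invisible(x)
}

#' Write a trial log to CSV (one row per step)
#'
#' @param trial an `"spb_trial"`.
#' @param file path to write to.
#' @export
write_trial_csv <- function(trial, file) {
  df <- data.frame(step = seq_len(trial$trial_length))
  add <- function(df, m, prefix) {
    colnames(m) <- sprintf("%s_%d", prefix, seq_len(ncol(m)))
    cbind(df, m)
  }
  df <- add(df, trial$observations, "obs")
  df <- add(df, trial$commands, "cmd")
  df <- add(df, trial$pb, "pb")
  df$pwpe <- trial$pwpe
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
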