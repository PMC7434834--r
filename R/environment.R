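#' Scripted virtual interaction environment
#'
#' Emulates the real-time ball interaction: at every step the environment
#' returns the vision channels of the active behavior's template (plus
#' sensory noise), and at `switch_step` the active behavior flips exactly
#' once -- the unpredictable situation change the network must recognize.
#' The environment is open-loop with respect to the arm: joint commands are
#' logged but do not alter the scripted ball, so task performance is judged
#' by trajectory similarity rather than contact physics.
#'
#' @param spec an [sequence_spec()] describing the underlying templates.
#' @param initial_situation behavior active at the start of the trial.
#' @param switch_step step at which the situation flips (0 < switch_step <
#'   trial_length).
#' @param trial_length total number of steps the environment serves.
#' @param jitter integer phase offset (steps) applied to the template,
#'   emulating timing differences from the training experiences.
#' @param noise_variance vision noise variance; defaults to the spec's.
#' @param seed seed for the environment's noise draws.
#' @return an object of class `"spb_env"` (an environment with mutable step
#'   state).
#' @export
interaction_env <- function(spec, initial_situation = c("right", "left"),
                            switch_step = 120, trial_length = 300,
                            jitter = 0, noise_variance = spec$noise_variance,
                            seed = NULL) {
  stopifnot(inherits(spec, "spb_spec"))
  initial_situation <- match.arg(initial_situation)
  check_scalar_num(switch_step, "switch_step", lower = 1,
                   upper = trial_length - 1)
  check_scalar_num(trial_length, "trial_length", lower = 2)
  check_scalar_num(noise_variance, "noise_variance", lower = 0)
  vis <- lapply(c(right = "right", left = "left"), function(b) {
    tm <- behavior_template(spec, b)
    tm[seq_len(spec$cycle_length), seq_roles(tm) == "vision", drop = FALSE]
  })
  noise <- with_seed(seed, matrix(rnorm(trial_length * spec$n_vision, 0,
                                        sqrt(noise_variance)),
                                  trial_length, spec$n_vision))
  env <- new.env(parent = emptyenv())
  env$spec <- spec
  env$templates <- vis
  env$situation <- initial_situation
  env$initial_situation <- initial_situation
  env$switch_step <- as.integer(switch_step)
  env$trial_length <- as.integer(trial_length)
  env$jitter <- as.integer(jitter)
  env$noise <- noise
  env$step <- 0L
  env$commands <- list()
  env$n_switches <- 0L
  class(env) <- "spb_env"
  env
}

#' Advance the virtual environment one step
#'
#' Logs the joint command, advances the step counter (flipping the situation
#' exactly once when the counter reaches `switch_step`) and returns the
#' current noisy vision observation.
#'
#' @param env an `"spb_env"` object.
#' @param joint_command numeric vector of commanded joint angles (logged,
#'   not acted upon -- the ball is scripted).
#' @return the vision observation for the new step (length `n_vision`).
#' @export
env_step <- function(env, joint_command) {
  stopifnot(inherits(env, "spb_env"))
  if (env$step >= env$trial_length)
    stop("environment exhausted: trial_length steps already served",
         call. = FALSE)
  env$step <- env$step + 1L
  env$commands[[env$step]] <- joint_command
  if (env$step == env$switch_step) {
    env$situation <- setdiff(c("right", "left"), env$situation)
    env$n_switches <- env$n_switches + 1L
  }
  P <- env$spec$cycle_length
  phase <- ((env$step - 1L + env$jitter) %% P) + 1L
  obs <- env$templates[[env$situation]][phase, ] + env$noise[env$step, ]
  pmax(pmin(obs, 0.999), -0.999)
}

#' @export
print.spb_env <- function(x, ...) {
  cat(sprintf(
    "Interaction environment: start '%s', switch at step %d, length %d (step %d)\n",
    x$initial_situation, x$switch_step, x$trial_length, x$step))
  invisible(x)
}
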