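#' Specification of a synthetic visuomotor sequence
#'
#' Describes the periodic ball-pass sequences used as training targets: a set
#' of proprioceptive (joint-angle) channels plus two vision channels tracking
#' the ball, all normalized well inside (-1, 1).  The full-scale defaults
#' mirror the robot recordings the generator emulates: 10 channels, cycles of
#' 106 steps, 10 cycles (1,060 steps), amplitude bound 0.8 and additive
#' sensory noise of variance 0.002.
#'
#' @param n_proprio number of proprioceptive channels.
#' @param n_vision number of vision channels (ball coordinates).
#' @param cycle_length steps per behavioral cycle (>= 4).
#' @param n_cycles number of cycles per sequence (>= 1).
#' @param amplitude amplitude bound; all template values lie in
#'   `[-amplitude, amplitude]`, strictly inside (-1, 1).
#' @param noise_variance variance of the i.i.d. Gaussian sensory noise added
#'   to each element of a realized sequence.
#' @param behavior default behavior class, `"right"` or `"left"`.
#' @return an object of class `"spb_spec"`.
#' @export
#' @examples
#' sequence_spec(cycle_length = 40, n_cycles = 5)
sequence_spec <- function(n_proprio = 8, n_vision = 2, cycle_length = 106,
                          n_cycles = 10, amplitude = 0.8,
                          noise_variance = 0.002,
                          behavior = c("right", "left")) {
  behavior <- match.arg(behavior)
  check_scalar_num(n_proprio, "n_proprio", lower = 1)
  check_scalar_num(n_vision, "n_vision", lower = 1)
  check_scalar_num(cycle_length, "cycle_length", lower = 4)
  check_scalar_num(n_cycles, "n_cycles", lower = 1)
  check_scalar_num(amplitude, "amplitude", lower = 0, upper = 1 - 1e-12,
                   strict_lower = TRUE)
  check_scalar_num(noise_variance, "noise_variance", lower = 0)
  structure(list(n_proprio = as.integer(n_proprio),
                 n_vision = as.integer(n_vision),
                 cycle_length = as.integer(cycle_length),
                 n_cycles = as.integer(n_cycles),
                 amplitude = amplitude,
                 noise_variance = noise_variance,
                 behavior = behavior),
            class = "spb_spec")
}

#' @export
print.spb_spec <- function(x, ...) {
  cat(sprintf(
    "Visuomotor sequence spec: %d proprio + %d vision channels, %d x %d = %d steps\n",
    x$n_proprio, x$n_vision, x$cycle_length, x$n_cycles,
    x$cycle_length * x$n_cycles))
  cat(sprintf("  amplitude bound %.2f, noise variance %.4g, behavior '%s'\n",
              x$amplitude, x$noise_variance, x$behavior))
  invisible(x)
}

# raised-cosine bump: periodic in phi with period 1, range [0, 1], peak at 0
rc_bump <- function(phi) (0.5 * (1 + cos(2 * pi * phi)))^2

#' Noiseless behavior template
#'
#' Builds the clean periodic waveform for one ball-pass behavior.  Each
#' proprioceptive channel is a phase-shifted raised-cosine bump train; the
#' arm driving the pass (the right arm for the "right" behavior) swings at
#' full amplitude while the opposite arm sways at 30% amplitude.  The first
#' vision channel dwells at the active side (at `0.5 * amplitude`, the
#' white-line landmark) and sweeps to the robot (0) and back once per cycle;
#' the "left" and "right" templates are exact mirror images in this channel.
#' The second vision channel encodes ball depth and is shared by both
#' behaviors.
#'
#' @param spec an [sequence_spec()] object.
#' @param behavior behavior class; defaults to `spec$behavior`.
#' @param phase_offset integer phase shift in steps (used for test-set
#'   jitter).
#' @return a `T x D` matrix of class `"spb_sequence"` with attributes
#'   `roles`, `behavior`, `split` (`"template"`) and `cycle_length`.
#' @export
behavior_template <- function(spec, behavior = spec$behavior,
                              phase_offset = 0L) {
  stopifnot(inherits(spec, "spb_spec"))
  behavior <- match.arg(behavior, c("right", "left"))
  P <- spec$cycle_length
  T_ <- P * spec$n_cycles
  A <- spec$amplitude
  # exact periodicity: phase from the integer step modulo the cycle length
  phi <- (((seq_len(T_) - 1L) + as.integer(phase_offset)) %% P) / P
  np <- spec$n_proprio
  X <- matrix(0, T_, np + spec$n_vision)
  half <- ceiling(np / 2)
  active <- function(j, n) A * (2 * rc_bump(phi - (j - 1) / n) - 1)
  passive <- function(j, n) 0.3 * A * (2 * rc_bump(phi - (j - 1) / n - 0.5) - 1)
  for (j in seq_len(np)) {
    arm1 <- j <= half   # channels of the first (right-arm) group
    grp_j <- if (arm1) j else j - half
    grp_n <- if (arm1) half else np - half
    drives <- (behavior == "right") == arm1
    X[, j] <- if (drives) active(grp_j, grp_n) else passive(grp_j, grp_n)
  }
  side <- if (behavior == "right") 1 else -1
  X[, np + 1] <- side * 0.5 * A * (1 - rc_bump(phi - 0.5))
  if (spec$n_vision >= 2)
    X[, np + 2] <- 0.2 * A + 0.5 * A * (2 * rc_bump(phi - 0.5) - 1)
  structure(X,
            roles = c(rep("proprio", np), rep("vision", spec$n_vision)),
            behavior = behavior, split = "template",
            cycle_length = P, class = c("spb_sequence", "matrix", "array"))
}

#' Add i.i.d. Gaussian sensory noise to a sequence
#'
#' Adds elementwise N(0, variance) noise and clips the result to
#' (-0.999, 0.999) so that inputs stay strictly inside the tanh range (at the
#' default amplitude 0.8 and variance 0.002 the clip essentially never
#' binds).
#'
#' @param x a sequence matrix.
#' @param variance noise variance (>= 0).
#' @param seed optional seed; when given, the draw is a pure function of
#'   `(x, variance, seed)` and the caller's RNG state is left untouched.
#' @return the noisy sequence with the attributes of `x` preserved.
#' @export
add_sensory_noise <- function(x, variance, seed = NULL) {
  check_scalar_num(variance, "variance", lower = 0)
  noise <- with_seed(seed,
    matrix(rnorm(length(x), 0, sqrt(variance)), nrow(x), ncol(x)))
  out <- x + noise
  out[] <- pmax(pmin(out, 0.999), -0.999)
  attributes(out) <- attributes(x)
  out
}

#' Generate a synthetic ball-pass dataset
#'
#' Produces, for each of the two behaviors, `n_train` training and `n_test`
#' test realizations of the behavior template with independent sensory noise.
#' Test sequences additionally receive a small uniform integer phase jitter
#' (default up to +-3 steps), emulating timing differences between training
#' and test experiences.
#'
#' @param spec an [sequence_spec()] object.
#' @param n_train,n_test sequences per behavior and split (>= 1 train).
#' @param seed master seed; the dataset is a pure function of
#'   `(spec, n_train, n_test, seed, test_jitter)`.
#' @param test_jitter maximum absolute phase jitter (steps) for test
#'   sequences; 0 disables jitter.
#' @return an object of class `"spb_dataset"`: a list with elements
#'   `sequences` (list of `"spb_sequence"` matrices), `spec` and `manifest`
#'   (a data frame of ids, behaviors, splits, seeds and jitters).
#' @export
#' @examples
#' ds <- build_dataset(sequence_spec(cycle_length = 40, n_cycles = 2),
#'                     n_train = 1, n_test = 1, seed = 1)
#' ds$manifest
build_dataset <- function(spec, n_train = 3, n_test = 3, seed = 1,
                          test_jitter = 3) {
  stopifnot(inherits(spec, "spb_spec"))
  check_scalar_num(n_train, "n_train", lower = 1)
  check_scalar_num(n_test, "n_test", lower = 0)
  sequences <- list()
  manifest <- NULL
  for (behavior in c("right", "left")) {
    for (i in seq_len(n_train + n_test)) {
      split <- if (i <= n_train) "train" else "test"
      sseed <- derive_seed(seed, 100 * (behavior == "left") + i)
      jit <- 0L
      if (split == "test" && test_jitter > 0)
        jit <- with_seed(derive_seed(sseed, 1),
                         sample.int(2L * as.integer(test_jitter) + 1L, 1L) -
                           as.integer(test_jitter) - 1L)
      tmpl <- behavior_template(spec, behavior, phase_offset = jit)
      x <- add_sensory_noise(tmpl, spec$noise_variance, seed = sseed)
      attr(x, "split") <- split
      attr(x, "jitter") <- jit
      id <- sprintf("%s_%s_%d", behavior, split,
                    if (split == "train") i else i - n_train)
      sequences[[id]] <- x
      manifest <- rbind(manifest,
                        data.frame(id = id, behavior = behavior,
                                   split = split, seed = sseed, jitter = jit))
    }
  }
  structure(list(sequences = sequences, spec = spec, seed = seed,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 manifest = manifest),
            class = "spb_dataset")
}

#' @export
print.spb_dataset <- function(x, ...) {
  cat(sprintf("Ball-pass dataset: %d sequences (%d train + %d test per behavior)\n",
              length(x$sequences), x$n_train, x$n_test))
  print(x$spec)
  invisible(x)
}

#' Extract sequences of one split (and optionally one behavior)
#'
#' @param dataset an `"spb_dataset"`.
#' @param split `"train"` or `"test"`.
#' @param behavior optional behavior filter.
#' @return a named list of sequence matrices.
#' @export
dataset_sequences <- function(dataset, split = "train", behavior = NULL) {
  stopifnot(inherits(dataset, "spb_dataset"))
  keep <- vapply(dataset$sequences, function(s) {
    attr(s, "split") == split &&
      (is.null(behavior) || attr(s, "behavior") == behavior)
  }, logical(1))
  dataset$sequences[keep]
}

#' Write a sequence to CSV (one row per step, role tags in the header)
#'
#' @param x a sequence matrix.
#' @param file path to write to.
#' @export
write_sequence_csv <- function(x, file) {
  roles <- seq_roles(x)
  df <- as.data.frame(unclass(x))
  names(df) <- sprintf("%s_%d", roles, stats::ave(seq_along(roles), roles,
                                                  FUN = seq_along))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a dataset manifest (specs, seeds, splits) as JSON
#'
#' @param dataset an `"spb_dataset"`.
#' @param file path to write to.
#' @export
write_dataset_manifest <- function(dataset, file) {
  jsonlite::write_json(
    list(spec = unclass(dataset$spec), seed = dataset$seed,
         n_train = dataset$n_train, n_test = dataset$n_test,
         sequences = dataset$manifest),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
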