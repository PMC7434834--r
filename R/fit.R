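#' Fit an S-CTRNNPB to a visuomotor dataset
#'
#' Trains the network by full-batch momentum gradient descent on the summed
#' heteroscedastic Gaussian negative log-likelihood (precision-weighted
#' prediction error) over all training sequences, with gradients computed by
#' backpropagation through time.  Trained parameters are the synaptic
#' weights, the mean/variance biases and one initial PB internal state per
#' training sequence; the context biases drawn at initialization (variance
#' `config$k`) stay frozen, fixing the heterogeneity of intrinsic neuronal
#' excitability.
#'
#' @param dataset an [build_dataset()] object (training split is used).
#' @param config an [sctrnnpb_config()]; its `n_input` must match the data
#'   dimensionality.
#' @param seed seed for parameter initialization; training itself is
#'   deterministic, so the fit is a pure function of `(dataset, config,
#'   seed)`.
#' @param thin record the training loss every `thin` epochs.
#' @return an object of class `"sctrnnpb"`: a list with elements `params`
#'   (trained `"sctrnnpb_params"` including `u0_pb`), `params_init`, `config`,
#'   `dataset`, `loss_trace` (data frame `epoch`, `loss`), `behaviors`
#'   (behavior of each training sequence) and `seed`.
#' @export
#' @examples
#' \donttest{
#' spec <- sequence_spec(cycle_length = 40, n_cycles = 5)
#' ds <- build_dataset(spec, n_train = 2, n_test = 2, seed = 1)
#' fit <- sctrnnpb(ds, desk_config(k = 10, n_epochs = 2000), seed = 1)
#' fit
#' }
sctrnnpb <- function(dataset, config = desk_config(), seed = 1, thin = 100) {
  stopifnot(inherits(dataset, "spb_dataset"),
            inherits(config, "sctrnnpb_config"))
  train <- dataset_sequences(dataset, "train")
  if (length(train) == 0) stop("dataset has no training sequences",
                               call. = FALSE)
  behaviors <- vapply(train, attr, character(1), "behavior")
  if (length(unique(behaviors)) < 1) stop("empty training set", call. = FALSE)
  D <- ncol(train[[1]])
  if (D != config$n_input)
    stop(sprintf("config$n_input (%d) does not match data dimension (%d)",
                 config$n_input, D), call. = FALSE)
  params <- init_network(config, n_sequences = length(train), seed = seed)
  X <- array(unlist(lapply(train, unclass)),
             dim = c(nrow(train[[1]]), D, length(train)))
  res <- cpp_train(unclass(params), params$u0_pb, X, config$n_epochs,
                   config$alpha, config$eta, as.integer(thin))
  trained <- res$params
  trained$u0_pb <- res$u0_pb
  colnames(trained$u0_pb) <- names(train)
  class(trained) <- "sctrnnpb_params"
  structure(list(params = trained, params_init = params, config = config,
                 dataset = dataset, behaviors = behaviors,
                 loss_trace = data.frame(epoch = res$epoch, loss = res$loss),
                 final_loss = res$final_loss, seed = seed,
                 call = match.call()),
            class = "sctrnnpb")
}

#' Trained PB internal state associated with a behavior
#'
#' The mean of the trained per-sequence PB internal states over the training
#' sequences of that behavior -- the network's "intention" for the behavior.
#'
#' @param object a fitted `"sctrnnpb"`.
#' @param behavior `"right"` or `"left"`.
#' @return PB internal-state vector.
#' @export
behavior_pb <- function(object, behavior) {
  stopifnot(inherits(object, "sctrnnpb"))
  cols <- object$behaviors == behavior
  if (!any(cols)) stop(sprintf("no training sequences of behavior '%s'",
                               behavior), call. = FALSE)
  rowMeans(object$params$u0_pb[, cols, drop = FALSE])
}

#' @export
print.sctrnnpb <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("S-CTRNNPB fit: %d context neurons, k = %.3g, %d epochs\n",
              cfg$n_context, cfg$k, cfg$n_epochs))
  cat(sprintf("  %d training sequences (%s), final NLL %.2f\n",
              length(x$behaviors),
              paste(sprintf("%d %s", table(x$behaviors),
                            names(table(x$behaviors))), collapse = ", "),
              x$final_loss))
  invisible(x)
}

#' @export
summary.sctrnnpb <- function(object, ...) {
  om <- overfitting_metrics(object)
  pb <- tanh(object$params$u0_pb)
  out <- list(fit = object, overfit = om, pb_activity = pb)
  class(out) <- "summary.sctrnnpb"
  out
}

#' @export
print.summary.sctrnnpb <- function(x, ...) {
  print(x$fit)
  om <- x$overfit
  cat(sprintf("  train MSE %.3g / test MSE %.3g\n", om$train_error,
              om$test_error))
  cat(sprintf("  mean predicted variance: train %.3g / test %.3g\n",
              om$train_variance, om$test_variance))
  cat("  PB activity per training sequence:\n")
  print(round(x$pb_activity, 3))
  invisible(x)
}

#' @export
coef.sctrnnpb <- function(object, ...) {
  object$params[c("W_xc", "W_cc", "W_pc", "W_cm", "W_cv", "b_c", "b_m",
                  "b_v", "u0_pb")]
}

#' Predictions from a fitted S-CTRNNPB
#'
#' `type = "open_loop"` runs a teacher-forced pass over `newdata` (a sequence
#' matrix); `type = "closed_loop"` generates a mental-simulation trace from
#' an initial input.
#'
#' @param object a fitted `"sctrnnpb"`.
#' @param newdata sequence matrix for open-loop prediction; defaults to the
#'   first training sequence.
#' @param type `"open_loop"` or `"closed_loop"`.
#' @param pb PB internal state; defaults to the trained state of `behavior`.
#' @param behavior behavior whose trained PB state to use when `pb` is not
#'   given.
#' @param n_steps closed-loop length (defaults to one training-sequence
#'   length minus 1).
#' @param x0 closed-loop initial input (defaults to the first frame of a
#'   training sequence of `behavior`).
#' @param ... unused.
#' @return an `"sctrnnpb_trace"`.
#' @export
predict.sctrnnpb <- function(object, newdata = NULL,
                             type = c("open_loop", "closed_loop"),
                             pb = NULL, behavior = NULL, n_steps = NULL,
                             x0 = NULL, ...) {
  type <- match.arg(type)
  train <- dataset_sequences(object$dataset, "train")
  if (type == "open_loop") {
    if (is.null(newdata)) newdata <- train[[1]]
    if (is.null(pb)) {
      b <- behavior %||% attr(newdata, "behavior") %||% object$behaviors[1]
      pb <- behavior_pb(object, b)
    }
    run_open_loop(object$params, pb, newdata)
  } else {
    b <- behavior %||% object$behaviors[1]
    if (is.null(pb)) pb <- behavior_pb(object, b)
    ref <- train[[which(object$behaviors == b)[1]]]
    if (is.null(x0)) x0 <- ref[1, ]
    if (is.null(n_steps)) n_steps <- nrow(ref) - 1
    run_closed_loop(object$params, pb, x0, n_steps)
  }
}

#' Mental-simulation draws from a fitted S-CTRNNPB
#'
#' Each simulation is a closed-loop generation started from the first frame
#' of a training sequence with that sequence's trained PB internal state
#' (sequences are cycled over in order).  The network is deterministic:
#' `nsim` controls how many training sequences are replayed, not sampling.
#'
#' @param object a fitted `"sctrnnpb"`.
#' @param nsim number of traces (defaults to one per training sequence).
#' @param seed unused (kept for the generic's signature).
#' @param n_steps length of each generated trace.
#' @param ... unused.
#' @return a list of `"sctrnnpb_trace"` objects named by training sequence.
#' @export
simulate.sctrnnpb <- function(object, nsim = length(object$behaviors),
                              seed = NULL, n_steps = NULL, ...) {
  train <- dataset_sequences(object$dataset, "train")
  idx <- rep(seq_along(train), length.out = nsim)
  out <- lapply(idx, function(s) {
    x <- train[[s]]
    run_closed_loop(object$params, object$params$u0_pb[, s],
                    x[1, ], n_steps %||% (nrow(x) - 1))
  })
  names(out) <- names(train)[idx]
  out
}

#' @export
residuals.sctrnnpb <- function(object, ...) {
  train <- dataset_sequences(object$dataset, "train")
  out <- lapply(seq_along(train), function(s) {
    x <- unclass(train[[s]])
    tr <- run_open_loop(object$params, object$params$u0_pb[, s], train[[s]])
    x[-1, , drop = FALSE] - tr$y
  })
  names(out) <- names(train)
  out
}

#' @export
fitted.sctrnnpb <- function(object, ...) {
  train <- dataset_sequences(object$dataset, "train")
  out <- lapply(seq_along(train), function(s)
    run_open_loop(object$params, object$params$u0_pb[, s], train[[s]])$y)
  names(out) <- names(train)
  out
}

#' Plot method for fitted S-CTRNNPB models
#'
#' `which = "loss"` draws the training-loss trace; `which = "simulation"`
#' overlays a closed-loop generation on the corresponding training sequence
#' (proprioceptive channels); `which = "variance"` shows the predicted
#' standard deviation band around the open-loop mean prediction for one
#' channel.
#'
#' @param x a fitted `"sctrnnpb"`.
#' @param which `"loss"`, `"simulation"` or `"variance"`.
#' @param sequence index of the training sequence used by the data panels.
#' @param channel channel shown by `which = "variance"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.sctrnnpb <- function(x, which = c("loss", "simulation", "variance"),
                          sequence = 1, channel = 1, ...) {
  which <- match.arg(which)
  train <- dataset_sequences(x$dataset, "train")
  if (which == "loss") {
    graphics::plot(x$loss_trace$epoch, x$loss_trace$loss, type = "l",
                   xlab = "epoch", ylab = "total NLL",
                   main = "Training loss", ...)
  } else if (which == "simulation") {
    xm <- unclass(train[[sequence]])
    tr <- run_closed_loop(x$params, x$params$u0_pb[, sequence], xm[1, ],
                          nrow(xm) - 1)
    np <- sum(seq_roles(train[[sequence]]) == "proprio")
    graphics::matplot(xm[-1, seq_len(min(4, np))], type = "l", lty = 1,
                      col = "grey60", xlab = "step", ylab = "state",
                      main = "Mental simulation vs. target", ...)
    graphics::matlines(tr$y[, seq_len(min(4, np))], lty = 2)
  } else {
    xm <- unclass(train[[sequence]])
    tr <- run_open_loop(x$params, x$params$u0_pb[, sequence],
                        train[[sequence]])
    s <- sqrt(tr$v[, channel])
    graphics::plot(xm[-1, channel], type = "l", col = "grey60",
                   xlab = "step", ylab = "state",
                   main = sprintf("Predicted mean +- sd (channel %d)",
                                  channel), ...)
    graphics::lines(tr$y[, channel])
    graphics::lines(tr$y[, channel] + s, lty = 3)
    graphics::lines(tr$y[, channel] - s, lty = 3)
  }
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is an RDS file holding the full fit plus a JSON sidecar
#' with the configuration and seeds; `read_checkpoint()` restores the fit
#' bit-exactly.
#'
#' @param object a fitted `"sctrnnpb"`.
#' @param file path of the checkpoint file (`.rds`); the sidecar gets the
#'   extension `.json`.
#' @export
write_checkpoint <- function(object, file) {
  stopifnot(inherits(object, "sctrnnpb"))
  saveRDS(object, file)
  jsonlite::write_json(
    list(config = unclass(object$config), seed = object$seed,
         dataset_seed = object$dataset$seed,
         final_loss = object$final_loss),
    paste0(sub("\\.rds$", "", file), ".json"), auto_unbox = TRUE,
    digits = NA)
  invisible(file)
}

#' @rdname write_checkpoint
#' @param file path of the checkpoint file.
#' @export
read_checkpoint <- function(file) readRDS(file)
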