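#' Time-compressed state histogram
#'
#' Compresses a time series along the time axis into a probability
#' distribution over the state space (-1, 1), divided into `n_bins` uniform
#' bins.  A pseudo-count of `pseudo` per bin is added before normalization so
#' that Kullback-Leibler divergences against the histogram stay finite.
#'
#' @param x numeric vector with all values inside (-1, 1); the boundary
#'   values +-1 (which tanh outputs can reach in floating point) are counted
#'   in the end bins.
#' @param n_bins number of bins (default 50).
#' @param pseudo pseudo-count per bin (default 1e-6; 0 disables smoothing).
#' @return an object of class `"spb_hist"` with elements `prob`, `counts`,
#'   `breaks`.
#' @export
state_histogram <- function(x, n_bins = 50, pseudo = 1e-6) {
  if (any(!is.finite(x)) || any(abs(x) > 1))
    stop("values must lie inside (-1, 1)", call. = FALSE)
  check_scalar_num(n_bins, "n_bins", lower = 1)
  idx <- pmax(pmin(floor((x + 1) / 2 * n_bins) + 1L, n_bins), 1L)
  counts <- tabulate(idx, nbins = n_bins)
  prob <- (counts + pseudo) / (length(x) + n_bins * pseudo)
  structure(list(prob = prob, counts = counts,
                 breaks = seq(-1, 1, length.out = n_bins + 1)),
            class = "spb_hist")
}

#' Kullback-Leibler divergence between two state histograms
#'
#' `sum(p * log(p / q))` over bins, with `0 * log(0 / q) = 0`.  Both
#' histograms must share identical bin edges.
#'
#' @param p,q `"spb_hist"` objects on the same bins.
#' @return nonnegative scalar.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "spb_hist"), inherits(q, "spb_hist"))
  if (!isTRUE(all.equal(p$breaks, q$breaks)))
    stop("mismatched histogram binning", call. = FALSE)
  pos <- p$prob > 0
  if (any(pos & q$prob == 0))
    stop("q assigns zero probability where p does not (use smoothing)",
         call. = FALSE)
  sum(p$prob[pos] * log(p$prob[pos] / q$prob[pos]))
}

#' Similarity score between a generated and a target sequence
#'
#' The sum over the selected channels of the KL divergences between the
#' time-compressed state histograms of the generated series and of the
#' target series.  By default only the proprioceptive (joint) channels enter
#' the score -- the decision variable -- but the all-channel variant is
#' always reported alongside.
#'
#' @param generated matrix of generated states (rows = steps).
#' @param target matrix of target states with the same number of columns.
#' @param dims channel indices entering the score; defaults to the
#'   proprioceptive channels of `target` (all channels if it carries no role
#'   tags).
#' @param n_bins histogram resolution.
#' @return an object of class `"spb_similarity"`: list with `ss` (selected
#'   channels), `ss_all`, `per_dim`, `dims`.
#' @export
similarity_score <- function(generated, target, dims = NULL, n_bins = 50) {
  generated <- as.matrix(generated)
  tm <- unclass(as.matrix(target))
  if (nrow(generated) == 0 || nrow(tm) == 0)
    stop("empty series", call. = FALSE)
  if (ncol(generated) != ncol(tm))
    stop("generated and target must have the same number of channels",
         call. = FALSE)
  if (is.null(dims)) {
    roles <- attr(target, "roles")
    dims <- if (is.null(roles)) seq_len(ncol(tm)) else proprio_idx(roles)
  }
  per_dim <- vapply(seq_len(ncol(tm)), function(d) {
    kl_divergence(state_histogram(generated[, d], n_bins),
                  state_histogram(tm[, d], n_bins))
  }, numeric(1))
  structure(list(ss = sum(per_dim[dims]), ss_all = sum(per_dim),
                 per_dim = per_dim, dims = dims),
            class = "spb_similarity")
}

#' @export
print.spb_similarity <- function(x, ...) {
  cat(sprintf("Similarity score: %.4f over %d channels (all channels: %.4f)\n",
              x$ss, length(x$dims), x$ss_all))
  invisible(x)
}

# minimum similarity score of `generated` against a set of target sequences
best_match_ss <- function(generated, targets, dims = NULL, n_bins = 50) {
  min(vapply(targets, function(tg)
    similarity_score(generated, tg, dims = dims, n_bins = n_bins)$ss,
    numeric(1)))
}

#' Success threshold for similarity-score judgments
#'
#' Half the minimum similarity score over ordered cross-behavior pairs of
#' training sequences (left-vs-right and right-vs-left): a generated series
#' whose score against the correct behavior falls below this threshold is
#' closer to that behavior than the two behaviors are to each other.
#'
#' @param dataset an [build_dataset()] object with training sequences of
#'   both behaviors.
#' @param dims channel indices entering the score (default: proprioceptive).
#' @param n_bins histogram resolution.
#' @return scalar threshold; 0 (flagged with a warning) when the two
#'   behaviors' training sets coincide.
#' @export
success_threshold <- function(dataset, dims = NULL, n_bins = 50) {
  left <- dataset_sequences(dataset, "train", "left")
  right <- dataset_sequences(dataset, "train", "right")
  if (length(left) == 0 || length(right) == 0)
    stop("need training sequences of both behaviors", call. = FALSE)
  ss <- c()
  for (a in left) for (b in right) {
    ss <- c(ss, similarity_score(a, b, dims = dims, n_bins = n_bins)$ss,
            similarity_score(b, a, dims = dims, n_bins = n_bins)$ss)
  }
  xi <- 0.5 * min(ss)
  if (xi == 0) warning("degenerate dataset: cross-behavior similarity is 0")
  xi
}

#' Judge mental simulation of learned behaviors
#'
#' For every training sequence, the fitted network generates a closed-loop
#' trace from that sequence's first frame with its trained PB internal
#' state; the trial succeeds when the similarity score against the best
#' matching training sequence of the same behavior is below the threshold
#' xi.
#'
#' @param fit a fitted `"sctrnnpb"`.
#' @param n_bins histogram resolution.
#' @param xi success threshold; computed from the training data by default.
#' @return list with `trials` (data frame: sequence, behavior, ss, success),
#'   `rate` and `xi`.
#' @export
judge_mental_simulation <- function(fit, n_bins = 50, xi = NULL) {
  stopifnot(inherits(fit, "sctrnnpb"))
  if (is.null(xi)) xi <- success_threshold(fit$dataset, n_bins = n_bins)
  train <- dataset_sequences(fit$dataset, "train")
  rows <- lapply(seq_along(train), function(s) {
    x <- train[[s]]
    b <- attr(x, "behavior")
    tr <- run_closed_loop(fit$params, fit$params$u0_pb[, s],
                          unclass(x)[1, ], nrow(x) - 1)
    ss <- best_match_ss(tr$y, dataset_sequences(fit$dataset, "train", b),
                        n_bins = n_bins)
    data.frame(sequence = names(train)[s], behavior = b, ss = ss,
               success = ss < xi)
  })
  trials <- do.call(rbind, rows)
  list(trials = trials, rate = mean(trials$success), xi = xi)
}

#' Judge cognitive flexibility after an interaction trial
#'
#' Closed-loop sequences are generated with the PB state the network reached
#' at the end of the trial (step 300), starting from each post-switch
#' training sequence's first frame; the trial counts as a successful
#' recognition of the situation switch when the best similarity score
#' against the post-switch behavior's training data is below xi.
#'
#' @param trial an [interaction_trial()] result.
#' @param fit the fitted `"sctrnnpb"` that produced the trial.
#' @param n_bins histogram resolution.
#' @param xi success threshold (computed from the training data by default).
#' @return logical (with attribute `"ss"`, the score).
#' @export
judge_flexibility <- function(trial, fit, n_bins = 50, xi = NULL) {
  stopifnot(inherits(trial, "spb_trial"), inherits(fit, "sctrnnpb"))
  if (any(!is.finite(trial$pb)))
    stop("incomplete trial", call. = FALSE)
  if (is.null(xi)) xi <- success_threshold(fit$dataset, n_bins = n_bins)
  targets <- dataset_sequences(fit$dataset, "train", trial$post_behavior)
  ss <- min(vapply(targets, function(tg) {
    tr <- run_closed_loop(fit$params, trial$u_pb_final, unclass(tg)[1, ],
                          nrow(tg) - 1)
    best_match_ss(tr$y, targets, n_bins = n_bins)
  }, numeric(1)))
  structure(ss < xi, ss = ss, xi = xi)
}

#' Judge generalization during the pre-switch phase
#'
#' The commanded joint trajectory of the trial's generalization phase (the
#' first `pre_steps` steps, before the situation switch) is compared by
#' similarity score against the proprioceptive channels of the initial
#' behavior's training data; success below xi.
#'
#' @param trial an [interaction_trial()] result.
#' @param fit the fitted `"sctrnnpb"` that produced the trial.
#' @param pre_steps length of the generalization phase (default 100; must
#'   not extend past the switch).
#' @param n_bins histogram resolution.
#' @param xi success threshold.
#' @return logical (with attribute `"ss"`).
#' @export
judge_generalization <- function(trial, fit, pre_steps = 100, n_bins = 50,
                                 xi = NULL) {
  stopifnot(inherits(trial, "spb_trial"))
  pre_steps <- min(pre_steps, trial$switch_step - 1)
  if (is.null(xi)) xi <- success_threshold(fit$dataset, n_bins = n_bins)
  gen <- trial$commands[seq_len(pre_steps), , drop = FALSE]
  targets <- dataset_sequences(fit$dataset, "train", trial$initial_behavior)
  ip <- proprio_idx(seq_roles(targets[[1]]))
  ss <- min(vapply(targets, function(tg)
    similarity_score(gen, unclass(tg)[, ip, drop = FALSE],
                     dims = seq_along(ip), n_bins = n_bins)$ss,
    numeric(1)))
  structure(ss < xi, ss = ss, xi = xi)
}

#' Train/test prediction error and estimated sensory variance
#'
#' Teacher-forced passes over every sequence of the dataset; reports the
#' mean squared error between mean prediction and target and the mean
#' predicted variance, averaged over steps, channels and sequences, per
#' split.  Training sequences use their own trained PB states; test
#' sequences use the trained PB state of their behavior.  Low training error
#' combined with high test error and variance estimates below the injected
#' noise floor is the overfitting-to-sensory-noise signature.
#'
#' @param fit a fitted `"sctrnnpb"`.
#' @param dataset dataset to evaluate on (defaults to the training dataset).
#' @return list with `train_error`, `test_error`, `train_variance`,
#'   `test_variance` and `per_sequence` (a data frame).
#' @export
overfitting_metrics <- function(fit, dataset = fit$dataset) {
  stopifnot(inherits(fit, "sctrnnpb"))
  train_ids <- names(dataset_sequences(fit$dataset, "train"))
  rows <- lapply(names(dataset$sequences), function(id) {
    x <- dataset$sequences[[id]]
    b <- attr(x, "behavior")
    pb <- if (id %in% train_ids) fit$params$u0_pb[, match(id, train_ids)]
          else behavior_pb(fit, b)
    tr <- run_open_loop(fit$params, pb, x)
    e <- unclass(x)[-1, , drop = FALSE] - tr$y
    data.frame(id = id, behavior = b, split = attr(x, "split"),
               mse = mean(e^2), mean_variance = mean(tr$v))
  })
  per_sequence <- do.call(rbind, rows)
  agg <- function(split, col) {
    v <- per_sequence[per_sequence$split == split, col]
    if (length(v)) mean(v) else NA_real_
  }
  list(train_error = agg("train", "mse"), test_error = agg("test", "mse"),
       train_variance = agg("train", "mean_variance"),
       test_variance = agg("test", "mean_variance"),
       per_sequence = per_sequence)
}

#' Prediction-error map over parametric-bias activity space
#'
#' Evaluates, on a grid over the PB activity square (-1, 1)^2, the
#' teacher-forced mean squared prediction error against one behavior's
#' training sequences (grid activities are converted to internal states by
#' atanh; the |activity| = 1 boundary nodes are excluded).  The low-error
#' basin encoding the behavior is summarized by its area fraction (cells
#' with error below `threshold_factor` times the minimum cell error) and
#' centroid.
#'
#' @param fit a fitted `"sctrnnpb"` with 2 PB neurons.
#' @param behavior behavior whose training data define the error.
#' @param resolution grid nodes per axis including the excluded boundary
#'   (default 41).
#' @param threshold_factor multiple of the minimum error that delimits the
#'   basin (default 2).
#' @return an object of class `"spb_pbmap"`: list with `p1`, `p2` (interior
#'   grid activities), `error` (matrix), `area_fraction`, `centroid`,
#'   `min_error`, `behavior`.
#' @export
pb_error_map <- function(fit, behavior, resolution = 41,
                         threshold_factor = 2) {
  stopifnot(inherits(fit, "sctrnnpb"))
  if (nrow(fit$params$u0_pb) != 2)
    stop("PB error maps require exactly 2 PB neurons", call. = FALSE)
  check_scalar_num(resolution, "resolution", lower = 11)
  grid <- seq(-1, 1, length.out = resolution)
  interior <- abs(grid) < 1
  p <- grid[interior]
  targets <- dataset_sequences(fit$dataset, "train", behavior)
  err <- matrix(NA_real_, length(p), length(p))
  for (i in seq_along(p)) for (j in seq_along(p)) {
    u <- atanh(c(p[i], p[j]))
    err[i, j] <- mean(vapply(targets, function(tg) {
      tr <- run_open_loop(fit$params, u, tg)
      mean((unclass(tg)[-1, , drop = FALSE] - tr$y)^2)
    }, numeric(1)))
  }
  basin <- err < threshold_factor * min(err)
  centroid <- c(mean(p[row(err)[basin]]), mean(p[col(err)[basin]]))
  structure(list(p1 = p, p2 = p, error = err,
                 area_fraction = mean(basin), centroid = centroid,
                 min_error = min(err), behavior = behavior,
                 threshold_factor = threshold_factor),
            class = "spb_pbmap")
}

#' @export
print.spb_pbmap <- function(x, ...) {
  cat(sprintf(
    "PB error map ('%s'): %dx%d cells, min error %.3g, basin area %.3f, centroid (%.2f, %.2f)\n",
    x$behavior, length(x$p1), length(x$p2), x$min_error, x$area_fraction,
    x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' @export
plot.spb_pbmap <- function(x, ...) {
  graphics::image(x$p1, x$p2, log10(x$error), xlab = "PB1", ylab = "PB2",
                  main = sprintf("log10 prediction error ('%s')",
                                 x$behavior), ...)
  graphics::points(x$centroid[1], x$centroid[2], pch = 3)
  invisible(x)
}

#' Distance between the PB representations of the two behaviors
#'
#' Euclidean distance in activity space between the basin centroids of the
#' two behaviors' error maps.
#'
#' @param map_left,map_right `"spb_pbmap"` objects for the two behaviors.
#' @return scalar distance.
#' @export
pb_map_distance <- function(map_left, map_right) {
  sqrt(sum((map_left$centroid - map_right$centroid)^2))
}

#' Distribution statistics of recurrent synaptic weights
#'
#' Pools the context-to-context weights of one or more fitted networks (one
#' heterogeneity condition) and reports the spread of the distribution and
#' the fraction of weak connections -- overdeveloped synapses show up as a
#' broader distribution with fewer weak weights.
#'
#' @param fits a fitted `"sctrnnpb"` or list of fits.
#' @param weak absolute-value threshold below which a weight counts as weak.
#' @param breaks histogram bin edges (weights outside are clamped into the
#'   end bins).
#' @return list with `sd`, `frac_weak`, `mids`, `density`, `n_models`,
#'   `n_weights`.
#' @export
weight_distribution_stats <- function(fits, weak = 0.01,
                                      breaks = seq(-2, 2, by = 0.05)) {
  if (inherits(fits, "sctrnnpb")) fits <- list(fits)
  w <- unlist(lapply(fits, function(f) as.numeric(f$params$W_cc)))
  wc <- pmax(pmin(w, max(breaks)), min(breaks))
  h <- graphics::hist(wc, breaks = breaks, plot = FALSE)
  list(sd = sd(w), frac_weak = mean(abs(w) < weak), mids = h$mids,
       density = h$density, n_models = length(fits), n_weights = length(w))
}

#' Periodicity index of context-neuron activity
#'
#' For each context neuron of a closed-loop trace, the ratio of spectral
#' power at the template frequency (+-1 frequency bin) to total power
#' (excluding the mean).  Near 1 for a pure oscillation at the template
#' period; near the reciprocal number of frequency bins for white noise.
#'
#' @param trace an `"sctrnnpb_trace"` covering at least 3 periods.
#' @param period template period in steps.
#' @return numeric vector, one index per context neuron.
#' @export
context_periodicity <- function(trace, period) {
  stopifnot(inherits(trace, "sctrnnpb_trace"))
  C <- trace$context
  T_ <- nrow(C)
  if (T_ < 3 * period)
    stop("trace must cover at least 3 periods", call. = FALSE)
  nf <- floor(T_ / 2)
  k0 <- round(T_ / period)
  band <- pmax(1, k0 - 1):pmin(nf, k0 + 1)
  apply(C, 2, function(x) {
    p <- Mod(fft(x - mean(x)))^2
    spec <- p[2:(nf + 1)]
    tot <- sum(spec)
    if (tot == 0) return(0)
    sum(spec[band]) / tot
  })
}
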