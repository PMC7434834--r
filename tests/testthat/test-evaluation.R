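test_that("state histograms partition (-1, 1) and normalize exactly", {
  h <- state_histogram(rep(0, 100), n_bins = 50)
  expect_equal(sum(h$prob), 1)
  expect_equal(which.max(h$counts), 26)  # the bin containing 0+
  expect_equal(sum(h$counts), 100)

  centers <- seq(-1, 1, length.out = 101)[seq(2, 100, by = 2)]
  h2 <- state_histogram(centers, n_bins = 50, pseudo = 0)
  expect_equal(h2$prob, rep(1 / 50, 50))

  x <- with_seed(1, pmax(pmin(rnorm(1000, 0, 0.3), 0.99), -0.99))
  expect_equal(sum(state_histogram(x)$prob), 1)
  expect_error(state_histogram(c(0, 1.5)), "inside")
})

test_that("KL divergence matches closed forms and a summation oracle", {
  x <- with_seed(2, runif(500, -0.9, 0.9))
  p <- state_histogram(x)
  expect_equal(kl_divergence(p, p), 0)

  # two bins, no smoothing: KL((1,0) || (.5,.5)) = ln 2
  p2 <- state_histogram(rep(-0.5, 10), n_bins = 2, pseudo = 0)
  q2 <- state_histogram(c(-0.5, 0.5), n_bins = 2, pseudo = 0)
  expect_equal(kl_divergence(p2, q2), log(2))

  y <- with_seed(3, runif(500, -0.9, 0.9))
  q <- state_histogram(y)
  direct <- sum(p$prob * log(p$prob / q$prob))
  expect_equal(kl_divergence(p, q), direct, tolerance = 1e-12)
  expect_gte(kl_divergence(p, q), 0)
  expect_error(kl_divergence(p, state_histogram(y, n_bins = 40)),
               "binning")
})

test_that("similarity scores separate behaviors and match brute force", {
  spec <- desk_spec()
  right <- behavior_template(spec, "right")
  left <- behavior_template(spec, "left")
  expect_equal(similarity_score(right, right)$ss, 0)
  expect_gt(similarity_score(left, right)$ss, 0)

  ss <- similarity_score(left, right)
  brute <- sum(vapply(proprio_idx <- which(seq_roles(right) == "proprio"),
                      function(d) {
    p <- state_histogram(unclass(left)[, d])
    q <- state_histogram(unclass(right)[, d])
    sum(p$prob * log(p$prob / q$prob))
  }, numeric(1)))
  expect_equal(ss$ss, brute, tolerance = 1e-12)
  expect_equal(length(ss$per_dim), 10)
  expect_error(similarity_score(right[0, ], right), "empty")
})

test_that("the success threshold halves the minimum cross-behavior score", {
  ds <- desk_dataset()
  xi <- success_threshold(ds)
  expect_gt(xi, 0)
  # oracle recomputation over ordered cross-behavior pairs
  lt <- dataset_sequences(ds, "train", "left")
  rt <- dataset_sequences(ds, "train", "right")
  ss <- c()
  for (a in lt) for (b in rt)
    ss <- c(ss, similarity_score(a, b)$ss, similarity_score(b, a)$ss)
  expect_equal(xi, 0.5 * min(ss), tolerance = 1e-12)

  # degenerate dataset: both behaviors share the same training data
  dg <- ds
  for (id in names(dg$sequences)) {
    if (attr(dg$sequences[[id]], "behavior") == "left") {
      twin <- sub("left", "right", id)
      x <- dg$sequences[[twin]]
      attr(x, "behavior") <- "left"
      dg$sequences[[id]] <- x
    }
  }
  expect_warning(xi0 <- success_threshold(dg), "degenerate")
  expect_equal(xi0, 0)
  expect_error(success_threshold(
    structure(list(sequences = rt, spec = ds$spec), class = "spb_dataset")),
    "both behaviors")
})

test_that("overfitting metrics are zero for a perfect predictor", {
  # all-zero network on all-zero sequences predicts exactly
  p <- zero_params(n_input = 2)
  mk <- function(split, behavior, id) {
    x <- matrix(0, 10, 2)
    attributes(x) <- c(attributes(x), list(
      roles = c("proprio", "vision"), behavior = behavior, split = split))
    x
  }
  ds <- structure(list(sequences = list(a = mk("train", "right"),
                                        b = mk("test", "right"),
                                        c = mk("train", "left")),
                       spec = NULL), class = "spb_dataset")
  fit <- structure(list(params = p, dataset = ds,
                        behaviors = c("right", "left"),
                        config = desk_config()), class = "sctrnnpb")
  fit$params$u0_pb <- matrix(0, 2, 2)
  om <- overfitting_metrics(fit)
  expect_equal(om$train_error, 0)
  expect_equal(om$test_error, 0)
  expect_equal(om$train_variance, 1)  # v = exp(0)
})

test_that("PB error maps are lowest near the trained intention", {
  exp <- desk_experiment()
  ids10 <- exp$sweep$manifest$id[exp$sweep$manifest$k == 10 &
                                   exp$sweep$manifest$converged]
  fit <- exp$sweep$fits[[ids10[1]]]
  map <- exp$maps[[ids10[1]]]$right
  # grid counting: resolution 21 leaves 19 interior nodes per axis
  expect_equal(dim(map$error), c(19, 19))
  expect_true(all(is.finite(map$error)))
  expect_true(map$area_fraction > 0 && map$area_fraction < 1)
  # the cell nearest the trained PB activity sits in the low-error basin
  pb <- tanh(behavior_pb(fit, "right"))
  i <- which.min(abs(map$p1 - pb[1]))
  j <- which.min(abs(map$p2 - pb[2]))
  expect_lt(map$error[i, j], map$threshold_factor * map$min_error)
})

test_that("weight statistics recover the initialization distribution", {
  cfg <- desk_config(k = 10)
  fake_fits <- lapply(1:4, function(s)
    list(params = init_network(cfg, seed = s)))
  ws <- weight_distribution_stats(fake_fits)
  b <- 1 / sqrt(30)
  expect_equal(ws$sd, b / sqrt(3), tolerance = 0.05)
  expect_equal(ws$frac_weak, 0.01 / b, tolerance = 0.05)
  expect_equal(ws$n_weights, 4 * 900)
})

test_that("the periodicity index separates oscillation from noise", {
  mk_trace <- function(C) structure(list(context = C, mode = "closed_loop"),
                                    class = "sctrnnpb_trace")
  t_ <- seq_len(200)
  pure <- mk_trace(cbind(sin(2 * pi * t_ / 40), cos(2 * pi * t_ / 40)))
  idx <- context_periodicity(pure, period = 40)
  expect_true(all(idx > 0.99))
  noise <- mk_trace(with_seed(4, matrix(rnorm(400), 200, 2)))
  idx_n <- context_periodicity(noise, period = 40)
  expect_true(all(idx_n < 0.3))
  expect_error(context_periodicity(mk_trace(matrix(0, 50, 1)), period = 40),
               "3 periods")
})

test_that("flexibility and generalization judgments are behavior-consistent", {
  exp <- desk_experiment()
  fit <- best_fit(exp$sweep, 10)
  mk_trial <- function(u_pb, post) structure(list(
    pb = matrix(tanh(u_pb), 1, 2), u_pb_final = u_pb,
    post_behavior = post,
    initial_behavior = setdiff(c("right", "left"), post),
    switch_step = 120, trial_length = 300), class = "spb_trial")
  # intention parked at the new behavior: recognized
  expect_true(judge_flexibility(mk_trial(behavior_pb(fit, "left"), "left"),
                                fit))
  # intention stuck at the old behavior: not recognized
  expect_false(judge_flexibility(mk_trial(behavior_pb(fit, "right"), "left"),
                                 fit))

  # command playback of the correct behavior template passes generalization;
  # a frozen arm does not
  tm <- behavior_template(exp$dataset$spec, "right")
  stub <- structure(list(commands = unclass(tm)[1:100, 1:8],
                         initial_behavior = "right", switch_step = 120),
                    class = "spb_trial")
  expect_true(judge_generalization(stub, fit))
  stub$commands <- matrix(0.1, 100, 8)
  expect_false(judge_generalization(stub, fit))
})
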