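test_that("PB adaptation is stationary at zero prediction error", {
  # all-zero network: window regeneration predicts 0 with v = 1; observing
  # exactly 0 leaves no error, so the PB state must not move
  p <- zero_params(n_input = 3)
  obs <- matrix(0, 5, 3)
  res <- adapt_pb_window(p, u_pb = c(0.2, -0.1), velocity = c(0, 0),
                         u_anchor = rep(0, 3), x_anchor = rep(0, 3),
                         observations = obs, dims = 3, iterations = 10,
                         alpha = 0.01, eta = 0.9)
  expect_equal(drop(res$u_pb), c(0.2, -0.1))
  expect_equal(drop(res$velocity), c(0, 0))
  expect_error(adapt_pb_window(p, c(0, 0), c(0, 0), rep(0, 3), rep(0, 3),
                               matrix(0, 0, 3), 3, 1), "buffer")
})

test_that("the PB window gradient matches finite differences", {
  ts <- tiny_setup(T_ = 5, S = 1, seed = 11)
  obs <- with_seed(12, matrix(runif(9 * 3, -0.5, 0.5), 9, 3))
  u_anchor <- with_seed(13, runif(4, -0.5, 0.5))
  x_anchor <- c(0.1, -0.2, 0.3)
  u_pb <- c(0.15, -0.25)
  dims <- 2:3
  # one plain gradient step of size alpha reveals the compiled gradient
  a <- 1e-6
  res <- adapt_pb_window(ts$params, u_pb, c(0, 0), u_anchor, x_anchor,
                         obs, dims, iterations = 1, alpha = a, eta = 0)
  g_cpp <- -(drop(res$u_pb) - u_pb) / a
  h <- 1e-5
  for (i in 1:2) {
    up <- u_pb; up[i] <- up[i] + h
    um <- u_pb; um[i] <- um[i] - h
    fd <- (window_loss_R(ts$params, up, u_anchor, x_anchor, obs, dims) -
             window_loss_R(ts$params, um, u_anchor, x_anchor, obs, dims)) /
      (2 * h)
    expect_lt(abs(g_cpp[i] - fd) / max(abs(fd), 1e-6), 1e-4)
  }
  # the reported windowed loss matches the R reference
  res0 <- adapt_pb_window(ts$params, u_pb, c(0, 0), u_anchor, x_anchor,
                          obs, dims, iterations = 0)
  expect_equal(res0$loss,
               window_loss_R(ts$params, u_pb, u_anchor, x_anchor, obs, dims),
               tolerance = 1e-10)
})

test_that("inflating a channel's predicted variance damps its PB drive", {
  ts <- tiny_setup(T_ = 5, S = 1, seed = 21)
  # silence the variance pathway so only the precision-weighted error term
  # (-e / v) drives the PB gradient
  ts$params$W_cv[] <- 0
  obs <- with_seed(22, matrix(runif(9 * 3, -0.5, 0.5), 9, 3))
  u_anchor <- rep(0, 4)
  x_anchor <- c(0.2, 0, -0.2)
  grad_norm <- function(params) {
    a <- 1e-7
    res <- adapt_pb_window(params, c(0.1, 0.1), c(0, 0), u_anchor, x_anchor,
                           obs, dims = 3, iterations = 1, alpha = a, eta = 0)
    sqrt(sum(((drop(res$u_pb) - c(0.1, 0.1)) / a)^2))
  }
  inflated <- ts$params
  inflated$b_v[3] <- inflated$b_v[3] + log(10)  # 10x predicted variance
  expect_lt(grad_norm(inflated), grad_norm(ts$params))
})

test_that("interaction trials log a complete, causal, weight-frozen record", {
  exp <- desk_experiment()
  fit <- best_fit(exp$sweep, 10)
  spec <- exp$dataset$spec
  params_before <- fit$params
  env <- interaction_env(spec, "right", switch_step = 120,
                         trial_length = 300, seed = 5)
  trial <- interaction_trial(fit, env)
  expect_s3_class(trial, "spb_trial")
  expect_equal(nrow(trial$pb), 300)
  expect_identical(fit$params, params_before)   # weights frozen
  # PB held at the trained intention through the warm-up
  W <- fit$config$window
  pb0 <- tanh(behavior_pb(fit, "right"))
  for (t in seq_len(W))
    expect_equal(trial$pb[t, ], pb0, tolerance = 1e-12)
  expect_true(all(is.na(trial$pwpe[seq_len(W)])))
  expect_true(all(is.finite(trial$pwpe[(W + 1):300])))

  # postdiction locality: perturbing the environment after step t must not
  # change anything logged up to step t
  env_a <- interaction_env(spec, "right", switch_step = 120,
                           trial_length = 300, seed = 6)
  env_b <- interaction_env(spec, "right", switch_step = 120,
                           trial_length = 300, seed = 6)
  env_b$noise[201:300, ] <- env_b$noise[201:300, ] + 0.5
  tr_a <- interaction_trial(fit, env_a)
  tr_b <- interaction_trial(fit, env_b)
  expect_identical(tr_a$pb[1:200, ], tr_b$pb[1:200, ])
  expect_identical(tr_a$commands[1:200, ], tr_b$commands[1:200, ])
  expect_false(isTRUE(all.equal(tr_a$pb[201:300, ], tr_b$pb[201:300, ])))
})

test_that("a matched intention keeps the windowed error at self-consistency", {
  # no switch is impossible (the environment always switches once), so park
  # the switch at the last step: steps 1..299 are an unchanged situation
  exp <- desk_experiment()
  fit <- best_fit(exp$sweep, 10)
  spec <- exp$dataset$spec
  env <- interaction_env(spec, "right", switch_step = 299,
                         trial_length = 300, jitter = 0, seed = 7)
  trial <- interaction_trial(fit, env)
  # reference: windowed NLL of the matched training data under open loop
  tr <- dataset_sequences(fit$dataset, "train", "right")
  ref <- unlist(lapply(seq_along(tr), function(s) {
    ol <- run_open_loop(fit$params, fit$params$u0_pb[, names(tr)[s]],
                        tr[[s]])
    iv <- which(seq_roles(tr[[s]]) == "vision")
    ls <- rowSums(ol$loss[, iv, drop = FALSE])
    w <- fit$config$window - 1
    vapply(seq_len(length(ls) - w + 1), function(i) sum(ls[i:(i + w - 1)]),
           numeric(1))
  }))
  pre <- trial$pwpe[(fit$config$window + 1):298]
  expect_lt(stats::median(pre), stats::quantile(ref, 0.95))
})
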