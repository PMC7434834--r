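test_that("parameter initialization respects the stated intervals", {
  cfg <- sctrnnpb_config(k = 10)  # full scale: 100 context neurons
  p <- init_network(cfg, n_sequences = 3, seed = 1)
  expect_true(all(abs(p$W_xc) <= 1 / sqrt(10)))
  expect_true(all(abs(p$W_cc) <= 1 / sqrt(100)))
  expect_true(all(abs(p$W_pc) <= 1 / sqrt(100)))
  expect_true(all(abs(p$W_cm) <= 1 / sqrt(100)))
  expect_true(all(abs(p$W_cv) <= 1 / sqrt(100)))
  expect_true(all(abs(p$b_m) <= 1) && all(abs(p$b_v) <= 1))
  expect_identical(p$u0_pb, matrix(0, 2, 3))
  # chi-square bounds: sample variance of 100 N(0, 10) draws in [4, 20]
  expect_gt(var(p$b_c), 4)
  expect_lt(var(p$b_c), 20)
  # pure function of (config, seed)
  expect_identical(p, init_network(cfg, n_sequences = 3, seed = 1))

  p0 <- init_network(sctrnnpb_config(k = 0, bias_mean = 0.5), seed = 2)
  expect_identical(p0$b_c, rep(0.5, 100))
  expect_error(sctrnnpb_config(k = -1), "k")
})

test_that("forward_step implements the leaky-integrator dynamics", {
  # all-zero parameters: c = 0, y = 0, v = exp(0) = 1
  p <- zero_params()
  st <- list(u_context = rep(0, 3), u_pb = c(0, 0))
  out <- forward_step(p, st, c(0.3, -0.2))
  expect_equal(out$c, rep(0, 3))
  expect_equal(out$y, rep(0, 2))
  expect_equal(out$v, rep(1, 2))
  expect_identical(out$u_pb, st$u_pb)  # PB states never move in a forward pass

  # single context neuron, tau = 4, zero weights, bias 4: u = 4/4 + 0 = 1
  p1 <- zero_params(n_input = 1, n_context = 1, b_c = 4)
  out <- forward_step(p1, list(u_context = 0, u_pb = c(0, 0)), 0)
  expect_equal(out$u_context, 1)

  # tau = 1, input weight 1, x = 0.5: u = 0.5, c = tanh(0.5)
  p2 <- zero_params(n_input = 1, n_context = 1, tau = 1)
  p2$W_xc[1, 1] <- 1
  out <- forward_step(p2, list(u_context = 0, u_pb = c(0, 0)), 0.5)
  expect_equal(out$u_context, 0.5)
  expect_equal(out$c, tanh(0.5))

  expect_error(forward_step(p, st, c(NA, 1)), "non-finite")
})

test_that("the compiled open-loop pass matches the R reference step", {
  ts <- tiny_setup(T_ = 8, S = 1)
  tr <- run_open_loop(ts$params, ts$u0[, 1], ts$seqs[[1]])
  expect_equal(nrow(tr$y), 7)  # T - 1 prediction steps
  st <- list(u_context = rep(0, 4), u_pb = ts$u0[, 1])
  for (t in 1:7) {
    st <- forward_step(ts$params, st, ts$seqs[[1]][t, ])
    expect_equal(unname(tr$y[t, ]), unname(st$y), tolerance = 1e-12)
    expect_equal(unname(tr$v[t, ]), unname(st$v), tolerance = 1e-12)
    expect_equal(unname(tr$u_context[t, ]), unname(st$u_context),
                 tolerance = 1e-12)
  }
  # determinism: bit-identical traces
  expect_identical(tr, run_open_loop(ts$params, ts$u0[, 1], ts$seqs[[1]]))
  expect_error(run_open_loop(ts$params, ts$u0[, 1],
                             ts$seqs[[1]][1, , drop = FALSE]), "2 steps")
})

test_that("stepwise and sequence NLL follow the Gaussian closed forms", {
  expect_equal(stepwise_nll(c(0.2, -0.1), c(1, 1), c(0.2, -0.1)),
               rep(log(2 * pi) / 2, 2))
  # minimizer over v of the per-step loss is v* = e^2
  e <- 0.3
  vs <- seq(0.01, 1, by = 0.001)
  ls <- stepwise_nll(0, vs, e)
  expect_equal(vs[which.min(ls)], e^2, tolerance = 2e-3)
  expect_equal(stepwise_nll(0, 0.01, 0.1), 0.5 * log(2 * pi * 0.01) + 0.5)
  expect_error(stepwise_nll(0, 0, 0), "variance")

  # zero-error unit-variance network: loss = (T-1) * D * ln(2 pi) / 2
  p <- zero_params()
  x <- matrix(0, 6, 2)
  tr <- run_open_loop(p, c(0, 0), x)
  expect_equal(sequence_nll(tr), 5 * 2 * log(2 * pi) / 2)
  # additivity over a duplicated dataset
  expect_equal(sequence_nll(list(tr, tr)), 2 * sequence_nll(tr))
})

test_that("closed-loop generation feeds predictions back as inputs", {
  ts <- tiny_setup(T_ = 4, S = 1)
  one <- run_closed_loop(ts$params, ts$u0[, 1], c(0.1, 0.2, -0.1), 1)
  expect_equal(nrow(one$y), 1)

  # all-zero network: y = 0 is a fixed point, trace constant
  p <- zero_params()
  tr <- run_closed_loop(p, c(0, 0), c(0.5, -0.5), 10)
  expect_true(all(tr$y == 0))

  # feedback check against the R reference
  tr <- run_closed_loop(ts$params, ts$u0[, 1], c(0.1, 0.2, -0.1), 5)
  st <- list(u_context = rep(0, 4), u_pb = ts$u0[, 1])
  x <- c(0.1, 0.2, -0.1)
  for (t in 1:5) {
    st <- forward_step(ts$params, st, x)
    expect_equal(unname(tr$y[t, ]), unname(st$y), tolerance = 1e-12)
    x <- st$y
  }
})

test_that("BPTT gradients match central finite differences on a tiny net", {
  ts <- tiny_setup(T_ = 5, S = 2)
  g <- bptt_gradients(ts$params, ts$seqs, ts$u0)
  loss_fn <- function(params, u0) {
    sum(vapply(1:2, function(s)
      sum(run_open_loop(params, u0[, s], ts$seqs[[s]])$loss), numeric(1)))
  }
  h <- 1e-5
  for (nm in names(g)) {
    tgt <- if (nm == "u0_pb") ts$u0 else ts$params[[nm]]
    for (i in seq_along(tgt)) {
      bump <- function(d) {
        tb <- tgt; tb[i] <- tb[i] + d
        if (nm == "u0_pb") loss_fn(ts$params, tb)
        else { pb <- ts$params; pb[[nm]] <- tb; loss_fn(pb, ts$u0) }
      }
      fd <- (bump(h) - bump(-h)) / (2 * h)
      expect_lt(abs(g[[nm]][i] - fd) / max(abs(fd), 1e-6), 1e-4)
    }
  }
  # no gradient block for the frozen context biases
  expect_false("b_c" %in% names(g))
  expect_false("tau" %in% names(g))
})

test_that("PB gradients are separable across sequences", {
  ts <- tiny_setup(T_ = 5, S = 2)
  g1 <- bptt_gradients(ts$params, ts$seqs, ts$u0)
  seqs_mod <- ts$seqs
  seqs_mod[[2]] <- matrix(runif(15, -0.5, 0.5), 5, 3)
  g2 <- bptt_gradients(ts$params, seqs_mod, ts$u0)
  expect_equal(g1$u0_pb[, 1], g2$u0_pb[, 1])
  expect_false(isTRUE(all.equal(g1$u0_pb[, 2], g2$u0_pb[, 2])))
})

test_that("momentum updates follow the two-term recursion", {
  ts <- tiny_setup()
  g <- bptt_gradients(ts$params, ts$seqs, ts$u0)
  # eta = 0: plain gradient descent
  up <- momentum_update(ts$params, g, alpha = 0.01, eta = 0)
  expect_equal(up$params$W_xc, ts$params$W_xc - 0.01 * g$W_xc)
  # zero gradient with prior velocity d: step is eta * d
  g0 <- lapply(g, function(x) x * 0)
  d <- lapply(g, function(x) x * 0 + 0.5)
  up0 <- momentum_update(ts$params, g0, velocity = d, alpha = 0.01, eta = 0.9)
  expect_equal(up0$params$b_m, ts$params$b_m + 0.45)
  # two epochs at constant gradient: cumulative change -alpha g (1 + 1.9)
  u1 <- momentum_update(ts$params, g, alpha = 0.01, eta = 0.9)
  u2 <- momentum_update(u1$params, g, velocity = u1$velocity,
                        alpha = 0.01, eta = 0.9)
  expect_equal(u2$params$W_cm, ts$params$W_cm - 0.01 * g$W_cm * (1 + 1.9))
  # context biases never touched
  expect_identical(u2$params$b_c, ts$params$b_c)
})

test_that("loss is non-increasing under plain gradient descent", {
  ts <- tiny_setup(T_ = 6, S = 1)
  params <- ts$params
  params$u0_pb <- ts$u0[, 1, drop = FALSE]
  losses <- numeric(100)
  vel <- NULL
  for (i in 1:100) {
    g <- bptt_gradients(params, ts$seqs[1])
    losses[i] <- attr(g, "loss")
    up <- momentum_update(params, g, velocity = vel, alpha = 1e-4, eta = 0)
    params <- up$params
    vel <- up$velocity
  }
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("a variance-only toy recovers the injected noise floor", {
  # i.i.d. N(0, 0.01) targets: the optimal prediction is y ~ 0, v ~ 0.01
  cfg <- sctrnnpb_config(n_input = 1, n_context = 3, n_pb = 1, k = 1,
                         n_epochs = 20000, alpha = 1e-5)
  x <- with_seed(9, matrix(pmax(pmin(rnorm(300, 0, 0.1), 0.9), -0.9), 300, 1))
  params <- init_network(cfg, n_sequences = 1, seed = 3)
  res <- sctrnnpb:::cpp_train(unclass(params), params$u0_pb,
                              array(x, c(300, 1, 1)), cfg$n_epochs,
                              cfg$alpha, cfg$eta, 1000L)
  tr <- run_open_loop(structure(res$params, class = "sctrnnpb_params"),
                      res$u0_pb[, 1], x)
  expect_lt(abs(mean(tr$v) - 0.01) / 0.01, 0.2)
})
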