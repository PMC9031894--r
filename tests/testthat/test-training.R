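# Loss assembly, regularizers, policy loss and the trainers' contracts.

test_that("firing-rate penalty matches its squared-count definition", {
  # every neuron spiking exactly at the target count gives zero penalty
  n <- 10; B <- 2; T <- 500; f0 <- 10
  target <- f0 / 1000 * B * T
  z <- array(0, c(n, B, T))
  for (j in 1:n) {
    idx <- cbind(j, rep(1:B, each = target / B), seq(1, T, length.out = target))
    z[idx] <- 1
  }
  expect_equal(firing_rate_regularizer(z, f0 = f0), 0, tolerance = 1e-12)
  # brute-force oracle on random rasters, and linearity in mu_f
  set.seed(14)
  z <- array(rbinom(n * B * T, 1, 0.05), c(n, B, T))
  counts <- apply(z, 1, sum)
  brute <- mean((counts - target)^2)
  expect_equal(firing_rate_regularizer(z, f0 = f0), brute, tolerance = 1e-9)
  expect_equal(firing_rate_regularizer(z, f0 = f0, mu_f = 3.7), 3.7 * brute,
               tolerance = 1e-9)
  # matrix (T x n) interface agrees
  z2 <- matrix(rbinom(200 * 4, 1, 0.1), 200, 4)
  expect_equal(firing_rate_regularizer(z2, f0 = f0),
               mean((colSums(z2) - f0 / 1000 * 200)^2), tolerance = 1e-9)
})

test_that("clipped-surrogate policy loss handles ratio-1, clipped and null cases", {
  set.seed(15)
  A <- rnorm(100); lp <- rnorm(100); om <- rnorm(100); v <- rnorm(100)
  same <- ppo_loss(lp, lp, A, om, v)
  expect_equal(same$surrogate, mean(A), tolerance = 1e-12)
  expect_equal(same$value_term, 0.5 * mean((om - v)^2), tolerance = 1e-12)
  expect_equal(same$loss, -same$surrogate + same$value_term, tolerance = 1e-12)
  # ratio pushed far above 1 + eps with positive advantage clips
  big <- ppo_loss(lp + 1, lp, advantages = rep(2, 100), om, v, clip_eps = 0.2)
  expect_equal(big$surrogate, mean(1.2 * 2), tolerance = 1e-12)
  zero <- ppo_loss(lp, lp, rep(0, 100), om, om)
  expect_equal(zero$loss, 0, tolerance = 1e-12)
  expect_error(ppo_loss(1:3, 1:2, 1:3, 1:3, 1:3), "equal length")
})

test_that("supervised training is reproducible, records history and respects lr = 0", {
  src <- function(n) gen_store_recall(n, T = 60)
  cfg <- train_config(lr = 0, K = 4, T = 60, n_iterations = 3, mu_f = 1e-5,
                      seed = 5)
  net <- init_network(network_config(40, 20, 1, seed = 5))
  res <- train_supervised(net, src, cfg)
  expect_s3_class(res, "snn_training")
  expect_equal(nrow(res$history), 3)
  expect_true(all(is.finite(res$history$loss)))
  # lr = 0: parameters and per-iteration losses cannot move
  expect_identical(res$net$proj$rec_m$W, net$proj$rec_m$W)
  expect_identical(res$net$W_out, net$W_out)
  cfg2 <- train_config(lr = 0.005, K = 4, T = 60, n_iterations = 3,
                       mu_f = 1e-5, seed = 5)
  r1 <- train_supervised(net, src, cfg2)
  r2 <- train_supervised(net, src, cfg2)
  expect_identical(r1$history, r2$history)
  expect_false(identical(r1$net$W_out, net$W_out))
})

test_that("pure-RMEE and pure-CE criteria pull the weights in different directions", {
  src <- function(n) gen_store_recall(n, T = 60)
  net <- init_network(network_config(40, 20, 1, seed = 6))
  w_mu1 <- train_supervised(net, src, train_config(mu = 1, lr = 0.01, K = 4,
    T = 60, n_iterations = 1, mu_f = 0, seed = 6))$net$W_out
  w_mu0 <- train_supervised(net, src, train_config(mu = 0, lr = 0.01, K = 4,
    T = 60, n_iterations = 1, mu_f = 0, seed = 6))$net$W_out
  expect_false(identical(w_mu1, net$W_out))
  expect_false(identical(w_mu0, net$W_out))
  expect_false(identical(w_mu1, w_mu0))
})

test_that("the firing-rate regularizer alone steers rates toward the target", {
  # constant Poisson drive, loss = rate penalty only; after 100 updates the
  # gap to f0 = 10 Hz should shrink several-fold and the rate should land in
  # the sane [2, 50] Hz band. (Exact factor-2 convergence is not attainable
  # with a pure count penalty: once neurons fall out of the surrogate
  # derivative's support the gradient stalls.)
  set.seed(16)
  T <- 200
  net <- init_network(network_config(10, 30, 1, sparsity = 0.3, seed = 16))
  cfg <- train_config(lr = 0.01, mu_f = 1 / T^2, f0 = 10)
  X <- array(rbinom(10 * 1 * T, 1, 0.3), c(10, 1, T))
  rate0 <- mean_rate_hz(simulate_forward(net, X, collect = FALSE))
  opt <- spikemee:::adam_init(c(lapply(net$proj, `[[`, "W"),
                                list(W_out = net$W_out, b_out = net$b_out)))
  for (it in 1:100) {
    sim <- simulate_forward(net, X)
    gz <- spikemee:::rate_reg_grad(sim, cfg$f0, cfg$mu_f, 1)
    grads <- bptt_gradients(net, sim, array(0, c(1, 1, T)), gz)
    net <- spikemee:::apply_update(net, grads, opt, cfg)
    opt <- attr(net, "opt"); attr(net, "opt") <- NULL
  }
  final_rate <- mean_rate_hz(simulate_forward(net, X, collect = FALSE))
  expect_lt(abs(final_rate - 10), abs(rate0 - 10) / 3)
  expect_gte(final_rate, 2)
  expect_lte(final_rate, 50)
})

test_that("reward learning runs, logs its loss decomposition and is reproducible", {
  net <- init_network(network_config(30, 25, 5, readout_gain = 5, seed = 8))
  net$b_out[3:4] <- -1.5
  cfg <- train_config(lr = 0.005, K = 2, T = 60, n_iterations = 3,
                      mu_f = 1e-5, seed = 8)
  r1 <- train_reward(net, cfg)
  expect_equal(nrow(r1$history), 3)
  expect_true(all(c("ppo_surrogate", "value_term", "rmee_term", "metric")
                  %in% names(r1$history)))
  expect_true(all(is.finite(r1$history$loss)))
  r2 <- train_reward(net, cfg)
  expect_identical(r1$history, r2$history)
})
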