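# Small networks and shared oracles used across test files.

tiny_net <- function(n_in = 2, n_hidden = 3, n_out = 1, sparsity = 1,
                     delay = 2, seed = 7, refractory = 0, boost = 2) {
  cfg <- network_config(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                        sparsity = sparsity, delay = delay, seed = seed)
  net <- init_network(cfg, neuron_params(dt = 1, refractory_steps = refractory))
  # boost weights so the toy dynamics straddle the threshold region
  for (nm in names(net$proj)) net$proj[[nm]]$W <- net$proj[[nm]]$W * boost
  net
}

# Finite-difference check of BPTT against the smoothed surrogate forward:
# returns the worst relative error over every active synapse and readout
# parameter, for a loss that probes all readout times and hidden spikes.
bptt_fd_max_rel_err <- function(net, T = 10, B = 2, h = 1e-6, seed = 42) {
  set.seed(seed)
  cfg <- net$config
  X <- array(rbinom(cfg$n_in * B * T, 1, 0.5), c(cfg$n_in, B, T))
  GL <- array(rnorm(cfg$n_out * B * T), c(cfg$n_out, B, T))
  GZ <- array(rnorm(cfg$n_hidden * B * T, sd = 0.1), c(cfg$n_hidden, B, T))
  loss_fn <- function(nn) {
    s <- simulate_forward(nn, X, surrogate = TRUE)
    sum(GL * s$LAM) + sum(GZ * s$Z)
  }
  g <- bptt_gradients(net, simulate_forward(net, X, surrogate = TRUE), GL, GZ)
  max_rel <- 0
  for (nm in c(names(net$proj), "W_out", "b_out")) {
    idx <- if (nm %in% names(net$proj)) which(net$proj[[nm]]$mask)
           else seq_along(if (nm == "b_out") net$b_out else net$W_out)
    for (i in idx) {
      np <- net; nm_proj <- nm %in% names(net$proj)
      w0 <- if (nm_proj) net$proj[[nm]]$W[i] else net[[nm]][i]
      if (nm_proj) np$proj[[nm]]$W[i] <- w0 + h else np[[nm]][i] <- w0 + h
      lp <- loss_fn(np)
      if (nm_proj) np$proj[[nm]]$W[i] <- w0 - h else np[[nm]][i] <- w0 - h
      lm <- loss_fn(np)
      fd <- (lp - lm) / (2 * h)
      max_rel <- max(max_rel, abs(fd - g[[nm]][i]) / max(abs(fd), abs(g[[nm]][i]), 1e-6))
    }
  }
  max_rel
}

gk <- function(x, s = 1) exp(-x^2 / (2 * s^2)) / (sqrt(2 * pi) * s)

# brute-force O(N^2) information potential
ip_brute <- function(e, s = 1) {
  acc <- 0
  for (i in seq_along(e)) for (j in seq_along(e)) acc <- acc + gk(e[i] - e[j], s)
  acc / length(e)^2
}
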