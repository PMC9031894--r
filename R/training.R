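# Training: surrogate-gradient BPTT with ADAM and deep rewiring, under the
# combined RMEE + cross-entropy criterion (supervised tasks) or the clipped
# policy-gradient loss plus RMEE on value-prediction errors (reward task).

#' Training configuration
#'
#' @param mu weight of the RMEE term in the combined criterion, in
#'   \code{[0, 1]} (\code{1 - mu} weights cross-entropy; in reward learning
#'   \code{mu} weights the RMEE term added to the policy loss).
#' @param mu_f weight of the firing-rate regularizer (see
#'   [firing_rate_regularizer()]; its squared spike-count form grows with the
#'   episode length, so task front-ends scale this weight accordingly).
#' @param f0 target firing rate in Hz.
#' @param sigma RMEE kernel bandwidth.
#' @param lr ADAM learning rate.
#' @param K episodes per training iteration.
#' @param T time steps per episode.
#' @param gamma discount factor for returns.
#' @param clip_eps clipping width of the policy-gradient surrogate.
#' @param mu_v weight of the value-prediction loss.
#' @param n_epochs optimization epochs per collected batch in reward
#'   learning; epochs beyond the first replay the recorded input streams
#'   open-loop under the updated weights, with the probability ratio
#'   clipped at \code{1 +/- clip_eps}.
#' @param n_iterations number of training iterations.
#' @param seed integer seed fixing the whole training run.
#' @return an object of class \code{"train_config"}.
#' @export
train_config <- function(mu = 0.8, mu_f = 1.0, f0 = 10, sigma = 1,
                         lr = 1e-3, K = 10, T = 2000, gamma = 0.99,
                         clip_eps = 0.2, mu_v = 0.5, n_epochs = 1,
                         n_iterations = 100, seed = 1) {
  if (mu < 0 || mu > 1) stop_invalid("mu must lie in [0, 1]")
  check_scalar_pos(f0, "f0"); check_scalar_pos(sigma, "sigma")
  if (gamma < 0 || gamma >= 1) stop_invalid("gamma must lie in [0, 1)")
  structure(list(mu = mu, mu_f = mu_f, f0 = f0, sigma = sigma, lr = lr,
                 K = as.integer(K), T = as.integer(T), gamma = gamma,
                 clip_eps = clip_eps, mu_v = mu_v,
                 n_epochs = as.integer(n_epochs),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Firing-rate regularization penalty
#'
#' \eqn{\mu_f \, n^{-1} \sum_j (\sum_{k,t} z_j(t,k) - f^0 K T)^2}: the squared
#' deviation of each neuron's total spike count from the count expected at
#' the target rate \code{f0} (given in Hz and converted to spikes/step via
#' \code{dt}), averaged over neurons.
#'
#' @param raster an \code{"snn_sim"} or a spike array with neurons in the
#'   first dimension (\code{n x B x T}), or a \code{T x n} matrix.
#' @param f0 target rate (Hz).
#' @param mu_f regularization weight.
#' @param dt step in ms.
#' @return a single non-negative number.
#' @export
firing_rate_regularizer <- function(raster, f0 = 10, mu_f = 1, dt = 1) {
  z <- raster_spikes(raster)
  counts <- rowSums(z, dims = 1L)
  target <- (f0 * dt / 1000) * (length(z) / nrow(z))
  mu_f * mean((counts - target)^2)
}

raster_spikes <- function(raster) {
  if (inherits(raster, "snn_sim")) return(matrix(raster$Z, dim(raster$Z)[1]))
  if (is.matrix(raster)) return(t(raster))          # T x n -> n x T
  if (is.array(raster)) return(matrix(raster, dim(raster)[1]))
  stop_invalid("raster must be a simulation, matrix or array of spikes")
}

# d(penalty)/dz_j(t,k): constant per neuron.
rate_reg_grad <- function(sim, f0, mu_f, dt) {
  z <- raster_spikes(sim)
  counts <- rowSums(z)
  target <- (f0 * dt / 1000) * ncol(z)
  mu_f * (2 / nrow(z)) * (counts - target)
}

#' Clipped-surrogate policy-gradient loss
#'
#' Assembles the policy loss \eqn{-\frac{1}{KT}\sum O^{PPO} + \mu_v
#' \overline{(\Omega - V)^2} - c_H \bar H} from per-step log-densities of the
#' behaviour and current policies, advantages, returns and value estimates,
#' with \eqn{O^{PPO} = \min(r A, \mathrm{clip}(r, 1\pm\epsilon) A)} and
#' \eqn{r = \exp(\log p - \log p_{old})}. With identical policies the ratio
#' is 1 and clipping is inactive.
#'
#' @param logp,logp_old per-step log-densities of the taken actions under the
#'   current and behaviour policies.
#' @param advantages per-step advantages \eqn{\Omega - V}.
#' @param returns,values per-step discounted returns and value predictions.
#' @param clip_eps clipping width.
#' @param mu_v value-loss weight.
#' @param entropy mean policy entropy (optional auxiliary).
#' @param entropy_coef entropy bonus weight.
#' @param weights optional 0/1 step weights (masking padded steps); the
#'   surrogate and value terms are normalized by \code{length(logp)}
#'   regardless, matching the \eqn{1/KT} average over the full horizon.
#' @return list with \code{loss}, \code{surrogate} (the mean of
#'   \eqn{O^{PPO}}), \code{value_term} and \code{entropy_term}.
#' @export
ppo_loss <- function(logp, logp_old, advantages, returns, values,
                     clip_eps = 0.2, mu_v = 0.5, entropy = 0,
                     entropy_coef = 0, weights = NULL) {
  if (length(logp) != length(logp_old) || length(logp) != length(advantages))
    stop_invalid("logp, logp_old and advantages must have equal length")
  if (length(returns) != length(values))
    stop_invalid("returns and values must have equal length")
  w <- weights %||% rep(1, length(logp))
  r <- exp(logp - logp_old)
  obj <- pmin(r * advantages, pmax(pmin(r, 1 + clip_eps), 1 - clip_eps) * advantages)
  surrogate <- sum(w * obj) / length(logp)
  value_term <- mu_v * sum(w * (returns - values)^2) / length(values)
  entropy_term <- -entropy_coef * entropy
  list(loss = -surrogate + value_term + entropy_term,
       surrogate = surrogate, value_term = value_term,
       entropy_term = entropy_term)
}

# ---- supervised training ----------------------------------------------------

# Readout logits and errors for a supervised batch: y[n, b] is the mean
# readout potential over that label's readout window.
batch_logits <- function(sim, batch) {
  nl <- nrow(batch$labels); B <- ncol(batch$labels)
  y <- matrix(0, nl, B)
  for (n in seq_len(nl)) {
    win <- batch$windows[[n]]
    for (b in seq_len(B)) y[n, b] <- mean(sim$LAM[1, b, win[, b]])
  }
  y
}

#' Frozen-weight evaluation of a supervised batch
#'
#' @param net an [init_network()] object.
#' @param batch a \code{"supervised_batch"} from [gen_store_recall()] or
#'   [gen_noisy_sequences()].
#' @return list with \code{prob} (predicted probabilities per label),
#'   \code{pred} (thresholded at 0.5), \code{errors} (label minus
#'   probability) and \code{accuracy}.
#' @export
predict_supervised <- function(net, batch) {
  sim <- simulate_forward(net, batch$X, collect = FALSE)
  y <- batch_logits(sim, batch)
  p <- sigmoid(y)
  list(prob = p, pred = (p >= 0.5) + 0,
       errors = as.numeric(batch$labels - p),
       accuracy = mean(((p >= 0.5) + 0) == batch$labels))
}

#' Train a network on a supervised episode source
#'
#' Iterates: generate a batch of episodes, simulate, evaluate the combined
#' RMEE + cross-entropy criterion at the readout times plus the firing-rate
#' penalty, backpropagate through time, take an ADAM step, and apply deep
#' rewiring. Errors for the RMEE term are \code{label - sigmoid(readout)},
#' which lie naturally in \code{[-1, 1]} to match the codebook; the
#' first iteration uses the startup codebook \code{(N, 0, 0)}.
#'
#' @param net an [init_network()] object.
#' @param source function \code{(n_episodes)} returning a
#'   \code{"supervised_batch"}; drawn from the seeded global RNG stream.
#' @param config a [train_config()]; \code{K} episodes per iteration.
#' @param verbose print progress every 25 iterations.
#' @return list of class \code{"snn_training"} with the trained \code{net}
#'   and a per-iteration \code{history} data frame.
#' @export
train_supervised <- function(net, source, config, verbose = FALSE) {
  set.seed(config$seed)
  dt <- net$params$dt
  opt <- adam_init(c(lapply(net$proj, `[[`, "W"),
                     list(W_out = net$W_out, b_out = net$b_out)))
  hist <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    batch <- source(config$K)
    B <- ncol(batch$labels)
    sim <- simulate_forward(net, batch$X)
    y <- batch_logits(sim, batch)
    p <- sigmoid(y)
    l <- batch$labels
    e <- as.numeric(l - p)
    N <- length(e)
    cb <- quantize_errors(e, first_iteration = it == 1L)
    aux <- hq_auxiliaries(e, config$sigma)
    rmee_term <- -rmee_hq_objective(e, cb, aux) / N^2
    ce_term <- sum(cross_entropy(as.numeric(p), as.numeric(l))) / B
    rate_pen <- firing_rate_regularizer(sim, config$f0, config$mu_f, dt)
    loss <- config$mu * rmee_term + (1 - config$mu) * ce_term + rate_pen
    if (!is.finite(loss))
      stop_invalid("training diverged (non-finite loss) at iteration %d", it)
    # readout gradients
    dle <- -rmee_gradient(e, cb, aux) / N^2          # d(rmee_term)/de
    gy <- matrix(config$mu * dle * as.numeric(-p * (1 - p)), nrow(l), B) +
      (1 - config$mu) * (p - l) / B
    gl <- array(0, c(net$config$n_out, B, sim$T))
    for (n in seq_len(nrow(l))) {
      win <- batch$windows[[n]]; m <- nrow(win)
      for (b in seq_len(B)) {
        gl[1, b, win[, b]] <- gl[1, b, win[, b]] + gy[n, b] / m
      }
    }
    gz <- rate_reg_grad(sim, config$f0, config$mu_f, dt)
    grads <- bptt_gradients(net, sim, gl, gz)
    net <- apply_update(net, grads, opt, config)
    opt <- attr(net, "opt"); attr(net, "opt") <- NULL
    hist[[it]] <- data.frame(iteration = it, loss = loss,
                             rmee_term = rmee_term, ce_term = ce_term,
                             rate_penalty = rate_pen,
                             mean_rate_hz = mean_rate_hz(sim, dt),
                             metric = mean(((p >= 0.5) + 0) == l))
    if (verbose && it %% 25 == 0)
      message(sprintf("iter %d: loss %.4f acc %.3f rate %.1f Hz", it, loss,
                      hist[[it]]$metric, hist[[it]]$mean_rate_hz))
  }
  structure(list(net = net, history = do.call(rbind, hist), config = config),
            class = "snn_training")
}

# ADAM step plus rewiring. The L1 rewiring penalty is applied decoupled
# from the adaptive step (a lr * l1 shrink toward zero per iteration, as in
# the plain-SGD rewiring rule): folding it into the ADAM moments would let
# the constant penalty dominate the normalized update whenever task
# gradients are small.
apply_update <- function(net, grads, opt, config) {
  l1 <- net$config$l1_reg
  st <- adam_step(opt, grads, lr = config$lr)
  for (nm in names(net$proj)) {
    pr <- net$proj[[nm]]
    net$proj[[nm]] <- apply_rewiring(pr, pr$W - st$deltas[[nm]] -
                                       config$lr * l1 * pr$signs * pr$mask)
  }
  net$W_out <- net$W_out - st$deltas$W_out
  net$b_out <- net$b_out - st$deltas$b_out
  attr(net, "opt") <- st$opt
  net
}

# ---- reward learning --------------------------------------------------------

nav_defaults <- function() {
  list(radius = 0.05, max_speed = 0.02, n_place = 10L, n_reward = 5L,
       reward_window = 5L, goal = NULL)
}

nav_n_in <- function(opts = nav_defaults()) 2L * opts$n_place + 2L * opts$n_reward

# Closed-loop rollout of K navigation episodes of T steps. Position is
# population-rate encoded per dimension into Poisson spikes; reward events
# drive a synchronous input group for reward_window steps (the negative
# group exists but never fires since rewards are 0/1). A reach teleports the
# agent to a fresh random start with the destination unchanged (the
# water-maze protocol), so episodes always run the full horizon and the
# destinations-reached number (DRN) counts all reaches.
collect_nav_episodes <- function(net, K, T, opts = nav_defaults(),
                                 collect = TRUE) {
  dt <- net$params$dt
  code <- population_code(opts$n_place)
  ar <- arena_init(K, radius = opts$radius, max_speed = opts$max_speed,
                   goal = opts$goal)
  n_in <- nav_n_in(opts)
  env <- new.env()
  env$ar <- ar
  env$timer <- numeric(K)
  env$REW <- matrix(0, K, T); env$VALID <- matrix(FALSE, K, T)
  env$LOGP <- matrix(0, K, T); env$VALUE <- matrix(0, K, T)
  env$RAW <- array(0, c(2, K, T)); env$MU <- array(0, c(2, K, T))
  env$VR <- array(0, c(2, K, T))
  input_fn <- function(t) {
    act <- !env$ar$done
    rates <- rbind(population_encode(env$ar$pos[1, ], code),
                   population_encode(env$ar$pos[2, ], code))
    pr <- rates * dt / 1000
    x <- matrix(0, n_in, K)
    x[1:(2 * opts$n_place), ] <- (matrix(stats::runif(length(pr)), nrow(pr)) < pr) + 0
    x[(2 * opts$n_place + 1):(2 * opts$n_place + opts$n_reward), ] <-
      rep((env$timer > 0) + 0, each = opts$n_reward)
    x[, !act] <- 0
    x
  }
  observe_fn <- function(t, lam, z) {
    dec <- decode_action(lam, opts$max_speed)
    res <- arena_step(env$ar, dec$action, respawn = TRUE)
    env$VALID[, t] <- TRUE
    env$REW[, t] <- res$reward
    env$LOGP[, t] <- dec$logp
    env$VALUE[, t] <- dec$value
    env$RAW[, , t] <- dec$raw; env$MU[, , t] <- dec$mean; env$VR[, , t] <- dec$var
    env$timer <- pmax(env$timer - 1, 0)
    env$timer[res$reward > 0] <- opts$reward_window
    env$ar <- res$arena
  }
  sim <- sim_engine(net, T, K, input_fn, observe_fn, collect = collect)
  list(sim = sim, rewards = env$REW, valid = env$VALID, logp = env$LOGP,
       value = env$VALUE, raw = env$RAW, mu = env$MU, vr = env$VR,
       reached = sum(env$REW), arena = env$ar)
}

#' Evaluate a frozen policy on the navigation task
#'
#' @param net an [init_network()] object with five readouts.
#' @param K,T episodes and steps per episode.
#' @param opts arena options (destination radius, speed bound, encoder
#'   sizes); defaults are the reference settings.
#' @return number of destinations reached (0..K).
#' @export
eval_navigation <- function(net, K, T, opts = nav_defaults()) {
  collect_nav_episodes(net, K, T, opts, collect = FALSE)$reached
}

#' Train a network on the navigation task by reward learning
#'
#' Each iteration collects \code{K} closed-loop episodes of \code{T} steps
#' under the current policy, then minimizes the clipped-surrogate policy
#' loss with value-prediction and firing-rate terms ([ppo_loss()],
#' [firing_rate_regularizer()]) plus the RMEE criterion applied to the
#' per-episode value-prediction errors \eqn{e_n = \overline{\Omega - V}}
#' (startup codebook \code{(N, 0, 0)} on iteration 1, binned quantization
#' afterwards), weighted by \code{config$mu}. Gradients flow through BPTT;
#' updates use ADAM and deep rewiring.
#'
#' @param net an [init_network()] with \code{n_out = 5} and
#'   \code{n_in = 30} (two place-code groups of 10, two reward groups of 5).
#' @param config a [train_config()].
#' @param opts arena options, see [eval_navigation()].
#' @param verbose print progress every 25 iterations.
#' @return list of class \code{"snn_training"}; the history's \code{metric}
#'   column is the per-iteration destinations-reached number (DRN).
#' @export
train_reward <- function(net, config, opts = nav_defaults(), verbose = FALSE) {
  set.seed(config$seed)
  dt <- net$params$dt
  K <- config$K; T <- config$T
  opt <- adam_init(c(lapply(net$proj, `[[`, "W"),
                     list(W_out = net$W_out, b_out = net$b_out)))
  hist <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    roll <- collect_nav_episodes(net, K, T, opts)
    Om <- t(apply(roll$rewards, 1L, discounted_returns, gamma = config$gamma))
    logp_old <- roll$logp
    # advantages are fixed for all epochs of the iteration, centered and
    # scaled; the floor on the scale keeps reward-free iterations (whose
    # advantages are pure value noise) from being amplified to the same
    # gradient size as real signal
    A <- Om - roll$value
    A <- (A - mean(A)) / max(stats::sd(A), 0.1)
    loss <- NA_real_
    for (ep in seq_len(config$n_epochs)) {
      if (ep == 1L) {
        sim <- roll$sim; mu_h <- roll$mu; vr_h <- roll$vr; V <- roll$value
        logp <- logp_old
      } else {
        # open-loop replay of the recorded inputs under the updated weights
        sim <- simulate_forward(net, roll$sim$X)
        mu_h <- tanh(sim$LAM[1:2, , , drop = FALSE])
        vr_h <- sigmoid(sim$LAM[3:4, , , drop = FALSE])
        V <- matrix(sim$LAM[5, , ], K, T)
        dev <- roll$raw - mu_h
        logp <- matrix(colSums(-0.5 * log(2 * pi * vr_h) -
                                 dev^2 / (2 * vr_h)), K, T)
      }
      pl <- ppo_loss(as.numeric(logp), as.numeric(logp_old),
                     as.numeric(A), as.numeric(Om), as.numeric(V),
                     clip_eps = config$clip_eps, mu_v = config$mu_v)
      e <- rowMeans(Om - V)
      cb <- quantize_errors(e, first_iteration = it == 1L)
      aux <- hq_auxiliaries(e, config$sigma)
      rmee_term <- -rmee_hq_objective(e, cb, aux) / K^2
      rate_pen <- firing_rate_regularizer(sim, config$f0, config$mu_f, dt)
      loss <- pl$loss + config$mu * rmee_term + rate_pen
      if (!is.finite(loss))
        stop_invalid("training diverged (non-finite loss) at iteration %d", it)
      # readout gradients: policy heads 1-4, value head 5
      r <- exp(logp - logp_old)
      unclipped <- !((r > 1 + config$clip_eps & A > 0) |
                       (r < 1 - config$clip_eps & A < 0))
      glogp <- -(1 / (K * T)) * r * A * unclipped
      dmu <- roll$raw - mu_h
      gl <- array(0, c(5, K, T))
      for (d in 1:2) {
        vr_d <- matrix(vr_h[d, , ], K, T)
        dev_d <- matrix(dmu[d, , ], K, T)
        gl[d, , ] <- glogp * (dev_d / vr_d) * (1 - matrix(mu_h[d, , ], K, T)^2)
        gl[d + 2, , ] <- glogp * (dev_d^2 / (2 * vr_d^2) - 1 / (2 * vr_d)) *
          vr_d * (1 - vr_d)
      }
      dle <- config$mu * (-rmee_gradient(e, cb, aux) / K^2)
      gl[5, , ] <- config$mu_v * 2 * (V - Om) / length(V) + (-dle / T)
      gz <- rate_reg_grad(sim, config$f0, config$mu_f, dt)
      grads <- bptt_gradients(net, sim, gl, gz)
      net <- apply_update(net, grads, opt, config)
      opt <- attr(net, "opt"); attr(net, "opt") <- NULL
    }
    hist[[it]] <- data.frame(iteration = it, loss = loss,
                             ppo_surrogate = pl$surrogate,
                             value_term = pl$value_term,
                             rmee_term = rmee_term, rate_penalty = rate_pen,
                             mean_rate_hz = mean_rate_hz(roll$sim, dt),
                             metric = roll$reached)
    if (verbose && it %% 25 == 0)
      message(sprintf("iter %d: loss %.4f DRN %d rate %.1f Hz", it, loss,
                      hist[[it]]$metric, hist[[it]]$mean_rate_hz))
  }
  structure(list(net = net, history = do.call(rbind, hist), config = config),
            class = "snn_training")
}
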