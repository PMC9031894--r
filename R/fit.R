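# User-facing modelling interface: one fitting function returning a classed
# object with the usual accessor methods.

#' Fit a recurrent spiking network to a benchmark task
#'
#' Builds a network sized for the chosen task and trains it: the supervised
#' tasks (store-recall working memory, noisy glyph sequences) with the
#' combined RMEE + cross-entropy criterion via [train_supervised()], the
#' navigation task by reward learning via [train_reward()]. Returns a fitted
#' model object supporting \code{print}, \code{summary}, \code{coef},
#' \code{plot}, \code{predict}, \code{residuals} and \code{simulate}.
#'
#' Task defaults (overridable through the arguments): store-recall uses 40
#' input channels, episodes of 120 steps and 96 episodes per iteration over
#' 200 iterations; glyph sequences use 28 channels, 120 steps (a cue plus
#' five images at 20 steps each) and 12 trials per iteration over 120
#' iterations; navigation uses 30 input channels (two place-code groups, two
#' reward groups), five readouts, K = 5 episodes of T = 200 steps over 150
#' iterations, a readout initialization gain of 5 and a negative initial
#' bias on the policy-variance heads so the policy has behavioural authority
#' from the start. The firing-rate penalty weight defaults to
#' \code{4 / (K * T)^2} per task, compensating the quadratic growth of the
#' squared-count penalty with the simulated horizon.
#'
#' @param task one of \code{"store_recall"}, \code{"noisy_seq"},
#'   \code{"navigation"}.
#' @param n_hidden hidden layer size.
#' @param n_iterations training iterations (task default if \code{NULL}).
#' @param batch_size episodes per iteration (task default if \code{NULL}).
#' @param mu RMEE weight of the combined criterion.
#' @param sigma RMEE kernel bandwidth.
#' @param lr ADAM learning rate.
#' @param noise_fraction salt-and-pepper corruption level (noisy_seq only).
#' @param T_steps episode length in steps (task default if \code{NULL}).
#' @param mu_f firing-rate penalty weight (task default if \code{NULL}).
#' @param f0 target firing rate (Hz).
#' @param sparsity recurrent connection fraction.
#' @param seed integer seed fixing initialization, episode generation and
#'   training.
#' @param verbose print progress.
#' @return an object of class \code{"snn_fit"}.
#' @examples
#' \donttest{
#' fit <- snn_fit("store_recall", n_hidden = 40, n_iterations = 20,
#'                batch_size = 8, seed = 1)
#' print(fit)
#' pr <- predict(fit, n_episodes = 50, seed = 2)
#' pr$accuracy
#' }
#' @export
snn_fit <- function(task = c("store_recall", "noisy_seq", "navigation"),
                    n_hidden = 100, n_iterations = NULL, batch_size = NULL,
                    mu = 0.8, sigma = 1, lr = 0.01, noise_fraction = 0.1,
                    T_steps = NULL, mu_f = NULL, f0 = 10, sparsity = 0.1,
                    seed = 1, verbose = FALSE) {
  task <- match.arg(task)
  def <- switch(task,
    store_recall = list(n_in = 40L, n_out = 1L, T = 120L, K = 96L, iters = 200L,
                        gain = 1),
    noisy_seq = list(n_in = 28L, n_out = 1L, T = 120L, K = 12L, iters = 120L,
                     gain = 1),
    navigation = list(n_in = nav_n_in(), n_out = 5L, T = 200L, K = 5L,
                      iters = 150L, gain = 5))
  T_steps <- as.integer(T_steps %||% def$T)
  K <- as.integer(batch_size %||% def$K)
  iters <- as.integer(n_iterations %||% def$iters)
  mu_f <- mu_f %||% (4 / (K * T_steps)^2)
  ncfg <- network_config(n_in = def$n_in, n_hidden = n_hidden,
                         n_out = def$n_out, sparsity = sparsity,
                         readout_gain = def$gain, seed = seed)
  net <- init_network(ncfg)
  if (task == "navigation") {
    # start the policy with moderate action noise: at zero bias the sampled
    # direction noise (sd ~ 0.7) would swamp the bounded action means, so
    # the policy would have no behavioural authority to learn from
    net$b_out[3:4] <- -1.5
  }
  tcfg <- train_config(mu = mu, mu_f = mu_f, f0 = f0, sigma = sigma, lr = lr,
                       K = K, T = T_steps, n_iterations = iters, seed = seed)
  res <- switch(task,
    store_recall = train_supervised(net, function(n) gen_store_recall(n, T = T_steps),
                                    tcfg, verbose = verbose),
    noisy_seq = train_supervised(net, function(n) gen_noisy_sequences(n, noise_fraction),
                                 tcfg, verbose = verbose),
    navigation = train_reward(net, tcfg, verbose = verbose))
  structure(list(task = task, net = res$net, history = res$history,
                 config = tcfg, net_config = ncfg,
                 noise_fraction = if (task == "noisy_seq") noise_fraction else NULL,
                 call = match.call()),
            class = "snn_fit")
}

metric_name <- function(task) {
  if (task == "navigation") "destinations reached (DRN)" else "accuracy"
}

#' @export
print.snn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Spiking network fit: task '%s', %d hidden neurons, %d iterations\n",
              x$task, x$net_config$n_hidden, nrow(h)))
  cat(sprintf("  final loss %.4f; final training %s %.3g; mean rate %.1f Hz\n",
              h$loss[nrow(h)], metric_name(x$task), h$metric[nrow(h)],
              h$mean_rate_hz[nrow(h)]))
  invisible(x)
}

#' @export
summary.snn_fit <- function(object, ...) {
  h <- object$history
  last10 <- utils::tail(h, 10L)
  out <- list(task = object$task, n_hidden = object$net_config$n_hidden,
              iterations = nrow(h), mu = object$config$mu,
              first_loss = h$loss[1], final_loss = h$loss[nrow(h)],
              final_metric = h$metric[nrow(h)],
              last10_metric = mean(last10$metric),
              mean_rate_hz = mean(last10$mean_rate_hz),
              metric_name = metric_name(object$task))
  class(out) <- "summary.snn_fit"
  out
}

#' @export
print.summary.snn_fit <- function(x, ...) {
  cat(sprintf("Task: %s (mu = %.2f, %d hidden, %d iterations)\n",
              x$task, x$mu, x$n_hidden, x$iterations))
  cat(sprintf("Loss: %.4f -> %.4f\n", x$first_loss, x$final_loss))
  cat(sprintf("Training %s: %.3g (mean of last 10 iterations)\n",
              x$metric_name, x$last10_metric))
  cat(sprintf("Mean hidden firing rate: %.1f Hz\n", x$mean_rate_hz))
  invisible(x)
}

#' @export
coef.snn_fit <- function(object, ...) {
  c(lapply(object$net$proj, `[[`, "W"),
    list(W_out = object$net$W_out, b_out = object$net$b_out))
}

#' @export
plot.snn_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$iteration, h$loss, type = "l", xlab = "iteration",
                 ylab = "loss", main = "training loss")
  graphics::plot(h$iteration, h$metric, type = "l", xlab = "iteration",
                 ylab = metric_name(x$task), main = "task performance")
  invisible(x)
}

#' Predict from a fitted spiking network
#'
#' For the supervised tasks, evaluates the frozen network on new episodes
#' (either supplied as a \code{"supervised_batch"} or freshly generated) and
#' returns per-label probabilities, predictions and accuracy. For the
#' navigation task, runs frozen-policy rollouts and reports the number of
#' destinations reached.
#'
#' @param object an [snn_fit()] object.
#' @param newdata optional \code{"supervised_batch"}.
#' @param n_episodes number of episodes to generate when \code{newdata} is
#'   missing.
#' @param seed seed for episode generation / rollouts.
#' @param ... unused.
#' @return a list of class \code{"snn_prediction"}.
#' @export
predict.snn_fit <- function(object, newdata = NULL, n_episodes = 100,
                            seed = 1, ...) {
  if (object$task == "navigation") {
    drn <- with_seed(seed, eval_navigation(object$net, K = n_episodes,
                                           T = object$config$T))
    return(structure(list(task = object$task, n_episodes = n_episodes,
                          reached = drn, rate = drn / n_episodes),
                     class = "snn_prediction"))
  }
  batch <- newdata %||% with_seed(seed, switch(object$task,
    store_recall = gen_store_recall(n_episodes, T = object$config$T),
    noisy_seq = gen_noisy_sequences(n_episodes, object$noise_fraction)))
  pr <- predict_supervised(object$net, batch)
  structure(c(list(task = object$task, labels = batch$labels), pr),
            class = "snn_prediction")
}

#' @export
print.snn_prediction <- function(x, ...) {
  if (x$task == "navigation") {
    cat(sprintf("Navigation evaluation: %d destinations reached over %d episodes (%.2f per episode)\n",
                x$reached, x$n_episodes, x$rate))
  } else {
    cat(sprintf("Supervised evaluation (%s): accuracy %.3f over %d predictions\n",
                x$task, x$accuracy, length(x$labels)))
  }
  invisible(x)
}

#' Readout errors of a fitted network
#'
#' The error samples the RMEE criterion acts on: \code{label -
#' sigmoid(readout)} at the readout times for the supervised tasks, and the
#' per-episode mean value-prediction error \eqn{\overline{\Omega - V}} for
#' navigation.
#'
#' @param object an [snn_fit()] object.
#' @param n_episodes episodes to evaluate.
#' @param seed generation seed.
#' @param ... unused.
#' @return numeric vector of error samples.
#' @export
residuals.snn_fit <- function(object, n_episodes = 100, seed = 1, ...) {
  if (object$task == "navigation") {
    roll <- with_seed(seed, collect_nav_episodes(object$net, n_episodes,
                                                 object$config$T,
                                                 collect = FALSE))
    Om <- t(apply(roll$rewards, 1L, discounted_returns,
                  gamma = object$config$gamma))
    w <- roll$valid + 0
    return(rowSums((Om - roll$value) * w) / pmax(rowSums(w), 1))
  }
  predict(object, n_episodes = n_episodes, seed = seed)$errors
}

#' Simulate episodes through a fitted network
#'
#' Generates \code{nsim} fresh task episodes and runs them through the
#' trained network, returning the full simulation (spike raster, readout
#' traces) for inspection or export via [raster_events()].
#'
#' @param object an [snn_fit()] object.
#' @param nsim number of episodes.
#' @param seed generation seed.
#' @param ... unused.
#' @return an \code{"snn_sim"} object; for supervised tasks the generating
#'   batch is attached as attribute \code{"batch"}.
#' @export
simulate.snn_fit <- function(object, nsim = 1, seed = 1, ...) {
  if (object$task == "navigation") {
    return(with_seed(seed, collect_nav_episodes(object$net, nsim,
                                                object$config$T))$sim)
  }
  batch <- with_seed(seed, switch(object$task,
    store_recall = gen_store_recall(nsim, T = object$config$T),
    noisy_seq = gen_noisy_sequences(nsim, object$noise_fraction)))
  sim <- simulate_forward(object$net, batch$X)
  attr(sim, "batch") <- batch
  sim
}
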