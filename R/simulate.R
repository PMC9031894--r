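# Batched forward simulation of the recurrent network.
#
# State is held in (n_hidden x n_batch) matrices so independent episodes run
# in parallel through the same matrix expressions. The engine accepts either
# a prerecorded input array or a closed-loop input provider (used by the
# navigation task, where each step's input depends on the previous action).
# All traces needed by backpropagation through time are recorded.

zeros <- function(n, B) matrix(0, n, B)

# input_fn(t) -> (n_in x B) input matrix for step t (spikes or analog).
# observe_fn(t, lam, z) is called after each step for closed-loop tasks.
# collect = FALSE skips the traces only backpropagation needs (UM, GAM, PD
# and the input echo), which keeps frozen-weight evaluation of large
# episode batches cheap.
sim_engine <- function(net, T, B, input_fn, observe_fn = NULL,
                       surrogate = FALSE, collect = TRUE) {
  p <- net$params; cfg <- net$config
  n <- cfg$n_hidden; n_in <- cfg$n_in; n_out <- cfg$n_out
  dly <- net$proj$in_m$delay
  dt <- p$dt; k <- p$k_pseudo
  dec_out <- 1 - dt / cfg$tau_out
  X <- array(0, c(n_in, B, if (collect) T else dly))
  Z <- array(0, c(n, B, T))
  UM <- if (collect) array(0, c(n, B, T))
  GAM <- if (collect) array(0, c(n, B, T))
  PD <- if (collect) array(0, c(n, B, T))
  LAM <- array(0, c(n_out, B, T))
  state <- neuron_state(params = p, dim = c(n, B))
  lam <- zeros(n_out, B)
  z0 <- zeros(n, B); x0 <- zeros(n_in, B)
  P <- net$proj
  for (t in seq_len(T)) {
    xt <- input_fn(t)
    if (collect) {
      X[, , t] <- xt
      xd <- if (t > dly) matrix(X[, , t - dly], n_in, B) else x0
    } else {
      # rolling input buffer of depth = delay
      slot <- ((t - 1L) %% dly) + 1L
      xd <- if (t > dly) matrix(X[, , slot], n_in, B) else x0
      X[, , slot] <- xt
    }
    zd <- if (t > dly) matrix(Z[, , t - dly], n, B) else z0
    I_m <- P$in_m$W %*% xd + P$rec_m$W %*% zd
    I_i <- P$in_i$W %*% xd + P$rec_i$W %*% zd
    I_e <- P$in_e$W %*% xd + P$rec_e$W %*% zd
    state <- step_neuron(state, I_m, I_i, I_e, p)
    state <- update_threshold(state, p)
    v <- normalized_potential(state$U_m, state$Gamma_j)
    if (surrogate) {
      state$z_j <- surrogate_spike(v, k)
      if (collect) PD[, , t] <- pseudo_derivative(v, k)
    } else {
      can <- state$refrac_count <= 0
      state <- emit_spike(state, p)
      if (collect) PD[, , t] <- pseudo_derivative(v, k) * can
    }
    Z[, , t] <- state$z_j
    if (collect) {
      UM[, , t] <- state$U_m
      GAM[, , t] <- state$Gamma_j
    }
    lam <- dec_out * lam + (dt / cfg$tau_out) * (net$W_out %*% state$z_j + net$b_out)
    LAM[, , t] <- lam
    if (!is.null(observe_fn)) observe_fn(t, lam, state$z_j)
  }
  structure(list(X = if (collect) X, Z = Z, UM = UM, GAM = GAM, PD = PD,
                 LAM = LAM, T = T, B = B, surrogate = surrogate,
                 collect = collect, state = state),
            class = "snn_sim")
}

#' Simulate the network on recorded input streams
#'
#' Runs the network forward over \code{T} steps for a batch of episodes,
#' recording the spike raster, readout membrane traces and the internal
#' traces backpropagation through time needs. Deterministic given the wiring
#' and inputs. Presynaptic spikes reach each compartment after the configured
#' synaptic delay; readouts are non-spiking leaky integrators of hidden
#' somatic spikes.
#'
#' @param net an [init_network()] object.
#' @param input either a \code{T x n_in} matrix (one episode) or an
#'   \code{n_in x B x T} array (a batch).
#' @param surrogate if \code{TRUE}, spikes are replaced by the smoothed
#'   primitive [surrogate_spike()] and refractoriness is disabled, giving the
#'   fully differentiable forward used for gradient checking.
#' @param collect store the internal traces backpropagation needs; set to
#'   \code{FALSE} for cheap frozen-weight evaluation of large batches.
#' @return an object of class \code{"snn_sim"} with arrays \code{Z}
#'   (\code{n_hidden x B x T} spikes), \code{LAM} (readout traces) and the
#'   internal traces \code{UM}, \code{GAM}, \code{PD}, \code{X}.
#' @seealso [bptt_gradients()], [raster_events()], [readout_traces()]
#' @export
simulate_forward <- function(net, input, surrogate = FALSE, collect = TRUE) {
  if (is.matrix(input)) {
    input <- array(t(input), c(ncol(input), 1L, nrow(input)))
  }
  if (length(dim(input)) != 3L || dim(input)[1] != net$config$n_in)
    stop_invalid("input must be T x n_in or an n_in x B x T array matching the network")
  T <- dim(input)[3]; B <- dim(input)[2]
  n_in <- dim(input)[1]
  sim_engine(net, T, B, function(t) matrix(input[, , t], n_in, B),
             surrogate = surrogate, collect = collect)
}

#' Spike raster as an event list
#'
#' @param sim an \code{"snn_sim"} from [simulate_forward()].
#' @param episode which batch element to extract.
#' @return data frame with columns \code{time} (step) and \code{neuron},
#'   one row per emitted spike; suitable for CSV export.
#' @export
raster_events <- function(sim, episode = 1) {
  zmat <- matrix(sim$Z[, episode, ], dim(sim$Z)[1], sim$T)  # n x T
  ev <- which(zmat >= 0.5, arr.ind = TRUE)
  data.frame(time = ev[, 2], neuron = ev[, 1])[order(ev[, 2], ev[, 1]), ]
}

#' Readout membrane traces
#'
#' @inheritParams raster_events
#' @return \code{T x n_out} matrix of readout potentials.
#' @export
readout_traces <- function(sim, episode = 1) {
  t(matrix(sim$LAM[, episode, ], dim(sim$LAM)[1], sim$T))
}

#' Mean hidden firing rate of a simulation
#'
#' @inheritParams raster_events
#' @param dt simulation step in ms (to convert spikes/step to Hz).
#' @return mean firing rate across neurons, batch and time, in Hz.
#' @export
mean_rate_hz <- function(sim, dt = 1) {
  mean(sim$Z) * 1000 / dt
}
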