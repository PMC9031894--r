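# Construction of the recurrent three-layer spiking network.
#
# Six synaptic projections feed the hidden layer: input and recurrent
# synapses onto each of the three compartments (soma, inhibitory dendrite,
# excitatory dendrite). Each projection carries per-synapse fixed signs
# (sampled once at initialization and never changed), a boolean connectivity
# mask, and a homogeneous conduction delay. Hidden somatic spikes drive
# non-spiking leaky readout neurons. Sparsity is maintained by deep
# rewiring: synapses whose weight would cross zero are disconnected and an
# equal number of dormant synapses are reconnected.

#' Network configuration
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param sparsity fraction of recurrent synapses that are active, in
#'   \code{(0, 1]}. Input and readout projections are dense.
#' @param dt simulation step (ms); the weight scale is \code{w0 = dt / R_m}.
#' @param delay synaptic conduction delay (ms), applied homogeneously to all
#'   input and recurrent synapse classes.
#' @param tau_out readout membrane time constant (ms); readouts are leaky
#'   integrators of hidden spikes, without spiking or reset.
#' @param l1_reg L1-norm regularization parameter of the rewiring update.
#' @param rewiring_temperature temperature of the rewiring noise term (the
#'   reference setting is 0, i.e. no noise, and only 0 is implemented).
#' @param spectral_target spectral radius the recurrent somatic weight matrix
#'   is rescaled to when its initial radius exceeds it (kept below 1 to avoid
#'   exploding gradients).
#' @param readout_gain multiplier on the readout weight initialization scale
#'   \code{w0 / sqrt(n_hidden)}. Policy readouts (navigation) use a larger
#'   gain so the initial readout potentials have enough dynamic range to
#'   steer behaviour.
#' @param seed integer seed making the initialization reproducible.
#' @return an object of class \code{"network_config"}.
#' @export
network_config <- function(n_in, n_hidden = 100, n_out = 1,
                           sparsity = 0.1, dt = 1, delay = 5,
                           tau_out = 20, l1_reg = 0.01,
                           rewiring_temperature = 0,
                           spectral_target = 0.95, readout_gain = 1,
                           seed = 1) {
  if (n_in < 1 || n_hidden < 1 || n_out < 1)
    stop_invalid("layer sizes must be at least 1")
  if (sparsity <= 0 || sparsity > 1) stop_invalid("sparsity must be in (0, 1]")
  if (rewiring_temperature != 0)
    stop_invalid("only rewiring_temperature = 0 is supported")
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 n_out = as.integer(n_out), sparsity = sparsity, dt = dt,
                 delay = delay, tau_out = tau_out, l1_reg = l1_reg,
                 rewiring_temperature = rewiring_temperature,
                 spectral_target = spectral_target,
                 readout_gain = readout_gain, seed = as.integer(seed)),
            class = "network_config")
}

spectral_radius <- function(W) {
  if (nrow(W) == 0L) return(0)
  max(Mod(eigen(W, only.values = TRUE)$values))
}

# One synaptic projection: dense weight matrix with zeros at inactive
# synapses, per-synapse signs over all eligible positions, boolean mask of
# active synapses, eligibility (self-connections are never eligible for
# recurrent projections), and delay in steps.
make_projection <- function(n_post, n_pre, scale, sign_type, sparsity,
                            delay_steps, recurrent) {
  signs <- matrix(switch(sign_type,
                         mixed = sample(c(-1, 1), n_post * n_pre, replace = TRUE),
                         neg = -1, pos = 1),
                  n_post, n_pre)
  elig <- matrix(TRUE, n_post, n_pre)
  if (recurrent) diag(elig) <- FALSE
  mask <- matrix(stats::runif(n_post * n_pre) < sparsity, n_post, n_pre) & elig
  mag <- matrix(abs(stats::rnorm(n_post * n_pre)) * scale, n_post, n_pre)
  W <- signs * mag
  W[!mask] <- 0
  list(W = W, signs = signs, mask = mask, eligible = elig,
       delay = as.integer(delay_steps), rewired = TRUE)
}

#' Initialize a recurrent spiking network
#'
#' Builds all synaptic projections. Weight magnitudes are Gaussian with scale
#' \eqn{w_0 / \sqrt{n_{pre}}} where \eqn{w_0 = dt / R_m}; each synapse gets a
#' fixed sign that deep rewiring preserves for the whole training run.
#' Projections onto the inhibitory dendrite carry negative signs, those onto
#' the excitatory dendrite positive signs, and somatic projections carry
#' Bernoulli-sampled mixed signs. Recurrent (lateral) projections are sparse
#' at \code{config$sparsity} with no self-connections; if the masked
#' recurrent somatic matrix has spectral radius above
#' \code{config$spectral_target}, all recurrent matrices are rescaled so it
#' equals the target (keeping it below 1). Readout weights are dense,
#' unsigned and not rewired.
#'
#' @param config a [network_config()].
#' @param params a [neuron_params()]; its \code{dt} is taken from the config.
#' @return an object of class \code{"snn_network"}.
#' @export
init_network <- function(config, params = neuron_params(dt = config$dt)) {
  if (!inherits(config, "network_config")) stop_invalid("config must be a network_config")
  set.seed(config$seed)
  n_in <- config$n_in; n_h <- config$n_hidden; n_out <- config$n_out
  w0 <- config$dt / params$R_m
  d_steps <- max(1L, as.integer(round(config$delay / config$dt)))
  in_scale <- w0 / sqrt(n_in)
  rec_scale <- w0 / sqrt(n_h)
  proj <- list(
    in_m  = make_projection(n_h, n_in, in_scale, "mixed", 1, d_steps, FALSE),
    in_i  = make_projection(n_h, n_in, in_scale, "neg", 1, d_steps, FALSE),
    in_e  = make_projection(n_h, n_in, in_scale, "pos", 1, d_steps, FALSE),
    rec_m = make_projection(n_h, n_h, rec_scale, "mixed", config$sparsity, d_steps, TRUE),
    rec_i = make_projection(n_h, n_h, rec_scale, "neg", config$sparsity, d_steps, TRUE),
    rec_e = make_projection(n_h, n_h, rec_scale, "pos", config$sparsity, d_steps, TRUE))
  rad <- spectral_radius(proj$rec_m$W)
  if (rad > config$spectral_target) {
    f <- config$spectral_target / rad
    for (nm in c("rec_m", "rec_i", "rec_e")) proj[[nm]]$W <- proj[[nm]]$W * f
  }
  W_out <- matrix(stats::rnorm(n_out * n_h,
                               sd = config$readout_gain * w0 / sqrt(n_h)),
                  n_out, n_h)
  structure(list(config = config, params = params, proj = proj,
                 W_out = W_out, b_out = numeric(n_out)),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cfg <- x$config
  act <- sum(x$proj$rec_m$mask) / sum(x$proj$rec_m$eligible)
  cat(sprintf("Recurrent spiking network: %d inputs -> %d hidden (3-compartment) -> %d readouts\n",
              cfg$n_in, cfg$n_hidden, cfg$n_out))
  cat(sprintf("  recurrent sparsity %.3f, delay %d ms, spectral radius %.3f\n",
              act, cfg$delay, spectral_radius(x$proj$rec_m$W)))
  invisible(x)
}

# Enforce the rewiring contract on a candidate weight matrix: active synapses
# whose updated weight crosses (or lands on) zero against their stored sign
# are disconnected; an equal number of dormant eligible synapses are
# reconnected at vanishing magnitude with their stored sign. Connection count
# is exactly conserved. Consumes RNG for the reconnection draw.
apply_rewiring <- function(proj, W_new) {
  if (!proj$rewired) { proj$W <- W_new; return(proj) }
  W_new[!proj$mask] <- 0
  crossed <- proj$mask & (W_new * proj$signs <= 0)
  n_flip <- sum(crossed)
  if (n_flip > 0L) {
    proj$mask[crossed] <- FALSE
    W_new[crossed] <- 0
    dormant <- which(proj$eligible & !proj$mask)
    pick <- if (length(dormant) > n_flip) sample(dormant, n_flip) else dormant
    proj$mask[pick] <- TRUE
    W_new[pick] <- proj$signs[pick] * 1e-12
  }
  proj$W <- W_new
  proj
}

#' One deep-rewiring gradient step
#'
#' Applies a plain gradient step with L1 penalty (temperature 0, so no noise
#' term) to every rewired projection, then enforces the rewiring contract:
#' active synapses whose updated weight would cross zero are disconnected and
#' an equal number of dormant synapses are reconnected at vanishing magnitude
#' with their stored sign, so no active synapse ever violates its sign and
#' the connection count is exactly conserved. Readout weights are updated
#' without rewiring.
#'
#' @param net an [init_network()] object.
#' @param gradients named list of gradient matrices as returned by
#'   [bptt_gradients()] (any subset of \code{in_m, in_i, in_e, rec_m, rec_i,
#'   rec_e, W_out, b_out}).
#' @param lr learning rate.
#' @param l1 L1 regularization parameter; defaults to the network's
#'   configured value.
#' @return the updated network.
#' @export
rewire_step <- function(net, gradients, lr, l1 = net$config$l1_reg) {
  for (nm in names(net$proj)) {
    g <- gradients[[nm]]
    if (is.null(g)) next
    p <- net$proj[[nm]]
    W_new <- p$W - lr * (g + l1 * p$signs * p$mask)
    net$proj[[nm]] <- apply_rewiring(p, W_new)
  }
  if (!is.null(gradients$W_out)) net$W_out <- net$W_out - lr * gradients$W_out
  if (!is.null(gradients$b_out)) net$b_out <- net$b_out - lr * gradients$b_out
  net
}
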