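# Three-compartment spiking neuron with an adaptive firing threshold.
#
# The soma integrates its own synaptic current plus conductance coupling from
# two point dendrites (one excitatory, one inhibitory), each a leaky
# integrator of its own current. Spiking uses a soft reset (the threshold is
# subtracted) and an adaptive threshold that increments with each spike and
# relaxes with time constant tau_a. All state operations are elementwise, so
# the same functions drive a single neuron or a whole population held in
# numeric arrays.

#' Neuron parameters
#'
#' Constants of the three-compartment adaptive-threshold neuron. The defaults
#' are the reference parameter set: membrane time constant 20 ms, unit
#' resistances and dendritic conductances, zero dendritic reversal potentials,
#' threshold baseline 0.01 with deviation scale 1.8 and adaptation time
#' constant 700 ms. The dendritic time constants default to the somatic one.
#' The surrogate-derivative amplitude \code{k_pseudo} defaults to 0.3.
#'
#' @param tau_m,tau_i,tau_e membrane time constants of soma and the
#'   inhibitory/excitatory dendrite (ms).
#' @param R_m,R_i,R_e compartment resistances (Ohm).
#' @param theta_i,theta_e dendritic reversal potentials (mV).
#' @param g_i,g_e dendritic conductances coupling dendrites into the soma (nS).
#' @param alpha scale of the threshold deviation.
#' @param tau0 baseline firing threshold.
#' @param tau_a threshold adaptation time constant (ms).
#' @param dt simulation step (ms); must satisfy \code{dt <= min(tau)/2} for
#'   the explicit-Euler integration to be stable.
#' @param refractory_steps number of steps a neuron is silenced after a spike.
#' @param k_pseudo amplitude of the surrogate spike derivative.
#' @return an object of class \code{"neuron_params"} (a named list).
#' @export
neuron_params <- function(tau_m = 20, tau_i = 20, tau_e = 20,
                          R_m = 1, R_i = 1, R_e = 1,
                          theta_i = 0, theta_e = 0, g_i = 1, g_e = 1,
                          alpha = 1.8, tau0 = 0.01, tau_a = 700,
                          dt = 1, refractory_steps = 3, k_pseudo = 0.3) {
  for (nm in c("tau_m", "tau_i", "tau_e", "R_m", "R_i", "R_e", "tau_a", "dt", "tau0"))
    check_scalar_pos(get(nm), nm)
  if (dt > min(tau_m, tau_i, tau_e, tau_a) / 2)
    stop_invalid("dt = %g exceeds half the smallest time constant; reduce dt", dt)
  if (refractory_steps < 0) stop_invalid("refractory_steps must be >= 0")
  p <- list(tau_m = tau_m, tau_i = tau_i, tau_e = tau_e,
            R_m = R_m, R_i = R_i, R_e = R_e,
            theta_i = theta_i, theta_e = theta_e, g_i = g_i, g_e = g_e,
            alpha = alpha, tau0 = tau0, tau_a = tau_a, dt = dt,
            refractory_steps = as.integer(refractory_steps),
            k_pseudo = k_pseudo)
  # precomputed discrete-time factors
  p$decay_m <- 1 - dt / tau_m
  p$decay_i <- 1 - dt / tau_i
  p$decay_e <- 1 - dt / tau_e
  p$beta <- exp(-dt / tau_a)
  structure(p, class = "neuron_params")
}

#' Neuron state
#'
#' Evolving variables of one or more neurons: compartment potentials
#' \code{U_m}, \code{U_i}, \code{U_e}, threshold deviation \code{tau_j},
#' current threshold \code{Gamma_j = tau0 + alpha * tau_j}, spike indicator
#' \code{z_j} in \code{\{0, 1\}}, and remaining refractory steps.
#'
#' @param n number of neurons (state fields are length-\code{n} vectors, or
#'   arrays of any shape if you supply \code{dim}).
#' @param params a [neuron_params()] object (sets the initial threshold).
#' @param dim optional dimensions for the state arrays, e.g.
#'   \code{c(n_neurons, n_batch)}.
#' @return an object of class \code{"neuron_state"}.
#' @export
neuron_state <- function(n = 1, params = neuron_params(), dim = NULL) {
  z <- if (is.null(dim)) numeric(n) else array(0, dim)
  structure(list(U_m = z, U_i = z, U_e = z, tau_j = z,
                 Gamma_j = z + params$tau0, z_j = z, refrac_count = z),
            class = "neuron_state")
}

#' One Euler step of the compartment potentials
#'
#' Advances the membrane potentials by one explicit-Euler step of the
#' three-compartment dynamics. Each dendrite leaks toward zero and integrates
#' its own current; the soma additionally receives the conductance-weighted
#' dendritic drive \eqn{g_i (U_i - \theta_i) + g_e (U_e - \theta_e)} and, if
#' the neuron spiked on the previous step, a soft reset that subtracts the
#' threshold \eqn{\Gamma_j z_j}.
#'
#' @param state a [neuron_state()].
#' @param I_m,I_i,I_e input currents to soma and the two dendrites (same
#'   shape as the state fields, recycled if scalar).
#' @param params a [neuron_params()].
#' @return the updated state.
#' @export
step_neuron <- function(state, I_m, I_i, I_e, params) {
  check_finite(I_m, "I_m"); check_finite(I_i, "I_i"); check_finite(I_e, "I_e")
  dt <- params$dt
  drive <- params$R_m * I_m +
    params$g_i * (state$U_i - params$theta_i) +
    params$g_e * (state$U_e - params$theta_e)
  state$U_m <- params$decay_m * state$U_m + (dt / params$tau_m) * drive -
    state$Gamma_j * state$z_j
  state$U_i <- params$decay_i * state$U_i + (dt / params$tau_i) * params$R_i * I_i
  state$U_e <- params$decay_e * state$U_e + (dt / params$tau_e) * params$R_e * I_e
  state
}

#' Update the adaptive threshold
#'
#' Advances the threshold deviation by its geometric recursion
#' \eqn{\tau_j \leftarrow \beta_j \tau_j + (1-\beta_j) z_j} with
#' \eqn{\beta_j = \exp(-dt/\tau_a)}, then recomputes the threshold
#' \eqn{\Gamma_j = \tau^0 + \alpha \tau_j}. Uses the spike indicator currently
#' stored in the state (i.e. the previous step's spikes).
#'
#' @inheritParams step_neuron
#' @return the updated state.
#' @export
update_threshold <- function(state, params) {
  state$tau_j <- params$beta * state$tau_j + (1 - params$beta) * state$z_j
  state$Gamma_j <- params$tau0 + params$alpha * state$tau_j
  state
}

#' Emit spikes and manage refractoriness
#'
#' Sets \eqn{z_j = 1} for every neuron whose somatic potential reaches its
#' (already updated) threshold and that is not refractory; spiking neurons
#' enter a refractory period of \code{params$refractory_steps} steps during
#' which they cannot fire again.
#'
#' @inheritParams step_neuron
#' @return the updated state.
#' @export
emit_spike <- function(state, params) {
  can <- state$refrac_count <= 0
  z <- (can & (state$U_m >= state$Gamma_j)) + 0  # keeps array shape
  state$refrac_count <- pmax(state$refrac_count - 1, 0) * (1 - z) +
    z * params$refractory_steps
  state$z_j <- z
  state
}

#' Normalized membrane potential
#'
#' \eqn{v_j = (U_m - \Gamma_j)/\Gamma_j}: zero at threshold, -1 at rest, +1 at
#' twice the threshold. This is the argument of the surrogate spike
#' derivative.
#'
#' @param U_m somatic membrane potential.
#' @param Gamma_j current threshold; must be positive.
#' @return dimensionless normalized potential, same shape as \code{U_m}.
#' @export
normalized_potential <- function(U_m, Gamma_j) {
  if (any(Gamma_j <= 0)) stop_invalid("threshold Gamma_j must be positive")
  (U_m - Gamma_j) / Gamma_j
}

#' Surrogate derivative of the spike nonlinearity
#'
#' The triangular pseudo-derivative \eqn{dz/dv = k \max(0, 1 - |v|)} used in
#' place of the non-existent derivative of the spike threshold function
#' during backpropagation through time. Continuous, bounded by \code{k}, and
#' zero outside \code{|v| < 1}.
#'
#' @param v normalized membrane potential (see [normalized_potential()]).
#' @param k amplitude, typically less than 1 (default 0.3).
#' @return values in \code{[0, k]}, same shape as \code{v}.
#' @export
pseudo_derivative <- function(v, k = 0.3) {
  k * pmax(0, 1 - abs(v))
}

#' Smoothed spike primitive
#'
#' The antiderivative of [pseudo_derivative()]: a C1 ramp rising from 0 (for
#' \code{v <= -1}) to \code{k} (for \code{v >= 1}). Replacing the hard
#' threshold by this function gives the fully differentiable "surrogate
#' forward" network whose exact gradients the BPTT implementation must match;
#' it is used by the gradient-correctness checks.
#'
#' @inheritParams pseudo_derivative
#' @return values in \code{[0, k]}, same shape as \code{v}.
#' @export
surrogate_spike <- function(v, k = 0.3) {
  vc <- pmin(pmax(v, -1), 1)
  k * ifelse(vc <= 0, (vc + vc^2 / 2) + 0.5, 0.5 + vc - vc^2 / 2)
}
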