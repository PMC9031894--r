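# Backpropagation through time for the three-compartment recurrent network.
#
# The backward pass mirrors the forward recursions of sim_engine() exactly,
# with the spike nonlinearity differentiated through the triangular
# surrogate derivative recorded in the PD trace. Gradients flow through the
# somatic and dendritic leak recursions, the conductance coupling, the
# threshold adaptation, the soft reset, and the delayed recurrent synapses.
# Environment interactions (closed-loop inputs) are treated as constants;
# policy-gradient terms account for them through the returns instead.

flatten_steps <- function(A, idx) {
  matrix(A[, , idx, drop = FALSE], nrow = dim(A)[1])
}

#' BPTT gradients of a simulated episode batch
#'
#' Computes gradients of a loss \eqn{L} with respect to every synaptic
#' weight, given the simulation traces and the direct derivatives of the
#' loss: \code{grad_readout[i, b, t]} \eqn{= \partial L / \partial
#' \lambda_i(t)} for each readout trace, and optionally
#' \code{grad_spikes} \eqn{= \partial L / \partial z_j(t)} for losses that
#' touch hidden spikes directly (e.g. the firing-rate penalty). The spike
#' discontinuity is smoothed by the recorded surrogate derivative, so on a
#' surrogate-mode simulation ([simulate_forward()] with
#' \code{surrogate = TRUE}) these gradients are exact and match finite
#' differences.
#'
#' @param net the [init_network()] object that produced the simulation.
#' @param sim an \code{"snn_sim"} with stored traces.
#' @param grad_readout array \code{n_out x B x T} (or a matrix \code{n_out x
#'   T} for a single episode) of loss derivatives w.r.t. readout traces.
#' @param grad_spikes optional array \code{n_hidden x B x T}, or a
#'   \code{n_hidden x B} matrix / length-\code{n_hidden} vector broadcast
#'   over time, of loss derivatives w.r.t. hidden spikes.
#' @return named list of gradients: \code{in_m, in_i, in_e, rec_m, rec_i,
#'   rec_e} (masked like their projections), \code{W_out}, \code{b_out}.
#' @export
bptt_gradients <- function(net, sim, grad_readout, grad_spikes = NULL) {
  if (!inherits(sim, "snn_sim")) stop_invalid("sim must come from simulate_forward()")
  if (!isTRUE(sim$collect))
    stop_invalid("simulation traces were not stored; rerun with collect = TRUE")
  p <- net$params; cfg <- net$config
  n <- cfg$n_hidden; n_out <- cfg$n_out; n_in <- cfg$n_in
  T <- sim$T; B <- sim$B
  if (is.matrix(grad_readout)) grad_readout <- array(grad_readout, c(n_out, 1L, T))
  if (!identical(dim(grad_readout), c(n_out, B, T)) &&
      !identical(as.integer(dim(grad_readout)), as.integer(c(n_out, B, T))))
    stop_invalid("grad_readout must be n_out x B x T")
  gz_fn <- if (is.null(grad_spikes)) {
    function(t) 0
  } else if (is.array(grad_spikes) && length(dim(grad_spikes)) == 3L) {
    function(t) matrix(grad_spikes[, , t], n, B)
  } else {
    gsm <- matrix(grad_spikes, n, B)
    function(t) gsm
  }
  dt <- p$dt
  dec_out <- 1 - dt / cfg$tau_out
  c_out <- dt / cfg$tau_out
  c_m <- dt / p$tau_m
  dly <- net$proj$in_m$delay
  P <- net$proj
  tWout <- t(net$W_out)
  tWrm <- t(P$rec_m$W); tWri <- t(P$rec_i$W); tWre <- t(P$rec_e$W)
  GIm <- array(0, c(n, B, T)); GIi <- array(0, c(n, B, T)); GIe <- array(0, c(n, B, T))
  GLAM <- array(0, c(n_out, B, T))
  glam_next <- zeros(n_out, B)
  gUm_next <- zeros(n, B); gUi_next <- zeros(n, B); gUe_next <- zeros(n, B)
  gtau_next <- zeros(n, B)
  for (t in T:1) {
    glam <- matrix(grad_readout[, , t], n_out, B) + dec_out * glam_next
    GLAM[, , t] <- glam
    Gam <- matrix(sim$GAM[, , t], n, B)
    Um <- matrix(sim$UM[, , t], n, B)
    Zt <- matrix(sim$Z[, , t], n, B)
    gz <- tWout %*% (c_out * glam) + gz_fn(t)
    if (t + dly <= T) {
      gz <- gz + tWrm %*% matrix(GIm[, , t + dly], n, B) +
        tWri %*% matrix(GIi[, , t + dly], n, B) +
        tWre %*% matrix(GIe[, , t + dly], n, B)
    }
    gz <- gz - Gam * gUm_next + (1 - p$beta) * gtau_next
    gv <- gz * matrix(sim$PD[, , t], n, B)
    gGam <- gv * (-Um / Gam^2) - Zt * gUm_next
    gtau <- p$beta * gtau_next + p$alpha * gGam
    gUm <- p$decay_m * gUm_next + gv / Gam
    GIm[, , t] <- c_m * p$R_m * gUm
    gUi <- p$decay_i * gUi_next + c_m * p$g_i * gUm_next
    gUe <- p$decay_e * gUe_next + c_m * p$g_e * gUm_next
    GIi[, , t] <- (dt / p$tau_i) * p$R_i * gUi
    GIe[, , t] <- (dt / p$tau_e) * p$R_e * gUe
    glam_next <- glam; gUm_next <- gUm; gUi_next <- gUi; gUe_next <- gUe
    gtau_next <- gtau
  }
  grads <- list()
  if (T > dly) {
    post <- (dly + 1L):T; pre <- 1L:(T - dly)
    Xf <- flatten_steps(sim$X, pre); Zf <- flatten_steps(sim$Z, pre)
    grads$in_m <- flatten_steps(GIm, post) %*% t(Xf)
    grads$in_i <- flatten_steps(GIi, post) %*% t(Xf)
    grads$in_e <- flatten_steps(GIe, post) %*% t(Xf)
    grads$rec_m <- flatten_steps(GIm, post) %*% t(Zf)
    grads$rec_i <- flatten_steps(GIi, post) %*% t(Zf)
    grads$rec_e <- flatten_steps(GIe, post) %*% t(Zf)
  } else {
    grads$in_m <- grads$in_i <- grads$in_e <- matrix(0, n, n_in)
    grads$rec_m <- grads$rec_i <- grads$rec_e <- matrix(0, n, n)
  }
  for (nm in names(P)) grads[[nm]] <- grads[[nm]] * P[[nm]]$mask
  GLf <- flatten_steps(GLAM, 1:T)
  grads$W_out <- c_out * (GLf %*% t(flatten_steps(sim$Z, 1:T)))
  grads$b_out <- c_out * rowSums(GLf)
  grads
}

# ADAM optimizer over a named list of parameter arrays.
adam_init <- function(template) {
  list(m = lapply(template, function(x) x * 0),
       v = lapply(template, function(x) x * 0),
       t = 0L)
}

adam_step <- function(opt, grads, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  deltas <- list()
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    deltas[[nm]] <- lr * mhat / (sqrt(vhat) + eps)
  }
  list(opt = opt, deltas = deltas)
}
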