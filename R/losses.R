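# Information-theoretic training criteria: kernel density estimates of Renyi
# quadratic entropy, quantized / restricted minimum-error-entropy information
# potentials, half-quadratic auxiliaries, and the combined RMEE +
# cross-entropy objective used for supervised sequence training.

#' Gaussian kernel
#'
#' Evaluates the Gaussian kernel with bandwidth \code{sigma},
#' \eqn{G_\sigma(x) = \exp(-x^2 / 2\sigma^2) / (\sqrt{2\pi}\,\sigma)}.
#' This is the kernel underlying all density and information-potential
#' estimates in the package.
#'
#' @param x numeric vector of evaluation points (error differences).
#' @param sigma kernel bandwidth, a single positive number.
#' @return numeric vector of non-negative densities, maximal at \code{x = 0}.
#' @examples
#' gaussian_kernel(0)            # 1/sqrt(2*pi)
#' gaussian_kernel(1, sigma = 1)
#' @export
gaussian_kernel <- function(x, sigma = 1) {
  check_scalar_pos(sigma, "sigma")
  exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

check_error_batch <- function(e) {
  if (length(e) < 1L) stop_invalid("error batch must contain at least one sample")
  check_finite(e, "error batch")
}

#' Information potential of an error sample
#'
#' The information potential is the pairwise kernel average
#' \eqn{V(e) = N^{-2} \sum_i \sum_j G_\sigma(e_i - e_j)}, i.e. the argument of
#' the negative log in the Renyi quadratic entropy estimator. Larger values
#' mean a more concentrated error distribution. \code{V} is invariant under
#' shifting every sample by the same constant.
#'
#' @param e numeric vector of scalar error samples.
#' @param sigma kernel bandwidth.
#' @return a single number in \code{(0, gaussian_kernel(0, sigma)]}.
#' @seealso [renyi_quadratic_entropy()], [rmee_potential()]
#' @export
information_potential <- function(e, sigma = 1) {
  check_error_batch(e)
  d <- outer(e, e, "-")
  mean(gaussian_kernel(d, sigma))
}

#' Renyi quadratic entropy of an error sample
#'
#' Kernel (Parzen) plug-in estimator \eqn{H_2(e) = -\log V(e)} where
#' \eqn{V} is the [information_potential()]. Minimizing \eqn{H_2} is
#' equivalent to maximizing \eqn{V}; both are shift invariant, which is the
#' deficiency the restricted criterion ([rmee_potential()]) removes.
#'
#' @inheritParams information_potential
#' @return the entropy estimate, a single number.
#' @export
renyi_quadratic_entropy <- function(e, sigma = 1) {
  -log(information_potential(e, sigma))
}

#' Instantaneous information potential over a Parzen window
#'
#' Sliding-window estimate of the information potential at sample index
#' \code{k}: \eqn{J_1 = W^{-1} \sum_{i=k-W+1}^{k} G_\sigma(e_k - e_i)}.
#'
#' @param e numeric vector of error samples, in arrival order.
#' @param window window length \code{W}, a positive integer.
#' @param k index (1-based) of the current sample; defaults to the last.
#' @param sigma kernel bandwidth.
#' @return a single number.
#' @export
parzen_instantaneous_ip <- function(e, window, k = length(e), sigma = 1) {
  check_error_batch(e)
  if (window < 1L || k > length(e) || window > k)
    stop_invalid("need 1 <= window <= k <= length(e); got window=%s, k=%s, N=%s",
                 window, k, length(e))
  idx <- (k - window + 1L):k
  mean(gaussian_kernel(e[k] - e[idx], sigma))
}

#' Quantize errors onto the restricted codebook (0, -1, 1)
#'
#' Counts error samples falling in the three bins of the restricted
#' minimum-error-entropy criterion: \eqn{\phi_0 = \#\{e \in (-0.5, 0.5)\}},
#' \eqn{\phi_{-1} = \#\{e \in (-1, -0.5)\}}, \eqn{\phi_1 = \#\{e \in (0.5, 1)\}}.
#' Samples outside these open intervals (magnitude at least 1, or exactly on a
#' bin boundary) are clamped to the nearest codeword, ties resolved toward 0,
#' so the counts always sum to \code{length(e)}. On the first training
#' iteration the counts are overridden to \code{(N, 0, 0)}, which is what
#' \code{first_iteration = TRUE} produces.
#'
#' @param e numeric vector of error samples.
#' @param first_iteration if \code{TRUE}, return the startup codebook
#'   \code{counts = (N, 0, 0)} regardless of the sample values.
#' @return an object of class \code{"rmee_codebook"}: a list with
#'   \code{centers = c(0, -1, 1)}, integer \code{counts} (phi0, phi-1, phi1)
#'   and \code{n}.
#' @export
quantize_errors <- function(e, first_iteration = FALSE) {
  check_error_batch(e)
  n <- length(e)
  if (isTRUE(first_iteration)) return(rmee_codebook(c(n, 0L, 0L)))
  phi0 <- sum(e > -0.5 & e < 0.5)
  phim <- sum(e > -1 & e < -0.5)
  phip <- sum(e > 0.5 & e < 1)
  rest <- e[!(abs(e) < 0.5) & !(e > -1 & e < -0.5) & !(e > 0.5 & e < 1)]
  if (length(rest)) {
    d <- abs(outer(rest, c(0, -1, 1), "-"))
    # ties go to the first (zero) codeword
    nearest <- apply(d, 1L, which.min)
    phi0 <- phi0 + sum(nearest == 1L)
    phim <- phim + sum(nearest == 2L)
    phip <- phip + sum(nearest == 3L)
  }
  rmee_codebook(c(phi0, phim, phip))
}

#' Restricted codebook constructor
#'
#' @param counts integer vector \code{(phi0, phi-1, phi1)} of samples
#'   quantized to each codeword.
#' @param centers codeword locations; the restricted criterion fixes them at
#'   \code{c(0, -1, 1)}, but arbitrary codebooks are accepted so the general
#'   quantized potential can be evaluated (e.g. one codeword per distinct
#'   sample recovers the unquantized potential exactly).
#' @return an object of class \code{"rmee_codebook"}.
#' @export
rmee_codebook <- function(counts, centers = c(0, -1, 1)) {
  if (length(counts) != length(centers))
    stop_invalid("counts and centers must have equal length")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("counts must be non-negative integers")
  structure(list(centers = centers, counts = as.integer(round(counts)),
                 n = sum(counts)),
            class = "rmee_codebook")
}

#' @export
print.rmee_codebook <- function(x, ...) {
  cat("RMEE codebook: centers (", paste(x$centers, collapse = ", "),
      "), counts (", paste(x$counts, collapse = ", "), "), N =", x$n, "\n")
  invisible(x)
}

check_codebook <- function(cb, e) {
  if (!inherits(cb, "rmee_codebook")) stop_invalid("codebook must be an rmee_codebook")
  if (cb$n != length(e) && cb$n > 0L)
    stop_invalid("codebook counts sum to %d but error batch has %d samples",
                 cb$n, length(e))
  invisible(cb)
}

#' Quantized / restricted information potential
#'
#' Evaluates the quantized information potential
#' \eqn{V_R(e) = N^{-2} \sum_i \sum_j \phi_j G_\sigma(e_i - c_j)}. With the
#' fixed codebook \code{(0, -1, 1)} this is the restricted
#' minimum-error-entropy (RMEE) potential, which pins the error distribution
#' to three peaks and is therefore not shift invariant.
#'
#' @param e numeric vector of error samples.
#' @param codebook an [rmee_codebook()] whose counts sum to \code{length(e)}
#'   (all-zero counts give potential 0).
#' @param sigma kernel bandwidth.
#' @return a single non-negative number.
#' @export
rmee_potential <- function(e, codebook, sigma = 1) {
  check_error_batch(e)
  check_codebook(codebook, e)
  n <- length(e)
  g <- gaussian_kernel(outer(e, codebook$centers, "-"), sigma)  # N x M
  sum(g %*% codebook$counts) / n^2
}

#' Half-quadratic auxiliary variables
#'
#' Computes the per-sample auxiliaries of the half-quadratic reformulation of
#' the RMEE potential: \eqn{u_i = -\exp(-e_i^2/2\sigma^2)},
#' \eqn{v_i = -\exp(-(e_i+1)^2/2\sigma^2)}, \eqn{s_i = -\exp(-(e_i-1)^2/2\sigma^2)}.
#' All components are strictly negative and lie in \eqn{[-1, 0)}. At these
#' values the quadratic surrogate [rmee_hq_objective()] touches the exact
#' potential, which is what makes the alternating scheme monotone.
#'
#' @inheritParams information_potential
#' @return an object of class \code{"hq_aux"}: list with vectors
#'   \code{u}, \code{v}, \code{s}.
#' @export
hq_auxiliaries <- function(e, sigma = 1) {
  check_error_batch(e)
  check_scalar_pos(sigma, "sigma")
  structure(list(u = -exp(-e^2 / (2 * sigma^2)),
                 v = -exp(-(e + 1)^2 / (2 * sigma^2)),
                 s = -exp(-(e - 1)^2 / (2 * sigma^2))),
            class = "hq_aux")
}

check_aux <- function(aux, e) {
  if (!inherits(aux, "hq_aux")) stop_invalid("aux must come from hq_auxiliaries()")
  if (length(aux$u) != length(e))
    stop_invalid("auxiliaries were computed for %d samples but batch has %d",
                 length(aux$u), length(e))
  invisible(aux)
}

#' Half-quadratic RMEE objective
#'
#' The quadratic surrogate of the restricted information potential for fixed
#' auxiliaries: \eqn{J_{R2} = \sum_i [\phi_0 u_i e_i^2 + \phi_{-1} v_i (e_i+1)^2
#' + \phi_1 s_i (e_i-1)^2]}. Because \eqn{u, v, s < 0}, \eqn{J_{R2} \le 0} and
#' it is to be maximized (toward 0): alternating [hq_auxiliaries()] updates
#' with quadratic maximization ([rmee_hq_update()]) never decreases
#' [rmee_potential()].
#'
#' @param e numeric vector of error samples.
#' @param codebook an [rmee_codebook()].
#' @param aux auxiliaries from [hq_auxiliaries()], possibly computed at an
#'   earlier error batch of the same length.
#' @return a single non-positive number.
#' @export
rmee_hq_objective <- function(e, codebook, aux) {
  check_error_batch(e)
  check_codebook(codebook, e)
  check_aux(aux, e)
  ph <- codebook$counts
  sum(ph[1L] * aux$u * e^2 + ph[2L] * aux$v * (e + 1)^2 + ph[3L] * aux$s * (e - 1)^2)
}

#' Gradient of the half-quadratic RMEE objective
#'
#' Per-sample derivative \eqn{\partial J_{R2}/\partial e_i =
#' 2[\phi_0 u_i e_i + \phi_{-1} v_i (e_i+1) + \phi_1 s_i (e_i-1)]} for fixed
#' auxiliaries. Downstream gradients with respect to network parameters are
#' obtained by chaining this factor through backpropagation through time
#' ([bptt_gradients()]), so no particular readout nonlinearity is assumed here.
#'
#' @inheritParams rmee_hq_objective
#' @return numeric vector, one derivative per error sample.
#' @export
rmee_gradient <- function(e, codebook, aux) {
  check_error_batch(e)
  check_codebook(codebook, e)
  check_aux(aux, e)
  ph <- codebook$counts
  2 * (ph[1L] * aux$u * e + ph[2L] * aux$v * (e + 1) + ph[3L] * aux$s * (e - 1))
}

#' One half-quadratic error-maximization step
#'
#' For fixed auxiliaries and codebook counts, returns the error vector that
#' maximizes the concave quadratic [rmee_hq_objective()]:
#' \eqn{e_i^* = (\phi_1 s_i - \phi_{-1} v_i) / (\phi_0 u_i + \phi_{-1} v_i +
#' \phi_1 s_i)}. Together with [hq_auxiliaries()] this forms the alternating
#' half-quadratic scheme whose iterates monotonically increase
#' [rmee_potential()].
#'
#' @inheritParams rmee_hq_objective
#' @return numeric vector of updated error samples.
#' @export
rmee_hq_update <- function(e, codebook, aux) {
  check_error_batch(e)
  check_codebook(codebook, e)
  check_aux(aux, e)
  ph <- codebook$counts
  den <- ph[1L] * aux$u + ph[2L] * aux$v + ph[3L] * aux$s
  num <- ph[3L] * aux$s - ph[2L] * aux$v
  out <- e
  ok <- abs(den) > .Machine$double.eps
  out[ok] <- num[ok] / den[ok]
  out
}

#' Binary cross-entropy
#'
#' \eqn{-[y \log \hat y + (1-y) \log(1-\hat y)]}, elementwise. Predicted
#' probabilities are clamped to \code{[1e-12, 1 - 1e-12]} before taking logs
#' so the loss is always finite; values outside \code{[0, 1]} are an error.
#'
#' @param yhat predicted probabilities in \code{[0, 1]}.
#' @param y labels in \code{\{0, 1\}} (recycled against \code{yhat}).
#' @return numeric vector of non-negative losses.
#' @export
cross_entropy <- function(yhat, y) {
  check_finite(yhat, "yhat")
  if (any(yhat < 0 | yhat > 1)) stop_invalid("yhat must lie in [0, 1]")
  if (any(!(y %in% c(0, 1)))) stop_invalid("labels must be 0 or 1")
  p <- clamp_prob(yhat)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Readout times of a rendered image sequence
#'
#' The sequential classification tasks render each image for
#' \code{steps_per_image} time steps after an equally long cue period, and the
#' readout for image \code{n} is taken at \eqn{t = 20 + 20 n} (for the default
#' 20 steps per image).
#'
#' @param n_images number of rendered images.
#' @param steps_per_image rendering duration per image, in time steps.
#' @return integer vector of readout time indices (1-based).
#' @export
readout_times <- function(n_images = 5, steps_per_image = 20) {
  as.integer(steps_per_image + steps_per_image * seq_len(n_images))
}

#' Cross-entropy loss of a sequence readout trace
#'
#' Sums the binary cross-entropy of the logistic readout at the five
#' image-boundary times: \eqn{J_2 = \sum_{n=1}^{5} -[l_n \log\sigma(y_{20+20n})
#' + (1-l_n)\log(1-\sigma(y_{20+20n}))]}. Only the readout at those times
#' enters the loss; the rest of the trace is ignored.
#'
#' @param trace numeric vector of pre-sigmoid readout values over time.
#' @param labels binary labels, one per rendered image (default length 5).
#' @param steps_per_image rendering duration per image.
#' @return a single non-negative number.
#' @export
sequence_readout_loss <- function(trace, labels, steps_per_image = 20) {
  if (any(!(labels %in% c(0, 1)))) stop_invalid("labels must be 0 or 1")
  tt <- readout_times(length(labels), steps_per_image)
  if (length(trace) < max(tt))
    stop_invalid("readout trace has %d steps but time %d is required",
                 length(trace), max(tt))
  sum(cross_entropy(sigmoid(trace[tt]), labels))
}

#' Combined RMEE + cross-entropy criterion
#'
#' The supervised training objective is the convex combination
#' \code{combined = mu * rmee_term + (1 - mu) * ce_term}. The RMEE term is the
#' negated, \eqn{1/N^2}-normalized half-quadratic objective
#' \eqn{-J_{R2}/N^2}, so that both terms are minimized (maximizing
#' \eqn{J_{R2}} concentrates errors on the codebook) and the trade-off weight
#' \code{mu} is insensitive to batch size. \code{mu = 1} gives the pure RMEE
#' criterion, \code{mu = 0} pure cross-entropy.
#'
#' @param e numeric vector of error samples at the readout times.
#' @param codebook an [rmee_codebook()] for \code{e}.
#' @param aux auxiliaries from [hq_auxiliaries()].
#' @param readout_trace pre-sigmoid readout time series.
#' @param labels binary labels for the rendered images.
#' @param mu weighting constant in \code{[0, 1]}.
#' @param steps_per_image rendering duration per image.
#' @return an object of class \code{"loss_breakdown"}: list with
#'   \code{rmee_term}, \code{ce_term}, \code{combined} and \code{mu}.
#' @export
combined_loss <- function(e, codebook, aux, readout_trace, labels, mu,
                          steps_per_image = 20) {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0 || mu > 1)
    stop_invalid("mu must be a single number in [0, 1]")
  n <- length(e)
  rmee <- -rmee_hq_objective(e, codebook, aux) / n^2
  ce <- sequence_readout_loss(readout_trace, labels, steps_per_image)
  structure(list(rmee_term = rmee, ce_term = ce,
                 combined = mu * rmee + (1 - mu) * ce, mu = mu),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("combined loss %.6g = %.2f * RMEE(%.6g) + %.2f * CE(%.6g)\n",
              x$combined, x$mu, x$rmee_term, 1 - x$mu, x$ce_term))
  invisible(x)
}
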