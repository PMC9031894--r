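# Synthetic task generators and encoders/decoders for the three benchmarks:
# store-recall working memory, noisy sequential glyph classification, and
# the 2D navigation arena.
#
# All generators are pure functions of their parameters and the seed: when a
# seed is supplied the caller's RNG stream is left untouched; with
# seed = NULL they draw from (and advance) the global RNG, which is how the
# trainers consume them so that a single training seed fixes the whole run.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

# ---- store-recall -----------------------------------------------------------

#' Generate store-recall episodes
#'
#' Working-memory episodes over 40 input channels: channels 1-10 carry value
#' stream A, 11-20 value stream B, 21-30 the store command, 31-40 the recall
#' command. Time is divided into frames of \code{frame_len} steps; in each
#' frame one of the two value streams is active (a Bernoulli bit) and emits
#' Poisson spikes at \code{value_rate} Hz. One frame in the first half of the
#' episode is accompanied by the store command (all command channels firing),
#' and one frame in the second half by the recall command, during which the
#' value streams are silenced. The target is the bit (1 = stream A) that was
#' active during the store frame, to be reproduced at recall.
#'
#' @param n_episodes batch size.
#' @param T episode length in steps; must hold at least four frames.
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @param frame_len frame (and command window) length in steps.
#' @param value_rate Poisson rate of the active value stream (Hz).
#' @param dt step in ms.
#' @return an object of class \code{"supervised_batch"}: input array \code{X}
#'   (\code{40 x n_episodes x T}), \code{labels} (\code{1 x n_episodes}),
#'   \code{windows} (readout steps per label and episode), and the store /
#'   recall frame indices in \code{meta}.
#' @export
gen_store_recall <- function(n_episodes, T = 120, seed = NULL,
                             frame_len = 10, value_rate = 50, dt = 1) {
  n_frames <- T %/% frame_len
  if (n_frames < 4) stop_invalid("T = %d holds fewer than 4 frames of %d steps", T, frame_len)
  with_seed(seed, {
    B <- n_episodes
    X <- array(0, c(40L, B, T))
    p_val <- value_rate * dt / 1000
    first_half <- 2:floor(n_frames / 2)
    second_half <- (floor(n_frames / 2) + 1L):n_frames
    store_f <- sample(first_half, B, replace = TRUE)
    recall_f <- sample(second_half, B, replace = TRUE)
    bits <- matrix(rbinom(n_frames * B, 1, 0.5), n_frames, B)
    labels <- matrix(bits[cbind(store_f, seq_len(B))], 1, B)
    windows <- matrix(0L, frame_len, B)
    for (b in seq_len(B)) {
      for (f in seq_len(n_frames)) {
        steps <- ((f - 1L) * frame_len + 1L):(f * frame_len)
        if (f == recall_f[b]) next  # value streams silent during recall
        ch <- if (bits[f, b] == 1) 1:10 else 11:20
        X[ch, b, steps] <- rbinom(10L * frame_len, 1, p_val)
      }
      st <- ((store_f[b] - 1L) * frame_len + 1L):(store_f[b] * frame_len)
      rc <- ((recall_f[b] - 1L) * frame_len + 1L):(recall_f[b] * frame_len)
      X[21:30, b, st] <- 1
      X[31:40, b, rc] <- 1
      windows[, b] <- rc
    }
    structure(list(X = X, labels = labels, windows = list(windows),
                   meta = list(task = "store_recall", store_frame = store_f,
                               recall_frame = recall_f, frame_len = frame_len)),
              class = "supervised_batch")
  })
}

# ---- noisy glyph sequences --------------------------------------------------

#' Procedural glyph templates
#'
#' Ten distinguishable binary 28 x 28 glyphs (bars, diagonals, cross, saltire,
#' box, checkerboard, half-fills) standing in for handwritten digits so the
#' sequential classification task needs no external data.
#'
#' @return list of ten 28 x 28 matrices with entries in \code{\{0, 1\}}.
#' @export
glyph_templates <- function() {
  n <- 28L
  idx <- function(cond) { m <- matrix(0, n, n); m[cond] <- 1; m }
  r <- row(matrix(0, n, n)); co <- col(matrix(0, n, n))
  list(
    vbar = idx(co >= 12 & co <= 16),
    hbar = idx(r >= 12 & r <= 16),
    diag = idx(abs(r - co) <= 2),
    anti = idx(abs(r + co - (n + 1)) <= 2),
    cross = idx((co >= 12 & co <= 16) | (r >= 12 & r <= 16)),
    saltire = idx(abs(r - co) <= 2 | abs(r + co - (n + 1)) <= 2),
    box = idx(pmin(r, co, n + 1 - r, n + 1 - co) <= 3),
    checker = idx((((r - 1) %/% 4) + ((co - 1) %/% 4)) %% 2 == 0),
    lefthalf = idx(co <= 14),
    tophalf = idx(r <= 14))
}

#' Salt-and-pepper pixel corruption
#'
#' Each pixel is independently selected with probability \code{fraction} and,
#' if selected, replaced by 0 or 1 with equal odds; unselected pixels are
#' untouched.
#'
#' @param image numeric matrix or array with values in \code{[0, 1]}.
#' @param fraction corruption probability per pixel, in \code{[0, 1]}.
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @return corrupted image of the same shape.
#' @export
salt_pepper <- function(image, fraction, seed = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0 || fraction > 1)
    stop_invalid("fraction must be a single number in [0, 1]")
  with_seed(seed, {
    hit <- stats::runif(length(image)) < fraction
    image[hit] <- stats::rbinom(sum(hit), 1, 0.5)
    image
  })
}

#' Generate noisy glyph-sequence trials
#'
#' Each trial presents a cue glyph for \code{steps_per_image} steps followed
#' by five test glyphs of \code{steps_per_image} steps each, all corrupted by
#' salt-and-pepper noise. Images are streamed as one scanned row of 28 pixel
#' channels per time step (analog intensities). The five binary labels mark
#' which test images belong to the reference class; the readout for image
#' \code{n} is taken at \eqn{t = 20 + 20 n} (the image boundaries, see
#' [readout_times()]). Each test image matches the reference class with
#' probability 1/2, so labels are balanced.
#'
#' By default the reference class is a fixed glyph class whose template is
#' rendered in the cue period of every trial, making the task noise-robust
#' recognition of that class. With \code{target_class = NULL} the cue class
#' instead cycles through all ten glyphs and the labels mean "same class as
#' this trial's cue" - a substantially harder within-trial matching variant.
#'
#' @param n_trials batch size.
#' @param noise_fraction salt-and-pepper corruption probability.
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @param steps_per_image rendering duration per image (steps).
#' @param target_class index of the fixed reference glyph (1..10), or
#'   \code{NULL} for the rotating-cue matching variant.
#' @return an object of class \code{"supervised_batch"} with \code{X}
#'   (\code{28 x n_trials x 6*steps_per_image}), \code{labels}
#'   (\code{5 x n_trials}), single-step readout \code{windows}, and the cue /
#'   test classes in \code{meta}.
#' @export
gen_noisy_sequences <- function(n_trials, noise_fraction = 0.1, seed = NULL,
                                steps_per_image = 20, target_class = 1) {
  with_seed(seed, {
    tmpl <- glyph_templates()
    n_cls <- length(tmpl)
    B <- n_trials
    T <- 6L * steps_per_image
    scan_rows <- round(seq(1, 28, length.out = steps_per_image))
    X <- array(0, c(28L, B, T))
    labels <- matrix(0, 5L, B)
    cue_cls <- integer(B); test_cls <- matrix(0L, 5L, B)
    render <- function(cls) {
      img <- salt_pepper(tmpl[[cls]], noise_fraction)
      t(img[scan_rows, , drop = FALSE])  # 28 channels x steps
    }
    for (b in seq_len(B)) {
      cue_cls[b] <- if (is.null(target_class)) ((b - 1L) %% n_cls) + 1L
                    else as.integer(target_class)
      X[, b, 1:steps_per_image] <- render(cue_cls[b])
      for (im in 1:5) {
        same <- stats::runif(1) < 0.5
        cls <- if (same) cue_cls[b] else sample(setdiff(seq_len(n_cls), cue_cls[b]), 1L)
        test_cls[im, b] <- cls
        labels[im, b] <- as.numeric(cls == cue_cls[b])
        steps <- (im * steps_per_image + 1L):((im + 1L) * steps_per_image)
        X[, b, steps] <- render(cls)
      }
    }
    tt <- readout_times(5, steps_per_image)
    windows <- lapply(tt, function(t) matrix(t, 1L, B))
    structure(list(X = X, labels = labels, windows = windows,
                   meta = list(task = "noisy_seq", cue_class = cue_cls,
                               test_class = test_cls,
                               target_class = target_class,
                               noise_fraction = noise_fraction,
                               steps_per_image = steps_per_image)),
              class = "supervised_batch")
  })
}

# ---- navigation arena -------------------------------------------------------

#' Gaussian population rate code
#'
#' Assigns each input neuron a preferred coordinate in \code{[0, 1]}; a value
#' \eqn{\xi} drives neuron \eqn{i} at rate \eqn{r_{max}\exp(-w(\xi_i -
#' \xi)^2)} with width factor \eqn{w = 100} and \eqn{r_{max} = 500} Hz by
#' default.
#'
#' @param n_neurons neurons per encoded dimension.
#' @param r_max peak firing rate (Hz).
#' @param width exponent coefficient (inverse squared tuning width).
#' @return an object of class \code{"population_code"}.
#' @export
population_code <- function(n_neurons = 10, r_max = 500, width = 100) {
  structure(list(centers = seq(0, 1, length.out = n_neurons),
                 r_max = r_max, width = width),
            class = "population_code")
}

#' Encode a scalar with a population rate code
#'
#' @param value coordinate in \code{[0, 1]} (scalar or vector; one column of
#'   rates per value).
#' @param code a [population_code()].
#' @return matrix of firing rates in Hz, \code{n_neurons x length(value)}
#'   (dropped to a vector for a single value).
#' @export
population_encode <- function(value, code = population_code()) {
  check_scalar_pos(code$r_max, "r_max")
  out <- sapply(value, function(v) code$r_max * exp(-code$width * (code$centers - v)^2))
  if (length(value) == 1L) as.numeric(out) else out
}

#' Create navigation arenas
#'
#' A batch of independent unit-square arenas. Agent start and destination are
#' uniform over the square; the agent moves by a velocity vector whose
#' Euclidean norm is clipped to \code{max_speed}, and receives reward 1 on
#' the step it first comes within \code{radius} of the destination, which
#' ends the episode.
#'
#' @param n number of parallel episodes.
#' @param radius destination radius.
#' @param max_speed per-step speed bound.
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @param goal optional fixed destination (length-2 vector) used for every
#'   episode instead of a random draw.
#' @return an object of class \code{"nav_arena"}.
#' @export
arena_init <- function(n = 1, radius = 0.05, max_speed = 0.02, seed = NULL,
                       goal = NULL) {
  with_seed(seed, {
    structure(list(pos = matrix(stats::runif(2 * n), 2, n),
                   goal = if (is.null(goal)) matrix(stats::runif(2 * n), 2, n)
                          else matrix(goal, 2, n),
                   radius = radius, max_speed = max_speed,
                   done = rep(FALSE, n), n = n),
              class = "nav_arena")
  })
}

clip_norm <- function(a, max_norm) {
  nr <- sqrt(colSums(a^2))
  s <- ifelse(nr > max_norm, max_norm / nr, 1)
  a * rep(s, each = 2)
}

#' Advance the arenas by one action
#'
#' Applies the (norm-clipped) velocity to each active episode, clips the
#' position to the unit square, and emits reward 1 for episodes reaching
#' their destination. By default a reach latches \code{done} and the episode
#' ignores further actions; with \code{respawn = TRUE} (the training
#' setting) the agent is instead teleported to a fresh uniform position
#' while the destination stays put, so it can exploit its stored knowledge
#' of the destination for the rest of the episode and the per-episode reach
#' count is unbounded.
#'
#' @param arena a [arena_init()] object.
#' @param action \code{2 x n} velocity matrix (or length-2 vector for
#'   \code{n = 1}).
#' @param respawn teleport reaching agents to a new random start instead of
#'   ending their episode.
#' @return list with the updated \code{arena}, numeric \code{reward} (0/1 per
#'   episode) and logical \code{done}.
#' @export
arena_step <- function(arena, action, respawn = FALSE) {
  a <- clip_norm(matrix(action, 2, arena$n), arena$max_speed)
  act <- !arena$done
  arena$pos[, act] <- pmin(pmax(arena$pos[, act, drop = FALSE] +
                                  a[, act, drop = FALSE], 0), 1)
  d <- sqrt(colSums((arena$pos - arena$goal)^2))
  reached <- act & (d <= arena$radius)
  if (respawn) {
    if (any(reached))
      arena$pos[, reached] <- matrix(stats::runif(2 * sum(reached)), 2)
  } else {
    arena$done <- arena$done | reached
  }
  list(arena = arena, reward = as.numeric(reached), done = arena$done)
}

#' Decode readout potentials into an action and a value estimate
#'
#' The five readout traces parameterize a diagonal Gaussian policy and a
#' value estimate: action mean \eqn{(\tanh\lambda_1, \tanh\lambda_2)},
#' variances \eqn{(\sigma(\lambda_3), \sigma(\lambda_4))}, value
#' \eqn{\lambda_5}. An action is sampled from the Gaussian and its Euclidean
#' norm clipped to \code{max_speed}; the log-density of the unclipped sample
#' is returned for the policy-gradient ratio.
#'
#' @param lambda readout potentials, a length-5 vector or \code{5 x n} matrix.
#' @param max_speed speed bound applied to the sampled action.
#' @return list with \code{mean}, \code{var} (\code{2 x n}), \code{raw} (the
#'   Gaussian sample), \code{action} (norm-clipped), \code{value} and
#'   \code{logp} (length-\code{n} vectors).
#' @export
decode_action <- function(lambda, max_speed = 0.02) {
  if ((is.matrix(lambda) && nrow(lambda) != 5) ||
      (!is.matrix(lambda) && length(lambda) %% 5 != 0))
    stop_invalid("five readout traces are required")
  lam <- matrix(lambda, 5)
  n <- ncol(lam)
  mu <- tanh(lam[1:2, , drop = FALSE])
  vr <- sigmoid(lam[3:4, , drop = FALSE])
  raw <- mu + sqrt(vr) * matrix(stats::rnorm(2 * n), 2, n)
  logp <- colSums(-0.5 * log(2 * pi * vr) - (raw - mu)^2 / (2 * vr))
  list(mean = mu, var = vr, raw = raw,
       action = clip_norm(raw, max_speed),
       value = lam[5, ], logp = logp)
}

#' Discounted future returns
#'
#' \eqn{\Omega(t) = \sum_{t' > t} \gamma^{t'-t} \omega(t')}: the discounted
#' sum of strictly future rewards, computed by backward recursion
#' \eqn{\Omega(t) = \gamma(\omega(t+1) + \Omega(t+1))}.
#'
#' @param rewards numeric vector of per-step rewards.
#' @param gamma discount factor in \code{[0, 1)}.
#' @return numeric vector of returns, same length.
#' @export
discounted_returns <- function(rewards, gamma = 0.99) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma >= 1)
    stop_invalid("gamma must lie in [0, 1)")
  T <- length(rewards)
  out <- numeric(T)
  if (T > 1) for (t in (T - 1):1) out[t] <- gamma * (rewards[t + 1] + out[t + 1])
  out
}
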