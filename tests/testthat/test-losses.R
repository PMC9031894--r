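# Kernel, entropy and RMEE loss machinery against closed forms and
# brute-force oracles.

test_that("Gaussian kernel matches its closed form and rejects bad bandwidths", {
  expect_equal(gaussian_kernel(0), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(gaussian_kernel(1), exp(-0.5) / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(gaussian_kernel(c(-2, 2), sigma = 0.5),
               gk(c(2, 2), 0.5), tolerance = 1e-12)
  expect_lt(gaussian_kernel(40), 1e-300)
  expect_error(gaussian_kernel(0, sigma = 0), "positive")
  expect_error(gaussian_kernel(0, sigma = -1), "positive")
})

test_that("information potential equals the pairwise kernel mean", {
  expect_equal(information_potential(rep(0.3, 5)), gk(0), tolerance = 1e-9)
  expect_equal(information_potential(c(0, 1)), (2 * gk(0) + 2 * gk(1)) / 4,
               tolerance = 1e-9)
  set.seed(11)
  for (r in 1:5) {
    e <- rnorm(sample(2:12, 1)); s <- runif(1, 0.3, 2)
    expect_equal(information_potential(e, s), ip_brute(e, s), tolerance = 1e-12)
  }
  expect_error(information_potential(numeric(0)), "at least one")
  expect_error(information_potential(c(1, NA)), "non-finite")
})

test_that("Renyi quadratic entropy is -log V and shift invariant", {
  expect_equal(renyi_quadratic_entropy(rep(1, 4)), -log(gk(0)), tolerance = 1e-9)
  expect_equal(renyi_quadratic_entropy(c(0, 1)), -log((2 * gk(0) + 2 * gk(1)) / 4),
               tolerance = 1e-9)
  set.seed(2)
  e <- rnorm(30)
  for (c0 in c(-5, 0.37, 120)) {
    expect_equal(information_potential(e + c0), information_potential(e),
                 tolerance = 1e-12)
    expect_equal(renyi_quadratic_entropy(e + c0), renyi_quadratic_entropy(e),
                 tolerance = 1e-12)
  }
  # entropy decreases as samples concentrate
  expect_gt(renyi_quadratic_entropy(c(-1, 1)), renyi_quadratic_entropy(c(-0.1, 0.1)))
})

test_that("kernel entropy estimate agrees with the analytic smoothed entropy", {
  # for N(0,1) samples, V converges to the density of N(0, sigma^2 + 2) at 0
  set.seed(4)
  e <- rnorm(10000)
  sig <- 0.1
  # chunked pairwise evaluation to keep memory modest
  tot <- 0
  for (chunk in split(e, (seq_along(e) - 1) %/% 1000))
    tot <- tot + sum(gaussian_kernel(outer(chunk, e, "-"), sig))
  h2 <- -log(tot / length(e)^2)
  expect_lt(abs(h2 - (-log(1 / sqrt(2 * pi * (sig^2 + 2))))), 0.05)
})

test_that("instantaneous Parzen-window potential matches the windowed sum", {
  expect_equal(parzen_instantaneous_ip(c(0.4, 2, -1), window = 1), gk(0),
               tolerance = 1e-9)
  expect_equal(parzen_instantaneous_ip(c(0, 1), window = 2), (gk(0) + gk(1)) / 2,
               tolerance = 1e-9)
  set.seed(5)
  for (r in 1:10) {
    e <- rnorm(sample(3:15, 1))
    k <- sample(seq_along(e), 1); w <- sample(k, 1); s <- runif(1, 0.4, 1.6)
    expect_equal(parzen_instantaneous_ip(e, w, k, s),
                 mean(gk(e[k] - e[(k - w + 1):k], s)), tolerance = 1e-12)
  }
  expect_error(parzen_instantaneous_ip(c(1, 2), window = 3), "window")
})

test_that("quantization bins errors onto the restricted codebook", {
  cb <- quantize_errors(c(0.1, -0.7, 0.9))
  expect_identical(cb$counts, c(1L, 1L, 1L))
  expect_identical(cb$centers, c(0, -1, 1))
  cb0 <- quantize_errors(rnorm(17), first_iteration = TRUE)
  expect_identical(cb0$counts, c(17L, 0L, 0L))
  # out-of-range and boundary samples clamp to the nearest codeword
  expect_identical(quantize_errors(2.0)$counts, c(0L, 0L, 1L))
  expect_identical(quantize_errors(-3.5)$counts, c(0L, 1L, 0L))
  expect_identical(quantize_errors(0.5)$counts, c(1L, 0L, 0L))  # tie -> 0
  expect_identical(quantize_errors(-1)$counts, c(0L, 1L, 0L))
  set.seed(6)
  for (r in 1:20) {
    e <- runif(sample(1:50, 1), -3, 3)
    expect_identical(sum(quantize_errors(e)$counts), length(e))
  }
})

test_that("half-quadratic auxiliaries take their closed form and stay negative", {
  a <- hq_auxiliaries(0)
  expect_equal(c(a$u, a$v, a$s), c(-1, -exp(-0.5), -exp(-0.5)), tolerance = 1e-6)
  a1 <- hq_auxiliaries(1)
  expect_equal(c(a1$u, a1$v, a1$s), c(-exp(-0.5), -exp(-2), -1), tolerance = 1e-6)
  set.seed(7)
  for (r in 1:10) {
    a <- hq_auxiliaries(rnorm(20, sd = 3), sigma = runif(1, 0.3, 2))
    expect_true(all(c(a$u, a$v, a$s) < 0))
    expect_true(all(c(a$u, a$v, a$s) >= -1))
  }
  expect_error(hq_auxiliaries(c(0, Inf)), "non-finite")
})

test_that("restricted potential matches brute force and generalizes QMEE to MEE", {
  n <- 6
  e0 <- rep(0, n)
  expect_equal(rmee_potential(e0, rmee_codebook(c(n, 0, 0))), gk(0), tolerance = 1e-9)
  expect_equal(rmee_potential(c(0, 1), rmee_codebook(c(1, 0, 1))),
               (gk(0) + gk(1) + gk(1) + gk(0)) / 4, tolerance = 1e-9)
  expect_equal(rmee_potential(c(0.3, -0.2), rmee_codebook(c(0, 0, 0))), 0)
  expect_error(rmee_potential(c(0, 1), rmee_codebook(c(2, 0, 1))), "sum to")
  # with one codeword per distinct sample, the quantized potential is exactly
  # the unquantized information potential
  set.seed(8)
  for (r in 1:10) {
    vals <- round(rnorm(sample(3:6, 1)), 2)
    e <- sample(vals, sample(5:20, 1), replace = TRUE)
    tab <- table(e)
    cb <- rmee_codebook(as.integer(tab), centers = as.numeric(names(tab)))
    expect_equal(rmee_potential(e, cb), information_potential(e), tolerance = 1e-12)
  }
})

test_that("half-quadratic objective, gradient and update are mutually consistent", {
  cb1 <- rmee_codebook(c(1, 0, 0))
  aux0 <- hq_auxiliaries(0)
  expect_equal(rmee_hq_objective(0, cb1, aux0), 0, tolerance = 1e-12)
  e5 <- 0.5
  aux5 <- hq_auxiliaries(e5)
  expect_equal(rmee_hq_objective(e5, cb1, aux5), -exp(-0.125) * 0.25,
               tolerance = 1e-6)
  expect_equal(rmee_gradient(e5, cb1, aux5), -exp(-0.125), tolerance = 1e-6)
  expect_equal(rmee_gradient(0, cb1, aux0), 0, tolerance = 1e-12)
  # gradient matches central differences of the objective
  set.seed(9)
  h <- 1e-6
  for (r in 1:20) {
    e <- runif(8, -1.5, 1.5)
    cb <- quantize_errors(e)
    aux <- hq_auxiliaries(runif(8, -1.5, 1.5), sigma = runif(1, 0.5, 1.5))
    g <- rmee_gradient(e, cb, aux)
    for (i in sample(8, 2)) {
      ep <- e; ep[i] <- e[i] + h
      em <- e; em[i] <- e[i] - h
      fd <- (rmee_hq_objective(ep, cb, aux) - rmee_hq_objective(em, cb, aux)) / (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("alternating half-quadratic steps never decrease the restricted potential", {
  set.seed(10)
  for (r in 1:30) {
    e <- runif(sample(3:15, 1), -2, 2)
    cb <- quantize_errors(e)
    sig <- runif(1, 0.5, 1.5)
    v_prev <- rmee_potential(e, cb, sig)
    for (it in 1:20) {
      aux <- hq_auxiliaries(e, sig)
      e <- rmee_hq_update(e, cb, aux)
      v_new <- rmee_potential(e, cb, sig)
      expect_gte(v_new, v_prev - 1e-12)
      v_prev <- v_new
    }
  }
})

test_that("cross-entropy takes its binary form with clamped probabilities", {
  expect_equal(cross_entropy(1, 1), 0, tolerance = 1e-9)
  expect_equal(cross_entropy(0.5, 1), log(2), tolerance = 1e-9)
  expect_equal(cross_entropy(0.25, 0), -log(0.75), tolerance = 1e-9)
  expect_true(is.finite(cross_entropy(0, 1)))  # clamp keeps the loss finite
  expect_lt(cross_entropy(0, 1), 30)
  expect_error(cross_entropy(1.2, 1), "\\[0, 1\\]")
  expect_error(cross_entropy(0.5, 2), "labels")
})

test_that("sequence readout loss reads only the image-boundary times", {
  expect_identical(readout_times(), c(40L, 60L, 80L, 100L, 120L))
  labels <- c(1, 0, 1, 1, 0)
  tr <- rep(0, 120)
  tr[readout_times()] <- ifelse(labels == 1, 40, -40)  # sigmoid ~ label
  expect_lt(sequence_readout_loss(tr, labels), 1e-10)
  expect_equal(sequence_readout_loss(rep(0, 120), labels), 5 * log(2),
               tolerance = 1e-9)
  tr2 <- tr
  tr2[-readout_times()] <- rnorm(115, sd = 10)
  expect_equal(sequence_readout_loss(tr2, labels), sequence_readout_loss(tr, labels))
  expect_error(sequence_readout_loss(rep(0, 100), labels), "120")
})

test_that("combined criterion is the stated convex combination", {
  set.seed(12)
  e <- runif(10, -1, 1)
  cb <- quantize_errors(e)
  aux <- hq_auxiliaries(e)
  tr <- rnorm(120)
  labels <- rbinom(5, 1, 0.5)
  a <- combined_loss(e, cb, aux, tr, labels, mu = 1)
  b <- combined_loss(e, cb, aux, tr, labels, mu = 0)
  m <- combined_loss(e, cb, aux, tr, labels, mu = 0.7)
  expect_equal(a$combined, a$rmee_term, tolerance = 1e-12)
  expect_equal(b$combined, b$ce_term, tolerance = 1e-12)
  expect_equal(m$combined, 0.7 * a$rmee_term + 0.3 * b$ce_term, tolerance = 1e-12)
  expect_equal(m$rmee_term, -rmee_hq_objective(e, cb, aux) / 100, tolerance = 1e-12)
  expect_error(combined_loss(e, cb, aux, tr, labels, mu = 1.4), "mu")
})
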