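# Synthetic task generators, encoders and decoders.

test_that("store-recall episodes have the stated channel layout and ordering", {
  b <- gen_store_recall(20, T = 120, seed = 31)
  expect_identical(dim(b$X)[1], 40L)
  expect_true(all(b$meta$store_frame < b$meta$recall_frame))
  expect_true(all(b$labels %in% c(0, 1)))
  # command channels fire through their windows; value streams are silent at
  # recall; the target matches the stream active during the store window
  for (ep in 1:5) {
    st <- ((b$meta$store_frame[ep] - 1) * 10 + 1):(b$meta$store_frame[ep] * 10)
    rc <- b$windows[[1]][, ep]
    expect_true(all(b$X[21:30, ep, st] == 1))
    expect_true(all(b$X[31:40, ep, rc] == 1))
    expect_true(all(b$X[1:20, ep, rc] == 0))
    active <- if (b$labels[1, ep] == 1) 1:10 else 11:20
    silent <- setdiff(1:20, active)
    expect_true(all(b$X[silent, ep, st] == 0))
  }
  expect_identical(gen_store_recall(4, T = 120, seed = 7)$X,
                   gen_store_recall(4, T = 120, seed = 7)$X)
  expect_error(gen_store_recall(2, T = 30), "frames")
})

test_that("salt-and-pepper corruption hits the right fraction with 0/1 values", {
  img <- matrix(0.5, 40, 40)
  expect_identical(salt_pepper(img, 0, seed = 1), img)
  out <- salt_pepper(matrix(0.5, 28, 28 * 1000 / 28), 0.1, seed = 2)
  frac <- mean(out != 0.5)
  # note corrupted pixels drawn as 0.5 would be invisible; none exist here
  n <- length(out)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  expect_true(all(out[out != 0.5] %in% c(0, 1)))
  expect_error(salt_pepper(img, 1.5), "fraction")
})

test_that("glyph classes are mutually distinguishable by template matching", {
  tm <- glyph_templates()
  expect_length(tm, 10)
  expect_true(all(sapply(tm, function(m) all(m %in% c(0, 1)))))
  # clean sequences are perfectly classified by template correlation
  b <- gen_noisy_sequences(20, noise_fraction = 0, seed = 3, target_class = NULL)
  scan_rows <- round(seq(1, 28, length.out = 20))
  flat <- sapply(tm, function(m) as.numeric(t(m[scan_rows, ])))
  hits <- 0; total <- 0
  for (ep in 1:20) for (im in 1:5) {
    steps <- (im * 20 + 1):((im + 1) * 20)
    cors <- cor(as.numeric(b$X[, ep, steps]), flat)
    total <- total + 1
    hits <- hits + (which.max(cors) == b$meta$test_class[im, ep])
  }
  expect_equal(hits, total)
})

test_that("noisy sequence trials carry balanced five-image labels at the readout grid", {
  b <- gen_noisy_sequences(40, noise_fraction = 0.1, seed = 5)
  expect_identical(dim(b$labels), c(5L, 40L))
  expect_true(all(b$labels %in% c(0, 1)))
  expect_lt(abs(mean(b$labels) - 0.5), 0.15)
  expect_identical(sapply(b$windows, function(w) w[1, 1]), readout_times())
  expect_identical(dim(b$X), c(28L, 40L, 120L))
  expect_true(all(b$X >= 0 & b$X <= 1))
  expect_identical(gen_noisy_sequences(5, 0.1, seed = 9)$X,
                   gen_noisy_sequences(5, 0.1, seed = 9)$X)
  # fixed reference class: all cues identical class
  expect_true(all(b$meta$cue_class == 1))
  # rotating-cue variant is class balanced
  b2 <- gen_noisy_sequences(20, 0.1, seed = 10, target_class = NULL)
  expect_identical(sort(unique(b2$meta$cue_class)), 1:10)
})

test_that("population code peaks at the preferred value and decays monotonically", {
  code <- population_code()
  # a value at a neuron's preferred coordinate drives it at exactly r_max
  expect_equal(max(population_encode(code$centers[4], code)), 500,
               tolerance = 1e-9)
  expect_equal(500 * exp(-100 * 0.1^2), 183.9397, tolerance = 1e-4)
  r <- population_encode(0, code)
  expect_true(all(diff(r) < 0))  # rates fall with distance from 0
  d <- abs(code$centers - 0.33)
  expect_true(all(diff(population_encode(0.33, code)[order(d)]) <= 0))
})

test_that("action decoding follows the Gaussian policy heads", {
  set.seed(8)
  d0 <- decode_action(rep(0, 5))
  expect_equal(as.numeric(d0$mean), c(0, 0))
  expect_equal(as.numeric(d0$var), c(0.5, 0.5))
  expect_equal(d0$value, 0)
  lam <- matrix(rnorm(5 * 200, sd = 2), 5)
  d <- decode_action(lam, max_speed = 0.02)
  expect_true(all(abs(d$mean) < 1))
  expect_true(all(sqrt(colSums(d$action^2)) <= 0.02 + 1e-12))
  expect_equal(d$value, lam[5, ])
  # log-density matches dnorm
  expect_equal(d$logp,
               colSums(matrix(dnorm(d$raw, d$mean, sqrt(d$var), log = TRUE), 2)),
               tolerance = 1e-9)
  expect_error(decode_action(1:4), "five")
})

test_that("arena dynamics reward reaching and reset uniformly", {
  ar <- arena_init(3, seed = 40)
  ar$pos <- ar$goal  # standing on the destination
  res <- arena_step(ar, matrix(0, 2, 3))
  expect_equal(res$reward, c(1, 1, 1))
  expect_true(all(res$done))
  # zero action far from the goal never rewards
  ar2 <- arena_init(1, seed = 41)
  ar2$pos <- matrix(c(0.1, 0.1), 2); ar2$goal <- matrix(c(0.9, 0.9), 2)
  for (t in 1:20) {
    res2 <- arena_step(ar2, c(0, 0)); ar2 <- res2$arena
    expect_equal(res2$reward, 0)
  }
  # respawn keeps episodes alive and teleports the agent
  ar3 <- arena_init(1, seed = 42)
  ar3$pos <- ar3$goal
  res3 <- arena_step(ar3, c(0, 0), respawn = TRUE)
  expect_equal(res3$reward, 1)
  expect_false(any(res3$done))
  # start positions are uniform over the square
  ar4 <- arena_init(10000, seed = 43)
  expect_gt(suppressWarnings(ks.test(ar4$pos[1, ], "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(ar4$pos[2, ], "punif"))$p.value, 0.01)
})

test_that("discounted returns sum strictly future rewards", {
  r <- rep(0, 10); r[6] <- 1
  om <- discounted_returns(r, 0.99)
  expect_equal(om[5], 0.99)
  expect_equal(om[6], 0)
  expect_equal(om[1], 0.99^5)
  expect_true(all(discounted_returns(rep(0, 7), 0.9) == 0))
  set.seed(12)
  for (rep_i in 1:5) {
    rw <- rnorm(30); g <- runif(1, 0.5, 0.99)
    brute <- sapply(1:30, function(t)
      if (t == 30) 0 else sum(g^((t + 1):30 - t) * rw[(t + 1):30]))
    expect_equal(discounted_returns(rw, g), brute, tolerance = 1e-12)
  }
  expect_error(discounted_returns(1:3, 1), "gamma")
})

test_that("Bernoulli spike sampling reproduces the encoded rates", {
  # rate r Hz over 1 s of 1 ms steps: mean count within 3*sqrt(r) of r
  set.seed(13)
  for (r in c(50, 183.9, 500)) {
    counts <- replicate(300, sum(runif(1000) < r / 1000))
    expect_lt(abs(mean(counts) - r), 3 * sqrt(r) / sqrt(300) * 3)
  }
})
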