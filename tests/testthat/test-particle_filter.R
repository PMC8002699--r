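intr <- camera_intrinsics()

test_that("particle prediction obeys the noise model", {
  ref <- pose(p = c(0, 0, 0.5), q = random_unit_quat())
  cfg0 <- filter_config(n_trans = 0, n_rot = 0, k = 25)
  ps <- predict_particles(ref, cfg0)
  expect_equal(nrow(ps$p), 25)
  expect_true(all(abs(ps$p - matrix(ref$p, 25, 3, byrow = TRUE)) < 1e-12))
  for (i in 1:25) expect_equal(ps$q[i, ], ref$q, tolerance = 1e-12)

  cfg <- filter_config(n_trans = 0.01, n_rot = 0.05, k = 1e4)
  set.seed(12)
  ps <- predict_particles(ref, cfg)
  expect_equal(rowSums(ps$q^2), rep(1, 1e4), tolerance = 1e-9)
  # with zero initial velocity the particle cloud is centred on the
  # reference: per-axis mean within 3 sd of the Monte-Carlo mean
  tol <- 3 * cfg$n_trans * cfg$dt^2 / sqrt(1e4)
  expect_true(all(abs(colMeans(ps$p) - ref$p) < tol))
})

test_that("pixel log-likelihood matches the naive oracle in all four cases", {
  cfg <- filter_config(w_uni = 0.1, w_gaus = 0.6, w_exp = 0.3, lam = 1.2)
  # expected invalid: 0 regardless of observation
  expect_equal(pixel_log_likelihood(0.7, NA, cfg, intr), 0)
  expect_equal(pixel_log_likelihood(NA, NA, cfg, intr), 0)
  # observed invalid: uniform floor; hand value log(0.1 / 2.7)
  expect_equal(pixel_log_likelihood(NA, 0.6, cfg, intr), log(0.1 / 2.7))
  grid <- c(NA, 0.31, 0.5, 0.9, 1.5, 2.9)
  for (xo in grid) {
    for (xe in grid) {
      expect_equal(pixel_log_likelihood(xo, xe, cfg, intr),
                   naive_pixel_ll(xo, xe, cfg, intr),
                   tolerance = 1e-12)
    }
  }
  # the occlusion branch only ever adds mass: case 2 >= case 3 at the
  # same (xo, xe); compare against a config with the exponential removed
  cfg_noexp <- filter_config(w_uni = 0.1, w_gaus = 0.6, w_exp = 0, lam = 1.2)
  expect_gte(pixel_log_likelihood(0.5, 0.9, cfg, intr),
             pixel_log_likelihood(0.5, 0.9, cfg_noexp, intr))
})

test_that("increasing the uniform weight never decreases the likelihood", {
  cfg1 <- filter_config(w_uni = 0.05)
  cfg2 <- filter_config(w_uni = 0.2)
  grid <- c(NA, 0.4, 0.8, 1.6)
  for (xo in grid) {
    for (xe in grid) {
      expect_gte(pixel_log_likelihood(xo, xe, cfg2, intr),
                 pixel_log_likelihood(xo, xe, cfg1, intr))
    }
  }
})

test_that("image weight equals the brute-force per-pixel double loop", {
  set.seed(42)
  cfg <- filter_config()
  mk <- function() {
    m <- matrix(stats::runif(12, 0.31, 2.9), 3, 4)
    m[stats::runif(12) < 0.3] <- NA
    m
  }
  for (rep in 1:5) {
    obs <- mk()
    expd <- mk()
    expect_equal(particle_weight(obs, expd, cfg, intr),
                 naive_image_weight(obs, expd, cfg, intr),
                 tolerance = 1e-9)
  }
  # all-invalid expectation: sum of case-1 zeros
  expect_equal(particle_weight(mk(), matrix(NA_real_, 3, 4), cfg, intr), 0)
  # permutation invariance under identical reshuffling of both images
  obs <- mk(); expd <- mk()
  perm <- sample(12)
  expect_equal(particle_weight(matrix(obs[perm], 3, 4),
                               matrix(expd[perm], 3, 4), cfg, intr),
               particle_weight(obs, expd, cfg, intr), tolerance = 1e-12)
  expect_error(particle_weight(obs, matrix(0.5, 2, 2), cfg, intr), "shape")
})

test_that("effective sample size has its closed forms and bounds", {
  for (k in c(1, 10, 100, 2000)) {
    expect_equal(effective_sample_size(rep(-7.3, k)), log(k),
                 tolerance = 1e-12)
  }
  expect_equal(effective_sample_size(c(0, -1e6, -1e6)), 0, tolerance = 1e-9)
  expect_equal(effective_sample_size(c(0, -Inf, -Inf)), 0)
  # invariance under constant shifts
  set.seed(3)
  w <- stats::rnorm(50, -100, 20)
  expect_equal(effective_sample_size(w), effective_sample_size(w + 500),
               tolerance = 1e-9)
  expect_error(effective_sample_size(numeric(0)), "empty")
  for (i in 1:200) {
    k <- sample(2:300, 1)
    w <- stats::rnorm(k, 0, stats::runif(1, 0.01, 50))
    e <- effective_sample_size(w)
    expect_gte(e, 0)
    expect_lte(e, log(k))
  }
})

test_that("filter step picks the exhaustive argmax particle", {
  shape <- target_box(c(0.06, 0.04, 0.03))
  truth <- pose(p = c(0, 0, 0.5))
  obs <- render_depth(shape, truth, intr)
  cfg <- filter_config(n_trans = 0.004, n_rot = 0.01, k = 3)
  # duplicate the prediction RNG stream, then weight each particle by
  # rendering its expected image explicitly
  set.seed(99)
  particles <- predict_particles(truth, cfg)
  w <- vapply(1:3, function(i) {
    expd <- render_depth(shape, particles$p[i, ], intr, q = particles$q[i, ])
    particle_weight(obs, expd, cfg, intr)
  }, numeric(1))
  set.seed(99)
  st <- filter_step(truth, obs, cfg, intr, shape)
  expect_equal(st$output[["ll_max"]], max(w), tolerance = 1e-9)
  expect_equal(st$pose$p, particles$p[which.max(w), ], tolerance = 1e-12)
  expect_equal(st$output[["ess"]], effective_sample_size(w), tolerance = 1e-9)
  expect_equal(st$output[["w_mean"]], mean(w), tolerance = 1e-9)
  expect_equal(st$output[["w_var"]], stats::var(w), tolerance = 1e-9)

  # k = 1: the single predicted particle is the track, ess is 0
  cfg1 <- filter_config(n_trans = 0, n_rot = 0, k = 1)
  st1 <- filter_step(truth, obs, cfg1, intr, shape)
  expect_equal(st1$output[["ess"]], 0)
  expect_equal(st1$pose$p, truth$p)
})

test_that("a noiseless static scene is tracked exactly", {
  sc <- scenario_config(n_frames = 20, trans_diffusion = 0,
                        rot_diffusion = 0, noise = noise_model(0, 0, 0),
                        target_shape = target_box(c(0.06, 0.04, 0.03)),
                        seed = 1)
  sq <- simulate_sequence(sc)
  cfg <- filter_config(n_trans = 0, n_rot = 0, k = 10)
  tr <- track_sequence(sq, cfg, seed = 2)
  expect_equal(nrow(tr), 20)
  expect_true(all(tr$delta < 1e-6))
  expect_true(all(tr$alpha < 1e-6))
})

test_that("tracking traces are reproducible and empty sequences allowed", {
  sc <- scenario_config(n_frames = 8, seed = 3,
                        target_shape = target_box(c(0.06, 0.04, 0.03)))
  sq <- simulate_sequence(sc)
  cfg <- filter_config(k = 40)
  t1 <- track_sequence(sq, cfg, seed = 5)
  t2 <- track_sequence(sq, cfg, seed = 5)
  expect_identical(t1, t2)

  empty <- sq
  empty$frames <- list()
  empty$poses <- list()
  tr0 <- track_sequence(empty, cfg, seed = 5)
  expect_equal(nrow(tr0), 0)
  expect_s3_class(tr0, "tracking_trace")
})
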