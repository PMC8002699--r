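intr_test <- camera_intrinsics(fx = 100, fy = 100, cx = 32, cy = 24,
                               width = 64, height = 48,
                               d_min = 0.3, d_max = 3.0)

test_that("sphere rendering matches the analytic ray-sphere oracle", {
  r <- 0.05
  center <- c(0.02, -0.01, 0.6)
  img <- render_depth(target_sphere(r), center, intr_test)
  oracle <- matrix(NA_real_, intr_test$height, intr_test$width)
  for (i in seq_len(intr_test$height)) {
    for (j in seq_len(intr_test$width)) {
      oracle[i, j] <- naive_sphere_depth(i, j, center, r, intr_test)
    }
  }
  expect_equal(img, oracle, tolerance = 1e-12)
  # the principal-point ray of an on-axis sphere sees the near pole at z - r
  on_axis <- render_depth(target_sphere(r), c(0, 0, 0.6), intr_test)
  expect_equal(on_axis[intr_test$cy + 1, intr_test$cx + 1], 0.6 - r)
})

test_that("rendering invalidates empty scenes and out-of-range depths", {
  # nothing in front of the camera
  behind <- render_depth(target_sphere(0.05), c(0, 0, -1), intr_test)
  expect_true(all(is.na(behind)))
  # beyond d_max
  far <- render_depth(target_sphere(0.05), c(0, 0, 5), intr_test)
  expect_true(all(is.na(far)))
  # nearer surface wins: a frame-filling occluder plane at half the depth
  occ <- list(shape = target_box(c(5, 5, 0.001)), p = c(0, 0, 0.31))
  img <- render_depth(target_sphere(0.05), c(0, 0, 0.6), intr_test,
                      occluder = occ)
  expect_true(all(abs(img - 0.309) < 1e-9))
})

test_that("image-plane translation shifts the footprint by the projection", {
  z <- 0.5
  shift_m <- 10 * z / intr_test$fx  # exactly 10 pixels at this depth
  a <- render_depth(target_sphere(0.05), c(0, 0, z), intr_test)
  b <- render_depth(target_sphere(0.05), c(shift_m, 0, z), intr_test)
  # the projection of an off-axis sphere is slightly distorted at the
  # silhouette boundary, so compare footprint centroids, not exact masks
  centroid_col <- function(img) mean(which(!is.na(img), arr.ind = TRUE)[, 2])
  expect_equal(centroid_col(b) - centroid_col(a), 10, tolerance = 0.05)
  # row centroid unchanged, footprint area nearly preserved
  centroid_row <- function(img) mean(which(!is.na(img), arr.ind = TRUE)[, 1])
  expect_equal(centroid_row(b), centroid_row(a), tolerance = 0.3)
  expect_equal(sum(!is.na(b)) / sum(!is.na(a)), 1, tolerance = 0.05)
})

test_that("box orientation changes the rendered silhouette", {
  q45 <- quat(cos(pi / 8), 0, sin(pi / 8), 0)
  a <- render_depth(target_box(c(0.06, 0.04, 0.01)), c(0, 0, 0.5), intr_test)
  b <- render_depth(target_box(c(0.06, 0.04, 0.01)), c(0, 0, 0.5), intr_test,
                    q = q45)
  expect_gt(sum(is.na(a) != is.na(b)), 0)
})

test_that("sensor noise has the configured variance and dropout", {
  img <- render_depth(target_sphere(0.05), c(0, 0, 0.6), intr_test)
  clean <- add_sensor_noise(img, noise_model(0, 0, 0), intr_test)
  expect_identical(clean, img)
  gone <- add_sensor_noise(img, noise_model(0, 0, 1), intr_test)
  expect_true(all(is.na(gone)))
  # Monte-Carlo moment check on a constant-depth pixel
  nm <- noise_model(df = 5e-5, bn = 2.5e-5, dropout_p = 0)
  x <- 1.2
  one_px <- matrix(x, 1, 1)
  set.seed(31)
  draws <- replicate(1e4, add_sensor_noise(one_px, nm, intr_test)[1, 1])
  expect_equal(stats::var(draws), nm$df * x^2 + nm$bn, tolerance = 0.05)
  # valid depths always stay inside the sensor range
  noisy <- add_sensor_noise(img, noise_model(0.5, 0.5, 0.1), intr_test)
  v <- noisy[!is.na(noisy)]
  expect_true(all(v >= intr_test$d_min & v <= intr_test$d_max))
})

test_that("simulated sequences are reproducible and respect events", {
  cfg <- scenario_config(n_frames = 25, seed = 77,
                         displacement_event = list(frame = 10,
                                                   translation = c(0.1, 0, 0)))
  s1 <- simulate_sequence(cfg, intr_test)
  s2 <- simulate_sequence(cfg, intr_test)
  expect_identical(s1$frames, s2$frames)
  expect_identical(lapply(s1$poses, `[[`, "p"), lapply(s2$poses, `[[`, "p"))
  expect_length(s1$frames, 25)
  # the displacement jump dominates one random-walk step
  dp <- sqrt(sum((s1$poses[[10]]$p - s1$poses[[9]]$p)^2))
  expect_gt(dp, 0.1 - 0.01)
})

test_that("occlusion events cover the configured fraction of target pixels", {
  cov <- 0.5
  cfg <- scenario_config(n_frames = 12, seed = 5,
                         noise = noise_model(0, 0, 0),
                         occlusion_event = list(start = 6, duration = 4,
                                                coverage = cov))
  sq <- simulate_sequence(cfg, intr_test)
  # compare the occluded frame against a clean render of the same pose
  ps <- sq$poses[[7]]
  clean <- render_depth(cfg$target_shape, ps$p, intr_test, ps$q)
  target_px <- which(!is.na(clean))
  # occluded pixels are those whose depth changed or disappeared
  got <- sq$frames[[7]]
  occluded <- sum(abs(got[target_px] - clean[target_px]) > 1e-6,
                  na.rm = TRUE) + sum(is.na(got[target_px]))
  frac <- occluded / length(target_px)
  expect_gte(frac, cov - 0.1)
  expect_lte(frac, cov + 0.1)
})

test_that("sequence archives round-trip through plain-text files", {
  cfg <- scenario_config(n_frames = 6, seed = 9,
                         occlusion_event = list(start = 3, duration = 2,
                                                coverage = 0.4))
  sq <- simulate_sequence(cfg, intr_test)
  d <- withr::local_tempdir()
  write_sequence(sq, d)
  expect_true(all(file.exists(file.path(d, c("depth.csv", "poses.csv",
                                             "meta.json")))))
  back <- read_sequence(d)
  expect_equal(back$frames, sq$frames, tolerance = 1e-12)
  expect_equal(lapply(back$poses, `[[`, "p"), lapply(sq$poses, `[[`, "p"),
               tolerance = 1e-12)
  expect_equal(back$cfg$occlusion_event, sq$cfg$occlusion_event)
  expect_equal(back$intr, sq$intr)
})
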