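#' Pinhole depth-camera intrinsics
#'
#' @param fx,fy Focal lengths in pixels.
#' @param cx,cy Principal point in pixels (0-based pixel coordinates).
#' @param width,height Image size in pixels.
#' @param d_min,d_max Minimum and maximum measurable depth (meters); rendered
#'   or observed depths outside this range are invalid.
#' @return Object of class `"camera_intrinsics"`.
#' @export
camera_intrinsics <- function(fx = 100, fy = 100, cx = 31.5, cy = 23.5,
                              width = 64, height = 48,
                              d_min = 0.3, d_max = 3.0) {
  stopifnot(d_max > d_min, d_min > 0, width >= 1, height >= 1)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 d_min = d_min, d_max = d_max),
            class = "camera_intrinsics")
}

#' Analytic target shapes
#'
#' Targets (and occluders) are analytic primitives rather than meshes: a
#' sphere, or a box given by its half-extents in the body frame. The box
#' responds to orientation; the sphere does not.
#'
#' @param radius Sphere radius (meters).
#' @return A shape list understood by [render_depth()].
#' @export
target_sphere <- function(radius = 0.05) {
  stopifnot(radius > 0)
  structure(list(type = 1L, params = radius, label = "sphere"),
            class = "target_shape")
}

#' @rdname target_sphere
#' @param half_extents Box half-extents `(hx, hy, hz)` in meters.
#' @export
target_box <- function(half_extents = c(0.05, 0.03, 0.02)) {
  stopifnot(length(half_extents) == 3L, all(half_extents > 0))
  structure(list(type = 2L, params = as.numeric(half_extents), label = "box"),
            class = "target_shape")
}

#' Depth sensor noise model
#'
#' Zero-mean Gaussian depth noise whose variance grows quadratically with
#' depth, `df * x^2 + bn`, plus independent pixel dropout.
#'
#' @param df Depth factor (dimensionless) scaling the quadratic term.
#' @param bn Base noise variance (square meters).
#' @param dropout_p Probability that a valid pixel returns no measurement.
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(df = 1e-5, bn = 4e-6, dropout_p = 0.02) {
  stopifnot(df >= 0, bn >= 0, dropout_p >= 0, dropout_p <= 1)
  structure(list(df = df, bn = bn, dropout_p = dropout_p),
            class = "noise_model")
}

#' Render a depth image of a target (and optional occluder)
#'
#' Casts one ray per pixel and records the z-depth (distance along the
#' optical axis) of the nearest surface. Pixels whose ray hits nothing, or
#' whose depth falls outside `[d_min, d_max]`, are invalid (`NA`). When an
#' occluder is present the nearer surface wins per pixel.
#'
#' @param shape A [target_sphere()] or [target_box()].
#' @param p Target position (camera frame, meters), or a [pose()].
#' @param intr [camera_intrinsics()].
#' @param q Target orientation quaternion (ignored when `p` is a pose).
#' @param occluder Optional list `list(shape =, p =, q =)` describing an
#'   occluding primitive.
#' @return `height x width` numeric matrix of depths; invalid pixels are
#'   `NA`.
#' @export
#' @examples
#' intr <- camera_intrinsics()
#' img <- render_depth(target_sphere(0.05), c(0, 0, 0.6), intr)
#' img[24, 32]   # on-axis pixel: depth of the near surface, 0.6 - 0.05
render_depth <- function(shape, p, intr, q = quat(1, 0, 0, 0), occluder = NULL) {
  stopifnot(inherits(shape, "target_shape"), inherits(intr, "camera_intrinsics"))
  if (inherits(p, "pose")) {
    q <- p$q
    p <- p$p
  }
  occ <- NULL
  if (!is.null(occluder)) {
    oq <- if (is.null(occluder$q)) quat(1, 0, 0, 0) else occluder$q
    occ <- list(type = occluder$shape$type, params = occluder$shape$params,
                p = as.numeric(occluder$p), q = as.numeric(oq))
  }
  .render_depth_cpp(shape$type, shape$params, as.numeric(p), as.numeric(q),
                    unclass(intr), occ)
}

#' Apply sensor noise to a depth image
#'
#' Each valid pixel is perturbed by zero-mean Gaussian noise with variance
#' `df * depth^2 + bn`, clipped back to `[d_min, d_max]`, and then dropped
#' (set invalid) independently with probability `dropout_p`. Uses the R
#' random number generator, so results are reproducible under `set.seed()`.
#'
#' @param img Depth matrix from [render_depth()].
#' @param noise [noise_model()].
#' @param intr [camera_intrinsics()] (for the clipping range).
#' @return Depth matrix of the same shape.
#' @export
add_sensor_noise <- function(img, noise, intr) {
  stopifnot(inherits(noise, "noise_model"), inherits(intr, "camera_intrinsics"))
  valid <- which(!is.na(img))
  if (length(valid)) {
    x <- img[valid]
    sd <- sqrt(noise$df * x^2 + noise$bn)
    x <- pmin(pmax(x + stats::rnorm(length(x), 0, sd), intr$d_min), intr$d_max)
    if (noise$dropout_p > 0) {
      drop <- stats::runif(length(x)) < noise$dropout_p
      x[drop] <- NA_real_
    }
    img[valid] <- x
  }
  img
}

#' Scenario configuration for synthetic tracking sequences
#'
#' Describes one synthetic sequence: a rigid target following a smooth
#' random walk in front of the camera, optionally disturbed by an occlusion
#' event (a nearer slab sweeping over part of the target) and/or a sudden
#' displacement event (an instantaneous pose jump), observed through a noisy
#' depth sensor.
#'
#' The random walk is an AR(1) velocity process: each frame the translational
#' velocity is damped by `motion_decay` and perturbed by
#' `N(0, trans_diffusion^2)` per axis (meters/frame), and likewise the
#' rotational-velocity increment with `rot_diffusion` (radians/frame scale).
#'
#' @param n_frames Number of frames.
#' @param target_shape [target_sphere()] or [target_box()].
#' @param start_p Initial target position (camera frame, meters).
#' @param trans_diffusion Per-frame translational velocity noise std
#'   (meters/frame).
#' @param rot_diffusion Per-frame rotational velocity noise std
#'   (radians/frame scale).
#' @param motion_decay AR(1) damping of the ground-truth velocities.
#' @param occlusion_event `NULL`, or `list(start =, duration =, coverage =)`
#'   with `coverage` the fraction of rendered target pixels to occlude.
#' @param displacement_event `NULL`, or `list(frame =, translation =,
#'   rotation =)` (rotation a quaternion).
#' @param noise [noise_model()].
#' @param seed Integer seed; the generated sequence is a pure function of
#'   the configuration including this seed.
#' @return Object of class `"scenario_config"`.
#' @export
scenario_config <- function(n_frames = 110,
                            target_shape = target_sphere(0.05),
                            start_p = c(0, 0, 0.5),
                            trans_diffusion = 5e-4,
                            rot_diffusion = 1e-3,
                            motion_decay = 0.9,
                            occlusion_event = NULL,
                            displacement_event = NULL,
                            noise = noise_model(),
                            seed = 1L) {
  stopifnot(n_frames >= 1)
  if (!is.null(occlusion_event)) {
    with(occlusion_event, stopifnot(start >= 1, start + duration - 1 <= n_frames,
                                    coverage >= 0, coverage <= 1))
  }
  if (!is.null(displacement_event)) {
    with(displacement_event, stopifnot(frame >= 2, frame <= n_frames,
                                       length(translation) == 3L))
    if (is.null(displacement_event$rotation)) {
      displacement_event$rotation <- quat(1, 0, 0, 0)
    }
  }
  structure(list(n_frames = as.integer(n_frames), target_shape = target_shape,
                 start_p = start_p, trans_diffusion = trans_diffusion,
                 rot_diffusion = rot_diffusion, motion_decay = motion_decay,
                 occlusion_event = occlusion_event,
                 displacement_event = displacement_event,
                 noise = noise, seed = as.integer(seed)),
            class = "scenario_config")
}

# Place a box occluder at a nearer depth so that it covers approximately the
# requested fraction of the target's currently rendered pixels, sweeping in
# from the left of the target's footprint.
.make_occluder <- function(coverage, clean_img, intr, z_occ) {
  cols <- which(colSums(!is.na(clean_img)) > 0)
  if (!length(cols) || coverage <= 0) return(NULL)
  counts <- colSums(!is.na(clean_img))[cols]
  total <- sum(counts)
  cum <- cumsum(counts)
  j_cut <- cols[which(cum >= coverage * total)[1]]          # rightmost occluded column
  # occluder: deep box spanning columns [0, j_cut] at depth z_occ
  x_right <- (j_cut + 0.5 - intr$cx) / intr$fx * z_occ
  x_left <- (-2 - intr$cx) / intr$fx * z_occ                 # beyond the left edge
  hx <- (x_right - x_left) / 2
  y_half <- (intr$height + 4) / 2 / intr$fy * z_occ
  list(shape = target_box(c(hx, y_half, 0.005)),
       p = c((x_left + x_right) / 2, 0, z_occ),
       q = quat(1, 0, 0, 0))
}

#' Simulate a synthetic depth-tracking sequence
#'
#' Generates ground-truth poses by the scenario's smooth random walk, applies
#' any displacement event as an instantaneous pose jump, renders each frame
#' (with the occluder inserted during the occlusion event, positioned each
#' frame to cover the configured fraction of rendered target pixels), and
#' corrupts the rendered images with sensor noise. Fully reproducible from
#' the scenario seed.
#'
#' @param cfg [scenario_config()].
#' @param intr [camera_intrinsics()].
#' @param dt Frame period in seconds, used for the timestamps only (the
#'   motion model works in per-frame units).
#' @return Object of class `"depth_sequence"`: list with `frames` (list of
#'   depth matrices), `poses` (list of ground-truth [pose()]s), `time`
#'   (timestamps, seconds), `intr`, `cfg`, `dt`.
#' @export
simulate_sequence <- function(cfg, intr = camera_intrinsics(), dt = 1 / 30) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(intr, "camera_intrinsics"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  n <- cfg$n_frames
  frames <- vector("list", n)
  poses <- vector("list", n)
  p <- cfg$start_p
  q <- quat(1, 0, 0, 0)
  v <- c(0, 0, 0)
  w <- c(0, 0, 0, 0)
  occ_ev <- cfg$occlusion_event
  dis_ev <- cfg$displacement_event

  for (t in seq_len(n)) {
    if (t > 1) {
      v <- cfg$motion_decay * v + stats::rnorm(3, 0, cfg$trans_diffusion)
      w <- cfg$motion_decay * w + stats::rnorm(4, 0, cfg$rot_diffusion)
      st <- integrate_pose(pose(p, q, v, w), 1)
      p <- st$p
      q <- st$q
      if (!is.null(dis_ev) && t == dis_ev$frame) {
        p <- p + dis_ev$translation
        q <- quat_normalize(quat_multiply(dis_ev$rotation, q))
      }
    }
    poses[[t]] <- pose(p, q, v, w)

    occluder <- NULL
    if (!is.null(occ_ev) && t >= occ_ev$start &&
        t < occ_ev$start + occ_ev$duration) {
      clean <- render_depth(cfg$target_shape, p, intr, q)
      occluder <- .make_occluder(occ_ev$coverage, clean, intr,
                                 z_occ = max(intr$d_min + 0.05, p[3] / 2))
    }
    img <- render_depth(cfg$target_shape, p, intr, q, occluder = occluder)
    frames[[t]] <- add_sensor_noise(img, cfg$noise, intr)
  }

  structure(list(frames = frames, poses = poses,
                 time = (seq_len(n) - 1) * dt,
                 intr = intr, cfg = cfg, dt = dt),
            class = "depth_sequence")
}

#' @export
print.depth_sequence <- function(x, ...) {
  cat("depth_sequence:", length(x$frames), "frames,",
      x$intr$width, "x", x$intr$height, "px, target:",
      x$cfg$target_shape$label, "\n")
  invisible(x)
}

# save/restore the global RNG state so simulators don't clobber user seeds
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a simulated sequence as plain-text files
#'
#' A sequence is stored as a directory with `depth.csv` (sparse valid-pixel
#' table: frame, row, col, depth; 1-based indices), `poses.csv` (ground
#' truth: frame, px, py, pz, qw, qx, qy, qz) and `meta.json` (intrinsics,
#' scenario, dt). Invalid pixels are implicit.
#'
#' @param seq A `"depth_sequence"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "depth_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(seq$frames), function(t) {
    idx <- which(!is.na(seq$frames[[t]]), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(frame = t, row = idx[, 1], col = idx[, 2],
               depth = seq$frames[[t]][idx])
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "depth.csv"),
                   row.names = FALSE)
  pz <- t(vapply(seq$poses, function(ps) c(ps$p, ps$q), numeric(7)))
  poses <- data.frame(frame = seq_along(seq$poses),
                      px = pz[, 1], py = pz[, 2], pz = pz[, 3],
                      qw = pz[, 4], qx = pz[, 5], qy = pz[, 6], qz = pz[, 7])
  utils::write.csv(poses, file.path(dir, "poses.csv"), row.names = FALSE)
  cfg <- seq$cfg
  meta <- list(intr = unclass(seq$intr), dt = seq$dt,
               n_frames = cfg$n_frames,
               target_shape = list(type = cfg$target_shape$type,
                                   params = cfg$target_shape$params),
               start_p = cfg$start_p, trans_diffusion = cfg$trans_diffusion,
               rot_diffusion = cfg$rot_diffusion,
               motion_decay = cfg$motion_decay,
               occlusion_event = cfg$occlusion_event,
               displacement_event = cfg$displacement_event,
               noise = unclass(cfg$noise), seed = cfg$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  intr <- do.call(camera_intrinsics, meta$intr[c("fx", "fy", "cx", "cy",
                                                 "width", "height",
                                                 "d_min", "d_max")])
  shape <- if (meta$target_shape$type == 1) target_sphere(meta$target_shape$params)
           else target_box(meta$target_shape$params)
  occ <- meta$occlusion_event
  dis <- meta$displacement_event
  if (!is.null(dis)) dis$rotation <- as.numeric(dis$rotation)
  cfg <- scenario_config(n_frames = meta$n_frames, target_shape = shape,
                         start_p = as.numeric(meta$start_p),
                         trans_diffusion = meta$trans_diffusion,
                         rot_diffusion = meta$rot_diffusion,
                         motion_decay = meta$motion_decay,
                         occlusion_event = occ, displacement_event = dis,
                         noise = do.call(noise_model, meta$noise),
                         seed = meta$seed)
  depth <- utils::read.csv(file.path(dir, "depth.csv"))
  poses_df <- utils::read.csv(file.path(dir, "poses.csv"))
  n <- meta$n_frames
  frames <- replicate(n, matrix(NA_real_, intr$height, intr$width),
                      simplify = FALSE)
  if (nrow(depth)) {
    sp <- split(depth, depth$frame)
    for (nm in names(sp)) {
      d <- sp[[nm]]
      frames[[as.integer(nm)]][cbind(d$row, d$col)] <- d$depth
    }
  }
  poses <- lapply(seq_len(n), function(t) {
    r <- poses_df[t, ]
    pose(c(r$px, r$py, r$pz), c(r$qw, r$qx, r$qy, r$qz))
  })
  structure(list(frames = frames, poses = poses,
                 time = (seq_len(n) - 1) * meta$dt,
                 intr = intr, cfg = cfg, dt = meta$dt),
            class = "depth_sequence")
}
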