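#' The 20 equidistant lost-track tolerance pairs
#'
#' Twenty threshold pairs `sigma_i = (d_i, a_i)` spanning distance
#' tolerances `d` from 0.05 to 0.2 m and angular tolerances `a` from 0.13
#' to 0.26 rad, ordered strict to tolerant; a track is "lost" under
#' `sigma_i` when its position error exceeds `d_i` or its angular error
#' exceeds `a_i`.
#'
#' @return Data frame with columns `i`, `d` (meters), `a` (radians);
#'   `sigma_1 = (0.05, 0.13)`, `sigma_20 = (0.2, 0.26)`.
#' @export
threshold_pairs <- function() {
  i <- 1:20
  data.frame(i = i,
             d = 0.05 + (i - 1) * 0.15 / 19,
             a = 0.13 + (i - 1) * 0.13 / 19)
}

# lattice of each tunable: values chosen between a and b in steps of c
.config_lattice <- list(
  n_trans = seq(0.0005, 0.01, by = 0.0005),
  n_rot  = seq(0.005, 0.1, by = 0.005),
  vf     = seq(0.8, 0.99, by = 0.01),
  w_exp  = seq(0.2, 0.39, by = 0.01),
  w_gaus = seq(0.5, 0.69, by = 0.01),
  w_uni  = seq(0.01, 0.2, by = 0.01),
  k      = seq(100, 2000, by = 100)
)

#' Sample a grid of filter configurations
#'
#' Draws `n` configurations uniformly from the per-parameter lattices
#' (each parameter ranges over `[a, b]` in fixed steps: `n_trans`
#' 0.0005–0.01 by 0.0005, `n_rot` 0.005–0.1 by 0.005, `vf` 0.8–0.99 by
#' 0.01, `w_exp` 0.2–0.39 by 0.01, `w_gaus` 0.5–0.69 by 0.01, `w_uni`
#' 0.01–0.2 by 0.01, `k` 100–2000 by 100). Sampling is stratified across
#' the particle count so every admitted `k` value is evenly represented.
#'
#' @param n Number of configurations.
#' @param seed Integer seed.
#' @param k_max Optional cap on the particle count: only lattice values
#'   `<= k_max` are sampled (the lattice itself is unchanged).
#' @param ... Further arguments passed to every [filter_config()] (e.g.
#'   `dt`, `lam`, `df`, `bn`).
#' @return Object of class `"config_grid"`: list of [filter_config()]s with
#'   the seed attached.
#' @export
sample_config_grid <- function(n, seed = 1L, k_max = NULL, ...) {
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lat <- .config_lattice
  if (!is.null(k_max)) lat$k <- lat$k[lat$k <= k_max]
  ks <- rep_len(lat$k, n)[sample.int(n)]  # stratified across k
  cfgs <- lapply(seq_len(n), function(j) {
    filter_config(n_trans = sample(lat$n_trans, 1),
                  n_rot = sample(lat$n_rot, 1),
                  vf = sample(lat$vf, 1),
                  w_exp = sample(lat$w_exp, 1),
                  w_gaus = sample(lat$w_gaus, 1),
                  w_uni = sample(lat$w_uni, 1),
                  k = ks[j], ...)
  })
  structure(cfgs, class = "config_grid", seed = seed)
}

#' Windowed feature vectors of a tracking trace
#'
#' Slides a `window`-frame window with stride `stride` over a trace and, for
#' each window, emits the 11-dimensional feature vector: the 7 configuration
#' values followed by the 4 filter outputs (`ll_max`, `ess`, `w_mean`,
#' `w_var`) averaged over the window.
#'
#' @param trace A `"tracking_trace"`.
#' @param cfg The [filter_config()] that produced it.
#' @param window Window length in frames (default 20).
#' @param stride Window advance in frames (default 10, i.e. 10-frame
#'   overlap).
#' @return Data frame: `start` (first frame of the window, 1-based) plus the
#'   11 feature columns; zero rows when the trace is shorter than `window`.
#' @export
window_features <- function(trace, cfg, window = 20, stride = 10) {
  n <- nrow(trace)
  if (n < window) {
    return(cbind(data.frame(start = integer(0)),
                 as.data.frame(matrix(numeric(0), 0, 11,
                                      dimnames = list(NULL, .feature_names)))))
  }
  starts <- seq(1, n - window + 1, by = stride)
  xc <- config_vector(cfg)
  feat <- t(vapply(starts, function(s) {
    idx <- s:(s + window - 1)
    c(xc,
      ll_max = mean(trace$ll_max[idx]),
      ess = mean(trace$ess[idx]),
      w_mean = mean(trace$w_mean[idx]),
      w_var = mean(trace$w_var[idx]))
  }, numeric(11)))
  colnames(feat) <- .feature_names
  cbind(data.frame(start = starts), as.data.frame(feat))
}

.feature_names <- c("n_trans", "n_rot", "vf", "w_exp", "w_gaus", "w_uni", "k",
                    "ll_max", "ess", "w_mean", "w_var")

#' Lost-track label of one window under one tolerance pair
#'
#' The window is labeled lost (1) iff any position error strictly exceeds
#' the distance tolerance or any angular error strictly exceeds the angular
#' tolerance; errors exactly at the tolerance are kept (0).
#'
#' @param deltas Position errors over the window (meters).
#' @param alphas Angular errors over the window (radians), same length.
#' @param sigma One row of [threshold_pairs()] (or any list with `d`, `a`).
#' @return 0 or 1.
#' @export
window_label <- function(deltas, alphas, sigma) {
  if (!length(deltas) || length(deltas) != length(alphas)) {
    stop("deltas and alphas must be non-empty and of equal length",
         call. = FALSE)
  }
  as.integer(any(deltas > sigma$d) || any(alphas > sigma$a))
}

#' Build the windowed feature/label dataset from many tracking runs
#'
#' Tracks every (sequence, configuration) pair, windows each trace, and
#' emits one row per window carrying the 11 features, the window-maximum
#' position and angular errors (the regression targets), and the 20 binary
#' lost-track labels (columns `y1`..`y20`, one per [threshold_pairs()] row).
#' Runs whose tracking fails are logged and skipped, never silently dropped.
#'
#' @param sequences List of `"depth_sequence"` objects.
#' @param grid A `"config_grid"`.
#' @param intr [camera_intrinsics()]; defaults to the first sequence's.
#' @param window,stride Windowing as in [window_features()].
#' @param seed Base seed; run `r` tracks under seed `seed + r` so the whole
#'   dataset is reproducible.
#' @param progress Print one line per run.
#' @return Data frame: `run`, `seq_id`, `config_id`, `start`, features,
#'   `max_delta`, `max_alpha`, `y1`..`y20`.
#' @export
build_dataset <- function(sequences, grid, intr = NULL,
                          window = 20, stride = 10, seed = 1L,
                          progress = FALSE) {
  sig <- threshold_pairs()
  out <- list()
  run <- 0L
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    for (si in seq_along(sequences)) {
      run <- run + 1L
      sq <- sequences[[si]]
      use_intr <- if (is.null(intr)) sq$intr else intr
      tr <- tryCatch(
        track_sequence(sq, cfg, use_intr, seed = seed + run),
        error = function(e) {
          warning(sprintf("tracking run %d (seq %d, config %d) failed: %s",
                          run, si, ci, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(tr)) next
      wf <- window_features(tr, cfg, window, stride)
      if (!nrow(wf)) next
      lab <- t(vapply(wf$start, function(s) {
        idx <- s:(s + window - 1)
        md <- max(tr$delta[idx])
        ma <- max(tr$alpha[idx])
        c(md, ma, as.integer(md > sig$d | ma > sig$a))
      }, numeric(2 + nrow(sig))))
      colnames(lab) <- c("max_delta", "max_alpha", paste0("y", sig$i))
      out[[run]] <- cbind(data.frame(run = run, seq_id = si, config_id = ci),
                          wf, as.data.frame(lab))
      if (progress) {
        message(sprintf("run %d/%d: seq %d config %d (k=%d) -> %d windows",
                        run, length(grid) * length(sequences), si, ci,
                        cfg$k, nrow(wf)))
      }
    }
  }
  if (!length(out)) {
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a dataset with its JSON schema sidecar
#'
#' @param dataset Data frame from [build_dataset()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.schema.json`.
#' @param extra Optional named list merged into the sidecar (seeds, grid
#'   description, ...).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, extra = list()) {
  utils::write.csv(dataset, path, row.names = FALSE)
  schema <- c(list(columns = names(dataset),
                   features = .feature_names,
                   units = list(delta = "m", alpha = "rad",
                                ll = "nats", d = "m", a = "rad"),
                   sigma = threshold_pairs()),
              extra)
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
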