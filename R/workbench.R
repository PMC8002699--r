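#' End-to-end workbench commands
#'
#' Programmatic entry points behind the `pfreject` command-line script
#' (`inst/cli/pfreject.R`): simulate sequences, track them over a
#' configuration grid, build the windowed dataset, and train/evaluate the
#' reject strategies. Every command writes a `manifest.json` listing its
#' inputs, resolved parameters, seeds and produced files, so any run can be
#' reproduced bit-for-bit.
#'
#' @name workbench
#' @keywords internal
NULL

.write_manifest <- function(dir, command, params, outputs) {
  manifest <- list(command = command,
                   package_version = as.character(utils::packageVersion("pfreject")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   params = params, outputs = outputs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.scenario_from_spec <- function(sp) {
  shape <- if (identical(sp$target_shape$type, "box")) {
    target_box(as.numeric(sp$target_shape$half_extents))
  } else if (!is.null(sp$target_shape$radius)) {
    target_sphere(sp$target_shape$radius)
  } else {
    target_sphere()
  }
  args <- sp[intersect(names(sp), c("n_frames", "start_p", "trans_diffusion",
                                    "rot_diffusion", "motion_decay",
                                    "occlusion_event", "displacement_event",
                                    "seed"))]
  if (!is.null(args$start_p)) args$start_p <- as.numeric(args$start_p)
  if (!is.null(args$displacement_event$translation)) {
    args$displacement_event$translation <-
      as.numeric(args$displacement_event$translation)
  }
  if (!is.null(sp$noise)) args$noise <- do.call(noise_model, sp$noise)
  do.call(scenario_config, c(args, list(target_shape = shape)))
}

#' Simulate sequences from a YAML config
#'
#' The config has a `scenarios:` map (name to scenario spec; each spec may
#' set `n_frames`, `seed`, `noise`, `occlusion_event`,
#' `displacement_event`, ...), an optional `intrinsics:` map and an
#' optional `dt`. Each scenario is written as a plain-text sequence archive
#' under `out/<name>/`.
#'
#' @param config_path YAML config file.
#' @param out Output directory.
#' @return Character vector of sequence directories, invisibly.
#' @export
cmd_simulate <- function(config_path, out) {
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$scenarios) || !length(cfg$scenarios)) {
    stop("config field 'scenarios' is missing or empty", call. = FALSE)
  }
  intr <- if (is.null(cfg$intrinsics)) camera_intrinsics() else
    do.call(camera_intrinsics, cfg$intrinsics)
  dt <- if (is.null(cfg$dt)) 1 / 30 else cfg$dt
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dirs <- character(0)
  for (nm in names(cfg$scenarios)) {
    sc <- .scenario_from_spec(cfg$scenarios[[nm]])
    sq <- simulate_sequence(sc, intr, dt)
    d <- file.path(out, nm)
    write_sequence(sq, d)
    dirs <- c(dirs, d)
    message("simulated '", nm, "': ", sc$n_frames, " frames -> ", d)
  }
  .write_manifest(out, "simulate",
                  list(config = config_path, dt = dt), as.list(dirs))
  invisible(dirs)
}

#' Track sequence archives over a configuration grid
#'
#' @param sequence_dirs Directories written by [cmd_simulate()] /
#'   [write_sequence()].
#' @param out Output directory; one trace CSV per (sequence,
#'   configuration).
#' @param n_configs Grid size.
#' @param seed Integer seed (grid sampling and tracking).
#' @param k_max Optional particle-count cap for the grid.
#' @return Character vector of trace CSV paths, invisibly.
#' @export
cmd_track <- function(sequence_dirs, out, n_configs = 10, seed = 1L,
                      k_max = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  grid <- sample_config_grid(n_configs, seed = seed, k_max = k_max)
  paths <- character(0)
  failed <- 0L
  run <- 0L
  for (ci in seq_along(grid)) {
    for (sd in sequence_dirs) {
      run <- run + 1L
      res <- tryCatch({
        sq <- read_sequence(sd)
        tr <- track_sequence(sq, grid[[ci]], seed = seed + run)
        p <- file.path(out, sprintf("trace_%s_cfg%03d.csv", basename(sd), ci))
        write_trace(tr, p)
        message("tracked ", basename(sd), " with config ", ci,
                " (k=", grid[[ci]]$k, ")")
        p
      }, error = function(e) {
        message("FAILED ", sd, " config ", ci, ": ", conditionMessage(e))
        NA_character_
      })
      if (is.na(res)) failed <- failed + 1L else paths <- c(paths, res)
    }
  }
  if (!length(paths)) stop("all tracking runs failed", call. = FALSE)
  .write_manifest(out, "track",
                  list(n_configs = n_configs, seed = seed, k_max = k_max,
                       failed = failed),
                  as.list(paths))
  invisible(paths)
}

#' Build the windowed dataset from sequence archives
#'
#' @param sequence_dirs Sequence archives to track.
#' @param out Output directory for `dataset.csv` (+ schema sidecar).
#' @param n_configs,seed,k_max Grid parameters as in [cmd_track()].
#' @param window,stride Windowing as in [window_features()].
#' @return Path of the dataset CSV, invisibly.
#' @export
cmd_build_dataset <- function(sequence_dirs, out, n_configs = 10, seed = 1L,
                              k_max = NULL, window = 20, stride = 10) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sequences <- lapply(sequence_dirs, read_sequence)
  grid <- sample_config_grid(n_configs, seed = seed, k_max = k_max)
  ds <- build_dataset(sequences, grid, window = window, stride = stride,
                      seed = seed, progress = TRUE)
  path <- file.path(out, "dataset.csv")
  write_dataset(ds, path, extra = list(seed = seed, n_configs = n_configs,
                                       k_max = k_max,
                                       sequences = as.list(sequence_dirs)))
  .write_manifest(out, "build-dataset",
                  list(n_configs = n_configs, seed = seed, k_max = k_max,
                       window = window, stride = stride),
                  list(path))
  invisible(path)
}

#' Train and evaluate reject strategies on a dataset
#'
#' Runs walk-forward cross-validation for each requested strategy, writes
#' one report per strategy plus a comparison table, and (for
#' classification kinds) a sparse ensemble built on the full dataset at
#' the requested goals with its per-pair operating points.
#'
#' @param dataset_path CSV written by [write_dataset()].
#' @param out Output directory.
#' @param strategies Character vector; entries `"chow"`,
#'   `"regression_<kind>"` or `"classification_<kind>"` (kinds per
#'   [fit_regressor()] / [fit_sigma_classifier()]).
#' @param goal_p,goal_r Ensemble precision/recall goals.
#' @param seed Integer seed.
#' @return The comparison data frame, invisibly.
#' @export
cmd_train_evaluate <- function(dataset_path, out,
                               strategies = c("chow", "regression_rf",
                                              "classification_rf"),
                               goal_p = 0.9, goal_r = 0.9, seed = 1L) {
  if (!length(strategies)) {
    stop("no strategies requested; choose from 'chow', 'regression_<kind>',",
         " 'classification_<kind>'", call. = FALSE)
  }
  ds <- utils::read.csv(dataset_path)
  needed <- c(.feature_names, "max_delta", "max_alpha", paste0("y", 1:20))
  missing_cols <- setdiff(needed, names(ds))
  if (length(missing_cols)) {
    stop("dataset is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  reports <- list()
  outputs <- list()
  for (s in strategies) {
    if (s == "chow") {
      rep <- evaluate_strategy(ds, "chow", seed = seed)
    } else {
      parts <- strsplit(s, "_", fixed = TRUE)[[1]]
      rep <- evaluate_strategy(ds, parts[1],
                               kind = paste(parts[-1], collapse = "_"),
                               seed = seed)
    }
    p <- file.path(out, paste0("report_", s, ".csv"))
    write_report(rep, p)
    reports[[s]] <- rep
    outputs[[length(outputs) + 1L]] <- p
    print(rep)
    if (startsWith(s, "classification")) {
      kind <- sub("^classification_", "", s)
      ens <- tryCatch(
        train_sparse_ensemble(ds, kind = kind, goal_p = goal_p,
                              goal_r = goal_r, seed = seed),
        error = function(e) {
          message("ensemble for ", s, " not built: ", conditionMessage(e))
          NULL
        })
      if (!is.null(ens)) {
        ep <- file.path(out, paste0("ensemble_", s, ".csv"))
        utils::write.csv(ens$assignment, ep, row.names = FALSE)
        outputs[[length(outputs) + 1L]] <- ep
        print(ens)
      }
    }
  }
  cmp <- if (length(reports) >= 2) compare_strategies(reports) else NULL
  if (!is.null(cmp)) {
    cp <- file.path(out, "comparison.csv")
    utils::write.csv(cmp, cp, row.names = FALSE)
    outputs[[length(outputs) + 1L]] <- cp
  }
  .write_manifest(out, "train-evaluate",
                  list(dataset = dataset_path, strategies = strategies,
                       goal_p = goal_p, goal_r = goal_r, seed = seed),
                  outputs)
  invisible(cmp)
}

#' Train per-pair classifiers and build the sparse ensemble
#'
#' Fits one classifier per tolerance pair on the full dataset (SMOTE
#' applied), then covers all pairs with the minimum number of
#' threshold-shifted members via [build_sparse_ensemble()].
#'
#' @param dataset Data frame from [build_dataset()].
#' @param kind Classifier family.
#' @param goal_p,goal_r Precision/recall goals.
#' @param seed Integer seed.
#' @param sigmas Tolerance pairs.
#' @param candidates Optional pre-trained candidate list (one per pair),
#'   reused across goal settings.
#' @return A `"sparse_ensemble"`.
#' @export
train_sparse_ensemble <- function(dataset, kind = "rf", goal_p = 0.9,
                                  goal_r = 0.9, seed = 1L,
                                  sigmas = threshold_pairs(),
                                  candidates = NULL) {
  x <- as.matrix(dataset[, .feature_names])
  labels <- as.matrix(dataset[, paste0("y", sigmas$i)])
  if (is.null(candidates)) {
    candidates <- lapply(seq_len(nrow(sigmas)), function(si) {
      tryCatch(
        fit_sigma_classifier(x, labels[, si], kind = kind,
                             seed = seed + si, sigma_index = si),
        error = function(e) {
          message("candidate for sigma ", si, " not trainable: ",
                  conditionMessage(e))
          NULL
        })
    })
    candidates <- candidates[!vapply(candidates, is.null, logical(1))]
    if (!length(candidates)) {
      stop("no trainable per-pair candidates", call. = FALSE)
    }
  }
  build_sparse_ensemble(candidates, x, labels, goal_p, goal_r, sigmas)
}
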