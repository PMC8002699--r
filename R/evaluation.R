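#' Walk-forward time-series cross-validation folds
#'
#' Partitions `n` time-ordered samples into 11 equal consecutive blocks
#' (any remainder spread one-per-block over the earliest blocks) and forms
#' 10 folds: fold `k` tests on block `k + 1` and trains on all preceding
#' blocks. Training data therefore always precede test data, and each
#' sample is tested at most once (block 1 is never tested).
#'
#' @param n Sample count (>= 11).
#' @return List of 10 folds, each `list(fold =, train =, test =)` with
#'   1-based index vectors satisfying `max(train) < min(test)`.
#' @export
time_series_folds <- function(n) {
  if (n < 11) stop("walk-forward CV needs at least 11 samples", call. = FALSE)
  base <- n %/% 11
  rem <- n %% 11
  sizes <- rep(base, 11) + c(rep(1L, rem), rep(0L, 11 - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-11] + 1L)
  lapply(1:10, function(k) {
    list(fold = k,
         train = 1:ends[k],
         test = starts[k + 1]:ends[k + 1])
  })
}

#' Walk-forward folds within each run, pooled across runs
#'
#' The window table concatenates many tracking runs (one per scenario and
#' filter configuration). A reject monitor is deployed on the *future* of
#' runs whose past it has seen, so folds are built per run: each run's
#' windows are cut into 11 consecutive blocks ([time_series_folds()]), and
#' fold `k` trains on blocks `1..k` of every run while testing on every
#' run's block `k + 1`. Training windows therefore always precede test
#' windows *within each run* (across runs there is no temporal relation),
#' and every configuration is represented in training.
#'
#' Runs with fewer than 11 windows cannot be split; their windows join
#' every training partition and are never tested.
#'
#' @param run_ids Vector of run identifiers, one per (time-ordered) row.
#' @return List of 10 folds, each `list(fold =, train =, test =)` with row
#'   indices into the original table.
#' @export
time_series_folds_by_run <- function(run_ids) {
  groups <- split(seq_along(run_ids),
                  factor(run_ids, levels = unique(run_ids)))
  splittable <- vapply(groups, function(g) length(g) >= 11, logical(1))
  if (!any(splittable)) {
    stop("no run has the 11 windows needed for walk-forward folds",
         call. = FALSE)
  }
  always_train <- unlist(groups[!splittable], use.names = FALSE)
  per_run <- lapply(groups[splittable],
                    function(g) time_series_folds(length(g)))
  lapply(1:10, function(k) {
    tr <- unlist(lapply(which(splittable), function(r) {
      groups[[r]][per_run[[sum(splittable[seq_len(r)])]][[k]]$train]
    }), use.names = FALSE)
    te <- unlist(lapply(which(splittable), function(r) {
      groups[[r]][per_run[[sum(splittable[seq_len(r)])]][[k]]$test]
    }), use.names = FALSE)
    list(fold = k, train = sort(c(always_train, tr)), test = sort(te))
  })
}

#' Precision and recall with "lost" as the positive class
#'
#' Zero-denominator metrics (no positive predictions, or no positives
#' present) are returned as `NA` so callers can exclude them from averages
#' rather than biasing them to 0.
#'
#' @param predictions,labels Equal-length binary vectors (1 = lost).
#' @return Named numeric `(precision, recall)`.
#' @export
precision_recall <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length", call. = FALSE)
  }
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  tp <- sum(predictions == 1L & labels == 1L)
  fp <- sum(predictions == 1L & labels == 0L)
  fn <- sum(predictions == 0L & labels == 1L)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Evaluate a reject strategy with walk-forward cross-validation
#'
#' Fits the chosen strategy on each fold's training prefix and scores its
#' test block, per tolerance pair. Strategies:
#' \describe{
#'   \item{`"chow"`}{per-pair likelihood threshold on the window-mean
#'     maximum log-likelihood feature ([fit_chow_threshold()]);}
#'   \item{`"regression"`}{one distance/angle regressor pair per fold
#'     ([fit_regressor()]) with the per-pair [regression_decision()];}
#'   \item{`"classification"`}{one binary classifier per tolerance pair
#'     ([fit_sigma_classifier()]), SMOTE on the training partition only.}
#' }
#' Folds where a fit is degenerate (single-class training labels) are
#' logged and skipped for that pair.
#'
#' @param dataset Data frame from [build_dataset()] (time-ordered rows).
#' @param strategy `"chow"`, `"regression"` or `"classification"`.
#' @param kind Model family for regression/classification (see
#'   [fit_regressor()], [fit_sigma_classifier()]).
#' @param sigmas Tolerance pairs (default [threshold_pairs()]).
#' @param use_smote Apply SMOTE inside classification training folds.
#' @param seed Integer seed for stochastic fits.
#' @param folds Optional precomputed folds; by default
#'   [time_series_folds_by_run()] on the `run` column when the dataset
#'   holds several runs, else [time_series_folds()] on the row count.
#' @return Object of class `"metrics_report"`: `strategy`, `kind`,
#'   `per_fold` (fold x sigma precision/recall rows), `per_sigma` (means
#'   per pair plus an `"all"` aggregate row) and `aggregate` (named vector
#'   of overall mean/sd precision and recall, `NA` cells excluded).
#' @export
evaluate_strategy <- function(dataset,
                              strategy = c("chow", "regression",
                                           "classification"),
                              kind = "rf", sigmas = threshold_pairs(),
                              use_smote = TRUE, seed = 1L, folds = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(folds)) {
    folds <- if ("run" %in% names(dataset) &&
                   length(unique(dataset$run)) > 1) {
      time_series_folds_by_run(dataset$run)
    } else {
      time_series_folds(nrow(dataset))
    }
  }
  x <- as.matrix(dataset[, .feature_names])
  ycols <- paste0("y", sigmas$i)
  labels <- as.matrix(dataset[, ycols])

  rows <- list()
  for (f in folds) {
    tr <- f$train
    te <- f$test
    if (strategy == "regression") {
      fit <- fit_regressor(x[tr, , drop = FALSE],
                           dataset[tr, c("max_delta", "max_alpha")],
                           kind = kind, seed = seed + f$fold)
      pred <- predict(fit, x[te, , drop = FALSE])
    }
    for (si in seq_len(nrow(sigmas))) {
      ylab_tr <- labels[tr, si]
      ylab_te <- labels[te, si]
      pr <- tryCatch({
        p <- switch(strategy,
          chow = {
            m <- fit_chow_threshold(dataset$ll_max[tr], ylab_tr)
            predict(m, dataset$ll_max[te])
          },
          regression = regression_decision(pred, sigmas[si, ]),
          classification = {
            m <- fit_sigma_classifier(x[tr, , drop = FALSE], ylab_tr,
                                      kind = kind, use_smote = use_smote,
                                      seed = seed + 1000 * f$fold + si)
            predict(m, x[te, , drop = FALSE])
          })
        precision_recall(p, ylab_te)
      }, error = function(e) {
        message(sprintf("fold %d sigma %d skipped: %s",
                        f$fold, si, conditionMessage(e)))
        c(precision = NA_real_, recall = NA_real_)
      })
      rows[[length(rows) + 1L]] <-
        data.frame(fold = f$fold, sigma = si,
                   precision = pr[["precision"]], recall = pr[["recall"]])
    }
  }
  per_fold <- do.call(rbind, rows)
  per_sigma <- do.call(rbind, lapply(split(per_fold, per_fold$sigma),
                                     function(d) {
    data.frame(sigma = as.character(d$sigma[1]),
               precision = mean(d$precision, na.rm = TRUE),
               recall = mean(d$recall, na.rm = TRUE))
  }))
  per_sigma <- rbind(per_sigma,
                     data.frame(sigma = "all",
                                precision = mean(per_fold$precision,
                                                 na.rm = TRUE),
                                recall = mean(per_fold$recall, na.rm = TRUE)))
  rownames(per_sigma) <- NULL
  aggregate <- c(precision_mean = mean(per_fold$precision, na.rm = TRUE),
                 precision_sd = stats::sd(per_fold$precision, na.rm = TRUE),
                 recall_mean = mean(per_fold$recall, na.rm = TRUE),
                 recall_sd = stats::sd(per_fold$recall, na.rm = TRUE),
                 n_undefined = sum(is.na(per_fold$precision) |
                                     is.na(per_fold$recall)))
  name <- if (strategy == "chow") "chow" else paste(strategy, kind, sep = "_")
  structure(list(strategy = name, per_fold = per_fold,
                 per_sigma = per_sigma, aggregate = aggregate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("%s: precision %.4f +/- %.4f, recall %.4f +/- %.4f\n",
              x$strategy, a["precision_mean"], a["precision_sd"],
              a["recall_mean"], a["recall_sd"]))
  invisible(x)
}

#' Side-by-side comparison of strategy reports
#'
#' @param reports List of `"metrics_report"` objects (>= 2).
#' @return Data frame with one row per strategy (mean and sd of precision
#'   and recall) and attributes `best_by_recall`, `best_by_precision`
#'   (character; several names when tied).
#' @export
compare_strategies <- function(reports) {
  stopifnot(length(reports) >= 2)
  tab <- do.call(rbind, lapply(reports, function(r) {
    a <- r$aggregate
    data.frame(strategy = r$strategy,
               precision_mean = a[["precision_mean"]],
               precision_sd = a[["precision_sd"]],
               recall_mean = a[["recall_mean"]],
               recall_sd = a[["recall_sd"]])
  }))
  rownames(tab) <- NULL
  br <- tab$strategy[tab$recall_mean >= max(tab$recall_mean) - 1e-12]
  bp <- tab$strategy[tab$precision_mean >= max(tab$precision_mean) - 1e-12]
  attr(tab, "best_by_recall") <- br
  attr(tab, "best_by_precision") <- bp
  attr(tab, "tie") <- length(br) > 1 || length(bp) > 1
  tab
}

#' Write a metrics report as CSV plus a plain-text summary
#'
#' @param report A `"metrics_report"`.
#' @param path CSV path for the per-fold table; the summary goes to
#'   `<path>.txt`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report$per_fold, path, row.names = FALSE)
  a <- report$aggregate
  txt <- c(sprintf("Strategy: %s", report$strategy),
           sprintf("Average Precision: %.4f +/- %.4f",
                   a["precision_mean"], a["precision_sd"]),
           sprintf("Average Recall:    %.4f +/- %.4f",
                   a["recall_mean"], a["recall_sd"]),
           sprintf("Undefined (excluded) fold/sigma cells: %d",
                   as.integer(a["n_undefined"])))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
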