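#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set by interpolating new minority-class
#' samples between each minority sample and one of its `k` nearest minority
#' neighbours (uniform interpolation fraction). Only ever applied to
#' training partitions. With balanced input the data are returned unchanged.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Binary labels (0/1), length `nrow(x)`.
#' @param k Number of nearest neighbours (default 5, capped at minority
#'   size - 1).
#' @return List `x`, `y` with the minority class oversampled to parity.
#' @section Auditing: if the option `pfreject.smote_hook` holds a function,
#'   it is called as `hook(nrow(x))` on entry — used to verify that
#'   resampling only ever sees training partitions.
#' @export
smote <- function(x, y, k = 5) {
  hook <- getOption("pfreject.smote_hook")
  if (is.function(hook)) hook(NROW(x))
  x <- as.matrix(x)
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("smote requires both classes", call. = FALSE)
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  if (need == 0L) return(list(x = x, y = y))
  xm <- x[y == minority, , drop = FALSE]
  nm <- nrow(xm)
  if (nm == 1L) {
    synth <- xm[rep(1, need), , drop = FALSE]
  } else {
    k <- min(k, nm - 1L)
    d <- as.matrix(stats::dist(xm))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
    nn <- matrix(nn, nrow = k) # k x nm
    base <- sample.int(nm, need, replace = TRUE)
    pick <- nn[cbind(sample.int(k, need, replace = TRUE), base)]
    u <- stats::runif(need)
    synth <- xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  }
  list(x = rbind(x, synth), y = c(y, rep(minority, need)))
}

#' Fit the Chow-style likelihood threshold baseline
#'
#' The baseline reject rule declares the track lost when the (window-mean)
#' maximum log-likelihood falls below a threshold `tau`. The threshold is
#' selected from an evenly spaced candidate grid on `[-200, 200]` (step 1,
#' 401 candidates) by maximizing the F1 score of the rule on the training
#' data; ties resolve to the smallest `tau`.
#'
#' @param ll_max Training log-likelihood scores (nats).
#' @param labels Binary lost-track labels (1 = lost).
#' @return Object of class `"chow_model"` with fields `tau` and `train_f1`.
#' @export
fit_chow_threshold <- function(ll_max, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("chow threshold fit needs both classes in the training labels",
         call. = FALSE)
  }
  taus <- seq(-200, 200, by = 1)
  f1 <- vapply(taus, function(tau) {
    pred <- as.integer(ll_max < tau)
    tp <- sum(pred == 1L & labels == 1L)
    fp <- sum(pred == 1L & labels == 0L)
    fn <- sum(pred == 0L & labels == 1L)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- which.max(f1) # ties: smallest tau
  structure(list(tau = taus[best], train_f1 = f1[best]),
            class = "chow_model")
}

#' @export
predict.chow_model <- function(object, ll_max, ...) {
  as.integer(ll_max < object$tau)
}

#' Fit a per-tolerance binary lost-track classifier
#'
#' Trains one binary classifier for a single tolerance pair `sigma` on the
#' 11-D window features. Two families are supported: a linear max-margin
#' classifier (SVM, linear kernel; score = signed distance to the decision
#' boundary) and a random forest (100 trees; score = fraction of trees
#' voting lost). SMOTE is applied to the training data by default.
#' Prediction is `lost` iff score >= phi, with `phi` defaulting to the
#' scorer's native boundary (0 for the margin, 0.5 for vote fractions).
#'
#' @param x Feature matrix (or data frame) of training windows.
#' @param y Binary labels for the trained-for sigma (1 = lost).
#' @param kind `"svm_linear"` or `"rf"`.
#' @param use_smote Balance the training data with [smote()] first.
#' @param seed Integer seed for SMOTE and the forest.
#' @param sigma_index Optional index of the tolerance pair this classifier
#'   was trained for (bookkeeping).
#' @return Object of class `"sigma_classifier"`.
#' @export
fit_sigma_classifier <- function(x, y, kind = c("rf", "svm_linear"),
                                 use_smote = TRUE, seed = 1L,
                                 sigma_index = NA_integer_) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("classifier fit needs both classes present", call. = FALSE)
  }
  set.seed(seed)
  if (use_smote) {
    b <- smote(x, y)
    x <- b$x
    y <- b$y
  }
  if (kind == "svm_linear") {
    # scale manually so degenerate constant columns don't trip the scaler
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    fit <- e1071::svm(scale(x, mu, sdv), factor(y, levels = c(0, 1)),
                      kernel = "linear", scale = FALSE)
    model <- list(fit = fit, mu = mu, sd = sdv)
  } else {
    fit <- randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                      ntree = 100)
    model <- list(fit = fit)
  }
  structure(list(kind = kind, model = model,
                 phi = if (kind == "rf") 0.5 else 0,
                 sigma_index = sigma_index),
            class = "sigma_classifier")
}

#' Continuous lost-track score of a classifier
#'
#' The margin distance for the linear model (positive = lost side), the
#' fraction of trees voting lost for the forest (in `[0, 1]`).
#'
#' @param model A `"sigma_classifier"`.
#' @param x Feature matrix.
#' @return Numeric score per row.
#' @export
classifier_score <- function(model, x) {
  x <- as.matrix(x)
  if (model$kind == "svm_linear") {
    xs <- scale(x, model$model$mu, model$model$sd)
    dv <- attr(stats::predict(model$model$fit, xs, decision.values = TRUE),
               "decision.values")
    s <- as.numeric(dv)
    # e1071 orients the decision value toward the first factor level seen in
    # training; flip so that larger always means "lost"
    if (colnames(dv)[1] == "0/1") -s else s
  } else {
    stats::predict(model$model$fit, x, type = "vote")[, "1"]
  }
}

#' @export
predict.sigma_classifier <- function(object, x, phi = object$phi, ...) {
  as.integer(classifier_score(object, x) >= phi)
}

# precision/recall of the rule score >= phi against labels
.pr_at_phi <- function(score, labels, phi) {
  pred <- score >= phi
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Coverage range of a classifier over the tolerance pairs
#'
#' A classifier trained for one tolerance pair can be extended to
#' neighbouring pairs by shifting its decision threshold `phi`. For each
#' tolerance pair, `phi` is swept over every cutpoint of the training
#' scores (the sorted unique scores plus +/- infinity); the pair is in the
#' classifier's range iff some `phi` attains both goal precision and goal
#' recall against that pair's labels. The recorded `phi` per covered pair
#' maximizes precision + recall.
#'
#' @param model A `"sigma_classifier"`.
#' @param x Training feature matrix.
#' @param labels_mat Matrix of labels, one column per tolerance pair.
#' @param goal_p,goal_r Target precision and recall in `(0, 1]`.
#' @return Data frame with one row per covered pair: `sigma` (column
#'   index), `phi`, `precision`, `recall`; zero rows when nothing is
#'   covered.
#' @export
classifier_range <- function(model, x, labels_mat, goal_p, goal_r) {
  stopifnot(goal_p > 0, goal_p <= 1, goal_r > 0, goal_r <= 1)
  score <- classifier_score(model, x)
  phis <- c(-Inf, sort(unique(score)), Inf)
  labels_mat <- as.matrix(labels_mat)
  rows <- lapply(seq_len(ncol(labels_mat)), function(si) {
    lab <- as.integer(labels_mat[, si])
    pr <- vapply(phis, function(phi) .pr_at_phi(score, lab, phi), numeric(2))
    ok <- which(!is.na(pr[1, ]) & !is.na(pr[2, ]) &
                  pr[1, ] >= goal_p & pr[2, ] >= goal_r)
    if (!length(ok)) return(NULL)
    best <- ok[which.max(pr[1, ok] + pr[2, ok])]
    data.frame(sigma = si, phi = phis[best],
               precision = pr[1, best], recall = pr[2, best])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(sigma = integer(0), phi = numeric(0),
                      precision = numeric(0), recall = numeric(0)))
  }
  do.call(rbind, rows)
}

# minimum set cover by exhaustive search in increasing cardinality;
# sets: list of integer vectors; universe: integer vector
.min_set_cover <- function(sets, universe) {
  m <- length(sets)
  covered_all <- sort(unique(unlist(sets)))
  if (!all(universe %in% covered_all)) {
    orphans <- setdiff(universe, covered_all)
    stop(sprintf("no candidate covers tolerance pair(s): %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  for (size in seq_len(m)) {
    combos <- utils::combn(m, size, simplify = FALSE)
    hits <- combos[vapply(combos, function(cc) {
      all(universe %in% unlist(sets[cc]))
    }, logical(1))]
    if (length(hits)) return(hits)
  }
  stop("unreachable: full candidate set does not cover", call. = FALSE)
}

#' Build a sparse ensemble of threshold-shifted classifiers
#'
#' Given one candidate classifier per tolerance pair, computes each
#' candidate's coverage range under the precision/recall goals (see
#' [classifier_range()]) and selects the minimum number of classifiers
#' whose ranges jointly cover all pairs (exhaustive set-cover search by
#' increasing cardinality; among minimum covers, the one with the highest
#' total precision + recall over its per-pair assignments wins). A pair
#' covered by several selected members is assigned to the member with the
#' highest precision + recall at that pair.
#'
#' @param candidates List of `"sigma_classifier"` candidates.
#' @param x Training feature matrix.
#' @param labels_mat Label matrix, one column per tolerance pair.
#' @param goal_p,goal_r Precision/recall goals.
#' @param sigmas Tolerance-pair table (default [threshold_pairs()]).
#' @return Object of class `"sparse_ensemble"`: `members` (the selected
#'   classifiers), `assignment` (data frame: `sigma`, `member`, `phi`,
#'   `precision`, `recall`), `goal_p`, `goal_r`.
#' @export
build_sparse_ensemble <- function(candidates, x, labels_mat,
                                  goal_p, goal_r,
                                  sigmas = threshold_pairs()) {
  ranges <- lapply(candidates, classifier_range, x = x,
                   labels_mat = labels_mat, goal_p = goal_p, goal_r = goal_r)
  sets <- lapply(ranges, `[[`, "sigma")
  universe <- seq_len(ncol(as.matrix(labels_mat)))
  covers <- .min_set_cover(sets, universe)

  score_cover <- function(cc) {
    # per-sigma best member among cc, summed precision+recall
    tot <- 0
    assign <- lapply(universe, function(si) {
      best <- NULL
      for (m in cc) {
        r <- ranges[[m]]
        row <- r[r$sigma == si, ]
        if (nrow(row) &&
            (is.null(best) ||
             row$precision + row$recall > best$precision + best$recall)) {
          best <- cbind(data.frame(sigma = si, member = m),
                        row[, c("phi", "precision", "recall")])
        }
      }
      best
    })
    assign <- do.call(rbind, assign)
    list(total = sum(assign$precision + assign$recall), assign = assign)
  }
  scored <- lapply(covers, score_cover)
  best <- which.max(vapply(scored, `[[`, numeric(1), "total"))
  cc <- covers[[best]]
  assign <- scored[[best]]$assign
  # renumber members 1..|cc|
  assign$member <- match(assign$member, cc)
  rownames(assign) <- NULL
  structure(list(members = candidates[cc], assignment = assign,
                 goal_p = goal_p, goal_r = goal_r),
            class = "sparse_ensemble")
}

#' @export
print.sparse_ensemble <- function(x, ...) {
  cat("sparse_ensemble:", length(x$members), "member(s) covering",
      nrow(x$assignment), "tolerance pairs at goals p >=", x$goal_p,
      ", r >=", x$goal_r, "\n")
  invisible(x)
}

#' Predict lost-track labels with a sparse ensemble
#'
#' @param object A `"sparse_ensemble"`.
#' @param x Feature matrix.
#' @param sigma Tolerance-pair index (1..20).
#' @param ... Unused.
#' @return Integer 0/1 predictions for that pair, using its assigned member
#'   and shifted threshold.
#' @export
predict.sparse_ensemble <- function(object, x, sigma, ...) {
  row <- object$assignment[object$assignment$sigma == sigma, ]
  if (!nrow(row)) stop("sigma not covered by this ensemble", call. = FALSE)
  member <- object$members[[row$member[1]]]
  as.integer(classifier_score(member, x) >= row$phi[1])
}

#' Fit the distance/angle regression reject model
#'
#' Trains two regressors predicting the window-maximum position error
#' (meters) and angular error (radians) from the 11-D features; a single
#' regression pair then serves every tolerance pair via
#' [regression_decision()]. Supported families: `"linear"` (least squares),
#' `"rf"` (random forest, 100 trees), `"svr"` (eps-regression, RBF kernel)
#' and `"gp"` (Gaussian process, RBF kernel).
#'
#' @param x Feature matrix.
#' @param targets Two-column matrix/data frame `(max_delta, max_alpha)`.
#' @param kind Model family.
#' @param seed Integer seed (forest).
#' @return Object of class `"reject_regressor"`.
#' @export
fit_regressor <- function(x, targets, kind = c("rf", "linear", "svr", "gp"),
                          seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  targets <- as.matrix(targets)
  stopifnot(nrow(x) >= 2, ncol(targets) == 2)
  set.seed(seed)
  fit_one <- function(yy) {
    switch(kind,
      linear = {
        d <- data.frame(y = yy, x)
        stats::lm(y ~ ., data = d)
      },
      rf = randomForest::randomForest(x, yy, ntree = 100),
      svr = e1071::svm(x, yy, type = "eps-regression", kernel = "radial"),
      gp = kernlab::gausspr(x, yy))
  }
  structure(list(kind = kind,
                 fit_d = fit_one(targets[, 1]),
                 fit_a = fit_one(targets[, 2]),
                 feature_names = colnames(x)),
            class = "reject_regressor")
}

#' @export
predict.reject_regressor <- function(object, x, ...) {
  x <- as.matrix(x)
  pred_one <- function(fit) {
    if (object$kind == "linear") {
      as.numeric(stats::predict(fit, newdata = as.data.frame(x)))
    } else if (object$kind == "gp") {
      as.numeric(kernlab::predict(fit, x))
    } else {
      as.numeric(stats::predict(fit, x))
    }
  }
  out <- cbind(d = pred_one(object$fit_d), a = pred_one(object$fit_a))
  pmax(out, 0) # errors are non-negative
}

#' Reject decision from a regression prediction
#'
#' Keeps the track (0) iff the predicted distance error is at most the
#' distance tolerance AND the predicted angular error is at most the
#' angular tolerance; otherwise lost (1). Predictions exactly at the
#' tolerance are kept, mirroring the strict exceedance in the labels.
#' Negative predictions are clamped to 0 first.
#'
#' @param pred Two-column matrix of predictions `(d, a)` (or length-2
#'   vector).
#' @param sigma A tolerance pair (list or row with `d`, `a`).
#' @return Integer 0/1 per row.
#' @export
regression_decision <- function(pred, sigma) {
  if (is.null(dim(pred))) pred <- matrix(pred, ncol = 2)
  pred <- pmax(pred, 0)
  as.integer(!(pred[, 1] <= sigma$d & pred[, 2] <= sigma$a))
}
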