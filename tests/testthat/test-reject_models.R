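make_toy <- function(n = 120, seed = 14, sep = 2) {
  # two Gaussian blobs in 2-D, label 1 shifted by `sep` along x
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- cbind(stats::rnorm(n) + sep * y, stats::rnorm(n))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = y)
}

test_that("smote balances the minority class by interpolation", {
  set.seed(2)
  x <- matrix(stats::rnorm(60), ncol = 2)
  y <- c(rep(1L, 5), rep(0L, 25))
  b <- smote(x, y)
  expect_equal(sum(b$y == 1), sum(b$y == 0))
  # synthetic minority points lie inside the minority bounding box
  xm <- x[y == 1, ]
  synth <- b$x[-seq_len(nrow(x)), , drop = FALSE]
  for (j in 1:2) {
    expect_true(all(synth[, j] >= min(xm[, j]) - 1e-12))
    expect_true(all(synth[, j] <= max(xm[, j]) + 1e-12))
  }
  # balanced input is a no-op
  yb <- rep(c(0L, 1L), 15)
  nb <- smote(x, yb)
  expect_equal(nb$x, x)
  expect_equal(nb$y, yb)
  expect_error(smote(x, rep(0L, 30)), "both classes")
})

test_that("chow threshold maximizes training F1 over the candidate grid", {
  # perfectly separated scores: lost windows have low likelihood
  ll <- c(seq(-150, -100, length.out = 30), seq(50, 150, length.out = 70))
  y <- c(rep(1L, 30), rep(0L, 70))
  m <- fit_chow_threshold(ll, y)
  expect_s3_class(m, "chow_model")
  expect_equal(m$train_f1, 1)
  pred <- predict(m, ll)
  expect_equal(pred, y)
  # the threshold is one of the 401 integer candidates in [-200, 200]
  expect_true(m$tau %in% seq(-200, 200, 1))
  # ties resolve to the smallest tau: any tau in (-100, 50] separates, so
  # the fitted one is the smallest working integer
  expect_equal(m$tau, -99)
  expect_error(fit_chow_threshold(ll, rep(1L, 100)), "both classes")
  # labels independent of the score: no crash, F1 near the base rate
  set.seed(6)
  y_rand <- sample(c(0L, 1L), 100, replace = TRUE)
  m2 <- fit_chow_threshold(ll, y_rand)
  expect_true(m2$train_f1 >= 0 && m2$train_f1 <= 1)
})

test_that("classifier families expose calibrated continuous scores", {
  toy <- make_toy(sep = 6)
  lin <- fit_sigma_classifier(toy$x, toy$y, kind = "svm_linear", seed = 3)
  expect_equal(predict(lin, toy$x), toy$y) # separable: zero training error
  s <- classifier_score(lin, toy$x)
  expect_true(mean(s[toy$y == 1]) > mean(s[toy$y == 0]))

  rf <- fit_sigma_classifier(toy$x, toy$y, kind = "rf", seed = 3)
  sc <- classifier_score(rf, toy$x)
  expect_true(all(sc >= 0 & sc <= 1))
  # vote-fraction audit: score equals the fraction of individual trees
  # predicting "lost"
  all_trees <- stats::predict(rf$model$fit, toy$x, predict.all = TRUE)
  votes <- rowMeans(all_trees$individual == "1")
  expect_equal(unname(sc), unname(votes), tolerance = 1e-12)
  expect_error(fit_sigma_classifier(toy$x, rep(1L, nrow(toy$x))),
               "both classes")
})

test_that("classifier range reproduces the exhaustive cutpoint sweep", {
  toy <- make_toy(n = 80, sep = 3)
  # three label columns: the trained-for labels, a noisier variant, and an
  # unrelated one
  set.seed(8)
  labels <- cbind(toy$y,
                  ifelse(stats::runif(80) < 0.15, 1L - toy$y, toy$y),
                  sample(toy$y))
  m <- fit_sigma_classifier(toy$x, toy$y, kind = "svm_linear", seed = 5)
  score <- classifier_score(m, toy$x)

  brute_feasible <- function(lab, gp, gr) {
    any(vapply(c(-Inf, sort(unique(score)), Inf), function(phi) {
      pred <- as.integer(score >= phi)
      tp <- sum(pred & lab); fp <- sum(pred & !lab); fn <- sum(!pred & lab)
      p <- if (tp + fp > 0) tp / (tp + fp) else NA
      r <- if (tp + fn > 0) tp / (tp + fn) else NA
      !is.na(p) && !is.na(r) && p >= gp && r >= gr
    }, logical(1)))
  }
  for (goals in list(c(0.9, 0.9), c(0.99, 0.99), c(0.7, 0.7))) {
    rng <- classifier_range(m, toy$x, labels, goals[1], goals[2])
    for (si in 1:3) {
      expect_equal(si %in% rng$sigma,
                   brute_feasible(labels[, si], goals[1], goals[2]),
                   info = sprintf("sigma %d at goals %.2f", si, goals[1]))
    }
  }
  # achievable goals on its own labels: self-coverage
  rng_self <- classifier_range(m, toy$x, matrix(toy$y, ncol = 1), 0.8, 0.8)
  expect_true(1 %in% rng_self$sigma)
  # impossible goals on scrambled labels: empty range
  rng_none <- classifier_range(m, toy$x, labels[, 3, drop = FALSE], 1, 1)
  expect_equal(nrow(rng_none), 0)
})

test_that("the covering algorithm finds a minimum-cardinality ensemble", {
  # internal set-cover solver against full subset enumeration
  set.seed(19)
  for (rep in 1:25) {
    m <- sample(3:8, 1)
    sets <- lapply(seq_len(m), function(i) {
      sort(sample(1:20, sample(3:15, 1)))
    })
    universe <- sort(unique(unlist(sets)))
    got <- pfreject:::.min_set_cover(sets, universe)
    expect_equal(length(got[[1]]), brute_min_cover(sets, universe))
  }
  orphan_sets <- list(1:5, 3:10)
  expect_error(pfreject:::.min_set_cover(orphan_sets, 1:20), "11")
})

test_that("sparse ensembles cover every pair and shrink with laxer goals", {
  toy <- make_toy(n = 200, sep = 4)
  # nested labels mimicking tolerance pairs: column j flips a growing
  # fraction of hard cases, so strict columns are noisier
  set.seed(23)
  noise_rate <- seq(0.3, 0, length.out = 6)
  labels <- vapply(1:6, function(j) {
    flip <- stats::runif(200) < noise_rate[j]
    ifelse(flip, 1L - toy$y, toy$y)
  }, integer(200))
  cands <- lapply(1:6, function(j) {
    fit_sigma_classifier(toy$x, labels[, j], kind = "rf", seed = 30 + j,
                         sigma_index = j)
  })
  ens_lax <- build_sparse_ensemble(cands, toy$x, labels, 0.6, 0.6)
  expect_s3_class(ens_lax, "sparse_ensemble")
  expect_equal(sort(ens_lax$assignment$sigma), 1:6)
  # every pair is assigned exactly once, to a selected member
  expect_equal(anyDuplicated(ens_lax$assignment$sigma), 0)
  expect_true(all(ens_lax$assignment$member %in%
                    seq_along(ens_lax$members)))
  # one candidate covering everything yields an ensemble of size one
  perfect <- fit_sigma_classifier(toy$x, labels[, 6], kind = "rf", seed = 44)
  ens_one <- build_sparse_ensemble(list(perfect), toy$x,
                                   labels[, 6, drop = FALSE], 0.7, 0.7)
  expect_length(ens_one$members, 1)
  # predictions for a pair depend only on its assigned member and phi
  p6 <- predict(ens_lax, toy$x, sigma = 6)
  row <- ens_lax$assignment[ens_lax$assignment$sigma == 6, ]
  manual <- as.integer(classifier_score(ens_lax$members[[row$member]],
                                        toy$x) >= row$phi)
  expect_equal(p6, manual)
  # relaxing goals never grows the minimum ensemble
  ens_strict <- tryCatch(
    build_sparse_ensemble(cands, toy$x, labels, 0.9, 0.9),
    error = function(e) NULL)
  if (!is.null(ens_strict)) {
    expect_gte(length(ens_strict$members), length(ens_lax$members))
  }
})

test_that("regression rejectors fit their families and decide by tolerance", {
  set.seed(51)
  x <- matrix(stats::runif(300), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  targets <- cbind(0.1 * x[, 1] + 0.02, 0.2 * x[, 2] + 0.01)
  lin <- fit_regressor(x, targets, kind = "linear")
  expect_lt(max(abs(predict(lin, x) - targets)), 1e-9)
  const <- fit_regressor(x, cbind(rep(0.07, 100), rep(0.2, 100)),
                         kind = "linear")
  expect_equal(unname(predict(const, x[1:5, ])),
               unname(cbind(rep(0.07, 5), rep(0.2, 5))), tolerance = 1e-9)
  # step-function target: the forest captures it better than a line
  xs <- matrix(seq(0, 1, length.out = 200), ncol = 1,
               dimnames = list(NULL, "a"))
  ys <- cbind(ifelse(xs[, 1] > 0.5, 0.3, 0.05), rep(0.1, 200))
  # the toy target has few unique values; the forest warns about that
  rf <- suppressWarnings(fit_regressor(xs, ys, kind = "rf", seed = 2))
  l2 <- fit_regressor(xs, ys, kind = "linear")
  rmse <- function(m) sqrt(mean((predict(m, xs)[, 1] - ys[, 1])^2))
  expect_lt(rmse(rf), rmse(l2))

  sig1 <- list(d = 0.05, a = 0.13)
  expect_equal(regression_decision(c(0.04, 0.10), sig1), 0)
  expect_equal(regression_decision(c(0.06, 0.10), sig1), 1)
  expect_equal(regression_decision(c(0.04, 0.20), sig1), 1)
  # boundary: exactly at tolerance is kept; negatives clamp to zero
  expect_equal(regression_decision(c(0.05, 0.13), sig1), 0)
  expect_equal(regression_decision(c(-0.2, -0.1), sig1), 0)
  # monotone in sigma: rejected under a tolerant pair implies rejected
  # under every stricter pair
  sig <- threshold_pairs()
  pred <- cbind(stats::runif(50, 0, 0.3), stats::runif(50, 0, 0.4))
  dec <- vapply(seq_len(nrow(sig)), function(i) {
    regression_decision(pred, sig[i, ])
  }, integer(50))
  for (r in 1:50) expect_true(all(diff(dec[r, ]) <= 0))
})
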