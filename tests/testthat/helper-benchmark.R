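# The packaged synthetic benchmark is expensive to build, and several tests
# evaluate different aspects of the same run (strategy ordering, ensemble
# sizes). Build it lazily, once per test session.

.bench_cache <- new.env(parent = emptyenv())

bench_dataset <- function() {
  if (is.null(.bench_cache$ds)) {
    .bench_cache$ds <- benchmark_dataset(n_configs = 60, seed = 1, k_max = 300)
  }
  .bench_cache$ds
}

# One candidate classifier per tolerance pair, trained once on the full
# benchmark; coverage ranges at different goals reuse the same candidates.
bench_rf_candidates <- function() {
  if (is.null(.bench_cache$cands)) {
    ds <- bench_dataset()
    x <- as.matrix(ds[, pfreject:::.feature_names])
    labels <- as.matrix(ds[, paste0("y", 1:20)])
    .bench_cache$cands <- lapply(1:20, function(si) {
      tryCatch(fit_sigma_classifier(x, labels[, si], kind = "rf",
                                    seed = 100 + si, sigma_index = si),
               error = function(e) NULL)
    })
  }
  .bench_cache$cands
}

bench_report <- function(strategy, kind = "rf") {
  key <- paste0("rep_", strategy, "_", kind)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- evaluate_strategy(bench_dataset(), strategy,
                                             kind = kind, seed = 11)
  }
  .bench_cache[[key]]
}
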