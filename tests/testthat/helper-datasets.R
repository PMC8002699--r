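# A small synthetic window dataset whose ll_max feature separates the
# labels perfectly, so the Chow baseline acts as an oracle on it.
make_eval_dataset <- function(n = 110, seed = 33) {
  set.seed(seed)
  lost <- rep(c(0L, 1L), length.out = n)
  # bounded, integer-separated score ranges so a training-selected integer
  # threshold generalizes exactly to held-out folds
  ll <- ifelse(lost == 1, stats::runif(n, -150, -141), stats::runif(n, 100, 110))
  feat <- data.frame(n_trans = 0.005, n_rot = 0.02, vf = 0.9,
                     w_exp = 0.3, w_gaus = 0.6, w_uni = 0.1, k = 200,
                     ll_max = ll, ess = stats::rnorm(n, 1),
                     w_mean = stats::rnorm(n, -50),
                     w_var = stats::rnorm(n, 4)^2)
  labs <- matrix(rep(lost, 20), ncol = 20,
                 dimnames = list(NULL, paste0("y", 1:20)))
  cbind(data.frame(run = 1, seq_id = 1, config_id = 1, start = seq_len(n)),
        feat,
        data.frame(max_delta = ifelse(lost == 1, 0.3, 0.01),
                   max_alpha = ifelse(lost == 1, 0.5, 0.02)),
        as.data.frame(labs))
}
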