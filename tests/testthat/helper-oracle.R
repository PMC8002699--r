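# Independent, naively-coded oracles used to cross-check the fast paths.

# Per-pixel mixture log-likelihood, written directly from the case
# definitions with stats::dnorm (independent of the compiled path).
naive_pixel_ll <- function(xo, xe, cfg, intr) {
  if (is.na(xe)) return(0)
  uni <- cfg$w_uni / (intr$d_max - intr$d_min)
  if (is.na(xo)) return(log(uni))
  v <- uni + cfg$w_gaus * stats::dnorm(xo, xe, sqrt(cfg$df * xe^2 + cfg$bn))
  if (xe >= xo) {
    v <- v + cfg$w_exp * cfg$lam * exp(-cfg$lam * xo) / (1 - exp(-cfg$lam * xe))
  }
  log(v)
}

# Brute-force image weight: double loop over all pixels.
naive_image_weight <- function(obs, expd, cfg, intr) {
  s <- 0
  for (i in seq_len(nrow(obs))) {
    for (j in seq_len(ncol(obs))) {
      s <- s + naive_pixel_ll(obs[i, j], expd[i, j], cfg, intr)
    }
  }
  s
}

# Analytic ray-sphere z-depth for pixel (row i, col j), 1-based, or NA.
naive_sphere_depth <- function(i, j, center, r, intr) {
  dx <- (j - 1 - intr$cx) / intr$fx
  dy <- (i - 1 - intr$cy) / intr$fy
  A <- dx^2 + dy^2 + 1
  B <- dx * center[1] + dy * center[2] + center[3]
  C <- sum(center^2) - r^2
  disc <- B^2 - A * C
  if (disc < 0) return(NA_real_)
  t <- (B - sqrt(disc)) / A
  if (t < intr$d_min || t > intr$d_max) return(NA_real_)
  t
}

# Minimum set cover by full subset enumeration (oracle for the ensemble
# covering algorithm): returns the smallest number of sets covering the
# universe, or Inf when impossible.
brute_min_cover <- function(sets, universe) {
  m <- length(sets)
  best <- Inf
  for (mask in seq_len(2^m - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(members) >= best) next
    if (all(universe %in% unlist(sets[members]))) best <- length(members)
  }
  best
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}
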