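# shared fixtures and independent oracles, built in code at test time

# small phantom cached per (seed, sigma, size) so suites don't regenerate
phantom_cache <- new.env(parent = emptyenv())
small_phantom <- function(seed = 1, sigma = 0.005, size = 320L) {
  key <- sprintf("s%d_n%g_d%d", seed, sigma, size)
  if (is.null(phantom_cache[[key]]))
    phantom_cache[[key]] <- generate_phantom(phantom_spec(
      width = size, height = size, seed = seed, noise_od_sigma = sigma))
  phantom_cache[[key]]
}

max_channel_diff <- function(a, b) {
  d <- abs(a - b)
  pmax(d[, , 1], d[, , 2], d[, , 3])
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# independent brute-force weighted kappa: observed disagreement as the
# mean pairwise weight along the diagonal of positions, expected
# disagreement as the mean weight over ALL position pairs (i, j) --
# a different computational route than the contingency-table formula
brute_force_kappa <- function(a, b, categories, weighting = "quadratic") {
  k <- length(categories)
  wfun <- function(u, v) {
    d <- abs(match(u, categories) - match(v, categories)) / (k - 1)
    if (weighting == "quadratic") d^2 else d
  }
  n <- length(a)
  o <- mean(wfun(a, b))
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) e <- e + wfun(a[i], b[j])
  e <- e / n^2
  if (e <= .Machine$double.eps) return(NA_real_)  # undefined agreement
  1 - o / e
}

# all rating vectors of length n over the given categories
all_vectors <- function(n, categories) {
  g <- do.call(expand.grid, rep(list(categories), n))
  as.matrix(g)
}
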