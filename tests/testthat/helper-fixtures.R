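# Shared fixture builders; everything is generated in code at test time.

random_points <- function(n, width = 40, height = 50, seed = NULL) {
  meadowpath:::with_seed(seed, cbind(runif(n, 0, width), runif(n, 0, height)))
}

# Brute-force Mantel permutation distribution: correlation of upper
# triangles under every (or n_perm sampled) joint relabeling of b.
enumerate_mantel <- function(a, b) {
  n <- nrow(a)
  perms <- permutations_of(n)
  ua <- a[upper.tri(a)]
  vapply(seq_len(ncol(perms)), function(k) {
    p <- perms[, k]
    bp <- b[p, p]
    cor(ua, bp[upper.tri(bp)])
  }, 0)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  n <- as.integer(n)
  sub <- permutations_of(n - 1L)
  do.call(cbind, lapply(seq_len(ncol(sub)), function(j)
    vapply(seq_len(n), function(pos) append(sub[, j], n, after = pos - 1L),
           integer(n))))
}

# Method-of-moments semivariogram estimate in a distance band.
semivariance_band <- function(locations, values, lo, hi) {
  h <- as.matrix(dist(locations))
  dv <- outer(values, values, "-")^2 / 2
  sel <- h > lo & h < hi & upper.tri(h)
  mean(dv[sel])
}

# A small study for network/pipeline tests (fast but non-trivial).
small_truth <- function(seed = 1, n_plants = 80) {
  truth_config(n_plants = n_plants, n_env_sites = 40, n_lines = 5, seed = seed)
}

study_analysis_frame <- function(study) {
  cbind(study$plant_env[, c("x", "y", "elevation", "soil_moisture", "vpd")],
        study$plants[, setdiff(names(study$plants), c("x", "y"))])
}
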