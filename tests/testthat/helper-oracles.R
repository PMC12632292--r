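# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# Benjamini-Hochberg step-up by explicit definition:
# q_(i) = min_{j >= i} ( p_(j) * n / j ), capped at 1
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) ps[j] * n / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# per-region median by explicit sorting
median_oracle <- function(values, labels) {
  regs <- sort(unique(labels))
  vapply(regs, function(r) {
    v <- sort(values[labels == r])
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }, numeric(1))
}

# bilateral symmetry by explicit pair enumeration
symmetry_oracle <- function(df) {
  ks <- sort(unique(df$cluster))
  M <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  regs <- unique(df$region)
  for (a in seq_along(ks)) for (b in seq_along(ks)) {
    i <- ks[a]; j <- ks[b]
    num <- 0; members <- character()
    for (r in regs) {
      cl <- df$cluster[df$region == r & df$hemisphere == "L"]
      cr <- df$cluster[df$region == r & df$hemisphere == "R"]
      if (cl == i && cr == j) num <- num + 1
      if (cl %in% c(i, j) || cr %in% c(i, j)) members <- union(members, r)
    }
    M[a, b] <- if (length(members)) num / length(members) else 0
  }
  M
}

# analytic sphere/shell quantities
sphere_area <- function(R) 4 * pi * R^2
shell_volume <- function(R, r) 4 / 3 * pi * (R^3 - r^3)

# three synthetic rate-curve archetypes on the midpoint grid, for clustering
# tests: distinct early/flat/late shapes
archetype_rate_curves <- function(midpoints = seq(22.05, 31.95, by = 0.1)) {
  t <- midpoints - 22
  rbind(early = 20 - 1.2 * t,
        flat = rep(10, length(t)),
        late = 2 + 1.0 * t)
}

make_rate_profiles <- function(n_per = 6, noise_sd = 0.1, seed = 1,
                               midpoints = seq(22.05, 31.95, by = 0.1)) {
  set.seed(seed)
  arch <- archetype_rate_curves(midpoints)
  prof <- do.call(rbind, lapply(1:3, function(a)
    matrix(rep(arch[a, ], n_per), nrow = n_per, byrow = TRUE) +
      matrix(rnorm(n_per * length(midpoints), 0, noise_sd), n_per)))
  rownames(prof) <- paste0("p", seq_len(nrow(prof)))
  attr(prof, "truth") <- rep(1:3, each = n_per)
  prof
}

# adjusted Rand index (only needed when mclust is unavailable the tests use
# mclust::adjustedRandIndex; this wrapper keeps a single call site)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# attach trivial labels (region 1, hemisphere by sign of x) to an unlabeled
# surface pair so the voxelizer accepts it
relabel_pair <- function(pair) {
  hemi <- ifelse(pair$outer$vertices[, 1] < 0, "L", "R")
  lab <- rep(1L, nrow(pair$outer$vertices))
  surface_pair(
    tri_mesh(pair$outer$vertices, pair$outer$faces, lab, hemi),
    tri_mesh(pair$inner$vertices, pair$inner$faces, lab, hemi))
}
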