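# Brute-force graph oracles, independent of the package's (igraph-backed)
# implementations: shortest-path lengths and counts from adjacency-matrix
# powers (walks of minimal length are exactly the shortest paths).

bf_shortest <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  Sig <- diag(1, n)
  Ak <- diag(1, n)
  for (t in seq_len(n)) {
    Ak <- Ak %*% adj
    new <- is.infinite(D) & Ak > 0
    D[new] <- t
    Sig[new] <- Ak[new]
  }
  list(D = D, Sig = Sig)
}

bf_betweenness <- function(adj, normalized = TRUE) {
  n <- nrow(adj)
  sp <- bf_shortest(adj)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s < t && s != v && t != v && is.finite(sp$D[s, t])) {
        if (is.finite(sp$D[s, v]) && is.finite(sp$D[v, t]) &&
            sp$D[s, v] + sp$D[v, t] == sp$D[s, t]) {
          b[v] <- b[v] + sp$Sig[s, v] * sp$Sig[v, t] / sp$Sig[s, t]
        }
      }
    }
  }
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  b
}

bf_efficiency <- function(adj) {
  n <- nrow(adj)
  D <- bf_shortest(adj)$D
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    sum(1 / d[is.finite(d)]) / (n - 1)
  }, 0)
}

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1L, p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# Small shared fixtures ------------------------------------------------------

tiny_atlas <- function(nRegions = 5, shape = c(12, 12, 10), seed = 1) {
  generateAtlas(shape, nRegions, seed = seed)
}

tiny_planted_cohort <- function(atlas = tiny_atlas(),
                                nPerGroup = 12, nT = 60,
                                effectRegions = c(1, 2), effectSize = 0.4,
                                seed = 7) {
  generateCohort(atlas, cohortSpec(
    nPatients = nPerGroup, nControls = nPerGroup, nTimepoints = nT,
    effectRegions = effectRegions, effectSize = effectSize, seed = seed))
}
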