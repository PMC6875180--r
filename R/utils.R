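# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user simulations.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-stream seed: namespaces a base seed by an integer tag so
# per-region / per-subject draws are independent of iteration order.
# Kept strictly below 2^31 - 1.
substream_seed <- function(seed, tag) {
  s <- (as.double(seed) %% 2147483647) + 1
  t <- (as.double(tag) %% 2147483647) + 1
  as.integer((s * 69621 + t * 40014) %% 2147483647)
}

# Round half away from zero (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Voxel-centre physical coordinates (mm) for linear indices into a 3D grid.
voxel_coords_mm <- function(idx, dim, spacing) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1L]
  j <- (idx0 %/% dim[1L]) %% dim[2L]
  k <- idx0 %/% (dim[1L] * dim[2L])
  cbind((i + 1) * spacing[1L], (j + 1) * spacing[2L], (k + 1) * spacing[3L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
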