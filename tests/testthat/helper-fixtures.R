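# Shared fixtures, all generated in code.

# a small but fully featured ground-truth striatum; island radius scaled down
# to fit the small nuclei
small_gt <- function(seed = 1, grid = c(20L, 24L, 20L), island_radius = 2L, ...) {
  generate_striatum(striatum_spec(grid_shape = grid, rng_seed = seed,
                                  island_radius = island_radius, ...))
}

# identity-spacing affine centred on the world origin
test_affine <- function(dim, voxel = c(1, 1, 1)) centered_affine(dim, voxel)

# a hand-sized target_counts object on an arbitrary striatum mask:
# `s` and `m` are arrays of summed striosome-/matrix-favoring counts, split
# evenly over one bait region per class
toy_counts <- function(s, m, striatum = NULL, voxel = c(1, 1, 1)) {
  dm <- dim(s)
  if (is.null(striatum)) striatum <- array(TRUE, dm)
  baits <- bait_region_set(data.frame(
    name = c("strio_bait", "matrix_bait"),
    favored = c("striosome", "matrix")))
  target_counts(list(strio_bait = s, matrix_bait = m), baits, striatum,
                test_affine(dm, voxel))
}

# a bias_map built directly from a P array (total = 1 where defined)
toy_bias <- function(p, striatum = NULL, voxel = c(1, 1, 1)) {
  dm <- dim(p)
  scale <- 100L
  s <- array(0L, dm); m <- array(0L, dm)
  def <- !is.na(p)
  s[def] <- as.integer(round(scale * p[def]))
  m[def] <- as.integer(round(scale * (1 - p[def])))
  if (is.null(striatum)) striatum <- def
  s[!striatum] <- 0L; m[!striatum] <- 0L
  compute_bias(toy_counts(s, m, striatum, voxel))
}

# brute-force top-k selection oracle: repeated argmax with the package's
# tie-break (bias desc, total desc, index asc), no vectorised ordering
brute_force_top_k <- function(p, total, candidates, k) {
  chosen <- integer(0)
  pool <- candidates
  for (i in seq_len(k)) {
    best <- pool[1]
    for (v in pool[-1]) {
      if (p[v] > p[best] ||
          (p[v] == p[best] && total[v] > total[best]) ||
          (p[v] == p[best] && total[v] == total[best] && v < best)) best <- v
    }
    chosen <- c(chosen, best)
    pool <- setdiff(pool, best)
  }
  chosen
}
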