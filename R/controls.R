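# Negative controls: random location jitter of seed masks (same
# "neighborhood", different voxels) and bundle-core Dice overlap. These
# establish that compartment-like effects depend on precise voxel location
# rather than the surrounding striatal territory.

#' Jitter specification
#'
#' @param max_shift maximum per-axis shift in voxels (>= 0); shifts are drawn
#'   uniformly from the integers `-max_shift..max_shift`, independently per
#'   axis and per voxel.
#' @param stay_in_striatum require shifted voxels to remain in the striatum.
#' @param exclude_original forbid shifted voxels from landing in either
#'   original compartment mask (so no jittered voxel is reselected).
#' @param max_attempts rejection-resampling cap per voxel.
#' @param rng_seed integer seed.
#' @return object of class `jitter_spec`.
#' @export
jitter_spec <- function(max_shift = 3L, stay_in_striatum = TRUE,
                        exclude_original = TRUE, max_attempts = 1000L,
                        rng_seed = 1L) {
  stopifnot(max_shift >= 0, max_attempts >= 1)
  structure(list(max_shift = as.integer(max_shift),
                 stay_in_striatum = stay_in_striatum,
                 exclude_original = exclude_original,
                 max_attempts = as.integer(max_attempts),
                 rng_seed = as.integer(rng_seed)),
            class = "jitter_spec")
}

#' Randomly jitter the voxels of a seed mask
#'
#' Each voxel is shifted by an independent uniform integer offset per axis.
#' Constraints (configurable in the [jitter_spec()]): the shifted voxel must
#' stay inside the striatum, must not land in either original compartment
#' mask, and must not collide with an already-placed shifted voxel
#' (collisions are rejection-resampled in stable voxel order). Cardinality is
#' preserved exactly.
#'
#' @param mask logical seed mask to jitter.
#' @param striatum logical striatum mask.
#' @param originals a `compartment_masks` object (or list with
#'   `striosome_like` and `matrix_like`) defining the excluded voxels;
#'   required when `exclude_original` is TRUE.
#' @param spec a [jitter_spec()].
#' @return list with `mask` (shifted logical array), `mean_shift` (signed
#'   per-axis means, voxels), `mean_euclidean_shift` and `rms_shift`
#'   (per-voxel displacement, voxels), `n`.
#' @export
jitter_mask <- function(mask, striatum, originals = NULL, spec = jitter_spec()) {
  stopifnot(is.logical(mask), is.logical(striatum),
            identical(dim(mask), dim(striatum)), inherits(spec, "jitter_spec"))
  dm <- dim(mask)
  excluded <- array(FALSE, dm)
  if (spec$exclude_original) {
    if (is.null(originals))
      stop("exclude_original requires the original compartment masks")
    excluded <- originals$striosome_like | originals$matrix_like
  }
  vox <- which(mask)
  n <- length(vox)
  ijk <- arrayInd(vox, dm)
  taken <- array(0L, dm)        # 0 = free, else index of the occupying voxel
  out_idx <- integer(n)
  set.seed(spec$rng_seed)
  m <- spec$max_shift

  # all admissible target cells of voxel i (in grid, in striatum, not in the
  # original compartment masks)
  feasible_cells <- function(i) {
    if (m == 0) {
      p <- matrix(ijk[i, ], 1)
    } else {
      p <- as.matrix(expand.grid(ijk[i, 1] + (-m:m), ijk[i, 2] + (-m:m),
                                 ijk[i, 3] + (-m:m)))
    }
    ok <- p[, 1] >= 1 & p[, 1] <= dm[1] & p[, 2] >= 1 & p[, 2] <= dm[2] &
      p[, 3] >= 1 & p[, 3] <= dm[3]
    lin <- p[ok, 1] + dm[1] * (p[ok, 2] - 1L) + dm[1] * dm[2] * (p[ok, 3] - 1L)
    if (spec$stay_in_striatum) lin <- lin[striatum[lin]]
    lin[!excluded[lin]]
  }

  # augmenting-path repair: free one of `cells` by relocating its occupant to
  # another of its own feasible cells (depth-limited chain search)
  augment <- function(cells, depth) {
    for (cell in cells) {
      j <- taken[cell]
      alt <- feasible_cells(j)
      free_alt <- alt[taken[alt] == 0L]
      if (length(free_alt) > 0) {
        new_cell <- free_alt[sample.int(length(free_alt), 1)]
        taken[cell] <<- 0L
        taken[new_cell] <<- j
        out_idx[j] <<- new_cell
        return(cell)
      }
    }
    if (depth <= 1) return(0L)
    for (cell in cells) {
      j <- taken[cell]
      alt <- feasible_cells(j)
      freed <- augment(setdiff(alt, cells), depth - 1L)
      if (freed > 0L) {
        taken[cell] <<- 0L
        taken[freed] <<- j
        out_idx[j] <<- freed
        return(cell)
      }
    }
    0L
  }

  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(spec$max_attempts)) {
      d <- if (m == 0) c(0L, 0L, 0L) else
        as.integer(sample(seq(-m, m), 3, replace = TRUE))
      p <- ijk[i, ] + d
      if (any(p < 1) || any(p > dm)) next
      lin <- p[1] + dm[1] * (p[2] - 1L) + dm[1] * dm[2] * (p[3] - 1L)
      if (spec$stay_in_striatum && !striatum[lin]) next
      if (excluded[lin] || taken[lin] > 0L) next
      taken[lin] <- i
      out_idx[i] <- lin
      placed <- TRUE
      break
    }
    if (!placed) {
      # every feasible cell is occupied: relocate an earlier voxel that has
      # an alternative, then take its cell
      cells <- feasible_cells(i)
      freed <- if (length(cells) > 0) augment(cells, depth = 4L) else 0L
      if (freed > 0L) {
        taken[freed] <- i
        out_idx[i] <- freed
        placed <- TRUE
      }
    }
    if (!placed)
      stop("could not place jittered voxel ", i, " (source index ", vox[i],
           ") within ", spec$max_attempts, " attempts")
  }
  shifted <- array(FALSE, dm)
  shifted[out_idx] <- TRUE
  shifts <- arrayInd(out_idx, dm) - ijk
  dist <- sqrt(rowSums(shifts^2))
  list(mask = shifted,
       mean_shift = colMeans(shifts),
       mean_euclidean_shift = mean(dist),
       rms_shift = sqrt(mean(dist^2)),
       n = n)
}

#' Mean compartment bias within a mask
#'
#' Mean bias probability over the mask's voxels and the fraction exceeding
#' the classification cutoff. For matrix-like masks the bias toward matrix,
#' `1 - P`, is assessed.
#'
#' @param bias a `bias_map`.
#' @param mask logical array; must lie within the defined-bias support.
#' @param cutoff classification cutoff (default 0.55).
#' @param compartment which compartment the mask represents.
#' @return list with `mean_bias` and `biased_fraction`.
#' @export
mask_bias <- function(bias, mask, cutoff = 0.55,
                      compartment = c("striosome", "matrix")) {
  stopifnot(inherits(bias, "bias_map"), is.logical(mask))
  compartment <- match.arg(compartment)
  vox <- which(mask)
  if (length(vox) == 0) stop("empty mask")
  p <- bias$p[vox]
  if (anyNA(p)) stop("mask includes voxels with undefined bias")
  if (compartment == "matrix") p <- 1 - p
  list(mean_bias = mean(p), biased_fraction = mean(p > cutoff))
}

#' Core of a tract-density bundle
#'
#' Thresholds a streamline/tract density volume at its uppermost
#' `top_fraction` of nonzero voxels (count-based quantile): the core holds
#' `ceiling(top_fraction * n_nonzero)` highest-amplitude voxels, ties broken
#' by ascending voxel index.
#'
#' @param density non-negative 3-D array.
#' @param top_fraction fraction of nonzero voxels to keep (default 0.25).
#' @return object of class `bundle_core`: list with `core` (logical array),
#'   `threshold` (smallest included amplitude), `n_core`, `top_fraction`.
#' @export
bundle_core <- function(density, top_fraction = 0.25) {
  stopifnot(length(dim(density)) == 3, all(density >= 0),
            top_fraction > 0, top_fraction <= 1)
  nz <- which(density > 0)
  if (length(nz) == 0) stop("all-zero density: no bundle to threshold")
  k <- ceiling(top_fraction * length(nz))
  sel <- nz[order(-density[nz], nz)][seq_len(k)]
  core <- array(FALSE, dim(density))
  core[sel] <- TRUE
  structure(list(core = core, threshold = min(density[sel]), n_core = k,
                 top_fraction = top_fraction),
            class = "bundle_core")
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks give 0 by convention
#' (reported with a message).
#'
#' @param a,b logical arrays on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b))
  if (!identical(dim(a), dim(b))) stop("masks are on different grids")
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    message("dsc: both masks empty; returning 0 by convention")
    return(0)
  }
  2 * sum(a & b) / denom
}
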