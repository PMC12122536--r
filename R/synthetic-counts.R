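# Synthetic streamline-count volumes for competing bait regions.
#
# Emulates the per-bait seed-to-target count maps produced by probabilistic
# tractography in classification-targets mode: at a pure striosome voxel the
# expected count toward a striosome-favoring bait exceeds the count toward a
# matrix-favoring bait by a factor `bias_odds`, and partial-volume mixing is
# modelled by Gaussian blurring of the expected rates before count noise.

#' Count model for synthetic streamline maps
#'
#' @param base_rate expected streamline count per voxel toward a favored bait
#'   region (> 0).
#' @param bias_odds ratio (> 1 for informative counts, >= 1 accepted) of
#'   favored:disfavored expected counts at a pure-compartment voxel.
#' @param partial_volume_sigma mm of Gaussian mixing applied to expected rates
#'   before sampling (>= 0); models sub-voxel striosome branches sampled by a
#'   rigid voxel grid.
#' @param noise_family "poisson" or "negative-binomial".
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); ignored for Poisson.
#' @return object of class `count_model`.
#' @export
count_model <- function(base_rate = 50, bias_odds = 9,
                        partial_volume_sigma = 0.75,
                        noise_family = c("poisson", "negative-binomial"),
                        dispersion = 0.1) {
  noise_family <- match.arg(noise_family)
  stopifnot(base_rate > 0, bias_odds >= 1, partial_volume_sigma >= 0,
            dispersion >= 0)
  structure(list(base_rate = base_rate, bias_odds = bias_odds,
                 partial_volume_sigma = partial_volume_sigma,
                 noise_family = noise_family, dispersion = dispersion),
            class = "count_model")
}

#' Generate per-bait streamline-count maps with planted compartment bias
#'
#' For each bait region, the expected count at a voxel of its favored
#' compartment is `base_rate` and at the other compartment
#' `base_rate / bias_odds`. Expected rates are blurred with a Gaussian kernel
#' of `partial_volume_sigma` mm, re-masked to the striatum, and counts drawn
#' from the chosen noise family. Counts are zero outside the striatum.
#'
#' @param gt a [generate_striatum()] ground truth.
#' @param baits a [bait_region_set()].
#' @param model a [count_model()].
#' @param seed integer RNG seed.
#' @return object of class `target_counts`: list with `counts` (named list of
#'   integer arrays), `baits`, `striatum` (logical array), `affine`,
#'   `voxel_size`.
#' @export
generate_counts <- function(gt, baits, model, seed = 1L) {
  stopifnot(inherits(gt, "gt_striatum"), inherits(baits, "bait_region_set"),
            inherits(model, "count_model"))
  striatum <- striatum_mask(gt)
  strio <- gt$compartment == 1L
  matx <- gt$compartment == 2L
  sigma_vox <- model$partial_volume_sigma / gt$voxel_size
  set.seed(as.integer(seed))
  counts <- list()
  for (i in seq_len(nrow(baits))) {
    fav_strio <- baits$favored[i] == "striosome"
    lam <- array(0, dim(striatum))
    lam[if (fav_strio) strio else matx] <- model$base_rate
    lam[if (fav_strio) matx else strio] <- model$base_rate / model$bias_odds
    if (any(sigma_vox > 0)) lam <- gaussian_smooth(lam, sigma_vox)
    lam[!striatum] <- 0
    x <- if (model$noise_family == "poisson") {
      rpois(length(lam), lam)
    } else if (model$dispersion > 0) {
      rnbinom(length(lam), size = 1 / model$dispersion, mu = lam)
    } else {
      rpois(length(lam), lam)
    }
    counts[[baits$name[i]]] <- array(as.integer(x), dim(striatum))
  }
  structure(list(counts = counts, baits = baits, striatum = striatum,
                 affine = gt$affine, voxel_size = gt$voxel_size),
            class = "target_counts")
}

#' Assemble a `target_counts` object from user-supplied grids
#'
#' Validates that all count grids share shape, are non-negative, and are zero
#' outside the striatum mask.
#'
#' @param counts named list of 3-D count arrays (one per bait region).
#' @param baits a [bait_region_set()]; names must match `counts`.
#' @param striatum logical striatum mask on the same grid.
#' @param affine shared 4x4 voxel-to-world matrix.
#' @return object of class `target_counts`.
#' @export
target_counts <- function(counts, baits, striatum, affine) {
  stopifnot(inherits(baits, "bait_region_set"), is.logical(striatum))
  if (!setequal(names(counts), baits$name))
    stop("count map names must match bait region names")
  counts <- counts[baits$name]
  dm <- dim(striatum)
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (!identical(dim(x), dm))
      stop("count grid for ", nm, " does not match the striatum grid shape")
    if (any(x < 0)) stop("negative counts in ", nm)
    if (any(x[!striatum] != 0))
      stop("nonzero counts outside the striatum mask in ", nm)
  }
  vx <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(counts = counts, baits = baits, striatum = striatum,
                 affine = affine, voxel_size = vx),
            class = "target_counts")
}
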