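# Synthetic striatum with planted striosome/matrix ground truth.
#
# The generator plants an island-like striosome compartment (~15% of striatal
# volume, the histologic proportion) inside contiguous matrix, with island
# centres drawn from a spatial intensity that increases rostrally (+y),
# ventrally (-z) and medially (|x| small) — the location bias reported for
# striosome across species.

NUCLEUS_LEVELS <- c("background", "caudate-L", "caudate-R", "putamen-L", "putamen-R")
COMPARTMENT_LEVELS <- c("none", "striosome", "matrix")

#' Specification for a synthetic striatum
#'
#' @param grid_shape voxels per axis (x = left-right, y = posterior-anterior,
#'   z = inferior-superior).
#' @param voxel_size mm per axis; 1.25 mm isotropic matches diffusion-grid
#'   resolution, 2.0 mm a typical BOLD grid.
#' @param striosome_fraction target proportion of striatal volume labelled
#'   striosome, in (0, 1); 0.15 is the histologic prior.
#' @param gradient_strength unitless >= 0; strength of the
#'   rostro-ventro-medial enrichment of striosome volume (0 = no gradient).
#' @param island_radius maximum striosome island radius in voxels (> 0).
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `striatum_spec`.
#' @export
striatum_spec <- function(grid_shape = c(40L, 50L, 40L),
                          voxel_size = c(1.25, 1.25, 1.25),
                          striosome_fraction = 0.15,
                          gradient_strength = 5,
                          island_radius = 3L,
                          rng_seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            is.numeric(striosome_fraction), length(striosome_fraction) == 1,
            striosome_fraction > 0, striosome_fraction < 1,
            gradient_strength >= 0, island_radius > 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 striosome_fraction = striosome_fraction,
                 gradient_strength = gradient_strength,
                 island_radius = as.integer(island_radius),
                 rng_seed = as.integer(rng_seed)),
            class = "striatum_spec")
}

# Ellipsoid nucleus masks, one caudate and one putamen per hemisphere.
# Geometry is expressed as fractions of the world-space grid extent so the
# same recipe scales with grid size. Caudate sits medial/dorsal and elongated
# rostro-caudally; putamen lateral and slightly ventral.
nucleus_geometry <- function(dim, affine) {
  extent <- dim * sqrt(colSums(affine[1:3, 1:3]^2))
  params <- list(
    caudate = list(center = c(0.15, 0.08, 0.12), radii = c(0.10, 0.32, 0.16)),
    putamen = list(center = c(0.33, -0.03, -0.04), radii = c(0.11, 0.26, 0.17))
  )
  xyz <- voxel_coords(NULL, dim, affine)
  nuc <- array(0L, dim)
  for (side in c("L", "R")) {
    s <- if (side == "L") -1 else 1
    for (nm in c("caudate", "putamen")) {
      p <- params[[nm]]
      ctr <- p$center * extent * c(s, 1, 1)
      rad <- p$radii * extent
      inside <- ((xyz[, 1] - ctr[1]) / rad[1])^2 +
                ((xyz[, 2] - ctr[2]) / rad[2])^2 +
                ((xyz[, 3] - ctr[3]) / rad[3])^2 <= 1
      code <- match(paste0(nm, "-", side), NUCLEUS_LEVELS) - 1L
      nuc[inside & nuc == 0L] <- code
    }
  }
  nuc
}

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  off[rowSums(off^2) <= radius^2, , drop = FALSE]
}

#' Generate a labelled synthetic striatum
#'
#' Places two nuclei (caudate, putamen) per hemisphere as ellipsoids, then
#' plants striosome islands. Because disjoint small islands with a one-voxel
#' moat pack to at most about the striosome fraction itself, the
#' rostro-ventro-medial gradient is carried mainly by island size: island
#' centres are proposed with weight `exp(gradient_strength * q)` and each
#' island's radius is drawn as
#' `1 + Binomial(island_radius - 1, plogis(gradient_strength * (q - 0.5)))`,
#' where `q` is the within-nucleus rank (0-1) of the combined
#' rostral + ventral + medial location score — large islands where striosome
#' is histologically abundant, small ones caudo-dorso-laterally. Islands are
#' accumulated until the target striosome fraction is met (the last island is
#' trimmed, outermost voxels first, to land on the target count). Island
#' centres keep a Chebyshev separation of the two radii + 2 voxels, so
#' islands are never 26-adjacent: striosome voxels form multiple disjoint
#' islands and the matrix remains one dominant connected component per
#' nucleus. If packing exhausts the nucleus before the target is met,
#' placement continues with progressively smaller islands.
#'
#' @param spec a [striatum_spec()].
#' @return object of class `gt_striatum`: list with `nucleus` (integer array,
#'   codes index [NUCLEUS_LEVELS]-1), `compartment` (0 none / 1 striosome /
#'   2 matrix), `affine`, `voxel_size`, `spec`.
#' @export
generate_striatum <- function(spec) {
  stopifnot(inherits(spec, "striatum_spec"))
  dm <- spec$grid_shape
  affine <- centered_affine(dm, spec$voxel_size)
  nuc <- nucleus_geometry(dm, affine)
  counts <- tabulate(nuc[nuc > 0L], nbins = 4)
  min_nucleus <- nrow(ball_offsets(spec$island_radius)) * 2
  if (any(counts < min_nucleus))
    stop("grid too small to place both nuclei per hemisphere: each nucleus ",
         "needs at least ", min_nucleus, " voxels but sizes are ",
         paste(counts, collapse = ", "),
         " (grid ", paste(dm, collapse = "x"), ")")

  set.seed(spec$rng_seed)
  comp <- array(0L, dm)
  comp[nuc > 0L] <- 2L   # matrix by default
  xyz <- voxel_coords(NULL, dm, affine)

  for (code in 1:4) {
    vox <- which(nuc == code)
    if (length(vox) == 0) next
    target <- round(spec$striosome_fraction * length(vox))
    if (target == 0) next
    co <- xyz[vox, , drop = FALSE]
    rostral <- (co[, 2] - min(co[, 2])) / max(1e-9, diff(range(co[, 2])))
    ventral <- (max(co[, 3]) - co[, 3]) / max(1e-9, diff(range(co[, 3])))
    medial  <- (max(abs(co[, 1])) - abs(co[, 1])) /
               max(1e-9, diff(range(abs(co[, 1]))))
    # rank-normalised combined location score in (0, 1]
    q <- rank(rostral + ventral + medial, ties.method = "first") / length(vox)
    w <- exp(spec$gradient_strength * q)
    ijk <- arrayInd(vox, dm)
    in_nuc <- array(FALSE, dm); in_nuc[vox] <- TRUE
    placed <- matrix(numeric(0), 0, 3)
    placed_r <- numeric(0)
    n_strio <- 0L
    max_r <- spec$island_radius
    shrink <- 0L    # lowers the radius ceiling once packing saturates
    avail <- rep(TRUE, length(vox))
    while (n_strio < target) {
      if (!any(avail)) {
        # packing is exhausted at the current ceiling: continue with smaller
        # islands (never merge; Chebyshev separation keeps islands disjoint)
        if (max_r - shrink <= 1L) break
        shrink <- shrink + 1L
        avail <- rep(TRUE, length(vox))
      }
      ci <- sample.int(length(vox), 1, prob = w * avail)
      ctr <- ijk[ci, ]
      avail[ci] <- FALSE
      # island size carries the rostro-ventro-medial gradient: larger
      # striosome islands where the location score is high
      radius <- if (max_r > 1L)
        1L + rbinom(1, max_r - 1L, plogis(spec$gradient_strength * (q[ci] - 0.5)))
      else 1L
      radius <- min(radius, max_r - shrink)
      if (nrow(placed) > 0 &&
          any(apply(abs(t(placed) - ctr), 2, max) < placed_r + radius + 2))
        next
      offs <- ball_offsets(radius)
      pts <- sweep(offs, 2, ctr, "+")
      ok <- pts[, 1] >= 1 & pts[, 1] <= dm[1] &
            pts[, 2] >= 1 & pts[, 2] <= dm[2] &
            pts[, 3] >= 1 & pts[, 3] <= dm[3]
      pts <- pts[ok, , drop = FALSE]
      lin <- pts[, 1] + dm[1] * (pts[, 2] - 1L) + dm[1] * dm[2] * (pts[, 3] - 1L)
      lin <- lin[in_nuc[lin] & comp[lin] == 2L]
      if (length(lin) == 0) next
      placed <- rbind(placed, ctr)
      placed_r <- c(placed_r, radius)
      if (n_strio + length(lin) > target) {
        # trim outermost voxels of the final island to hit the target exactly
        d2 <- colSums((t(arrayInd(lin, dm)) - ctr)^2)
        lin <- lin[order(d2, lin)][seq_len(target - n_strio)]
      }
      comp[lin] <- 1L
      n_strio <- n_strio + length(lin)
    }
  }

  structure(list(nucleus = nuc, compartment = comp, affine = affine,
                 voxel_size = spec$voxel_size, spec = spec),
            class = "gt_striatum")
}

#' Striatum mask of a ground-truth striatum
#' @param gt a `gt_striatum`.
#' @return logical array.
#' @export
striatum_mask <- function(gt) {
  stopifnot(inherits(gt, "gt_striatum"))
  gt$nucleus > 0L
}

#' Realized striosome fraction
#' @param gt a `gt_striatum`.
#' @export
striosome_fraction <- function(gt) {
  sum(gt$compartment == 1L) / sum(gt$nucleus > 0L)
}

#' The default bait-region set
#'
#' Ten competing tractography targets: five with histologically established
#' striosome-favoring connectivity and five matrix-favoring, mirroring the
#' regions used for connectivity-based striatal parcellation.
#'
#' @param regions optional data.frame with columns `name`,
#'   `favored` ("striosome"/"matrix") to override the default.
#' @return object of class `bait_region_set` (data.frame).
#' @export
bait_region_set <- function(regions = NULL) {
  if (is.null(regions)) {
    regions <- data.frame(
      name = c("posterior_orbitofrontal", "anterior_insula",
               "basolateral_amygdala", "basal_operculum",
               "posterior_fusiform",
               "supplementary_motor", "primary_motor", "primary_sensory",
               "superior_parietal", "inferior_frontal_pars_opercularis"),
      favored = rep(c("striosome", "matrix"), each = 5),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(regions), all(c("name", "favored") %in% names(regions)))
  if (anyDuplicated(regions$name)) stop("bait region names must be unique")
  if (!all(regions$favored %in% c("striosome", "matrix")))
    stop("favored must be 'striosome' or 'matrix'")
  if (length(unique(regions$favored)) < 2)
    stop("both compartment classes need at least one bait region")
  structure(regions, class = c("bait_region_set", "data.frame"))
}
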