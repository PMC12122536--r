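# Summary metrics over significance masks and cluster tables: laterality
# percentages, significant volumes, compartment fold ratios, and Dice overlap
# between contrast maps.

#' Laterality of a significance mask
#'
#' Ipsilateral voxels are those whose world-x sign matches the seed
#' hemisphere (x < 0 for "L", x > 0 for "R"); exact midline voxels (x = 0)
#' are counted as ipsilateral and reported.
#'
#' @param sig_mask logical significance mask.
#' @param seed_hemisphere "L" or "R".
#' @param affine 4x4 voxel-to-world matrix.
#' @return one-row data.frame: `seed_hemisphere`, `n_sig`, `ipsilateral_pct`,
#'   `contralateral_pct` (NA when the mask is empty), `volume_mm3`,
#'   `n_midline`.
#' @export
laterality <- function(sig_mask, seed_hemisphere = c("L", "R"), affine) {
  seed_hemisphere <- match.arg(seed_hemisphere)
  stopifnot(is.logical(sig_mask))
  vox <- which(sig_mask)
  n <- length(vox)
  if (n == 0)
    return(data.frame(seed_hemisphere = seed_hemisphere, n_sig = 0L,
                      ipsilateral_pct = NA_real_, contralateral_pct = NA_real_,
                      volume_mm3 = 0, n_midline = 0L))
  x <- voxel_coords(vox, dim(sig_mask), affine)[, 1]
  ipsi_sign <- if (seed_hemisphere == "L") -1 else 1
  ipsi <- sign(x) == ipsi_sign | x == 0
  data.frame(seed_hemisphere = seed_hemisphere, n_sig = n,
             ipsilateral_pct = 100 * mean(ipsi),
             contralateral_pct = 100 * mean(!ipsi),
             volume_mm3 = n * voxel_volume(affine),
             n_midline = sum(x == 0))
}

#' Compartment fold ratio from significant-cluster volumes
#'
#' `sum(striosome volumes) / sum(matrix volumes)`, reported both raw and
#' rounded the way such ratios are conventionally presented: to the nearest
#' integer at >= 10, to one decimal below 10. A zero denominator is flagged
#' as infinite. The ratio is invariant to the volume unit (mm^3 or voxels)
#' as long as both sides use the same one.
#'
#' @param striosome_volumes,matrix_volumes non-negative volumes (any common
#'   unit); summed before the ratio.
#' @return list with `ratio` (raw), `rounded`, `infinite` (logical).
#' @export
fold_ratio <- function(striosome_volumes, matrix_volumes) {
  stopifnot(all(striosome_volumes >= 0), all(matrix_volumes >= 0))
  num <- sum(striosome_volumes)
  den <- sum(matrix_volumes)
  if (den == 0)
    return(list(ratio = Inf, rounded = Inf, infinite = TRUE))
  r <- num / den
  list(ratio = r, rounded = if (r >= 10) round(r) else round(r, 1),
       infinite = FALSE)
}

#' Dice overlap between two contrast significance masks
#'
#' Delegates to [dsc()]; optionally reports which atlas regions the overlap
#' touches.
#'
#' @param mask_a,mask_b logical masks on a common grid.
#' @param atlas optional named list of logical region masks.
#' @return list with `dsc` and, when an atlas is given, `overlap_regions`.
#' @export
contrast_dsc <- function(mask_a, mask_b, atlas = NULL) {
  d <- dsc(mask_a, mask_b)
  out <- list(dsc = d)
  if (!is.null(atlas)) {
    ov <- mask_a & mask_b
    out$overlap_regions <- names(atlas)[vapply(atlas, function(m)
      any(m & ov), logical(1))]
  }
  out
}

#' Laterality report over a contrast suite
#'
#' One row per contrast combining cluster-table volumes and laterality of the
#' significance mask.
#'
#' @param contrasts named list of `cluster_table` objects from
#'   [contrast_suite()]; names encode the seed (e.g. "L-STR>L-MAT").
#' @param affine 4x4 matrix of the analysis grid.
#' @return data.frame with one row per contrast.
#' @export
laterality_report <- function(contrasts, affine) {
  rows <- lapply(names(contrasts), function(nm) {
    hemi <- substr(nm, 1, 1)
    lat <- laterality(contrasts[[nm]]$sig_mask, hemi, affine)
    cbind(contrast = nm, seed = sub(">.*", "", nm), lat)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
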