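# Seed-based resting-state functional connectivity: mean seed time course,
# voxel-wise Pearson correlation with every non-striatal brain voxel, Fisher
# z transform (atanh), optional restriction to network ROI masks.

#' Mean seed time course
#'
#' Arithmetic mean of the BOLD signal over the seed voxels at each timepoint.
#'
#' @param bold a `bold_series`.
#' @param seed logical seed mask within the brain mask.
#' @return numeric vector of length t.
#' @export
seed_timecourse <- function(bold, seed) {
  stopifnot(inherits(bold, "bold_series"), is.logical(seed),
            identical(dim(seed), dim(bold$data)[1:3]))
  vox <- which(seed)
  if (length(vox) == 0) stop("empty seed mask")
  if (any(!bold$brain_mask[vox])) stop("seed extends outside the brain mask")
  tn <- dim(bold$data)[4]
  m <- matrix(bold$data, ncol = tn)
  colMeans(m[vox, , drop = FALSE])
}

#' Voxel-wise Fisher-z correlation map for a seed time course
#'
#' Pearson correlation between the seed time course and every brain voxel,
#' transformed to Fisher z (`atanh`). Voxels in `exclude` (the striatum for
#' compartment seeds), outside the brain mask, or with zero variance are
#' undefined (NA). |r| = 1 is clipped to `atanh(1 - 1e-7)` so maps stay
#' finite; clipped voxels are counted in the `n_clipped` attribute.
#'
#' @param bold a `bold_series`.
#' @param tc seed time course (length t).
#' @param exclude logical array of voxels to exclude (e.g. the striatum), or
#'   NULL.
#' @return 3-D array of z values (class `zmap` via attribute), with
#'   attributes `n_clipped` and `seed`.
#' @export
corr_map <- function(bold, tc, exclude = NULL) {
  stopifnot(inherits(bold, "bold_series"))
  dm <- dim(bold$data)[1:3]
  tn <- dim(bold$data)[4]
  if (length(tc) != tn) stop("time course length does not match the series")
  if (sd(tc) == 0) stop("zero-variance seed time course")
  if (is.null(exclude)) exclude <- array(FALSE, dm)
  stopifnot(identical(dim(exclude), dm))
  vox <- which(bold$brain_mask & !exclude)
  m <- matrix(bold$data, ncol = tn)[vox, , drop = FALSE]
  mc <- m - rowMeans(m)
  tcc <- tc - mean(tc)
  ss <- sqrt(rowSums(mc^2))
  r <- as.vector(mc %*% tcc) / (ss * sqrt(sum(tcc^2)))
  r[ss == 0] <- NA_real_
  lim <- 1 - 1e-7
  clipped <- sum(abs(r) > lim, na.rm = TRUE)
  z <- atanh(pmin(pmax(r, -lim), lim))
  out <- array(NA_real_, dm)
  out[vox] <- z
  attr(out, "n_clipped") <- clipped
  out
}

#' Per-subject compartment-seeded connectivity maps
#'
#' One Fisher-z map per seed (left/right striosome-like and matrix-like),
#' each excluding the whole striatum from the target voxels.
#'
#' @param bold a `bold_series`.
#' @param masks_L,masks_R `compartment_masks` for each hemisphere.
#' @param striatum logical striatum mask (excluded from all maps).
#' @return named list of 4 z-map arrays: `L-STR`, `L-MAT`, `R-STR`, `R-MAT`.
#' @export
subject_maps <- function(bold, masks_L, masks_R, striatum) {
  seeds <- list(`L-STR` = masks_L$striosome_like,
                `L-MAT` = masks_L$matrix_like,
                `R-STR` = masks_R$striosome_like,
                `R-MAT` = masks_R$matrix_like)
  lapply(seeds, function(s) {
    if (sum(s) == 0) stop("empty seed mask")
    corr_map(bold, seed_timecourse(bold, s), exclude = striatum)
  })
}

#' Restrict a z map to a set of ROI masks
#'
#' Each ROI is assessed independently: the map is masked to the ROI and
#' returned per ROI (no full-factorial analysis).
#'
#' @param zmap 3-D z array.
#' @param rois named list of logical ROI masks.
#' @return named list of masked z arrays.
#' @export
restrict_to_rois <- function(zmap, rois) {
  lapply(rois, function(m) {
    stopifnot(identical(dim(m), dim(zmap)))
    out <- array(NA_real_, dim(zmap))
    out[m] <- zmap[m]
    out
  })
}
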