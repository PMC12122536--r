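# Anatomic validation of parcellated compartments: clustering, intra-striatal
# location relative to the nucleus centroid, and 2-mm coronal-plane volume
# profiles. Striosome-like voxels should be scattered in small islands
# enriched rostro-ventro-medially; matrix-like voxels should form large
# contiguous clusters spread along the rostro-caudal extent.

#' Connected-cluster sizes of a mask
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26 (26 is the FSL cluster default).
#' @return object of class `cluster_report`: list with `sizes` (voxel counts,
#'   largest first) and `connectivity`. An empty mask gives an empty report.
#' @export
cluster_sizes <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  sizes <- sizes[sizes > 0L]
  structure(list(sizes = sort(sizes, decreasing = TRUE),
                 connectivity = connectivity),
            class = "cluster_report")
}

#' Offsets of mask voxels from their nucleus centroid
#'
#' For each nucleus, computes the mean signed world-mm offset (x, y, z) of the
#' mask's voxels from the centroid of the whole nucleus, and the
#' root-mean-square distance `sqrt(mean(dx^2 + dy^2 + dz^2))`.
#'
#' @param mask logical array of voxels to measure.
#' @param nuclei named list of logical nucleus masks.
#' @param affine 4x4 voxel-to-world matrix.
#' @return data.frame with one row per nucleus containing voxels:
#'   `nucleus`, `n`, `mean_dx`, `mean_dy`, `mean_dz`, `rms`.
#' @export
centroid_offsets <- function(mask, nuclei, affine) {
  stopifnot(is.logical(mask), is.list(nuclei), length(nuclei) > 0)
  dm <- dim(mask)
  covered <- Reduce(`|`, nuclei)
  if (any(mask & !covered))
    stop(sum(mask & !covered), " mask voxel(s) lie outside every nucleus")
  rows <- list()
  for (nm in names(nuclei)) {
    nuc <- nuclei[[nm]]
    ctr <- colMeans(voxel_coords(which(nuc), dm, affine))
    vox <- which(mask & nuc)
    if (length(vox) == 0) next
    d <- sweep(voxel_coords(vox, dm, affine), 2, ctr)
    rows[[nm]] <- data.frame(nucleus = nm, n = length(vox),
                             mean_dx = mean(d[, 1]), mean_dy = mean(d[, 2]),
                             mean_dz = mean(d[, 3]),
                             rms = sqrt(mean(rowSums(d^2))))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Coronal-plane volume profile with per-plane compartment tests
#'
#' Bins compartment-like voxels into coronal planes of `thickness` mm along
#' world y (half-open bins `[y0, y0 + thickness)` anchored at y = 0), per
#' nucleus, for every subject. Planes with striatal data for fewer than
#' `min_coverage` of the cohort are excluded. For each retained plane an
#' unequal-variance two-tailed t-test compares striosome-like vs matrix-like
#' volume across subjects, with Holm family-wise correction over planes.
#'
#' @param labels list of per-subject classified label arrays
#'   (from [classify_voxels()]: 1 striosome-like, 2 matrix-like).
#' @param nucleus logical nucleus mask, or a list of per-subject masks when
#'   striatal geometry varies by subject.
#' @param affine 4x4 voxel-to-world matrix.
#' @param thickness plane thickness in mm (> 0).
#' @param min_coverage minimum fraction of subjects with striatal data in a
#'   plane (default 0.5).
#' @return list with `table` (per retained plane: `plane_mm` at bin centre,
#'   mean volumes in voxels and mm^3, `n_subjects_with_data`, `t`, `p`,
#'   `p_holm`) and `excluded_planes_mm`.
#' @export
plane_profile <- function(labels, nucleus, affine, thickness = 2,
                          min_coverage = 0.5) {
  if (thickness <= 0) stop("thickness must be positive")
  stopifnot(is.list(labels), length(labels) >= 2)
  n_sub <- length(labels)
  per_subject_nucleus <- is.list(nucleus) && !is.array(nucleus)
  dm <- dim(labels[[1]])
  y <- voxel_coords(NULL, dm, affine)[, 2]
  bin <- floor(y / thickness)
  bins <- sort(unique(bin))
  vol <- voxel_volume(affine)
  svol <- mvol <- has <- matrix(0, n_sub, length(bins),
                                dimnames = list(NULL, bins))
  for (s in seq_len(n_sub)) {
    nuc <- if (per_subject_nucleus) nucleus[[s]] else nucleus
    lab <- labels[[s]]
    stopifnot(identical(dim(lab), dm), identical(dim(nuc), dm))
    in_nuc <- which(nuc)
    b <- factor(bin[in_nuc], levels = bins)
    has[s, ] <- tabulate(b, nbins = length(bins)) > 0
    svol[s, ] <- tabulate(b[lab[in_nuc] == 1L], nbins = length(bins))
    mvol[s, ] <- tabulate(b[lab[in_nuc] == 2L], nbins = length(bins))
  }
  coverage <- colMeans(has)
  keep <- coverage >= min_coverage & coverage > 0
  res <- lapply(which(keep), function(j) {
    sv <- svol[has[, j] > 0, j]; mv <- mvol[has[, j] > 0, j]
    tt <- if (sd(sv) == 0 && sd(mv) == 0) {
      # degenerate: zero variance in both groups
      if (mean(sv) == mean(mv)) list(statistic = 0, p.value = 1)
      else list(statistic = sign(mean(sv) - mean(mv)) * Inf, p.value = 0)
    } else t.test(sv, mv, var.equal = FALSE)
    data.frame(plane_mm = (bins[j] + 0.5) * thickness,
               striosome_voxels = mean(sv), matrix_voxels = mean(mv),
               striosome_mm3 = mean(sv) * vol, matrix_mm3 = mean(mv) * vol,
               n_subjects_with_data = sum(has[, j]),
               t = unname(tt$statistic), p = tt$p.value)
  })
  table <- do.call(rbind, res)
  if (!is.null(table)) table$p_holm <- p.adjust(table$p, "holm")
  list(table = table,
       excluded_planes_mm = (bins[!keep & coverage > 0] + 0.5) * thickness)
}
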