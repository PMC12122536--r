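# Connectivity-based striatal parcellation.
#
# The compartment-like bias of a striatal voxel is the probability-like ratio
# P = S / (S + M), where S is the summed streamline count reaching
# striosome-favoring bait regions and M the summed count reaching
# matrix-favoring regions. High-bias, equal-volume seed masks are built by
# taking the k most-biased voxels from each end of the distribution, with
# k = round(target_fraction x hemisphere striatal volume).

#' Compute the per-voxel compartment bias map
#'
#' @param counts a `target_counts` object (see [generate_counts()],
#'   [target_counts()]).
#' @return object of class `bias_map`: list with `p` (array of P in `[0, 1]`,
#'   NA where S + M = 0 or outside the striatum), `total` (S + M), `striatum`,
#'   `affine`, `voxel_size`.
#' @export
compute_bias <- function(counts) {
  stopifnot(inherits(counts, "target_counts"))
  b <- counts$baits
  if (!any(b$favored == "striosome") || !any(b$favored == "matrix"))
    stop("need at least one bait region per compartment class")
  S <- Reduce(`+`, counts$counts[b$name[b$favored == "striosome"]])
  M <- Reduce(`+`, counts$counts[b$name[b$favored == "matrix"]])
  tot <- S + M
  p <- array(NA_real_, dim(tot))
  ok <- counts$striatum & tot > 0
  p[ok] <- S[ok] / tot[ok]
  structure(list(p = p, total = tot, striatum = counts$striatum,
                 affine = counts$affine, voxel_size = counts$voxel_size),
            class = "bias_map")
}

#' Two-sided Gaussian tail mass beyond k standard deviations
#'
#' The fraction of a Gaussian distribution lying more than `k_sd` standard
#' deviations from the mean (both tails): `2 * (1 - pnorm(k_sd))`. At
#' `k_sd = 1.5` this is 0.1336, i.e. 13% to the nearest percent — the
#' equal-volume mask target used for the high-bias seed masks.
#'
#' @param k_sd number of standard deviations (>= 0).
#' @return fraction in `[0, 1]`.
#' @export
gaussian_tail_fraction <- function(k_sd) {
  if (!is.numeric(k_sd) || length(k_sd) != 1 || is.na(k_sd) || k_sd < 0)
    stop("k_sd must be a single non-negative number")
  2 * (1 - pnorm(k_sd))
}

# deterministic most-biased-first ordering: bias desc, total count desc,
# linear voxel index asc
order_by_bias <- function(p, total, idx) {
  idx[order(-p[idx], -total[idx], idx)]
}

#' Equal-volume high-bias compartment masks
#'
#' For one hemisphere, selects the `k` most striosome-biased voxels and the
#' `k` most matrix-biased voxels, `k = round(target_fraction * hemisphere
#' striatal volume)` (13% corresponds to the mass beyond 1.5 SD of a
#' Gaussian). Striosome-like voxels are selected first; matrix-like selection
#' excludes them, so the masks are disjoint and exactly equal in volume. Ties
#' are broken by (bias desc, total count desc, voxel index asc).
#'
#' @param bias a `bias_map`.
#' @param hemisphere "L" or "R".
#' @param target_fraction fraction of hemisphere striatal volume per mask.
#' @return object of class `compartment_masks`: list with `striosome_like`,
#'   `matrix_like` (logical arrays), `k`, `thresholds_used` (least-extreme P
#'   included in each mask), `hemisphere`, `target_fraction`, `affine`.
#' @export
equal_volume_masks <- function(bias, hemisphere = c("L", "R"),
                               target_fraction = 0.13) {
  stopifnot(inherits(bias, "bias_map"),
            target_fraction > 0, target_fraction <= 0.5)
  hemisphere <- match.arg(hemisphere)
  dm <- dim(bias$p)
  hemi <- hemisphere_mask(dm, bias$affine, hemisphere)
  striat_h <- which(bias$striatum & hemi)
  k <- round(target_fraction * length(striat_h))
  if (k < 1) stop("hemisphere striatum too small for target fraction")
  defined <- striat_h[!is.na(bias$p[striat_h])]
  if (length(defined) < 2 * k)
    stop("insufficient defined-bias voxels: need 2 x k = ", 2 * k,
         " but only ", length(defined), " available")
  strio_sel <- order_by_bias(bias$p, bias$total, defined)[seq_len(k)]
  rest <- setdiff(defined, strio_sel)
  matx_sel <- order_by_bias(1 - bias$p, bias$total, rest)[seq_len(k)]
  sl <- array(FALSE, dm); sl[strio_sel] <- TRUE
  ml <- array(FALSE, dm); ml[matx_sel] <- TRUE
  structure(list(striosome_like = sl, matrix_like = ml, k = k,
                 thresholds_used = c(striosome = min(bias$p[strio_sel]),
                                     matrix = min(1 - bias$p[matx_sel])),
                 hemisphere = hemisphere, target_fraction = target_fraction,
                 affine = bias$affine),
            class = "compartment_masks")
}

#' Threshold classification of striatal voxels
#'
#' Labels voxels striosome-like where `P > cutoff`, matrix-like where
#' `1 - P > cutoff`, indeterminate otherwise; voxels with undefined bias stay
#' unlabelled. `cutoff` must exceed 0.5 so the classes cannot overlap.
#'
#' @param bias a `bias_map`.
#' @param cutoff bias threshold in (0.5, 1].
#' @return integer array: 0 unlabelled/undefined, 1 striosome-like,
#'   2 matrix-like, 3 indeterminate.
#' @export
classify_voxels <- function(bias, cutoff = 0.55) {
  stopifnot(inherits(bias, "bias_map"))
  if (!is.numeric(cutoff) || cutoff <= 0.5 || cutoff > 1)
    stop("cutoff must lie in (0.5, 1]; at or below 0.5 the classes overlap")
  out <- array(0L, dim(bias$p))
  def <- !is.na(bias$p)
  out[def & bias$p > cutoff] <- 1L
  out[def & (1 - bias$p) > cutoff] <- 2L
  out[def & out == 0L] <- 3L
  out
}

#' Leave-one-out (N-1) parcellation
#'
#' Recomputes the bias map with one bait region removed from the competing
#' target set.
#'
#' @param counts a `target_counts` object.
#' @param leave_out name of the bait region to drop.
#' @return `bias_map` for the reduced bait set.
#' @export
n1_parcellate <- function(counts, leave_out) {
  stopifnot(inherits(counts, "target_counts"))
  b <- counts$baits
  if (!leave_out %in% b$name) stop("unknown bait region: ", leave_out)
  cls <- b$favored[b$name == leave_out]
  if (sum(b$favored == cls) < 2)
    stop("cannot remove the last ", cls, "-favoring bait region")
  keep <- b$name != leave_out
  reduced <- target_counts(counts$counts[b$name[keep]],
                           bait_region_set(as.data.frame(b[keep, ])),
                           counts$striatum, counts$affine)
  compute_bias(reduced)
}
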