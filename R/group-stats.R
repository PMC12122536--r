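# Group-level paired contrasts of compartment-seeded z maps.
#
# Per-subject difference maps d = z_striosome - z_matrix are fit voxel-wise
# against an intercept plus mean-centered age and +/-0.5-coded sex; the
# intercept t is the covariate-adjusted paired contrast. Cluster-level
# family-wise error is controlled by sign-flip permutation of the difference
# maps (exact under exchangeability of d's sign), using cluster extent as the
# cluster statistic.

#' Paired design from per-subject difference maps
#'
#' @param d_maps list of per-subject 3-D difference arrays
#'   (z_striosome - z_matrix); NA voxels are dropped from the common mask.
#' @param age numeric vector (years); mean-centered internally.
#' @param sex character/factor with two levels; coded -0.5 / +0.5 (first
#'   sorted level negative), so the intercept stays the covariate-adjusted
#'   mean difference.
#' @return object of class `paired_design`: list with `D` (n x V matrix),
#'   `X` (design), `mask` (logical array of analysed voxels), `dim`, `df`.
#' @export
paired_design <- function(d_maps, age, sex) {
  n <- length(d_maps)
  stopifnot(n >= 2, length(age) == n, length(sex) == n)
  dm <- dim(d_maps[[1]])
  ok <- !is.na(d_maps[[1]])
  for (m in d_maps) {
    stopifnot(identical(dim(m), dm))
    ok <- ok & !is.na(m)
  }
  vox <- which(ok)
  D <- t(vapply(d_maps, function(m) m[vox], numeric(length(vox))))
  sex <- as.factor(sex)
  if (nlevels(droplevels(sex)) > 2) stop("sex must have at most two levels")
  sex_num <- ifelse(sex == sort(levels(droplevels(sex)))[1], -0.5, 0.5)
  if (length(unique(sex_num)) == 1) sex_num <- NULL  # constant covariate dropped
  X <- cbind(intercept = 1, age = age - mean(age), sex = sex_num)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  if (n <= ncol(X)) stop("need more subjects than regressors")
  mask <- array(FALSE, dm); mask[vox] <- TRUE
  structure(list(D = D, X = X, mask = mask, dim = dm, df = n - ncol(X)),
            class = "paired_design")
}

# intercept t statistics for all voxels at once; sign_flip multiplies subject
# rows by +/-1 (the covariates are refit against the flipped data)
intercept_t <- function(D, X, flips = NULL, t_cap = 1e6) {
  if (!is.null(flips)) D <- D * flips
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, D)
  resid <- D - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(XtXinv[1, 1] * sigma2)
  t <- beta[1, ] / se
  t[se == 0] <- sign(beta[1, se == 0]) * t_cap
  t[se == 0 & beta[1, se == 0] == 0] <- 0
  t
}

#' Voxel-wise paired t map
#'
#' Fits `d ~ intercept + age + sex` at each voxel and returns the intercept's
#' t statistic. Degenerate voxels (zero residual variance) are capped at
#' +/- 1e6 and counted.
#'
#' @param design a [paired_design()].
#' @return list with `t` (3-D array, NA outside the mask), `df`, `n_capped`.
#' @export
voxelwise_t <- function(design) {
  stopifnot(inherits(design, "paired_design"))
  t <- intercept_t(design$D, design$X)
  out <- array(NA_real_, design$dim)
  out[design$mask] <- t
  list(t = out, df = design$df, n_capped = sum(abs(t) >= 1e6))
}

#' Candidate clusters above a cluster-forming threshold
#'
#' Thresholds the positive tail of the t map at the one-sided p < `p_unc`
#' critical value and groups supra-threshold voxels into connected components.
#'
#' @param tmap 3-D t array (NA outside the analysis mask).
#' @param df degrees of freedom of the t map.
#' @param p_unc uncorrected one-sided cluster-forming p (default 0.001).
#' @param connectivity 6, 18 or 26.
#' @return list with `labels` (integer array, largest cluster = 1), `sizes`
#'   (voxel counts, largest first), `t_crit`.
#' @export
form_clusters <- function(tmap, df, p_unc = 0.001, connectivity = 26) {
  stopifnot(df >= 1, p_unc > 0, p_unc < 1)
  t_crit <- qt(1 - p_unc, df)
  supra <- !is.na(tmap) & tmap > t_crit
  labels <- label_components(supra, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  sizes <- sort(sizes[sizes > 0L], decreasing = TRUE)
  list(labels = labels, sizes = sizes, t_crit = t_crit)
}

# max cluster extent of the positive tail of a t vector on the design mask
max_cluster_size <- function(tvec, mask, dm, t_crit, connectivity) {
  supra <- array(FALSE, dm)
  supra[mask][tvec > t_crit] <- TRUE
  if (!any(supra)) return(0L)
  lab <- label_components(supra, connectivity)
  max(tabulate(lab[lab > 0L]))
}

#' Cluster-level FWE by sign-flip permutation
#'
#' Builds the null distribution of the maximum cluster extent from random
#' sign flips of the subject difference maps (covariates refit per
#' permutation) and assigns each observed cluster
#' `p_FWE = (1 + #{perm max >= size}) / (1 + n_perm)`. Clusters with
#' `p_FWE < alpha` are significant.
#'
#' @param design a [paired_design()].
#' @param p_unc cluster-forming one-sided p (default 0.001).
#' @param connectivity cluster connectivity (default 26).
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param alpha cluster-level FWE threshold (default 0.05).
#' @param seed integer RNG seed.
#' @return object of class `cluster_table`: list with `table` (data.frame:
#'   cluster, size_voxels, volume_mm3 if affine given, peak_t, peak_x/y/z,
#'   p_fwe, significant), `sig_mask` (logical array), `null_max_sizes`,
#'   `t_crit`, `n_perm`, `seed`.
#' @param affine optional 4x4 matrix for mm^3 volumes and peak coordinates.
#' @export
permute_fwe <- function(design, p_unc = 0.001, connectivity = 26,
                        n_perm = 1000, alpha = 0.05, seed = 1L,
                        affine = NULL) {
  stopifnot(inherits(design, "paired_design"))
  if (n_perm < 100) stop("n_perm must be at least 100 for FWE resolution")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (1 / (1 + n_perm) > alpha)
    stop("n_perm too small to resolve alpha = ", alpha)
  n <- nrow(design$D)
  tobs <- intercept_t(design$D, design$X)
  t_crit <- qt(1 - p_unc, design$df)
  tmap <- array(NA_real_, design$dim)
  tmap[design$mask] <- tobs
  cl <- form_clusters(tmap, design$df, p_unc, connectivity)
  obs_sizes <- if (max(cl$labels) > 0) tabulate(cl$labels[cl$labels > 0]) else integer(0)

  set.seed(as.integer(seed))
  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    tb <- intercept_t(design$D, design$X, flips = flips)
    null_max[b] <- max_cluster_size(tb, design$mask, design$dim, t_crit,
                                    connectivity)
  }

  vol <- if (is.null(affine)) NA_real_ else voxel_volume(affine)
  rows <- lapply(seq_along(obs_sizes), function(k) {
    vox <- which(cl$labels == k)
    pk <- vox[which.max(tmap[vox])]
    xyz <- if (is.null(affine)) c(NA_real_, NA_real_, NA_real_) else
      voxel_coords(pk, design$dim, affine)[1, ]
    p_fwe <- (1 + sum(null_max >= obs_sizes[k])) / (1 + n_perm)
    data.frame(cluster = k, size_voxels = obs_sizes[k],
               volume_mm3 = obs_sizes[k] * vol, peak_t = max(tmap[vox]),
               peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3],
               p_fwe = p_fwe, significant = p_fwe < alpha)
  })
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size_voxels = integer(0),
               volume_mm3 = numeric(0), peak_t = numeric(0),
               peak_x = numeric(0), peak_y = numeric(0), peak_z = numeric(0),
               p_fwe = numeric(0), significant = logical(0))
  sig <- array(FALSE, design$dim)
  if (any(table$significant))
    sig[cl$labels %in% table$cluster[table$significant]] <- TRUE
  structure(list(table = table, sig_mask = sig, null_max_sizes = null_max,
                 t_crit = t_crit, n_perm = n_perm, seed = seed,
                 alpha = alpha),
            class = "cluster_table")
}

#' Four-contrast suite over a cohort of compartment-seeded z maps
#'
#' For each hemisphere's seed pair, forms per-subject difference maps
#' `z_STR - z_MAT` and tests both one-sided contrasts (STR > MAT on `d`,
#' MAT > STR on `-d`) with sign-flip cluster-level FWE.
#'
#' @param zmaps list (one element per subject) of named lists with z maps
#'   `L-STR`, `L-MAT`, `R-STR`, `R-MAT` (see [subject_maps()]).
#' @param covariates data.frame with columns `age`, `sex` (one row per
#'   subject).
#' @param affine 4x4 matrix of the analysis grid.
#' @param ... further arguments passed to [permute_fwe()] (`p_unc`,
#'   `connectivity`, `n_perm`, `alpha`, `seed`).
#' @return named list of `cluster_table` objects: `L-STR>L-MAT`,
#'   `L-MAT>L-STR`, `R-STR>R-MAT`, `R-MAT>R-STR`.
#' @export
contrast_suite <- function(zmaps, covariates, affine = NULL, ...) {
  stopifnot(is.list(zmaps), length(zmaps) >= 2,
            all(c("age", "sex") %in% names(covariates)),
            nrow(covariates) == length(zmaps))
  need <- c("L-STR", "L-MAT", "R-STR", "R-MAT")
  for (s in zmaps)
    if (!all(need %in% names(s))) stop("each subject needs the four seed maps")
  out <- list()
  for (side in c("L", "R")) {
    d <- lapply(zmaps, function(s)
      s[[paste0(side, "-STR")]] - s[[paste0(side, "-MAT")]])
    des_pos <- paired_design(d, covariates$age, covariates$sex)
    des_neg <- des_pos
    des_neg$D <- -des_pos$D
    out[[paste0(side, "-STR>", side, "-MAT")]] <-
      permute_fwe(des_pos, affine = affine, ...)
    out[[paste0(side, "-MAT>", side, "-STR")]] <-
      permute_fwe(des_neg, affine = affine, ...)
  }
  out
}
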