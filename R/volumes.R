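#' @importFrom stats pnorm qt rnorm rpois rnbinom runif p.adjust t.test lm anova cor sd setNames
#' @importFrom utils read.delim write.table
NULL

#' Build a voxel-to-world affine for a centred grid
#'
#' Returns a 4x4 RAS affine whose rotation part is `diag(voxel_size)` and whose
#' translation centres the grid on the world origin, so that the mid-sagittal
#' plane (world x = 0) splits the grid into left (x < 0) and right (x > 0)
#' hemispheres. Voxel indices are 0-based in the affine convention:
#' `world = A %*% c(i, j, k, 1)` with `i, j, k` starting at 0.
#'
#' @param grid_shape integer vector of length 3, voxels per axis.
#' @param voxel_size numeric vector of length 3, mm per voxel.
#' @return 4x4 numeric matrix.
#' @export
centered_affine <- function(grid_shape, voxel_size) {
  stopifnot(length(grid_shape) == 3, length(voxel_size) == 3,
            all(grid_shape >= 1), all(voxel_size > 0))
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  a
}

#' World-mm coordinates of voxels
#'
#' @param idx integer vector of linear (1-based) array indices, or NULL for all
#'   voxels.
#' @param dim grid shape (length 3).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel convention).
#' @return matrix with columns x, y, z in world mm.
#' @export
voxel_coords <- function(idx = NULL, dim, affine) {
  if (is.null(idx)) idx <- seq_len(prod(dim))
  ijk <- arrayInd(idx, dim) - 1L
  xyz <- cbind(ijk, 1) %*% t(affine[1:3, , drop = FALSE])
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Volume of one voxel in mm^3
#' @param affine 4x4 voxel-to-world matrix.
#' @export
voxel_volume <- function(affine) abs(det(affine[1:3, 1:3]))

#' Hemisphere membership of voxels
#'
#' Voxels with world x < 0 are "L", x > 0 are "R"; exact midline voxels
#' (x == 0) are assigned to neither here (callers counting laterality treat
#' midline as ipsilateral; see [laterality()]).
#'
#' @param dim grid shape.
#' @param affine voxel-to-world matrix.
#' @param side "L" or "R".
#' @return logical array of shape `dim`.
#' @export
hemisphere_mask <- function(dim, affine, side = c("L", "R")) {
  side <- match.arg(side)
  x <- voxel_coords(NULL, dim, affine)[, 1]
  m <- if (side == "L") x < 0 else x > 0
  array(m, dim = dim)
}

neighbour_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6"  = rowSums(abs(off)) == 1,
                 "18" = rowSums(abs(off)) <= 2,
                 "26" = rep(TRUE, nrow(off)))
  off <- off[keep, , drop = FALSE]
  # half-neighbourhood: keep offsets whose first nonzero component is positive
  first_sign <- apply(off, 1, function(o) o[which(o != 0)[1]])
  off[first_sign > 0, , drop = FALSE]
}

#' Label connected components of a 3-D mask
#'
#' Components are computed under 6-, 18- or 26-connectivity (26 = faces,
#' edges and corners, the FSL cluster default) and relabelled in decreasing
#' size order, so label 1 is always the largest component.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array; 0 outside the mask, component label inside.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  dm <- dim(mask)
  idx <- which(mask)
  out <- array(0L, dm)
  if (length(idx) == 0) return(out)
  id <- array(0L, dm)
  id[idx] <- seq_along(idx)
  offs <- neighbour_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    xr <- max(1, 1 - o[1]):min(dm[1], dm[1] - o[1])
    yr <- max(1, 1 - o[2]):min(dm[2], dm[2] - o[2])
    zr <- max(1, 1 - o[3]):min(dm[3], dm[3] - o[3])
    a <- id[xr, yr, zr]
    b <- id[xr + o[1], yr + o[2], zr + o[3]]
    keep <- a > 0L & b > 0L
    edges[[r]] <- cbind(a[keep], b[keep])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # relabel by decreasing size, ties by smallest member index (deterministic)
  ord <- order(-comp$csize, vapply(seq_len(comp$no),
                                   function(k) min(which(comp$membership == k)),
                                   integer(1)))
  relab <- integer(comp$no)
  relab[ord] <- seq_len(comp$no)
  out[idx] <- relab[comp$membership]
  out
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' Convolves with a truncated (radius 3 sigma), renormalised Gaussian kernel
#' along each axis in turn. `sigma` is given per axis in voxel units; zero
#' sigma on an axis leaves that axis untouched.
#'
#' @param arr numeric 3-D array.
#' @param sigma numeric length 1 or 3, standard deviation in voxels.
#' @return smoothed array, same shape.
#' @export
gaussian_smooth <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3)
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  stopifnot(all(sigma >= 0))
  dm <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s == 0) next
    n <- dm[ax]
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    K <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[d + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = n)
    m <- K %*% m
    arr <- aperm(array(m, dm[perm]), order(perm))
  }
  arr
}

#' Read a NIfTI volume as a plain array with affine metadata
#'
#' @param path file path (.nii or .nii.gz).
#' @param ndim required dimensionality (3 or 4), or NULL for any.
#' @return list with `data` (array), `affine` (4x4), `tr` (seconds, 4-D only).
#' @export
read_volume <- function(path, ndim = NULL) {
  if (!file.exists(path)) stop("volume not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!is.null(ndim) && length(d) != ndim)
    stop("expected a ", ndim, "-D volume but ", path, " has ", length(d),
         " dimensions")
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  out <- list(data = array(as.vector(img), dim = d), affine = aff)
  if (length(d) == 4) out$tr <- RNifti::pixdim(img)[4]
  out
}

#' Write an array as NIfTI-1, preserving affine (and TR for 4-D series)
#'
#' @param data 3-D or 4-D numeric/integer/logical array.
#' @param path output path (.nii or .nii.gz).
#' @param affine 4x4 voxel-to-world matrix.
#' @param tr repetition time in seconds for 4-D data.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, affine, tr = NULL) {
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  if (length(dim(data)) == 4) {
    if (is.null(tr)) stop("4-D volumes require a TR")
    vx <- sqrt(colSums(affine[1:3, 1:3]^2))
    img <- RNifti::`pixdim<-`(img, c(vx, tr))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a TSV table
#' @param path file path.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @param x data.frame to write.
#' @rdname read_table_tsv
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
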