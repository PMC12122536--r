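# Synthetic BOLD series with compartment-coupled network latents.
#
# Two latent time courses, one per hemisphere, drive the planted functional
# architecture: network-node voxels follow their hemisphere's latent;
# striosome voxels couple to the ipsilateral latent and matrix voxels to the
# contralateral latent, reproducing the ipsi/contra dissociation the analysis
# is designed to detect. All remaining voxels are independent noise.

#' Specification for synthetic BOLD generation
#'
#' @param n_timepoints number of volumes (>= 2); 2400 matches two concatenated
#'   1,200-timepoint resting-state runs.
#' @param tr_seconds repetition time (default 0.72 s).
#' @param network_nodes named list of nodes, each
#'   `list(mask = <logical array>, hemisphere = "L"/"R", network = <name>)`,
#'   or NULL to place default nodes with [default_network_nodes()].
#' @param coupling named numeric vector with entries `striosome_ipsi`,
#'   `striosome_contra`, `matrix_ipsi`, `matrix_contra`, each in `[0, 1)`:
#'   correlation amplitude between a compartment voxel and the latent of the
#'   same/opposite hemisphere. For each compartment the squared amplitudes
#'   must sum to < 1 (positive-definite voxel variance).
#' @param noise_sd amplitude of the idiosyncratic voxel noise (> 0); scales
#'   signal amplitude only, not planted correlations.
#' @param node_noise residual noise amplitude on node voxels in `[0, 1)`;
#'   keeps node series from being exactly the latent.
#' @param rng_seed integer seed.
#' @return object of class `bold_spec`.
#' @export
bold_spec <- function(n_timepoints = 2400L, tr_seconds = 0.72,
                      network_nodes = NULL,
                      coupling = c(striosome_ipsi = 0.6, striosome_contra = 0,
                                   matrix_ipsi = 0, matrix_contra = 0.6),
                      noise_sd = 1, node_noise = 0.3, rng_seed = 1L) {
  stopifnot(n_timepoints >= 2, tr_seconds > 0, noise_sd > 0,
            node_noise >= 0, node_noise < 1)
  need <- c("striosome_ipsi", "striosome_contra", "matrix_ipsi", "matrix_contra")
  if (!all(need %in% names(coupling)))
    stop("coupling must name: ", paste(need, collapse = ", "))
  coupling <- coupling[need]
  if (any(coupling < 0) || any(coupling >= 1))
    stop("coupling amplitudes must lie in [0, 1)")
  if (coupling["striosome_ipsi"]^2 + coupling["striosome_contra"]^2 >= 1 ||
      coupling["matrix_ipsi"]^2 + coupling["matrix_contra"]^2 >= 1)
    stop("invalid covariance: squared coupling amplitudes must sum to < 1 ",
         "per compartment")
  structure(list(n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, network_nodes = network_nodes,
                 coupling = coupling, noise_sd = noise_sd,
                 node_noise = node_noise, rng_seed = as.integer(rng_seed)),
            class = "bold_spec")
}

#' Place default triple-network node masks outside the striatum
#'
#' Places one cubic node per network per hemisphere (DMN, SN, FPN by default)
#' in the dorsal "cortical" margin of the grid, verified disjoint from the
#' striatum.
#'
#' @param gt a `gt_striatum`.
#' @param networks character vector of network names.
#' @param node_half_width half-width of the cubic node in voxels.
#' @return named list of nodes (`mask`, `hemisphere`, `network`).
#' @export
default_network_nodes <- function(gt, networks = c("DMN", "SN", "FPN"),
                                  node_half_width = 1L) {
  dm <- dim(gt$nucleus)
  h <- node_half_width
  if (dm[3] < 2 * h + 2 || dm[1] < 4 * h + 4 || dm[2] < length(networks) * (2 * h + 2))
    stop("grid too small to place network nodes")
  z0 <- dm[3] - h  # dorsal margin
  ys <- round(seq(1 + h, dm[2] - h, length.out = length(networks) + 2))[
    seq_along(networks) + 1]
  nodes <- list()
  for (side in c("L", "R")) {
    xc <- if (side == "L") 1 + h else dm[1] - h
    for (i in seq_along(networks)) {
      m <- array(FALSE, dm)
      m[max(1, xc - h):min(dm[1], xc + h),
        max(1, ys[i] - h):min(dm[2], ys[i] + h),
        max(1, z0 - h):min(dm[3], z0 + h)] <- TRUE
      if (any(m & gt$nucleus > 0L))
        stop("default node placement intersects the striatum")
      nodes[[paste0(networks[i], "-", side)]] <-
        list(mask = m, hemisphere = side, network = networks[i])
    }
  }
  nodes
}

#' Generate compartment-coupled synthetic BOLD
#'
#' Striosome voxels in hemisphere h are `c_si * U_h + c_sc * U_h' + e`,
#' matrix voxels `c_mi * U_h + c_mc * U_h' + e`, where `U_L`, `U_R` are
#' independent standard-normal latents, `c` are the coupling amplitudes and
#' `e` is scaled so each voxel's planted correlation with the latent equals
#' its coupling amplitude. Node voxels follow their hemisphere's latent with
#' residual amplitude `node_noise`. All series are demeaned.
#'
#' @param gt a `gt_striatum`.
#' @param spec a [bold_spec()].
#' @return object of class `bold_series`: list with `data`
#'   (4-D array x,y,z,t), `tr`, `affine`, `brain_mask`, `nodes`, `latents`
#'   (t x 2 matrix, columns L and R).
#' @export
generate_bold <- function(gt, spec) {
  stopifnot(inherits(gt, "gt_striatum"), inherits(spec, "bold_spec"))
  dm <- dim(gt$nucleus)
  nodes <- spec$network_nodes
  if (is.null(nodes)) nodes <- default_network_nodes(gt)
  striatum <- striatum_mask(gt)
  for (nm in names(nodes)) {
    stopifnot(identical(dim(nodes[[nm]]$mask), dm))
    if (any(nodes[[nm]]$mask & striatum))
      stop("node mask ", nm, " overlaps the striatum")
  }
  set.seed(spec$rng_seed)
  tn <- spec$n_timepoints
  V <- prod(dm)
  U <- matrix(rnorm(2 * tn), tn, 2, dimnames = list(NULL, c("L", "R")))
  U <- scale(U, center = TRUE, scale = FALSE)

  # start from pure noise everywhere, then overwrite structured voxels
  dat <- matrix(rnorm(V * tn, sd = spec$noise_sd), nrow = tn, ncol = V)

  hemiL <- hemisphere_mask(dm, gt$affine, "L")
  cp <- spec$coupling
  mix <- function(ipsi, contra, vox_idx, is_left) {
    if (length(vox_idx) == 0) return()
    uh <- if (is_left) U[, "L"] else U[, "R"]
    uo <- if (is_left) U[, "R"] else U[, "L"]
    res <- sqrt(max(0, 1 - ipsi^2 - contra^2))
    sig <- ipsi * uh / sd(uh) + contra * uo / sd(uo)
    dat[, vox_idx] <<- spec$noise_sd *
      (matrix(sig, tn, length(vox_idx)) + res * dat[, vox_idx] / spec$noise_sd)
  }
  strio <- gt$compartment == 1L
  matx <- gt$compartment == 2L
  hemiR <- hemisphere_mask(dm, gt$affine, "R")
  for (is_left in c(TRUE, FALSE)) {
    hm <- if (is_left) hemiL else hemiR
    mix(cp["striosome_ipsi"], cp["striosome_contra"], which(strio & hm), is_left)
    mix(cp["matrix_ipsi"], cp["matrix_contra"], which(matx & hm), is_left)
  }
  eta <- spec$node_noise
  for (nm in names(nodes)) {
    vox <- which(nodes[[nm]]$mask)
    uh <- U[, nodes[[nm]]$hemisphere]
    dat[, vox] <- spec$noise_sd *
      (matrix(sqrt(1 - eta^2) * uh / sd(uh), tn, length(vox)) +
         eta * dat[, vox] / spec$noise_sd)
  }
  dat <- dat - matrix(colMeans(dat), tn, V, byrow = TRUE)
  structure(list(data = array(t(dat), dim = c(dm, tn)), tr = spec$tr_seconds,
                 affine = gt$affine, brain_mask = array(TRUE, dm),
                 nodes = nodes, latents = U),
            class = "bold_series")
}

#' Assemble a `bold_series` from a 4-D array
#'
#' @param data 4-D array (x, y, z, t).
#' @param affine 4x4 voxel-to-world matrix.
#' @param tr repetition time in seconds.
#' @param brain_mask optional logical 3-D array (default: all voxels).
#' @return object of class `bold_series`.
#' @export
bold_series <- function(data, affine, tr, brain_mask = NULL) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] >= 3, tr > 0)
  dm <- dim(data)[1:3]
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dm)
  stopifnot(identical(dim(brain_mask), dm))
  structure(list(data = data, tr = tr, affine = affine,
                 brain_mask = brain_mask, nodes = NULL, latents = NULL),
            class = "bold_series")
}
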