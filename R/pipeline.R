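# Pipeline configuration and the end-to-end driver chaining all stages on a
# synthetic (or pre-simulated) cohort.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default: the 13% equal-volume
#' target (Gaussian mass beyond 1.5 SD), the 0.55 classification and 0.87
#' high-segregation bias cutoffs, +/-3-voxel jitter, 25% bundle-core
#' fraction, 0.001 cluster-forming p, 0.05 cluster FWE alpha, permutation
#' count, and cluster connectivity. Validated on construction and
#' round-trippable through JSON.
#'
#' @param target_fraction equal-volume mask fraction per hemisphere.
#' @param bias_cutoff classification cutoff (P > cutoff).
#' @param high_bias_cutoff cutoff for the cluster-segregation metric.
#' @param jitter_max_shift maximum jitter in voxels per axis.
#' @param bundle_top_fraction bundle-core amplitude fraction.
#' @param p_unc cluster-forming one-sided p.
#' @param alpha cluster-level FWE threshold.
#' @param n_perm sign-flip permutations.
#' @param connectivity cluster connectivity (6, 18, 26).
#' @param seed master RNG seed (integer, required for pipeline runs).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_fraction = 0.13, bias_cutoff = 0.55,
                            high_bias_cutoff = 0.87, jitter_max_shift = 3L,
                            bundle_top_fraction = 0.25, p_unc = 0.001,
                            alpha = 0.05, n_perm = 1000L, connectivity = 26L,
                            seed = NULL) {
  if (is.null(seed)) stop("pipeline runs require an explicit integer seed")
  if (target_fraction <= 0 || target_fraction > 0.5)
    stop("target_fraction must lie in (0, 0.5]")
  if (bias_cutoff <= 0.5 || bias_cutoff > 1)
    stop("bias_cutoff must lie in (0.5, 1]")
  if (high_bias_cutoff <= 0.5 || high_bias_cutoff > 1)
    stop("high_bias_cutoff must lie in (0.5, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (p_unc <= 0 || p_unc >= 1) stop("p_unc must lie in (0, 1)")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (jitter_max_shift < 0) stop("jitter_max_shift must be >= 0")
  if (bundle_top_fraction <= 0 || bundle_top_fraction > 1)
    stop("bundle_top_fraction must lie in (0, 1]")
  if (n_perm < 100) stop("n_perm must be at least 100")
  structure(list(target_fraction = target_fraction,
                 bias_cutoff = bias_cutoff,
                 high_bias_cutoff = high_bias_cutoff,
                 jitter_max_shift = as.integer(jitter_max_shift),
                 bundle_top_fraction = bundle_top_fraction,
                 p_unc = p_unc, alpha = alpha, n_perm = as.integer(n_perm),
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulate -> parcellate (per subject and hemisphere) -> anatomy metrics ->
#' jitter control -> rsFC -> group contrasts -> N-1 somatotopy -> report.
#' Outputs are written under `out_dir` as TSV/JSON; all randomness flows from
#' `config$seed`, so re-running with the same configuration reproduces the
#' outputs bit-identically.
#'
#' @param out_dir results directory (created).
#' @param n_subjects cohort size.
#' @param config a [pipeline_config()].
#' @param striatum,baits,counts,bold generator specifications.
#' @return list of in-memory stage results, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(out_dir, n_subjects, config,
                         striatum = striatum_spec(),
                         baits = bait_region_set(),
                         counts = count_model(), bold = bold_spec()) {
  stopifnot(inherits(config, "pipeline_config"), n_subjects >= 2)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  set.seed(seed)
  age <- sample(22:36, n_subjects, replace = TRUE)
  sex <- ifelse(runif(n_subjects) < 0.58, "F", "M")
  covars <- data.frame(subject_id = sprintf("sub-%02d", seq_len(n_subjects)),
                       age = age, sex = sex)

  subjects <- vector("list", n_subjects)
  zmaps <- vector("list", n_subjects)
  labels <- vector("list", n_subjects)
  cohort_counts <- vector("list", n_subjects)
  jitter_rows <- list()
  dm <- striatum$grid_shape
  for (i in seq_len(n_subjects)) {
    s_seed <- subject_seed(seed, i)
    sub <- simulate_subject(striatum, baits, counts, bold, seed = s_seed)
    gt <- sub$gt
    bias <- compute_bias(sub$counts)
    mL <- equal_volume_masks(bias, "L", config$target_fraction)
    mR <- equal_volume_masks(bias, "R", config$target_fraction)
    labels[[i]] <- classify_voxels(bias, config$bias_cutoff)
    cohort_counts[[i]] <- sub$counts
    striat <- striatum_mask(gt)
    for (mm in list(mL, mR)) {
      for (cls in c("striosome", "matrix")) {
        mk <- if (cls == "striosome") mm$striosome_like else mm$matrix_like
        jit <- jitter_mask(mk, striat, mm,
                           jitter_spec(config$jitter_max_shift,
                                       rng_seed = s_seed + 3L))
        before <- mask_bias(bias, mk, config$bias_cutoff, cls)
        after <- mask_bias(bias, jit$mask, config$bias_cutoff, cls)
        jitter_rows[[length(jitter_rows) + 1]] <- data.frame(
          subject_id = covars$subject_id[i], hemisphere = mm$hemisphere,
          compartment = cls, bias_before = before$mean_bias,
          bias_after = after$mean_bias,
          mean_euclidean_shift = jit$mean_euclidean_shift)
      }
    }
    if (!is.null(sub$bold))
      zmaps[[i]] <- subject_maps(sub$bold, mL, mR, striat)
    subjects[[i]] <- list(gt = gt, bias = bias, masks = list(L = mL, R = mR))
  }
  affine <- subjects[[1]]$gt$affine

  # anatomy: cluster segregation at the high-bias cutoff, plane profile
  seg <- lapply(seq_len(n_subjects), function(i) {
    hc <- classify_voxels(subjects[[i]]$bias, config$high_bias_cutoff)
    c(strio = max(c(0, cluster_sizes(hc == 1L, config$connectivity)$sizes)),
      matx = max(c(0, cluster_sizes(hc == 2L, config$connectivity)$sizes)))
  })
  seg <- do.call(rbind, seg)
  nuc_mask <- lapply(seq_len(n_subjects),
                     function(i) striatum_mask(subjects[[i]]$gt))
  planes <- plane_profile(labels, nuc_mask, affine)
  jitter_tab <- do.call(rbind, jitter_rows)
  write_table_tsv(jitter_tab, file.path(out_dir, "jitter_control.tsv"))
  if (!is.null(planes$table))
    write_table_tsv(planes$table, file.path(out_dir, "plane_profile.tsv"))
  write_table_tsv(data.frame(subject_id = covars$subject_id, seg),
                  file.path(out_dir, "cluster_segregation.tsv"))
  write_table_tsv(covars, file.path(out_dir, "covariates.tsv"))

  contrasts <- NULL
  lat <- NULL
  if (!is.null(bold)) {
    contrasts <- contrast_suite(zmaps, covars, affine = affine,
                                p_unc = config$p_unc, n_perm = config$n_perm,
                                alpha = config$alpha,
                                connectivity = config$connectivity,
                                seed = seed + 17L)
    for (nm in names(contrasts))
      write_table_tsv(contrasts[[nm]]$table,
                      file.path(out_dir, paste0("clusters_",
                                                gsub("[^A-Za-z]", "_", nm),
                                                ".tsv")))
    lat <- laterality_report(contrasts, affine)
    write_table_tsv(lat, file.path(out_dir, "laterality.tsv"))
  }

  contrib <- contribution_maps(cohort_counts, baits)
  zones <- segment_zones(contrib)
  refined <- suppressWarnings(refine_zones(contrib, zones))
  anova_res <- if (length(refined$masks) >= 2 &&
                   length(unique(baits$favored[baits$name %in%
                     sub("\\.[LR]$", "", names(refined$masks))])) == 2)
    zone_bias_anova(refined, labels, baits, config$bias_cutoff) else NULL
  if (!is.null(anova_res))
    write_table_tsv(data.frame(F = anova_res$F, df1 = anova_res$df[1],
                               df2 = anova_res$df[2], p = anova_res$p,
                               r_squared = anova_res$r_squared),
                    file.path(out_dir, "zone_anova.tsv"))

  meta <- list(config = unclass(config), n_subjects = n_subjects,
               grid_shape = dm, package_version =
                 as.character(utils::packageVersion("striocompart")))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(covariates = covars, segregation = seg, planes = planes,
                 jitter = jitter_tab, contrasts = contrasts,
                 laterality = lat, zones = zones, refined = refined,
                 anova = anova_res))
}
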