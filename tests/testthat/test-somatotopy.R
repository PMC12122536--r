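# toy cohort: one subject, 5-voxel grid, two bait regions per class
toy_cohort_counts <- function() {
  dm <- c(5L, 1L, 1L)
  striatum <- array(TRUE, dm)
  baits <- bait_region_set(data.frame(
    name = c("s1", "s2", "m1", "m2"),
    favored = c("striosome", "striosome", "matrix", "matrix")))
  counts <- list(
    s1 = array(c(8L, 2L, 0L, 4L, 1L), dm),
    s2 = array(c(1L, 6L, 2L, 4L, 1L), dm),
    m1 = array(c(1L, 1L, 7L, 4L, 1L), dm),
    m2 = array(c(0L, 1L, 1L, 4L, 7L), dm))
  list(tc = target_counts(counts, baits, striatum, test_affine(dm)),
       baits = baits, counts = counts, dm = dm)
}

test_that("contribution maps equal hand-computed P differences", {
  ct <- toy_cohort_counts()
  contrib <- contribution_maps(list(ct$tc), ct$baits)
  S <- ct$counts$s1 + ct$counts$s2
  M <- ct$counts$m1 + ct$counts$m2
  p_full <- S / (S + M)
  for (r in ct$baits$name) {
    rest <- setdiff(ct$baits$name, r)
    Sr <- Reduce(`+`, ct$counts[intersect(rest, c("s1", "s2"))])
    Mr <- Reduce(`+`, ct$counts[intersect(rest, c("m1", "m2"))])
    expect_equal(contrib$maps[[r]], p_full - Sr / (Sr + Mr),
                 info = r)
  }
})

test_that("zero-count regions contribute nothing; identical regions tie", {
  ct <- toy_cohort_counts()
  cts <- ct$counts
  cts$s2 <- array(0L, ct$dm)
  tc <- target_counts(cts, ct$baits, array(TRUE, ct$dm), test_affine(ct$dm))
  contrib <- contribution_maps(list(tc), ct$baits)
  expect_true(all(contrib$maps$s2 == 0))
  # identical striosome-favoring regions produce identical contribution maps
  cts$s2 <- cts$s1
  tc <- target_counts(cts, ct$baits, array(TRUE, ct$dm), test_affine(ct$dm))
  contrib <- contribution_maps(list(tc), ct$baits)
  expect_equal(contrib$maps$s1, contrib$maps$s2)
})

test_that("winner-take-all zones partition the support deterministically", {
  ct <- toy_cohort_counts()
  contrib <- contribution_maps(list(ct$tc), ct$baits)
  zones <- segment_zones(contrib)
  # every supported voxel gets exactly one label (or none)
  expect_true(all(zones$labels[contrib$support] %in%
                    0:length(ct$baits$name)))
  # voxel 1 is dominated by s1, voxel 3 by m1, voxel 5 by m2
  expect_equal(zones$region_names[zones$labels[1]], "s1")
  expect_equal(zones$region_names[zones$labels[3]], "m1")
  expect_equal(zones$region_names[zones$labels[5]], "m2")
})

test_that("mirror-symmetric counts give mirror-symmetric zones", {
  gt <- small_gt(15)
  tc <- generate_counts(gt, bait_region_set(), count_model(), seed = 15)
  # symmetrise the cohort by reflecting counts across the mid-sagittal plane
  reflect <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  sym <- lapply(tc$counts, function(a) {
    s <- array(a, dim(a)) + reflect(array(a, dim(a)))
    array(as.integer(s), dim(a))
  })
  striatum <- tc$striatum | array(reflect(tc$striatum), dim(tc$striatum))
  tc_sym <- target_counts(sym, tc$baits, striatum, tc$affine)
  contrib <- contribution_maps(list(tc_sym), tc$baits)
  zones <- segment_zones(contrib)
  lab <- zones$labels
  expect_identical(array(lab, dim(lab)),
                   array(reflect(lab), dim(lab)))
})

test_that("zone refinement respects size bounds and L/R matching", {
  gt <- generate_striatum(striatum_spec(rng_seed = 16))
  cohort <- lapply(1:2, function(i)
    generate_counts(gt, bait_region_set(), count_model(), seed = 16 + i))
  contrib <- contribution_maps(cohort)
  zones <- segment_zones(contrib)
  refined <- suppressWarnings(refine_zones(contrib, zones))
  expect_gt(length(refined$masks), 0)
  for (key in names(refined$masks)) {
    n <- sum(refined$masks[[key]])
    expect_gte(n, 50); expect_lte(n, 100)
    # refined zones sit inside their coarse zone
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    i <- match(paste(parts[-length(parts)], collapse = "."),
               zones$region_names)
    expect_true(all(zones$labels[refined$masks[[key]]] == i))
  }
  # pairwise disjoint
  all_masks <- Reduce(`+`, lapply(refined$masks, function(m) m * 1L))
  expect_lte(max(all_masks), 1)
  # left/right volumes matched within tolerance
  sz <- refined$sizes
  for (r in unique(sz$region)) {
    s <- sz[sz$region == r, ]
    if (nrow(s) == 2) expect_lte(abs(diff(s$n_voxels)), 3)
  }
  # FWHM dispersion volumes exist for contributing regions
  expect_true(all(refined$fwhm >= 0))
})

test_that("refinement keeps in-range zones and trims degenerate amplitudes", {
  dm <- c(20L, 10L, 2L)
  aff <- test_affine(dm)
  support <- array(TRUE, dm)
  amp <- array(0, dm)
  # left hemisphere (x < 0): 75 voxels above half-max -> returned unchanged
  vox_L <- which(hemisphere_mask(dm, aff, "L"))
  amp[vox_L[1:75]] <- 1
  amp[vox_L[76:100]] <- 0.2
  # right hemisphere: uniform amplitudes, 120 voxels -> deterministic top-k
  vox_R <- which(hemisphere_mask(dm, aff, "R"))
  amp[vox_R[1:120]] <- 1
  contrib <- structure(list(
    maps = list(reg = amp), own_class = list(reg = amp),
    baits = bait_region_set(data.frame(name = c("reg", "other"),
                                       favored = c("striosome", "matrix"))),
    affine = aff, support = support), class = "contribution_maps")
  zones <- structure(list(labels = array(ifelse(amp > 0, 1L, 0L), dm),
                          region_names = c("reg", "other"), affine = aff,
                          support = support), class = "zone_labels")
  refined <- suppressWarnings(refine_zones(contrib, zones, lr_tolerance = 3))
  nL <- sum(refined$masks[["reg.L"]])
  nR <- sum(refined$masks[["reg.R"]])
  expect_equal(nL, 75)
  expect_lte(abs(nL - nR), 3)
  r2 <- suppressWarnings(refine_zones(contrib, zones, lr_tolerance = 100))
  expect_equal(sum(r2$masks[["reg.R"]]), 100)  # capped at the upper bound
  r3 <- suppressWarnings(refine_zones(contrib, zones, lr_tolerance = 100))
  expect_identical(r2$masks[["reg.R"]], r3$masks[["reg.R"]])
})

test_that("zone ANOVA detects planted compartment bias and calibrates", {
  gt <- generate_striatum(striatum_spec(rng_seed = 17))
  baits <- bait_region_set()
  cohort <- lapply(1:4, function(i)
    generate_counts(gt, baits, count_model(), seed = 40 + i))
  labels <- lapply(cohort, function(tc) classify_voxels(compute_bias(tc)))
  contrib <- contribution_maps(cohort)
  zones <- segment_zones(contrib)
  refined <- suppressWarnings(refine_zones(contrib, zones))
  res <- zone_bias_anova(refined, labels, baits)
  expect_gt(res$F, 1)
  expect_lt(res$p, 0.05)
  expect_gt(mean(res$data$frac_striosome[res$data$class == "striosome"]),
            mean(res$data$frac_striosome[res$data$class == "matrix"]))
  # permutation of region-class labels calibrates the F statistic
  perm <- zone_bias_permutation(refined, labels, baits, n_perm = 60, seed = 2)
  expect_lte(perm$p_perm, 0.05)
  expect_gt(mean(perm$null_F < perm$F_obs), 0.9)
})

test_that("a null cohort yields an unremarkable compartment F", {
  gt <- generate_striatum(striatum_spec(rng_seed = 18))
  baits <- bait_region_set()
  # unbiased counts: no compartment structure at all
  cohort <- lapply(1:3, function(i)
    generate_counts(gt, baits, count_model(bias_odds = 1), seed = 60 + i))
  labels <- lapply(cohort, function(tc) classify_voxels(compute_bias(tc)))
  biased <- lapply(1:3, function(i)
    generate_counts(gt, baits, count_model(), seed = 60 + i))
  contrib <- contribution_maps(biased)   # zones from structured counts
  zones <- segment_zones(contrib)
  refined <- suppressWarnings(refine_zones(contrib, zones))
  perm <- zone_bias_permutation(refined, labels, baits, n_perm = 60, seed = 3)
  expect_gt(perm$p_perm, 0.05)
})
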