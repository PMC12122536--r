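test_that("generated striatum hits the planted striosome fraction", {
  gt <- generate_striatum(striatum_spec(rng_seed = 11))
  expect_gte(striosome_fraction(gt), 0.12)
  expect_lte(striosome_fraction(gt), 0.18)
  # compartment labels exactly cover the striatum
  expect_true(all((gt$compartment > 0L) == (gt$nucleus > 0L)))
})

test_that("vanishing striosome fraction leaves almost pure matrix", {
  gt <- generate_striatum(striatum_spec(striosome_fraction = 0.001,
                                        rng_seed = 2))
  expect_gte(sum(gt$compartment == 2L) / sum(gt$nucleus > 0L), 0.99)
})

test_that("striatum generation is deterministic given spec and seed", {
  sp <- striatum_spec(grid_shape = c(20L, 24L, 20L), island_radius = 2L,
                      rng_seed = 7)
  a <- generate_striatum(sp)
  b <- generate_striatum(sp)
  expect_identical(a$nucleus, b$nucleus)
  expect_identical(a$compartment, b$compartment)
})

test_that("striosome forms small islands inside one contiguous matrix", {
  for (seed in 1:3) {
    gt <- generate_striatum(striatum_spec(rng_seed = seed))
    # striosome islands pooled over the striatum stay small and numerous
    cs <- cluster_sizes(gt$compartment == 1L)$sizes
    expect_lte(max(cs) / sum(cs), 0.20)
    for (code in 1:4) {
      strio <- gt$compartment == 1L & gt$nucleus == code
      matx <- gt$compartment == 2L & gt$nucleus == code
      expect_gt(length(cluster_sizes(strio)$sizes), 1)  # disjoint islands
      cm <- cluster_sizes(matx)$sizes
      expect_gte(max(cm) / sum(cm), 0.90)               # one matrix sea
    }
  }
})

test_that("striosome volume is enriched rostrally, ventrally and medially", {
  signs <- sapply(1:4, function(seed) {
    gt <- generate_striatum(striatum_spec(rng_seed = seed + 20))
    xyz <- voxel_coords(NULL, dim(gt$nucleus), gt$affine)
    strio <- which(gt$compartment == 1L)
    matx <- which(gt$compartment == 2L)
    c(rostral = mean(xyz[strio, 2]) > mean(xyz[matx, 2]),
      ventral = mean(xyz[strio, 3]) < mean(xyz[matx, 3]),
      medial = mean(abs(xyz[strio, 1])) < mean(abs(xyz[matx, 1])))
  })
  expect_true(all(rowMeans(signs) >= 0.75))
  expect_true(all(signs[, 1]))
})

test_that("too-small grids fail with an explicit constraint message", {
  expect_error(generate_striatum(striatum_spec(grid_shape = c(6L, 6L, 6L))),
               "grid too small")
})

test_that("bait region sets are validated", {
  b <- bait_region_set()
  expect_equal(nrow(b), 10)
  expect_equal(sum(b$favored == "striosome"), 5)
  expect_error(bait_region_set(data.frame(name = c("a", "a"),
                                          favored = c("striosome", "matrix"))),
               "unique")
  expect_error(bait_region_set(data.frame(name = c("a", "b"),
                                          favored = c("striosome", "striosome"))),
               "both compartment classes")
})

test_that("count maps carry the planted bias odds at pure voxels", {
  gt <- small_gt(3)
  baits <- bait_region_set()
  tc <- generate_counts(gt, baits,
                        count_model(bias_odds = 9, partial_volume_sigma = 0),
                        seed = 5)
  S <- Reduce(`+`, tc$counts[baits$name[baits$favored == "striosome"]])
  M <- Reduce(`+`, tc$counts[baits$name[baits$favored == "matrix"]])
  strio <- gt$compartment == 1L
  expect_equal(mean(S[strio]) / mean(M[strio]), 9, tolerance = 0.05)
  # counts confined to the striatum
  for (x in tc$counts) expect_true(all(x[gt$nucleus == 0L] == 0))
})

test_that("unbiased counts give bias probability one half", {
  gt <- small_gt(4)
  tc <- generate_counts(gt, bait_region_set(),
                        count_model(bias_odds = 1, partial_volume_sigma = 0),
                        seed = 6)
  p <- compute_bias(tc)$p
  expect_equal(mean(p, na.rm = TRUE), 0.5, tolerance = 0.01)
})

test_that("partial-volume mixing matches a brute-force convolution oracle", {
  gt <- generate_striatum(striatum_spec(rng_seed = 6))
  strio_idx <- which(gt$compartment == 1L)
  expect_gte(length(strio_idx), 100)
  base <- 50; odds <- 9; sigma_mm <- 2
  sigma_vox <- sigma_mm / gt$voxel_size[1]

  # independent oracle: direct truncated-Gaussian convolution of the planted
  # per-class rates at each striosome voxel (no call into the generator's
  # smoothing path)
  dm <- dim(gt$nucleus)
  rad <- ceiling(3 * sigma_vox)
  offs <- as.matrix(expand.grid(-rad:rad, -rad:rad, -rad:rad))
  kern <- exp(-rowSums(offs^2) / (2 * sigma_vox^2))
  lamS <- array(0, dm); lamM <- array(0, dm)
  lamS[gt$compartment == 1L] <- base
  lamS[gt$compartment == 2L] <- base / odds
  lamM[gt$compartment == 1L] <- base / odds
  lamM[gt$compartment == 2L] <- base
  sample_idx <- strio_idx[seq(1, length(strio_idx), length.out = 120)]
  oracle_bias <- vapply(sample_idx, function(v) {
    ctr <- arrayInd(v, dm)
    pts <- sweep(offs, 2, as.integer(ctr), "+")
    ok <- pts[, 1] >= 1 & pts[, 1] <= dm[1] & pts[, 2] >= 1 &
      pts[, 2] <= dm[2] & pts[, 3] >= 1 & pts[, 3] <= dm[3]
    lin <- pts[ok, 1] + dm[1] * (pts[ok, 2] - 1) + dm[1] * dm[2] * (pts[ok, 3] - 1)
    s <- sum(kern[ok] * lamS[lin]); m <- sum(kern[ok] * lamM[lin])
    s / (s + m)
  }, numeric(1))

  tc <- generate_counts(gt, bait_region_set(),
                        count_model(base_rate = base, bias_odds = odds,
                                    partial_volume_sigma = sigma_mm),
                        seed = 7)
  p <- compute_bias(tc)$p
  expect_equal(mean(p[sample_idx], na.rm = TRUE), mean(oracle_bias),
               tolerance = 0.05)
  # dilution is monotone in the mixing width and never inverts the contrast
  m_by_sigma <- vapply(c(0, 1, 2), function(sg) {
    pp <- compute_bias(generate_counts(gt, bait_region_set(),
                                       count_model(bias_odds = odds,
                                                   partial_volume_sigma = sg),
                                       seed = 7))$p
    mean(pp[strio_idx], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(m_by_sigma) < 0))
  expect_gt(m_by_sigma[1], 0.85)
  expect_gt(mean(p[gt$compartment == 1L], na.rm = TRUE),
            mean(p[gt$compartment == 2L], na.rm = TRUE))
})

test_that("count generation is deterministic and monotone in bias odds", {
  gt <- small_gt(8)
  cm <- count_model()
  a <- generate_counts(gt, bait_region_set(), cm, seed = 9)
  b <- generate_counts(gt, bait_region_set(), cm, seed = 9)
  expect_identical(a$counts, b$counts)
  # raising bias_odds never decreases mean P over planted striosome voxels
  strio <- gt$compartment == 1L
  means <- vapply(c(2, 5, 9), function(odds) {
    ms <- vapply(1:5, function(s) {
      p <- compute_bias(generate_counts(gt, bait_region_set(),
                                        count_model(bias_odds = odds,
                                                    partial_volume_sigma = 0),
                                        seed = s))$p
      mean(p[strio], na.rm = TRUE)
    }, numeric(1))
    mean(ms)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("null coupling leaves voxel-node correlations at chance level", {
  gt <- small_gt(2, grid = c(16L, 20L, 16L), island_radius = 1L)
  bs <- bold_spec(n_timepoints = 500,
                  coupling = c(striosome_ipsi = 0, striosome_contra = 0,
                               matrix_ipsi = 0, matrix_contra = 0),
                  rng_seed = 3)
  b <- generate_bold(gt, bs)
  tn <- dim(b$data)[4]
  m <- matrix(b$data, ncol = tn)
  node_tc <- colMeans(m[which(b$nodes[["DMN-L"]]$mask), , drop = FALSE])
  vox <- which(gt$compartment == 1L)
  r <- as.vector(cor(node_tc, t(m[vox, ])))
  expect_gte(mean(abs(r) < 3 / sqrt(tn)), 0.95)
})

test_that("planted coupling amplitude is recovered from sample correlations", {
  rs <- numeric(0)
  for (seed in 1:3) {
    gt <- small_gt(seed, grid = c(16L, 20L, 16L), island_radius = 1L)
    b <- generate_bold(gt, bold_spec(n_timepoints = 2400, rng_seed = seed))
    tn <- dim(b$data)[4]
    m <- matrix(b$data, ncol = tn)
    node_tc <- colMeans(m[which(b$nodes[["DMN-L"]]$mask), , drop = FALSE])
    hemiL <- hemisphere_mask(dim(gt$nucleus), gt$affine, "L")
    vox <- which(gt$compartment == 1L & hemiL)
    rs <- c(rs, as.vector(cor(node_tc, t(m[vox, ]))))
  }
  expect_equal(mean(rs), 0.6, tolerance = 0.05 / 0.6)
})

test_that("BOLD generation is deterministic and validates its inputs", {
  gt <- small_gt(2, grid = c(16L, 20L, 16L), island_radius = 1L)
  bs <- bold_spec(n_timepoints = 100, rng_seed = 5)
  a <- generate_bold(gt, bs)
  b <- generate_bold(gt, bs)
  expect_identical(a$data, b$data)
  # every voxel series is demeaned
  expect_true(all(abs(rowMeans(matrix(a$data, ncol = 100))) < 1e-10))
  expect_error(bold_spec(coupling = c(striosome_ipsi = 0.9,
                                      striosome_contra = 0.9,
                                      matrix_ipsi = 0, matrix_contra = 0)),
               "invalid covariance")
  # node masks must avoid the striatum
  bad <- default_network_nodes(gt)
  bad[[1]]$mask <- striatum_mask(gt)
  expect_error(generate_bold(gt, bold_spec(n_timepoints = 10,
                                           network_nodes = bad)),
               "overlaps the striatum")
})

test_that("written cohorts list every volume and regenerate identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  striatum <- striatum_spec(grid_shape = c(16L, 20L, 16L), island_radius = 1L)
  bs <- bold_spec(n_timepoints = 20)
  mf1 <- write_cohort(3, dir1, striatum = striatum, bold = bs, seed = 42)
  co <- read_cohort(file.path(dir1, "manifest.json"))
  expect_equal(co$manifest$n_subjects, 3)
  expect_equal(nrow(co$covariates), 3)
  expect_true(all(co$covariates$age >= 22 & co$covariates$age <= 36))
  for (s in co$manifest$subjects) {
    expect_length(s$files$counts, 10)
    expect_true(file.exists(file.path(dir1, s$files$labels)))
    expect_true(file.exists(file.path(dir1, s$files$bold)))
  }
  # 3 subjects x (1 label + 10 counts + 1 bold)
  expect_length(list.files(dir1, pattern = "nii.gz$"), 36)
  write_cohort(3, dir2, striatum = striatum, bold = bs, seed = 42)
  for (f in list.files(dir1, pattern = "nii.gz$"))
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  expect_error(write_cohort(0, dir1), "at least 1")
})
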