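# Leave-one-out somatotopic mapping.
#
# For each bait region, the cohort-averaged full parcellation minus the
# cohort-averaged N-1 parcellation (that region left out) reveals where and
# how strongly the region contributed to compartment-like bias. Winner-take-
# all segmentation of these contribution maps yields coarse somatotopic
# zones; thresholding within each zone yields refined 50-100-voxel zones
# whose compartment bias can be tested against the region's class.

#' Per-region contribution maps from N-1 parcellations
#'
#' `contribution(region) = Avg_cohort(P_full) - Avg_cohort(P_without_region)`,
#' cohort averaging before subtraction. Contributions are stored signed in
#' the striosome direction: positive where the region pushed bias toward
#' striosome. The own-class amplitude of a matrix-favoring region is the
#' negative of its stored map.
#'
#' @param cohort_counts list of `target_counts`, one per subject (all on one
#'   grid, same bait set).
#' @param baits a [bait_region_set()]; defaults to the first subject's.
#' @return object of class `contribution_maps`: list with `maps` (named list
#'   of 3-D arrays, striosome-signed), `own_class` (named list, positive
#'   toward the region's own class), `baits`, `affine`, `support` (logical
#'   array: voxels with defined bias in every averaged map).
#' @export
contribution_maps <- function(cohort_counts, baits = NULL) {
  stopifnot(is.list(cohort_counts), length(cohort_counts) >= 1)
  if (is.null(baits)) baits <- cohort_counts[[1]]$baits
  nm <- baits$name
  avg <- function(maps) {
    # cohort average of P, voxel defined where every subject defines it
    acc <- maps[[1]]
    for (m in maps[-1]) acc <- acc + m
    acc / length(maps)
  }
  full <- avg(lapply(cohort_counts, function(tc) compute_bias(tc)$p))
  maps <- own <- list()
  support <- !is.na(full)
  for (r in nm) {
    n1 <- avg(lapply(cohort_counts, function(tc) n1_parcellate(tc, r)$p))
    d <- full - n1
    maps[[r]] <- d
    s <- if (baits$favored[baits$name == r] == "striosome") 1 else -1
    own[[r]] <- s * d
    support <- support & !is.na(d)
  }
  structure(list(maps = maps, own_class = own, baits = baits,
                 affine = cohort_counts[[1]]$affine, support = support),
            class = "contribution_maps")
}

#' Winner-take-all somatotopic zone segmentation
#'
#' At each supported voxel, the zone label is the region with the largest
#' own-class contribution; voxels where no region contributes positively
#' toward its own class stay unlabelled. Ties are broken by bait list order.
#'
#' @param contrib a [contribution_maps()].
#' @return object of class `zone_labels`: list with `labels` (integer array,
#'   0 = none, i = i-th bait region), `region_names`, `affine`, `support`.
#' @export
segment_zones <- function(contrib) {
  stopifnot(inherits(contrib, "contribution_maps"))
  nm <- contrib$baits$name
  if (length(nm) < 2) stop("need at least two contribution maps")
  vox <- which(contrib$support)
  A <- vapply(nm, function(r) contrib$own_class[[r]][vox],
              numeric(length(vox)))
  best <- max.col(A, ties.method = "first")
  best[A[cbind(seq_along(vox), best)] <= 0] <- 0L
  labels <- array(0L, dim(contrib$support))
  labels[vox] <- best
  structure(list(labels = labels, region_names = nm, affine = contrib$affine,
                 support = contrib$support),
            class = "zone_labels")
}

# top-k voxels of a zone by own-class amplitude (ties: ascending index)
top_k_amplitude <- function(vox, amp, k) vox[order(-amp, vox)][seq_len(k)]

#' Refined somatotopic zones
#'
#' Within each coarse zone and hemisphere: threshold at `percentile`% of the
#' region's maximum own-class amplitude, then adjust the threshold so the
#' zone holds between `target_size[1]` and `target_size[2]` voxels (taking
#' the largest admissible size, i.e. the lowest admissible threshold). Left
#' and right zone volumes are then matched within `lr_tolerance` voxels by
#' trimming the larger side's lowest-amplitude voxels. Zones that cannot
#' reach the minimum size are dropped with a warning. No cluster-forming is
#' applied. A full-width-at-half-maximum dispersion volume (voxels with
#' own-class amplitude above half the region's maximum) is reported per
#' region.
#'
#' @param contrib a [contribution_maps()].
#' @param zones a [segment_zones()] result.
#' @param percentile amplitude percentile of the maximum (default 50).
#' @param target_size two integers, min and max zone voxels per hemisphere.
#' @param lr_tolerance left/right volume match tolerance in voxels.
#' @return object of class `refined_zones`: list with `masks` (named list
#'   `region.hemisphere` -> logical array), `sizes` (data.frame), `fwhm`
#'   (named vector: FWHM dispersion volume in voxels per region), `dropped`.
#' @export
refine_zones <- function(contrib, zones, percentile = 50,
                         target_size = c(50L, 100L), lr_tolerance = 3L) {
  stopifnot(inherits(contrib, "contribution_maps"),
            inherits(zones, "zone_labels"),
            percentile > 0, percentile <= 100, length(target_size) == 2,
            target_size[1] <= target_size[2])
  dm <- dim(zones$labels)
  hemi <- list(L = hemisphere_mask(dm, contrib$affine, "L"),
               R = hemisphere_mask(dm, contrib$affine, "R"))
  nm <- contrib$baits$name
  masks <- list()
  dropped <- character(0)
  rows <- list()
  fwhm <- setNames(numeric(length(nm)), nm)
  for (i in seq_along(nm)) {
    r <- nm[i]
    amp_map <- contrib$own_class[[r]]
    sup <- which(contrib$support & amp_map > 0)
    fwhm[r] <- if (length(sup)) sum(amp_map[sup] >= max(amp_map[sup]) / 2) else 0
    sel <- list()
    for (h in c("L", "R")) {
      vox <- which(zones$labels == i & hemi[[h]])
      if (length(vox) < target_size[1]) {
        dropped <- c(dropped, paste0(r, ".", h))
        warning("zone ", r, " (", h, ") has only ", length(vox),
                " voxels; cannot reach ", target_size[1], "; dropped")
        next
      }
      amp <- amp_map[vox]
      n_at_pct <- sum(amp >= max(amp) * percentile / 100)
      k <- min(max(n_at_pct, target_size[1]), target_size[2], length(vox))
      sel[[h]] <- top_k_amplitude(vox, amp, k)
    }
    if (length(sel) == 2 && abs(length(sel$L) - length(sel$R)) > lr_tolerance) {
      big <- if (length(sel$L) > length(sel$R)) "L" else "R"
      small_k <- min(length(sel$L), length(sel$R))
      sel[[big]] <- sel[[big]][seq_len(small_k + lr_tolerance)]
    }
    for (h in names(sel)) {
      m <- array(FALSE, dm); m[sel[[h]]] <- TRUE
      masks[[paste0(r, ".", h)]] <- m
      rows[[paste0(r, ".", h)]] <- data.frame(region = r, hemisphere = h,
                                              n_voxels = length(sel[[h]]))
    }
  }
  structure(list(masks = masks,
                 sizes = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 fwhm = fwhm, dropped = dropped,
                 target_size = target_size, percentile = percentile),
            class = "refined_zones")
}

#' Compartment-bias ANOVA across somatotopic zones
#'
#' For every (subject, region, hemisphere) cell, measures the striosome-like
#' volume fraction within the refined zone — striosome-like voxels (P > cutoff)
#' over all compartment-like voxels — and fits
#' `fraction ~ class + class:region + hemisphere + subject`, where `class` is
#' the region's favored compartment and the class:region interaction (regions
#' nested in class) is the nuisance term. Reports the F test of the
#' compartment-class effect.
#'
#' @param refined a [refine_zones()] result.
#' @param subject_labels list of per-subject classified arrays
#'   (from [classify_voxels()]).
#' @param baits the [bait_region_set()].
#' @param cutoff classification cutoff used for `subject_labels` (metadata).
#' @return list with `data` (cell-level data.frame), `anova` (table),
#'   `F`, `df`, `p`, `r_squared`.
#' @export
zone_bias_anova <- function(refined, subject_labels, baits, cutoff = 0.55) {
  stopifnot(inherits(refined, "refined_zones"), is.list(subject_labels),
            length(subject_labels) >= 2)
  if (length(refined$masks) == 0) stop("no refined zones to test")
  rows <- list()
  for (s in seq_along(subject_labels)) {
    lab <- subject_labels[[s]]
    for (key in names(refined$masks)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      region <- paste(parts[-length(parts)], collapse = ".")
      h <- parts[length(parts)]
      vox <- which(refined$masks[[key]])
      n_strio <- sum(lab[vox] == 1L)
      n_comp <- sum(lab[vox] %in% c(1L, 2L))
      rows[[paste(s, key)]] <- data.frame(
        subject = factor(s), region = region, hemisphere = h,
        class = baits$favored[baits$name == region],
        frac_striosome = if (n_comp > 0) n_strio / n_comp else NA_real_)
    }
  }
  dat <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  dat <- dat[!is.na(dat$frac_striosome), ]
  for (v in c("region", "hemisphere", "class")) dat[[v]] <- factor(dat[[v]])
  if (nlevels(dat$class) < 2) stop("need zones of both compartment classes")
  terms <- "class"
  if (nlevels(dat$region) > nlevels(dat$class)) terms <- c(terms, "class:region")
  if (nlevels(dat$hemisphere) > 1) terms <- c(terms, "hemisphere")
  if (nlevels(dat$subject) > 1) terms <- c(terms, "subject")
  fit <- lm(stats::reformulate(terms, response = "frac_striosome"), data = dat)
  an <- anova(fit)
  i <- which(rownames(an) == "class")
  list(data = dat, anova = an,
       F = an[i, "F value"], df = c(an[i, "Df"], an[nrow(an), "Df"]),
       p = an[i, "Pr(>F)"], r_squared = summary(fit)$r.squared)
}

#' Permutation calibration of the zone-bias ANOVA
#'
#' Recomputes the compartment-class F statistic under random permutations of
#' the region-to-class assignment, giving a permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` for the observed class effect.
#'
#' @param refined,subject_labels,baits,cutoff as in [zone_bias_anova()].
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list with `F_obs`, `p_perm`, `null_F`.
#' @export
zone_bias_permutation <- function(refined, subject_labels, baits,
                                  cutoff = 0.55, n_perm = 200, seed = 1L) {
  obs <- zone_bias_anova(refined, subject_labels, baits, cutoff)
  set.seed(as.integer(seed))
  null_F <- vapply(seq_len(n_perm), function(b) {
    pb <- baits
    pb$favored <- sample(baits$favored)
    zone_bias_anova(refined, subject_labels, pb, cutoff)$F
  }, numeric(1))
  list(F_obs = obs$F,
       p_perm = (1 + sum(null_F >= obs$F)) / (1 + n_perm),
       null_F = null_F)
}
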