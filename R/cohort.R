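# Cohort simulation and on-disk layout: per-subject NIfTI volumes, a TSV
# covariate table (age, sex) and a JSON manifest recording files and seeds so
# any cohort can be regenerated bit-identically.

subject_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) + 7919 * i) %% .Machine$integer.max)
}

# nucleus and compartment codes packed into one label volume:
# label = nucleus_code * 10 + compartment_code
encode_labels <- function(gt) gt$nucleus * 10L + gt$compartment

decode_labels <- function(lab) {
  list(nucleus = array(as.integer(lab %/% 10), dim(lab)),
       compartment = array(as.integer(lab %% 10), dim(lab)))
}

#' Simulate one subject
#'
#' @param striatum a [striatum_spec()] (its `rng_seed` is overridden by
#'   `seed`).
#' @param baits a [bait_region_set()].
#' @param counts a [count_model()].
#' @param bold a [bold_spec()] or NULL to skip BOLD generation.
#' @param seed integer seed driving all of this subject's randomness.
#' @return list with `gt`, `counts`, `bold` (or NULL), `seed`.
#' @export
simulate_subject <- function(striatum = striatum_spec(),
                             baits = bait_region_set(),
                             counts = count_model(), bold = bold_spec(),
                             seed = 1L) {
  striatum$rng_seed <- as.integer(seed)
  gt <- generate_striatum(striatum)
  tc <- generate_counts(gt, baits, counts, seed = seed + 1L)
  bs <- NULL
  if (!is.null(bold)) {
    bold$rng_seed <- seed + 2L
    bs <- generate_bold(gt, bold)
  }
  list(gt = gt, counts = tc, bold = bs, seed = as.integer(seed))
}

#' Write a synthetic cohort to disk
#'
#' Writes, per subject, one packed label volume (nucleus x compartment), one
#' count volume per bait region, and one 4-D BOLD series; plus a cohort-level
#' TSV of covariates (age ~ uniform integers 22-36; sex ~ Bernoulli, 58%
#' female) and a JSON manifest listing files and per-subject seeds.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param out_dir output directory (created if needed).
#' @param striatum,baits,counts,bold generator specifications (see
#'   [simulate_subject()]); `bold = NULL` skips BOLD volumes.
#' @param seed master integer seed.
#' @return path of the manifest JSON, invisibly.
#' @export
write_cohort <- function(n_subjects, out_dir, striatum = striatum_spec(),
                         baits = bait_region_set(), counts = count_model(),
                         bold = bold_spec(), seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("n_subjects must be at least 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  set.seed(as.integer(seed))
  age <- sample(22:36, n_subjects, replace = TRUE)
  sex <- ifelse(runif(n_subjects) < 0.58, "F", "M")
  covars <- data.frame(subject_id = sprintf("sub-%02d", seq_len(n_subjects)),
                       age = age, sex = sex)
  write_table_tsv(covars, file.path(out_dir, "covariates.tsv"))
  subjects <- list()
  for (i in seq_len(n_subjects)) {
    sid <- covars$subject_id[i]
    s_seed <- subject_seed(seed, i)
    sub <- simulate_subject(striatum, baits, counts, bold, seed = s_seed)
    files <- list()
    f <- file.path(out_dir, paste0(sid, "_labels.nii.gz"))
    write_volume(encode_labels(sub$gt), f, sub$gt$affine)
    files$labels <- basename(f)
    files$counts <- list()
    for (nm in names(sub$counts$counts)) {
      f <- file.path(out_dir, paste0(sid, "_counts_", nm, ".nii.gz"))
      write_volume(sub$counts$counts[[nm]], f, sub$gt$affine)
      files$counts[[nm]] <- basename(f)
    }
    if (!is.null(sub$bold)) {
      f <- file.path(out_dir, paste0(sid, "_bold.nii.gz"))
      write_volume(sub$bold$data, f, sub$gt$affine, tr = sub$bold$tr)
      files$bold <- basename(f)
    }
    subjects[[sid]] <- list(subject_id = sid, seed = s_seed, files = files)
  }
  manifest <- list(
    n_subjects = n_subjects, master_seed = as.integer(seed),
    covariates = "covariates.tsv",
    baits = as.data.frame(baits),
    specs = list(striatum = unclass(striatum), counts = unclass(counts),
                 bold = if (!is.null(bold))
                   unclass(bold)[setdiff(names(bold), "network_nodes")]),
    subjects = subjects)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Read a cohort manifest
#'
#' @param manifest_path path to `manifest.json` written by [write_cohort()].
#' @return list with `manifest` (parsed JSON), `covariates` (data.frame),
#'   `dir`.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  d <- dirname(manifest_path)
  list(manifest = man,
       covariates = read_table_tsv(file.path(d, man$covariates)),
       dir = d)
}
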