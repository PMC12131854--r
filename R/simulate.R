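# Synthetic cohort generator: clinical covariates, profiling matrices on two
# quantification platforms, and long-format MRM peak areas with known ground
# truth, reproducing the statistical structure the analysis assumes.

GROUPS <- c("NPDR", "PDR", "NVG")
CONTRASTS <- c("PDR_vs_NPDR", "NVG_vs_PDR")

#' Cohort design
#'
#' Group sizes and per-group covariate distributions of a simulated
#' validation cohort. Defaults mirror the printed characteristics of the
#' validation set (37/38/9 patients; ages 66.1 +/- 8.3, 54.9 +/- 8.9,
#' 53.3 +/- 12.1 years; male and hypertension prevalences near 50-60%);
#' macular edema, panretinal photocoagulation, phakia and cataract-grade
#' distributions are field-realistic defaults (see the package vignette).
#'
#' @param n_per_group Integer counts named NPDR/PDR/NVG, all >= 1.
#' @param age_means,age_sds Per-group age mean / SD in years.
#' @param male_prev,htn_prev,me_prev,prp_prev,phakia_prev Per-group
#'   prevalences in `[0, 1]`.
#' @param cataract_grade_probs 3 x 3 matrix, rows = groups, columns =
#'   grades 0/1/2; rows must sum to 1.
#' @param age_range Truncation bounds for ages, years.
#' @param seed Integer seed used by the generators unless overridden.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(NPDR = 37L, PDR = 38L, NVG = 9L),
                          age_means = c(66.1, 54.9, 53.3),
                          age_sds = c(8.3, 8.9, 12.1),
                          male_prev = c(0.486, 0.605, 0.556),
                          htn_prev = c(0.568, 0.553, 0.556),
                          me_prev = c(0.25, 0.55, 0.45),
                          prp_prev = c(0.15, 0.75, 0.90),
                          phakia_prev = c(0.90, 0.65, 0.60),
                          cataract_grade_probs = rbind(
                            NPDR = c(0.20, 0.40, 0.40),
                            PDR  = c(0.45, 0.35, 0.20),
                            NVG  = c(0.40, 0.35, 0.25)),
                          age_range = c(30, 90),
                          seed = 1L) {
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 1L))
  probs <- c(male_prev, htn_prev, me_prev, prp_prev, phakia_prev,
             cataract_grade_probs)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(abs(rowSums(cataract_grade_probs) - 1) < 1e-8),
            all(age_sds > 0))
  names(n_per_group) <- GROUPS
  structure(list(n_per_group = as.integer(n_per_group),
                 age_means = age_means, age_sds = age_sds,
                 male_prev = male_prev, htn_prev = htn_prev,
                 me_prev = me_prev, prp_prev = prp_prev,
                 phakia_prev = phakia_prev,
                 cataract_grade_probs = cataract_grade_probs,
                 age_range = age_range, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Ground truth for the generators
#'
#' True marker effects, platform shifts, missingness model, duplicate CV
#' and spike-in level driving the synthetic data; kept alongside the
#' generated tables so recovery can be scored.
#'
#' @param marker_effects List with elements `PDR_vs_NPDR` and `NVG_vs_PDR`,
#'   each a named numeric vector of log2 effects per true-marker protein.
#' @param lfq_location,tmt_location Additive log2 platform shift (scalar or
#'   per-protein vector).
#' @param lfq_scale,tmt_scale Multiplicative scale on the noise (scalar or
#'   per-protein).
#' @param miss_intercept,miss_slope Detection-probability model for the LFQ
#'   platform: P(detected) = plogis(intercept + slope * log2 abundance);
#'   slope must be >= 0.
#' @param cv_target Expected technical-duplicate coefficient of variation,
#'   in (0, 1).
#' @param spikein_level Constant log2 peak area of the spike-in peptides.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(marker_effects = list(
                           PDR_vs_NPDR = numeric(), NVG_vs_PDR = numeric()),
                         lfq_location = 0, lfq_scale = 1,
                         tmt_location = 0, tmt_scale = 1,
                         miss_intercept = -17, miss_slope = 1,
                         cv_target = 0.10, spikein_level = 17) {
  stopifnot(all(CONTRASTS %in% names(marker_effects)),
            miss_slope >= 0, cv_target >= 0, cv_target < 1)
  structure(list(marker_effects = marker_effects,
                 lfq_location = lfq_location, lfq_scale = lfq_scale,
                 tmt_location = tmt_location, tmt_scale = tmt_scale,
                 miss_intercept = miss_intercept, miss_slope = miss_slope,
                 cv_target = cv_target, spikein_level = spikein_level),
            class = "ground_truth")
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  # inverse-CDF sampling of a truncated normal
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a clinical covariate table
#'
#' One row per simulated patient with group sizes exactly as designed;
#' covariates drawn independently per the design's prevalences, ages from a
#' truncated normal on the design's range.
#'
#' @param design A [cohort_design()].
#' @param cohort Cohort label stored in the table.
#' @param seed Integer seed (defaults to the design's).
#' @return data.frame of class `clinical_table`: `patient_id`, `group`,
#'   `cohort`, `age`, `sex`, `hypertension`, `cataract_cortical`,
#'   `cataract_nuclear`, `cataract_posterior`, `phakic`, `me`, `prp`.
#' @export
generate_clinical_table <- function(design, cohort = "validation",
                                    seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (any(design$n_per_group < 1L)) stop("non-positive group size")
  set.seed(seed)
  rows <- lapply(seq_along(GROUPS), function(g) {
    n <- design$n_per_group[g]
    grade <- function() sample(0:2, n, replace = TRUE,
                               prob = design$cataract_grade_probs[g, ])
    data.frame(
      patient_id = sprintf("%s_%02d", GROUPS[g], seq_len(n)),
      group = GROUPS[g], cohort = cohort,
      age = round(.rtruncnorm(n, design$age_means[g], design$age_sds[g],
                              design$age_range[1L], design$age_range[2L]), 1),
      sex = ifelse(stats::runif(n) < design$male_prev[g], "male", "female"),
      hypertension = stats::runif(n) < design$htn_prev[g],
      cataract_cortical = grade(),
      cataract_nuclear = grade(),
      cataract_posterior = grade(),
      phakic = stats::runif(n) < design$phakia_prev[g],
      me = stats::runif(n) < design$me_prev[g],
      prp = stats::runif(n) < design$prp_prev[g],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("clinical_table", "data.frame")
  out
}

# cumulative group means implied by the two stage contrasts
.group_effects <- function(truth, proteins) {
  e1 <- e2 <- stats::setNames(numeric(length(proteins)), proteins)
  m1 <- truth$marker_effects$PDR_vs_NPDR
  m2 <- truth$marker_effects$NVG_vs_PDR
  missing <- setdiff(c(names(m1), names(m2)), proteins)
  if (length(missing) > 0L) {
    stop("ground truth references protein(s) absent from universe: ",
         paste(missing, collapse = ", "))
  }
  e1[names(m1)] <- m1
  e2[names(m2)] <- m2
  cbind(NPDR = 0 * e1, PDR = e1, NVG = e1 + e2)
}

#' Generate profiling matrices for both platforms
#'
#' Log2 intensities are protein baseline + cumulative group effect (for
#' true markers) + platform location shift + platform-scaled Gaussian
#' noise. The LFQ matrix carries `lfq_replicates` columns per group and
#' abundance-dependent missingness (Bernoulli detection with logistic
#' probability in the log2 value); the TMT matrix carries two replicate
#' channel columns per group and is complete.
#'
#' @param design A [cohort_design()] (groups only are used here).
#' @param truth A [ground_truth()].
#' @param n_proteins Size of the protein universe.
#' @param lfq_replicates LFQ columns per group.
#' @param noise_sd Residual log2 SD before platform scaling.
#' @param baseline_mean,baseline_sd Distribution of protein baselines (log2).
#' @param seed Integer seed.
#' @return List with `lfq` and `tmt` [intensity_matrix()] objects and
#'   `baselines`.
#' @export
generate_profiling_matrices <- function(design, truth, n_proteins = 200L,
                                        lfq_replicates = 3L, noise_sd = 0.5,
                                        baseline_mean = 20, baseline_sd = 1.5,
                                        seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "ground_truth"))
  set.seed(seed)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  baselines <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
  eff <- .group_effects(truth, proteins)

  expand <- function(v) if (length(v) == 1L) rep(v, n_proteins) else v
  lfq_loc <- expand(truth$lfq_location); lfq_sc <- expand(truth$lfq_scale)
  tmt_loc <- expand(truth$tmt_location); tmt_sc <- expand(truth$tmt_scale)

  lfq_groups <- rep(GROUPS, each = lfq_replicates)
  mu_lfq <- baselines + lfq_loc
  lfq <- sapply(lfq_groups, function(g)
    mu_lfq + eff[, g] + lfq_sc * stats::rnorm(n_proteins, 0, noise_sd))
  colnames(lfq) <- paste0("LFQ_", lfq_groups, "_",
                          sequence(rep(lfq_replicates, 3L)))
  rownames(lfq) <- proteins
  # abundance-dependent missingness
  p_det <- stats::plogis(truth$miss_intercept + truth$miss_slope * lfq)
  lfq[stats::runif(length(lfq)) >= p_det] <- NA_real_

  channels <- list(NPDR = c("126", "129"), PDR = c("127", "130"),
                   NVG = c("128", "131"))
  tmt_groups <- rep(GROUPS, each = 2L)
  mu_tmt <- baselines + tmt_loc
  tmt <- sapply(tmt_groups, function(g)
    mu_tmt + eff[, g] + tmt_sc * stats::rnorm(n_proteins, 0, noise_sd))
  colnames(tmt) <- paste0("TMT_", tmt_groups, "_", unlist(channels))
  rownames(tmt) <- proteins

  list(lfq = intensity_matrix(lfq, "LFQ", lfq_groups),
       tmt = intensity_matrix(tmt, "TMT", tmt_groups),
       baselines = stats::setNames(baselines, proteins))
}

#' Generate a long-format MRM peak-area table
#'
#' Exactly two technical replicates per (sample, transition). Log2 areas
#' are transition baseline + cumulative group effect of the parent protein
#' + a per-sample log-normal loading factor + replicate noise whose SD is
#' set so the technical-duplicate CV equals the truth's `cv_target`.
#' The four spike-in peptides are present in every sample at
#' `spikein_level` (plus the loading factor and replicate noise), so
#' spike-in normalization is the exact inverse of the loading. Designated
#' "poor" samples have a fraction of their target transitions forced below
#' the detection threshold.
#'
#' @param design A [cohort_design()].
#' @param transitions Transition data.frame (`protein`, `peptide`, `ion`,
#'   `fragment_index`) as produced by [design_transitions()]; spike-in rows
#'   are added automatically if absent.
#' @param truth A [ground_truth()].
#' @param clinical Optional pre-generated [generate_clinical_table()] output
#'   (its patient ids become the sample ids).
#' @param loading_sd SD of the per-sample log2 loading factor.
#' @param bio_sd Between-subject biological SD (log2) of each target
#'   protein's abundance; shared by the protein's transitions and both
#'   replicates of a sample. Spike-ins carry no biological variance.
#' @param baseline_mean,baseline_sd Distribution of per-transition log2
#'   baselines.
#' @param poor_samples Character vector of sample ids to degrade.
#' @param poor_fraction Fraction of target transitions set undetectable in
#'   each poor sample.
#' @param seed Integer seed.
#' @return data.frame (PeakAreaTable layout): `sample`, `replicate`,
#'   `group`, `protein`, `peptide`, `transition`, `area`.
#' @export
generate_mrm_peak_areas <- function(design, transitions, truth,
                                    clinical = NULL, loading_sd = 0.5,
                                    bio_sd = 0.8,
                                    baseline_mean = 15, baseline_sd = 1.2,
                                    poor_samples = character(),
                                    poor_fraction = 0.6,
                                    seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"), inherits(truth, "ground_truth"),
            nrow(transitions) >= 1L)
  set.seed(seed)
  if (is.null(clinical)) {
    samples <- unlist(lapply(seq_along(GROUPS), function(g)
      sprintf("%s_%02d", GROUPS[g], seq_len(design$n_per_group[g]))))
    groups <- rep(GROUPS, design$n_per_group)
  } else {
    samples <- clinical$patient_id
    groups <- clinical$group
  }
  tr <- transitions
  tr$transition <- paste(tr$peptide, tr$ion, tr$fragment_index, sep = "_")
  if (anyDuplicated(tr$transition)) stop("duplicate transition identifiers")
  # append spike-in peptide transitions if the list lacks them
  have_spike <- SPIKEIN_PEPTIDES %in% tr$peptide
  if (!all(have_spike)) {
    sp <- do.call(rbind, lapply(SPIKEIN_PEPTIDES[!have_spike], function(p)
      select_transitions(p, protein = "BGAL_ECOLI")))
    sp$transition <- paste(sp$peptide, sp$ion, sp$fragment_index, sep = "_")
    tr <- rbind(tr[intersect(names(tr), names(sp))],
                sp[intersect(names(tr), names(sp))])
  }
  is_spike <- tr$peptide %in% SPIKEIN_PEPTIDES
  n_tr <- nrow(tr)
  eff <- .group_effects(truth, unique(tr$protein[!is_spike]))

  base_tr <- stats::rnorm(n_tr, baseline_mean, baseline_sd)
  base_tr[is_spike] <- truth$spikein_level
  # replicate noise SD on the log2 scale implied by the target CV
  rep_sd <- if (truth$cv_target == 0) 0 else
    sqrt(log(1 + truth$cv_target^2)) / log(2)
  loading <- stats::setNames(stats::rnorm(length(samples), 0, loading_sd),
                             samples)

  out <- vector("list", length(samples))
  target_prot <- unique(tr$protein[!is_spike])
  for (i in seq_along(samples)) {
    s <- samples[i]; g <- groups[i]
    bio <- stats::setNames(stats::rnorm(length(target_prot), 0, bio_sd),
                           target_prot)
    mu <- base_tr + loading[s]
    mu[!is_spike] <- mu[!is_spike] + eff[tr$protein[!is_spike], g] +
      bio[tr$protein[!is_spike]]
    if (s %in% poor_samples) {
      kill <- which(!is_spike &
                      stats::runif(n_tr) < poor_fraction)
      mu[kill] <- 5   # log2 area 5 => area 32, far below the 10^3 threshold
    }
    reps <- lapply(1:2, function(r)
      data.frame(sample = s, replicate = r, group = g,
                 protein = tr$protein, peptide = tr$peptide,
                 transition = tr$transition,
                 area = 2^(mu + stats::rnorm(n_tr, 0, rep_sd)),
                 stringsAsFactors = FALSE))
    out[[i]] <- do.call(rbind, reps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a simulated cohort to a directory
#'
#' Writes the clinical table, both profiling matrices (with sample
#' annotation sidecars), the MRM peak-area table, and a key-value manifest
#' of the ground truth as plain comma-separated text.
#'
#' @param dir Output directory (created if needed).
#' @param clinical,lfq,tmt,peaks,truth Generated objects (any may be NULL).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(dir, clinical = NULL, lfq = NULL, tmt = NULL,
                         peaks = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(clinical)) {
    utils::write.csv(as.data.frame(clinical),
                     file.path(dir, "clinical.csv"), row.names = FALSE)
  }
  if (!is.null(lfq)) write_intensity_matrix(lfq, file.path(dir, "lfq.csv"))
  if (!is.null(tmt)) write_intensity_matrix(tmt, file.path(dir, "tmt.csv"))
  if (!is.null(peaks)) write_peak_areas(peaks, file.path(dir, "peak_areas.csv"))
  if (!is.null(truth)) {
    kv <- c(
      sprintf("cv_target,%g", truth$cv_target),
      sprintf("spikein_level,%g", truth$spikein_level),
      sprintf("miss_intercept,%g", truth$miss_intercept),
      sprintf("miss_slope,%g", truth$miss_slope),
      unlist(lapply(CONTRASTS, function(ct)
        sprintf("effect_%s_%s,%g", ct, names(truth$marker_effects[[ct]]),
                truth$marker_effects[[ct]])))
    )
    writeLines(c("key,value", kv), file.path(dir, "ground_truth.csv"))
  }
  invisible(dir)
}
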