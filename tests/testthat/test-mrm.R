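# Spike-in normalization, detection, sample/CV filters, peptide quantities.

# tiny hand-built peak table: 2 samples x 2 reps, 1 target peptide with 3
# transitions + 1 spike-in peptide with 3 transitions
tiny_peaks <- function(s2_scale = 1, areas = c(2000, 3000, 4000),
                       spike = 5000) {
  rows <- expand.grid(sample = c("s1", "s2"), replicate = 1:2,
                      idx = 1:3, stringsAsFactors = FALSE)
  tgt <- data.frame(rows[c("sample", "replicate")],
                    protein = "TGT", peptide = "LNDGLTAFESK",
                    transition = paste0("t", rows$idx),
                    area = areas[rows$idx] *
                      ifelse(rows$sample == "s2", s2_scale, 1))
  sp <- data.frame(rows[c("sample", "replicate")],
                   protein = "BGAL", peptide = "IDPNAWVER",
                   transition = paste0("sp", rows$idx),
                   area = spike * ifelse(rows$sample == "s2", s2_scale, 1))
  rbind(tgt, sp)
}

test_that("equal spike-ins leave the table unchanged", {
  tb <- tiny_peaks()
  out <- normalize_spikein(tb)
  expect_equal(out$factors$factor, rep(1, 4))
  expect_equal(out$table$area, out$table$area_raw)
})

test_that("a doubled sample is pulled back level by normalization", {
  tb <- tiny_peaks(s2_scale = 2)
  out <- normalize_spikein(tb)
  a <- out$table
  s1 <- sort(a$area[a$sample == "s1" & a$replicate == 1 & !a$is_spikein])
  s2 <- sort(a$area[a$sample == "s2" & a$replicate == 1 & !a$is_spikein])
  # before normalization s2 sat 2x above s1; afterwards they coincide
  expect_equal(s2 / s1, rep(1, 3), tolerance = 1e-9)
  # factors straddle the cohort median geometric mean (7500): 2/3 and 4/3
  expect_setequal(round(unique(out$factors$factor), 9),
                  round(c(5000, 10000) / 7500, 9))
  # within-sample ratios are untouched
  expect_equal(s2[2] / s2[1], 3000 / 2000, tolerance = 1e-12)
})

test_that("samples with no positive spike-in areas are excluded with reason", {
  tb <- tiny_peaks()
  tb$area[tb$sample == "s2" & tb$peptide == "IDPNAWVER"] <- 0
  out <- normalize_spikein(tb)
  expect_identical(out$excluded_samples, "s2")
  expect_false("s2" %in% out$table$sample)
})

test_that("normalization reduces spike-in spread under log-normal loading", {
  set.seed(17)
  design <- cohort_design(n_per_group = c(NPDR = 15L, PDR = 15L, NVG = 2L))
  truth <- default_truth(cv_target = 0.05)
  peaks <- generate_mrm_peak_areas(design, small_transition_list(), truth,
                                   loading_sd = 0.25 * log2(exp(1)),
                                   seed = 17)
  out <- normalize_spikein(peaks)
  spike_gm <- function(tb) {
    sp <- tb[tb$peptide %in% SPIKEIN_PEPTIDES, ]
    g <- tapply(log(sp$area), sp$sample, mean)
    stats::sd(g) / abs(mean(g))
  }
  cv_pre <- spike_gm(transform(peaks,
                               area = peaks$area))
  out$table$area_pre <- NULL
  cv_post <- spike_gm(out$table)
  expect_lt(cv_post / cv_pre, 0.2)
})

test_that("detection threshold is strict and uses raw areas", {
  tb <- tiny_peaks(areas = c(1000, 1000.1, 500))
  out <- normalize_spikein(tb)
  det <- detection_filter(out$table)
  a1000 <- det[det$transition == "t1", ]
  expect_false(any(a1000$detected))       # exactly 10^3 is not "exceeding"
  expect_true(all(det$detected[det$transition == "t2"]))
  expect_false(any(det$detected[det$transition == "t3"]))
  # an all-zero sample detects nothing
  tb0 <- tiny_peaks()
  tb0$area[tb0$sample == "s1" & tb0$protein == "TGT"] <- 0
  det0 <- detection_filter(normalize_spikein(tb0)$table)
  expect_false(any(det0$detected[det0$sample == "s1" & !det0$is_spikein]))
})

test_that("sample filter removes < 50% detection, keeps exactly 50%", {
  # 10 target transitions in sample s1: 4 detected -> excluded;
  # s2: 5 of 10 -> retained
  mk <- function(sample, n_det) {
    data.frame(sample = sample, replicate = rep(1:2, each = 10),
               protein = "T", peptide = "PEP",
               transition = paste0("t", rep(1:10, 2)),
               area = rep(c(rep(2000, n_det), rep(10, 10 - n_det)), 2),
               area_raw = rep(c(rep(2000, n_det), rep(10, 10 - n_det)), 2),
               is_spikein = FALSE)
  }
  tb <- rbind(mk("s1", 4), mk("s2", 5))
  det <- detection_filter(tb)
  out <- sample_filter(det)
  expect_identical(out$excluded$sample, "s1")
  expect_equal(out$excluded$detected_fraction, 0.4)
  expect_true(all(out$table$sample == "s2"))
  # fully detected cohort: nothing excluded
  tb2 <- rbind(mk("s1", 10), mk("s2", 10))
  expect_equal(nrow(sample_filter(detection_filter(tb2))$excluded), 0L)
})

test_that("CV filter implements the sd/mean duplicate rule", {
  base <- tiny_peaks()
  base <- detection_filter(normalize_spikein(base)$table)
  # plant duplicate pairs on transition t1 of each sample
  tweak <- function(tb, r1, r2) {
    tb$area[tb$transition == "t1" & tb$replicate == 1] <- r1
    tb$area[tb$transition == "t1" & tb$replicate == 2] <- r2
    tb
  }
  ok <- cv_filter(tweak(base, 900, 1100), min_samples = 2L)  # CV ~ 0.141
  expect_false("t1" %in% ok$excluded$transition)
  bad <- cv_filter(tweak(base, 500, 1500), min_samples = 2L) # CV ~ 0.707
  expect_true("t1" %in% bad$excluded$transition)
  expect_equal(bad$excluded$summary_cv[bad$excluded$transition == "t1"],
               sd(c(500, 1500)) / 1000, tolerance = 1e-9)
  ident <- cv_filter(base, min_samples = 2L)    # identical duplicates: CV 0
  expect_equal(nrow(ident$excluded), 0L)
})

test_that("transitions detected in too few samples are removed with reason", {
  tb <- tiny_peaks()
  det <- detection_filter(normalize_spikein(tb)$table)
  out <- cv_filter(det, min_samples = 3L)   # only 2 samples exist
  expect_true(all(out$excluded$reason == "insufficient observations"))
  expect_true(all(c("t1", "t2", "t3") %in% out$excluded$transition))
})

test_that("peptide quantities require >= 3 detected transitions", {
  tb <- tiny_peaks()
  det <- detection_filter(normalize_spikein(tb)$table)
  q3 <- peptide_quantity(det)
  expect_equal(q3["LNDGLTAFESK", "s1"], 2000 + 3000 + 4000)
  # with one transition removed the peptide is never quantified
  det2 <- det[det$transition != "t1", ]
  q2 <- peptide_quantity(det2)
  expect_true(all(is.na(q2)))
})

test_that("the full cascade is a no-op on its own output", {
  set.seed(23)
  design <- cohort_design(n_per_group = c(NPDR = 10L, PDR = 10L, NVG = 2L))
  truth <- default_truth(cv_target = 0.08)
  peaks <- generate_mrm_peak_areas(design, small_transition_list(), truth,
                                   seed = 23)
  run1 <- mrm_qc(peaks)
  run2 <- mrm_qc(run1$table)
  expect_equal(run2$table$area, run1$table$area, tolerance = 1e-12)
  expect_equal(run2$quantities, run1$quantities, tolerance = 1e-12)
  expect_equal(nrow(run2$report$excluded_transitions), 0L)
})

test_that("QC counts reconcile and are monotone through the cascade", {
  set.seed(29)
  design <- cohort_design(n_per_group = c(NPDR = 12L, PDR = 12L, NVG = 3L))
  truth <- default_truth(cv_target = 0.08)
  peaks <- generate_mrm_peak_areas(design, small_transition_list(), truth,
                                   poor_samples = c("NPDR_01", "PDR_02"),
                                   poor_fraction = 0.8, seed = 29)
  res <- mrm_qc(peaks)
  cnt <- res$report$counts
  expect_true(all(diff(cnt) <= 0))
  excluded_rows <- cnt["input"] - cnt["after_cv_filter"]
  expect_gte(excluded_rows, 0)
  # poor samples fall to the 50% rule
  expect_true(all(c("NPDR_01", "PDR_02") %in%
                    res$report$excluded_samples$sample))
})

test_that("planted two-fold markers survive the cascade with accurate FC", {
  set.seed(37)
  design <- cohort_design(n_per_group = c(NPDR = 60L, PDR = 60L, NVG = 2L))
  tl <- small_transition_list()
  truth <- default_truth(
    effects1 = c(TGT1 = 1),   # 2-fold PDR vs NPDR on protein TGT1
    cv_target = 0.10)
  peaks <- generate_mrm_peak_areas(design, tl, truth, seed = 37)
  res <- mrm_qc(peaks)
  groups <- sub("_.*", "", colnames(res$quantities))
  mk <- classify_markers(res$quantities, groups, c("PDR", "NPDR"),
                         proteins = attr(res$quantities, "protein"))
  fc <- mk$log2fc[mk$protein == "TGT1"]
  expect_length(fc, 2L)
  expect_true(all(abs(fc - 1) < 0.5))   # ~3 SE at n = 60 per arm
  null_fc <- mk$log2fc[mk$protein == "TGT2"]
  expect_length(null_fc, 2L)
  expect_true(all(abs(null_fc) < 0.5))
  expect_true(all(fc > null_fc))
})

test_that("peak tables round-trip through disk", {
  tb <- tiny_peaks()
  path <- tempfile(fileext = ".csv")
  write_peak_areas(tb, path)
  back <- read_peak_areas(path)
  expect_equal(back$area, tb$area)
  expect_identical(back$transition, tb$transition)
})
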