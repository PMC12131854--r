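# Targeted-MS (MRM) quality-control cascade: spike-in normalization,
# detection, sample and CV filters, and per-peptide quantities.

#' β-galactosidase spike-in peptides
#'
#' The four E. coli β-galactosidase peptides spiked into every sample before
#' digestion as process controls, used for loading normalization.
#' @export
SPIKEIN_PEPTIDES <- c("APLDNDIGVSEATR", "VDEDQPFPAVPK",
                      "IDPNAWVER", "VNWLGLGPQENYPDR")

.check_peak_table <- function(table) {
  need <- c("sample", "replicate", "protein", "peptide", "transition", "area")
  stopifnot(all(need %in% names(table)))
  if (any(!is.finite(table$area)) || any(table$area < 0)) {
    stop("areas must be finite and >= 0")
  }
  key <- paste(table$sample, table$replicate, table$transition)
  if (anyDuplicated(key)) stop("duplicate (sample, replicate, transition) rows")
  invisible(table)
}

#' Spike-in loading normalization
#'
#' Computes, per (sample, replicate), the geometric mean of the spike-in
#' transition areas, divides it by the cohort-wide median of those geometric
#' means to obtain the loading factor, and divides every area by its
#' factor. Spike-in rows are retained and flagged. Samples with no positive
#' spike-in area are excluded with a reason.
#'
#' @param table Long-format peak-area data.frame with columns `sample`,
#'   `replicate`, `protein`, `peptide`, `transition`, `area`.
#' @param spikein_peptides Peptide sequences treated as spike-ins.
#' @return List with `table` (normalized; gains `area_raw`, `is_spikein`,
#'   `norm_factor`), `factors` (per sample/replicate), `excluded_samples`.
#' @export
normalize_spikein <- function(table, spikein_peptides = SPIKEIN_PEPTIDES) {
  .check_peak_table(table)
  tb <- table
  if (is.null(tb$area_raw)) tb$area_raw <- tb$area
  tb$is_spikein <- tb$peptide %in% spikein_peptides
  key <- paste(tb$sample, tb$replicate, sep = "\r")
  sp <- tb[tb$is_spikein & tb$area > 0, , drop = FALSE]
  gm <- tapply(log(sp$area), paste(sp$sample, sp$replicate, sep = "\r"),
               function(z) exp(mean(z)))
  bad <- setdiff(unique(key), names(gm))
  bad_samples <- unique(tb$sample[key %in% bad])
  if (length(bad_samples) > 0L) {
    tb <- tb[!(tb$sample %in% bad_samples), , drop = FALSE]
    key <- paste(tb$sample, tb$replicate, sep = "\r")
  }
  factors <- as.numeric(gm / stats::median(gm))
  names(factors) <- names(gm)
  tb$norm_factor <- unname(factors[key])
  tb$area <- tb$area / tb$norm_factor
  rownames(tb) <- NULL
  list(table = tb,
       factors = data.frame(
         sample = sub("\r.*", "", names(factors)),
         replicate = sub(".*\r", "", names(factors)),
         factor = unname(factors), stringsAsFactors = FALSE),
       excluded_samples = bad_samples)
}

#' Transition detection flags
#'
#' A transition observation is detected when its peak area strictly exceeds
#' the instrument-scale threshold (10^3 by default). Detection is assessed
#' on raw, pre-normalization areas by default, since the threshold is an
#' instrument constant; a transition counts as detected in a sample only
#' when it is detected in every technical replicate.
#'
#' @param table Peak-area table (normalized or not; `area_raw` is used when
#'   present and `use_raw` is TRUE).
#' @param area_threshold Detection threshold (strict `>`).
#' @param use_raw Assess detection on pre-normalization areas.
#' @return The table with logical columns `detected` (per observation) and
#'   `detected_sample` (per sample x transition, both replicates).
#' @export
detection_filter <- function(table, area_threshold = 1e3, use_raw = TRUE) {
  tb <- table
  basis <- if (use_raw && !is.null(tb$area_raw)) tb$area_raw else tb$area
  tb$detected <- basis > area_threshold
  key <- paste(tb$sample, tb$transition, sep = "\r")
  all_det <- tapply(tb$detected, key, all)
  tb$detected_sample <- unname(all_det[key])
  tb
}

#' Sample-level detection filter
#'
#' Excludes samples in which fewer than `min_fraction` of the target
#' transitions are detected. Spike-in transitions are excluded from both
#' numerator and denominator. Exactly `min_fraction` detected is retained
#' (the rule removes strictly "fewer than" the cutoff).
#'
#' @param table Output of [detection_filter()] (must carry `detected_sample`
#'   and `is_spikein`).
#' @param min_fraction Minimum detected fraction (default 0.5).
#' @return List with `table` (surviving rows) and `excluded` (data.frame
#'   sample/fraction).
#' @export
sample_filter <- function(table, min_fraction = 0.5) {
  stopifnot(!is.null(table$detected_sample), !is.null(table$is_spikein))
  tgt <- table[!table$is_spikein, , drop = FALSE]
  st <- unique(tgt[c("sample", "transition", "detected_sample")])
  frac <- tapply(st$detected_sample, st$sample, mean)
  drop_samples <- names(frac)[frac < min_fraction]
  list(table = table[!(table$sample %in% drop_samples), , drop = FALSE],
       excluded = data.frame(sample = drop_samples,
                             detected_fraction = unname(frac[drop_samples]),
                             stringsAsFactors = FALSE))
}

#' Technical-duplicate CV filter
#'
#' Per transition and sample, the coefficient of variation is the sample
#' standard deviation over the replicate (normalized) areas divided by their
#' mean. Each transition's summary CV is the median over the samples where
#' it was detected; transitions whose summary CV meets or exceeds
#' `cv_threshold` are removed cohort-wide, as are transitions detected in
#' fewer than `min_samples` samples.
#'
#' @param table Output of [sample_filter()] (or [detection_filter()]).
#' @param cv_threshold Removal threshold (rule: pass when CV < threshold).
#' @param min_samples Minimum samples with detection per transition.
#' @return List with `table` (surviving rows), `excluded` (transition,
#'   summary CV, reason), and `cv_by_sample` (audit table).
#' @export
cv_filter <- function(table, cv_threshold = 0.20, min_samples = 3L) {
  stopifnot(!is.null(table$detected_sample))
  key <- paste(table$sample, table$transition, sep = "\r")
  cv_one <- tapply(table$area, key, function(a)
    if (length(a) < 2L || mean(a) == 0) NA_real_ else stats::sd(a) / mean(a))
  det <- tapply(table$detected_sample, key, all)
  cv_tab <- data.frame(
    sample = sub("\r.*", "", names(cv_one)),
    transition = sub(".*\r", "", names(cv_one)),
    cv = unname(cv_one), detected = unname(det),
    stringsAsFactors = FALSE)
  per_tr <- split(cv_tab, cv_tab$transition)
  summary_cv <- vapply(per_tr, function(d) {
    v <- d$cv[d$detected & !is.na(d$cv)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1L))
  n_det <- vapply(per_tr, function(d) sum(d$detected), integer(1L))
  spike_tr <- unique(table$transition[table$is_spikein])
  reason <- rep(NA_character_, length(summary_cv))
  names(reason) <- names(summary_cv)
  target <- !(names(summary_cv) %in% spike_tr)
  reason[target & n_det < min_samples] <- "insufficient observations"
  reason[target & is.na(reason) &
           (is.na(summary_cv) | summary_cv >= cv_threshold)] <-
    sprintf("CV >= %.2f", cv_threshold)
  drop_tr <- names(reason)[!is.na(reason)]
  list(table = table[!(table$transition %in% drop_tr), , drop = FALSE],
       excluded = data.frame(transition = drop_tr,
                             summary_cv = unname(summary_cv[drop_tr]),
                             reason = unname(reason[drop_tr]),
                             stringsAsFactors = FALSE),
       cv_by_sample = cv_tab)
}

#' Per-peptide quantities
#'
#' A peptide is quantified in a sample when at least `min_transitions` of
#' its surviving transitions are detected there; the quantity is the mean
#' over technical replicates of the sum of its surviving transition areas
#' (normalized scale). Spike-in peptides are excluded.
#'
#' @param table Peak-area table after the filters.
#' @param min_transitions Minimum detected transitions per quantified
#'   peptide (default 3, matching the 3-transition design).
#' @return Matrix peptides x samples of quantities, `NA` where not
#'   quantified; peptide -> protein map in `attr(, "protein")`.
#' @export
peptide_quantity <- function(table, min_transitions = 3L) {
  tb <- table[!table$is_spikein, , drop = FALSE]
  if (nrow(tb) == 0L) return(matrix(numeric(), 0L, 0L))
  peptides <- sort(unique(tb$peptide))
  samples <- sort(unique(tb$sample))
  out <- matrix(NA_real_, length(peptides), length(samples),
                dimnames = list(peptides, samples))
  for (p in peptides) {
    sub <- tb[tb$peptide == p, , drop = FALSE]
    for (s in unique(sub$sample)) {
      ss <- sub[sub$sample == s, , drop = FALSE]
      n_det <- length(unique(ss$transition[ss$detected_sample]))
      if (n_det < min_transitions) next
      per_rep <- tapply(ss$area, ss$replicate, sum)
      out[p, s] <- mean(per_rep)
    }
  }
  prot <- tb$protein[match(peptides, tb$peptide)]
  attr(out, "protein") <- stats::setNames(prot, peptides)
  out
}

#' Full MRM quality-control cascade
#'
#' Runs the order-fixed cascade: spike-in normalization, detection flagging,
#' sample filter, CV filter, peptide quantities. Each stage only removes
#' rows; rerunning the cascade on its own surviving table is a no-op
#' (normalization factors come out 1 and detection reuses the retained raw
#' areas).
#'
#' @param table Raw long-format peak-area table.
#' @param spikein_peptides Spike-in peptide sequences.
#' @param area_threshold,min_fraction,cv_threshold,min_samples,min_transitions
#'   Stage parameters; see the stage functions.
#' @return Object of class `mrm_qc`: list with `quantities` (peptide x
#'   sample matrix), `table` (surviving rows), and `report` (class
#'   `qc_report`).
#' @export
mrm_qc <- function(table, spikein_peptides = SPIKEIN_PEPTIDES,
                   area_threshold = 1e3, min_fraction = 0.5,
                   cv_threshold = 0.20, min_samples = 3L,
                   min_transitions = 3L) {
  n_input <- nrow(table)
  norm <- normalize_spikein(table, spikein_peptides)
  det <- detection_filter(norm$table, area_threshold)
  sf <- sample_filter(det, min_fraction)
  cf <- cv_filter(sf$table, cv_threshold, min_samples)
  q <- peptide_quantity(cf$table, min_transitions)
  quantified <- rownames(q)[rowSums(!is.na(q)) > 0L]
  all_peps <- setdiff(unique(table$peptide), spikein_peptides)
  report <- structure(list(
    n_input_rows = n_input,
    counts = c(input = n_input,
               after_normalization = nrow(norm$table),
               after_sample_filter = nrow(sf$table),
               after_cv_filter = nrow(cf$table)),
    excluded_samples = rbind(
      if (length(norm$excluded_samples) > 0L)
        data.frame(sample = norm$excluded_samples,
                   detected_fraction = NA_real_,
                   reason = "no positive spike-in areas",
                   stringsAsFactors = FALSE),
      if (nrow(sf$excluded) > 0L)
        cbind(sf$excluded, reason = "fewer than 50% transitions detected")),
    excluded_transitions = cf$excluded,
    excluded_peptides = setdiff(all_peps, quantified),
    cv_by_sample = cf$cv_by_sample,
    factors = norm$factors
  ), class = "qc_report")
  structure(list(quantities = q, table = cf$table, report = report),
            class = "mrm_qc")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("MRM QC report\n")
  cat("  rows: ", paste(sprintf("%s=%d", names(x$counts), x$counts),
                        collapse = " -> "), "\n")
  ns <- if (is.null(x$excluded_samples)) 0L else nrow(x$excluded_samples)
  cat("  samples excluded:", ns, "\n")
  cat("  transitions excluded:", nrow(x$excluded_transitions), "\n")
  cat("  peptides not quantified:", length(x$excluded_peptides), "\n")
  invisible(x)
}

#' @export
print.mrm_qc <- function(x, ...) {
  print(x$report)
  cat(sprintf("  quantities: %d peptides x %d samples\n",
              nrow(x$quantities), ncol(x$quantities)))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report `qc_report` object.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read / write long-format peak-area tables
#'
#' @param table Peak-area data.frame.
#' @param path CSV path.
#' @export
write_peak_areas <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_peak_areas
#' @export
read_peak_areas <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample = "character",
                                 protein = "character",
                                 peptide = "character",
                                 transition = "character"))
}
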