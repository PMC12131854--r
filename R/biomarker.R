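# Rank-based biomarker validation statistics: Wilcoxon rank-sum, ROC/AUC,
# multiplicity adjustment, and tier classification.

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of distributional shift between two samples. For combined
#' n <= `exact_max` without ties, the p-value is exact, computed by full
#' enumeration of the U distribution over all group labelings of the ranks.
#' Otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric vectors, each with at least one observation.
#' @param exact_max Largest combined sample size for the exact branch.
#' @return List with `U` (number of (x, y) pairs with x > y, ties counted
#'   half), `p_value`, and `method` ("exact" or "normal approximation").
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = u, p_value = 1, method = "degenerate"))
  }
  if (N <= exact_max && !ties) {
    # enumerate U over all C(N, n1) assignments of ranks 1..N to group x
    combs <- utils::combn(N, n1)
    u_all <- colSums(combs) - n1 * (n1 + 1) / 2
    lo <- mean(u_all <= u)
    hi <- mean(u_all >= u)
    p <- min(1, 2 * min(lo, hi))
    return(list(U = u, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_counts <- table(c(x, y))
  tie_term <- sum(tie_counts^3 - tie_counts) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sigma   # continuity correction
  p <- 2 * stats::pnorm(-abs(z))
  list(U = u, p_value = min(1, p), method = "normal approximation")
}

#' ROC area under the curve
#'
#' AUC via the rank-sum identity: the fraction of (case, control) pairs in
#' which the case value exceeds the control value, ties counted one half.
#' When the raw AUC is below 0.5 the orientation is flipped (marker lower in
#' cases) and the flip recorded.
#'
#' @param case_values,control_values Numeric vectors, non-empty.
#' @param orient Flip orientation so the reported AUC is >= 0.5
#'   (default TRUE).
#' @return List with `auc`, `auc_raw` (case-high orientation), `flipped`.
#' @export
roc_auc <- function(case_values, control_values, orient = TRUE) {
  case_values <- case_values[!is.na(case_values)]
  control_values <- control_values[!is.na(control_values)]
  n1 <- length(case_values); n2 <- length(control_values)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(case_values, control_values))
  auc_raw <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  flipped <- orient && auc_raw < 0.5
  list(auc = if (flipped) 1 - auc_raw else auc_raw,
       auc_raw = auc_raw, flipped = flipped)
}

#' ROC curve coordinates
#'
#' Sensitivity / 1-specificity pairs over all observed thresholds, for
#' plotting a marker's ROC curve.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `tpr`, `fpr`.
#' @export
roc_curve <- function(case_values, control_values) {
  th <- sort(unique(c(case_values, control_values, Inf)), decreasing = TRUE)
  data.frame(
    threshold = th,
    tpr = vapply(th, function(t) mean(case_values >= t), numeric(1L)),
    fpr = vapply(th, function(t) mean(control_values >= t), numeric(1L))
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, order-preserving);
#' NAs propagate.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment method, `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = method)
}

#' Classify validated biomarker peptides
#'
#' Computes per-peptide fold change (log2 ratio of group means), Wilcoxon
#' p-value, BH-adjusted p, and AUC for one case/control contrast, then tiers
#' each peptide: `candidate` when AUC > 0.7 and the fold-change direction
#' agrees with the profiling experiment, `strong` additionally when
#' AUC > 0.9 (both cutoffs strict). Significance requires adjusted p < 0.05.
#'
#' @param quantities Peptides x samples matrix of (normalized) quantities;
#'   `NA` marks samples where a peptide was not quantified.
#' @param groups Character/factor of group labels, one per column.
#' @param contrast `c(case_group, control_group)`.
#' @param directions Named numeric vector: expected sign of log2 fold change
#'   per protein (or peptide) from the profiling experiment; peptides absent
#'   from the map skip the concordance check and are flagged.
#' @param proteins Optional named map peptide -> protein for reporting and
#'   direction lookup (falls back to the peptide name).
#' @param auc_candidate,auc_strong,alpha Tier and significance cutoffs.
#' @return Object of class `marker_result`: data.frame with one row per
#'   peptide (log2fc, p_raw, p_adj, auc, tier, significant,
#'   direction_checked, direction_concordant).
#' @export
classify_markers <- function(quantities, groups, contrast, directions = NULL,
                             proteins = NULL, auc_candidate = 0.7,
                             auc_strong = 0.9, alpha = 0.05) {
  stopifnot(length(groups) == ncol(quantities),
            all(contrast %in% groups), length(contrast) == 2L)
  case_idx <- which(groups == contrast[1L])
  ctrl_idx <- which(groups == contrast[2L])
  peps <- rownames(quantities)
  if (is.null(peps)) peps <- paste0("peptide", seq_len(nrow(quantities)))
  res <- data.frame(
    peptide = peps,
    protein = if (is.null(proteins)) peps else
      unname(proteins[peps]),
    contrast = paste(contrast[1L], "vs", contrast[2L]),
    log2fc = NA_real_, p_raw = NA_real_, auc = NA_real_,
    auc_flipped = NA, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(quantities))) {
    x <- as.numeric(quantities[i, case_idx]); x <- x[!is.na(x)]
    y <- as.numeric(quantities[i, ctrl_idx]); y <- y[!is.na(y)]
    if (length(x) < 1L || length(y) < 1L) next
    res$log2fc[i] <- log2(mean(x) / mean(y))
    res$p_raw[i] <- wilcoxon_rank_sum(x, y)$p_value
    a <- roc_auc(x, y)
    res$auc[i] <- a$auc
    res$auc_flipped[i] <- a$flipped
  }
  res$p_adj <- bh_adjust(res$p_raw)
  dir_key <- ifelse(is.na(res$protein), res$peptide, res$protein)
  res$direction_checked <- !is.null(directions) &
    (dir_key %in% names(directions) | res$peptide %in% names(directions))
  expected <- rep(NA_real_, nrow(res))
  if (!is.null(directions)) {
    expected <- ifelse(res$peptide %in% names(directions),
                       directions[res$peptide], directions[dir_key])
  }
  res$direction_concordant <- ifelse(
    res$direction_checked, sign(res$log2fc) == sign(expected), NA)
  pass_dir <- !res$direction_checked | res$direction_concordant %in% TRUE
  res$tier <- ifelse(res$auc > auc_strong & pass_dir, "strong",
              ifelse(res$auc > auc_candidate & pass_dir, "candidate", "none"))
  res$tier[is.na(res$auc)] <- "none"
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  class(res) <- c("marker_result", "data.frame")
  res
}

#' @export
print.marker_result <- function(x, ...) {
  cat("Biomarker validation:", x$contrast[1L], "—", nrow(x), "peptides\n")
  cat("  candidate tier (AUC > 0.7):", sum(x$tier != "none"), "\n")
  cat("  strong tier (AUC > 0.9):  ", sum(x$tier == "strong"), "\n")
  cat("  adjusted p < 0.05:        ", sum(x$significant), "\n")
  NextMethod()
}

#' Write a marker result table
#'
#' @param x `marker_result` object.
#' @param path Output CSV path.
#' @export
write_marker_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}
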