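# Profiling-stage differential expression: platform-specific DEP calling and
# cross-platform candidate selection.

#' Construct an intensity matrix
#'
#' Container for a proteins x samples quantification table on the log2
#' scale with a platform tag and per-sample group labels. Missing entries
#' (`NA`) are allowed on the LFQ platform only; isobaric-tag reporter
#' matrices are complete by construction.
#'
#' @param values Numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns, log2 scale.
#' @param platform `"LFQ"` or `"TMT"`.
#' @param groups Character/factor group label per column.
#' @return Object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, platform = c("LFQ", "TMT"), groups) {
  platform <- match.arg(platform)
  stopifnot(is.matrix(values), length(groups) == ncol(values),
            !is.null(rownames(values)))
  if (platform == "TMT" && anyNA(values)) {
    stop("TMT matrices must have no missing entries")
  }
  structure(list(values = values, platform = platform,
                 groups = as.character(groups)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix (%s): %d proteins x %d samples\n",
              x$platform, nrow(x$values), ncol(x$values)))
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  cat("  missing entries:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' Classic Student's two-sided t test with a pooled variance estimate
#' (Welch available via `var_equal = FALSE`), used for the profiling-stage
#' per-protein comparisons.
#'
#' @param x,y Numeric vectors with at least two non-missing values each.
#' @param var_equal Pool the variances (default TRUE).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each side needs >= 2 non-missing values")
  }
  df0 <- length(x) + length(y) - 2L
  if (stats::sd(c(x, y)) == 0) {
    return(list(statistic = 0, df = df0, p_value = 1))
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # distinct constants: separation is perfect, the t statistic diverges
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, df = df0,
                p_value = 0))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Platform-specific differential expression calls
#'
#' Per-protein contrast on one platform. The fold change is the difference of
#' group means on the log2 scale. The call rule is platform-specific:
#' LFQ calls on fold change alone (|log2FC| >= `lfq_fc`); TMT requires both
#' p < `alpha` from the pooled t test and |log2FC| >= `tmt_fc`.
#'
#' Missing-value handling (LFQ): when one group is partially missing, the
#' available values of that group are compared to the mean of the fully
#' observed group (`basis = "missing-fallback"`). When a protein is entirely
#' missing in one group it is a group-specific protein: the fold change is
#' capped at `±max_abs_fc` toward the observed group and no p-value is
#' computed (`basis = "group-specific"`).
#'
#' @param x An [intensity_matrix()].
#' @param contrast `c(case_group, control_group)`.
#' @param lfq_fc,tmt_fc,alpha Call thresholds.
#' @param max_abs_fc Log2 cap for group-specific proteins.
#' @param var_equal Passed to [two_sample_t()].
#' @return data.frame, one row per protein: `protein`, `contrast`, `log2fc`,
#'   `p_value`, `call`, `basis`.
#' @export
dep_call <- function(x, contrast, lfq_fc = 1, tmt_fc = 0.58, alpha = 0.05,
                     max_abs_fc = 10, var_equal = TRUE) {
  stopifnot(inherits(x, "intensity_matrix"), length(contrast) == 2L)
  if (!all(contrast %in% x$groups)) stop("contrast group absent from matrix")
  ci <- which(x$groups == contrast[1L])
  ki <- which(x$groups == contrast[2L])
  v <- x$values
  out <- data.frame(protein = rownames(v),
                    contrast = paste(contrast[1L], "vs", contrast[2L]),
                    log2fc = NA_real_, p_value = NA_real_,
                    call = FALSE, basis = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(v))) {
    a <- v[i, ci]; b <- v[i, ki]
    na_a <- sum(is.na(a)); na_b <- sum(is.na(b))
    if (na_a == length(a) && na_b == length(b)) {
      out$basis[i] <- "group-specific"   # seen nowhere in this contrast
      next
    }
    if (na_a == length(a) || na_b == length(b)) {
      sgn <- if (na_b == length(b)) 1 else -1
      out$log2fc[i] <- sgn * max_abs_fc
      out$basis[i] <- "group-specific"
    } else if (na_a > 0L || na_b > 0L) {
      out$log2fc[i] <- mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)
      out$basis[i] <- "missing-fallback"
      av <- a[!is.na(a)]; bv <- b[!is.na(b)]
      if (length(av) >= 2L && length(bv) >= 2L) {
        out$p_value[i] <- two_sample_t(av, bv, var_equal)$p_value
      }
    } else {
      out$log2fc[i] <- mean(a) - mean(b)
      out$basis[i] <- "normal"
      if (length(a) >= 2L && length(b) >= 2L) {
        out$p_value[i] <- two_sample_t(a, b, var_equal)$p_value
      }
    }
  }
  if (x$platform == "LFQ") {
    out$call <- !is.na(out$log2fc) & abs(out$log2fc) >= lfq_fc
  } else {
    out$call <- !is.na(out$log2fc) & !is.na(out$p_value) &
      out$p_value < alpha & abs(out$log2fc) >= tmt_fc
  }
  out
}

#' Cross-platform candidate selection
#'
#' Per platform, takes the union of called proteins over the supplied
#' contrasts; the final candidates are the intersection (default) or union
#' of the two platform sets, ordered by descending maximum |log2FC| across
#' all results, ties broken lexicographically.
#'
#' @param lfq_results,tmt_results Lists of [dep_call()] result data.frames,
#'   one per contrast.
#' @param rule `"intersection"` (default) or `"union"` of the platform sets.
#' @return Character vector of candidate protein ids, deterministically
#'   ordered.
#' @export
candidate_selection <- function(lfq_results, tmt_results,
                                rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  called <- function(results) {
    unique(unlist(lapply(results, function(r) r$protein[r$call])))
  }
  lfq_set <- called(lfq_results)
  tmt_set <- called(tmt_results)
  cand <- if (rule == "intersection") intersect(lfq_set, tmt_set)
          else union(lfq_set, tmt_set)
  if (length(cand) == 0L) return(character())
  all_res <- do.call(rbind, c(lfq_results, tmt_results))
  all_res <- all_res[!is.na(all_res$log2fc), , drop = FALSE]
  max_fc <- tapply(abs(all_res$log2fc), all_res$protein, max)
  cand[order(-max_fc[cand], cand)]
}

#' Cross-platform identification overlap
#'
#' @param lfq_proteins,tmt_proteins Character vectors of identified proteins.
#' @return Named integer vector `(common, lfq_only, tmt_only)`.
#' @export
platform_overlap <- function(lfq_proteins, tmt_proteins) {
  lfq_proteins <- unique(lfq_proteins)
  tmt_proteins <- unique(tmt_proteins)
  c(common = length(intersect(lfq_proteins, tmt_proteins)),
    lfq_only = length(setdiff(lfq_proteins, tmt_proteins)),
    tmt_only = length(setdiff(tmt_proteins, lfq_proteins)))
}

#' Read / write intensity matrices as delimited text
#'
#' The matrix is stored as CSV with proteins in rows ("NA" for missing); the
#' sample annotation (sample, group, platform) travels in a sidecar CSV.
#'
#' @param x An [intensity_matrix()].
#' @param path Matrix CSV path; the annotation sidecar is `<path>.samples.csv`.
#' @export
write_intensity_matrix <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  utils::write.csv(data.frame(protein = rownames(x$values), x$values,
                              check.names = FALSE),
                   path, row.names = FALSE, na = "NA")
  utils::write.csv(data.frame(sample = colnames(x$values), group = x$groups,
                              platform = x$platform),
                   paste0(path, ".samples.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_matrix
#' @export
read_intensity_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ann <- utils::read.csv(paste0(path, ".samples.csv"),
                         stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$protein
  intensity_matrix(m, platform = ann$platform[1L],
                   groups = ann$group[match(colnames(m), ann$sample)])
}
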