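# Stage-wise single-sample gene-set enrichment with the NES-difference
# statistic and an empirical, gene-permutation FDR.

#' Read / write gene-set collections (GMT)
#'
#' Tab-separated GMT: set name, description, then member identifiers.
#'
#' @param path GMT file path.
#' @param min_size,max_size Set-size bounds applied after reading (and, in
#'   the analysis, after intersection with the measured universe).
#' @return Named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path, min_size = 5L, max_size = Inf) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1L), 1L)
  desc <- vapply(parts, `[`, character(1L), 2L)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  sets <- sets[keep]
  attr(sets, "description") <- desc[keep]
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample enrichment score
#'
#' Integrated-difference enrichment score of one gene set in one expression
#' profile: genes are ranked by decreasing expression, and the score is the
#' sum over ranked positions of the difference between the weighted
#' empirical distribution of hits (weights = rank value^alpha, normalized
#' over hits; rank value N for the top gene down to 1) and the uniform
#' distribution of misses.
#'
#' @param expression Named numeric vector, one profile over the measured
#'   universe.
#' @param gene_set Character vector of member identifiers.
#' @param alpha Rank-weighting exponent (0 = unweighted).
#' @return Numeric enrichment score.
#' @export
ssgsea_es <- function(expression, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(expression)))
  universe <- names(expression)
  hits_genes <- intersect(gene_set, universe)
  if (length(hits_genes) == 0L) stop("gene set does not intersect universe")
  if (length(hits_genes) == length(universe)) {
    stop("gene set covers the whole universe; misses undefined")
  }
  ord <- order(expression, decreasing = TRUE)
  n <- length(expression)
  is_hit <- names(expression)[ord] %in% hits_genes
  rank_value <- n - seq_len(n) + 1   # N for top gene, 1 for bottom
  w <- abs(rank_value)^alpha * is_hit
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!is_hit) / sum(!is_hit)
  sum(p_hit - p_miss)
}

#' Stage-wise enrichment with NES differences and empirical FDR
#'
#' Computes per-stage enrichment scores for every gene set, normalizes them
#' against a gene-permutation null (size-matched random sets drawn from the
#' universe, shared across sets of equal size), derives the per-stage
#' NES difference (stage NES minus the mean NES across stages), and an
#' empirical significance: the fraction of null |NES| at the set's size that
#' meet or exceed the observed |NES|, Benjamini-Hochberg adjusted across
#' sets. A set passes the gate when its adjusted FDR < 0.05 in the stage.
#'
#' @param expression Numeric matrix, genes x stages (one profile per
#'   stage), rownames = gene ids.
#' @param gene_sets Named list of character vectors.
#' @param alpha Rank-weighting exponent for [ssgsea_es()].
#' @param n_permutations Null sets per distinct set size (>= 100 advised).
#' @param min_size Minimum set size after intersection with the universe.
#' @param seed Integer seed for the permutation null.
#' @return Object of class `enrichment_result`: data.frame with one row per
#'   gene set x stage: `set`, `stage`, `size`, `es`, `nes`, `nes_diff`,
#'   `fdr`.
#' @export
nes_and_fdr <- function(expression, gene_sets, alpha = 0.25,
                        n_permutations = 1000L, min_size = 5L, seed = 1L) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  if (n_permutations < 100L) {
    warning("fewer than 100 permutations; FDR estimates will be coarse")
  }
  universe <- rownames(expression)
  sets <- lapply(gene_sets, intersect, universe)
  sets <- sets[lengths(sets) >= min_size & lengths(sets) < length(universe)]
  if (length(sets) == 0L) stop("no gene set of sufficient size in universe")
  stages <- colnames(expression)
  if (is.null(stages)) stages <- paste0("stage", seq_len(ncol(expression)))

  # precompute per-stage orderings once; ES then only needs the hit mask
  n <- length(universe)
  rank_w <- (n - seq_len(n) + 1)^alpha
  stage_order <- lapply(seq_along(stages), function(s)
    universe[order(expression[, s], decreasing = TRUE)])
  es_fast <- function(ordered_names, gs) {
    is_hit <- ordered_names %in% gs
    w <- rank_w * is_hit
    sum(cumsum(w) / sum(w) - cumsum(!is_hit) / sum(!is_hit))
  }
  es <- sapply(seq_along(stages), function(s)
    vapply(sets, function(gs) es_fast(stage_order[[s]], gs), numeric(1L)))
  es <- matrix(es, nrow = length(sets),
               dimnames = list(names(sets), stages))

  # gene-permutation null, one block per distinct set size, shared across
  # sets of that size; null ES pooled over stages
  sizes <- lengths(sets)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  null_by_size <- lapply(sort(unique(sizes)), function(k) {
    vals <- matrix(NA_real_, n_permutations, length(stages))
    for (j in seq_len(n_permutations)) {
      gs <- sample(universe, k)
      for (s in seq_along(stages)) {
        vals[j, s] <- es_fast(stage_order[[s]], gs)
      }
    }
    as.numeric(vals)
  })
  names(null_by_size) <- as.character(sort(unique(sizes)))

  res <- do.call(rbind, lapply(names(sets), function(nm) {
    null_es <- null_by_size[[as.character(sizes[[nm]])]]
    denom <- mean(abs(null_es))
    nes <- es[nm, ] / denom
    nes_diff <- nes - mean(nes)
    p_emp <- vapply(nes, function(v)
      mean(abs(null_es) / denom >= abs(v)), numeric(1L))
    data.frame(set = nm, stage = stages, size = sizes[[nm]],
               es = unname(es[nm, ]), nes = unname(nes),
               nes_diff = unname(nes_diff), p_emp = unname(p_emp),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  # BH across sets, within stage
  res$fdr <- NA_real_
  for (st in stages) {
    idx <- res$stage == st
    res$fdr[idx] <- bh_adjust(res$p_emp[idx])
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Stage-wise enrichment:", length(unique(x$set)), "gene sets x",
      length(unique(x$stage)), "stages\n")
  cat("  sets with FDR < 0.05 in any stage:",
      length(unique(x$set[x$fdr < 0.05])), "\n")
  NextMethod()
}

#' Export enrichment results for circular plotting
#'
#' Writes `set, stage, nes_diff, fdr` as CSV, the layout a circular bar
#' plot of stage-wise NES differences consumes.
#'
#' @param x `enrichment_result`.
#' @param path Output CSV path.
#' @export
write_enrichment <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("set", "stage", "nes_diff", "fdr")],
                   path, row.names = FALSE)
  invisible(path)
}
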