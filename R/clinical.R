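# Clinical-cohort statistics: sample size, contingency tests, odds ratios,
# covariate-adjusted regression, stratified re-testing.

#' Per-group sample size for a two-group comparison
#'
#' Classic normal-approximation formula n = (z_alpha + z_beta)^2 * 2 / d^2
#' for the per-group size of a two-sample comparison at standardized effect
#' size d, two-sided significance alpha and power 1 - beta.
#'
#' @param d Standardized effect size (Cohen's d), > 0.
#' @param alpha Two-sided significance level (used when `z_alpha` missing).
#' @param power Target power (used when `z_beta` missing).
#' @param z_alpha,z_beta Optional explicit critical values; when supplied they
#'   override `alpha`/`power` (e.g. the conventional rounded 1.96 / 1.28).
#' @return List with `n_raw`, `n_per_group` (ceiling), `n_total`
#'   (ceiling of twice the raw size).
#' @examples
#' sample_size(d = 0.759, z_alpha = 1.96, z_beta = 1.28)
#' @export
sample_size <- function(d, alpha = 0.05, power = 0.90,
                        z_alpha = NULL, z_beta = NULL) {
  stopifnot(d > 0)
  if (is.null(z_alpha)) {
    stopifnot(alpha > 0, alpha < 1)
    z_alpha <- stats::qnorm(1 - alpha / 2)
  }
  if (is.null(z_beta)) {
    stopifnot(power > 0, power < 1)
    z_beta <- stats::qnorm(power)
  }
  n_raw <- (z_alpha + z_beta)^2 * 2 / d^2
  # round away floating slop before the ceiling so algebraically integral
  # designs are not bumped up a whole participant
  list(n_raw = n_raw,
       n_per_group = as.integer(ceiling(round(n_raw, 9))),
       n_total = as.integer(ceiling(round(2 * n_raw, 9))))
}

#' Pearson chi-square test on an R x C table
#'
#' Pearson chi-square without continuity correction, the convention used for
#' the cohort-comparison frequency tables.
#'
#' @param table Matrix of counts with positive row and column sums.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_rc <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) <= 0) || any(colSums(table) <= 0)) {
    stop("degenerate table: zero row or column sum")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

# Enumerate all 2 x K tables with the observed margins; returns first-row
# count vectors and their multivariate hypergeometric probabilities.
.enumerate_2xk <- function(col_sums, r1) {
  k <- length(col_sums)
  grids <- lapply(col_sums, function(cs) 0:min(cs, r1))
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  combos <- combos[rowSums(combos) == r1, , drop = FALSE]
  logp <- apply(combos, 1L, function(a)
    sum(lchoose(col_sums, as.numeric(a))) - lchoose(sum(col_sums), r1))
  list(tables = as.matrix(combos), prob = exp(logp))
}

#' Exact test for a 2 x K contingency table
#'
#' Two-sided Fisher exact test; for K > 2 this is the Freeman-Halton
#' extension: the p-value sums the multivariate hypergeometric probabilities
#' (margins fixed) of every table whose probability does not exceed the
#' observed table's. Computed by full enumeration, so totals must be modest.
#'
#' @param table 2 x K matrix of counts (first row = cases).
#' @param max_tables Safety cap on the enumeration size.
#' @return List with `p_value`, `n_tables` enumerated, and the total
#'   enumerated probability `prob_total` (== 1 up to rounding).
#' @examples
#' fisher_exact(rbind(c(2, 0, 0), c(35, 38, 9)))
#' @export
fisher_exact <- function(table, max_tables = 1e6) {
  table <- as.matrix(table)
  if (nrow(table) != 2L) stop("fisher_exact expects a 2 x K table")
  col_sums <- colSums(table)
  r1 <- sum(table[1L, ])
  n_grid <- prod(vapply(col_sums, function(cs) min(cs, r1) + 1, numeric(1L)))
  if (n_grid > max_tables) {
    stop("table too large for enumeration; use chi_square_rc() instead")
  }
  enum <- .enumerate_2xk(col_sums, r1)
  obs_idx <- which(apply(enum$tables, 1L, function(a)
    all(a == table[1L, ])))
  p_obs <- enum$prob[obs_idx]
  # tolerance guards against ties lost to floating rounding
  p <- sum(enum$prob[enum$prob <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1), n_tables = nrow(enum$tables),
       prob_total = sum(enum$prob))
}

#' Odds ratio of a 2 x 2 table
#'
#' OR = ad/bc with the Haldane-Anscombe +0.5 correction applied to every cell
#' when any cell is zero, and a Woolf (log-scale normal) 95% confidence
#' interval. The log2 OR is reported for plotting on a symmetric axis.
#'
#' @param table 2 x 2 matrix of counts.
#' @param conf_level Confidence level for the Woolf interval.
#' @return List with `or`, `log2_or`, `ci` (length-2 OR-scale interval),
#'   and `corrected` (whether the +0.5 adjustment was applied).
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  corrected <- any(table == 0)
  tb <- if (corrected) table + 0.5 else table
  or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  se <- sqrt(sum(1 / tb))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  list(or = or, log2_or = log2(or), ci = ci, corrected = corrected)
}

#' Two-sample t test from printed summary statistics
#'
#' Pooled (Student) and Welch t tests computed from group means, SDs and
#' sizes only, for re-testing published summary rows (e.g. the age
#' comparison between profiling and validation cohorts). Note the cohort
#' table's printed age p-value (0.700) is reproduced by neither variant
#' (both give ~0.45-0.49 from the printed summaries); both are reported so
#' the discrepancy is visible rather than hidden.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return data.frame with one row per variant: `method`, `statistic`,
#'   `df`, `p_value`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  delta <- mean1 - mean2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t_p <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  df_p <- n1 + n2 - 2
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t_w <- delta / sqrt(v1 + v2)
  df_w <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  data.frame(
    method = c("pooled", "welch"),
    statistic = c(t_p, t_w),
    df = c(df_p, df_w),
    p_value = 2 * stats::pt(-abs(c(t_p, t_w)), c(df_p, df_w)),
    stringsAsFactors = FALSE
  )
}

#' Cohort characteristics summary table
#'
#' Mean +/- SD for age and count (%) rows for the binary covariates, per
#' disease group, with a three-group p-value (Pearson chi-square, or the
#' Freeman-Halton exact test when any expected cell is below 5).
#'
#' @param clinical A clinical covariate data.frame (see
#'   [generate_clinical_table()]).
#' @return data.frame with one row per characteristic.
#' @export
table1_summary <- function(clinical) {
  groups <- c("NPDR", "PDR", "NVG")
  by_grp <- split(clinical, factor(clinical$group, groups))
  fmt_age <- vapply(by_grp, function(d)
    sprintf("%.1f ± %.1f", mean(d$age), stats::sd(d$age)), character(1L))
  age_p <- stats::anova(stats::lm(age ~ group, clinical))$`Pr(>F)`[1L]
  bin_row <- function(col, label) {
    cnt <- vapply(by_grp, function(d) sum(d[[col]] == TRUE |
                                            d[[col]] == "male"), integer(1L))
    n <- vapply(by_grp, nrow, integer(1L))
    tab <- rbind(cnt, n - cnt)
    p <- if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 5)) {
      fisher_exact(tab)$p_value
    } else {
      chi_square_rc(tab)$p_value
    }
    data.frame(characteristic = label,
               NPDR = sprintf("%d (%.1f%%)", cnt[1], 100 * cnt[1] / n[1]),
               PDR = sprintf("%d (%.1f%%)", cnt[2], 100 * cnt[2] / n[2]),
               NVG = sprintf("%d (%.1f%%)", cnt[3], 100 * cnt[3] / n[3]),
               p_value = p, stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(characteristic = "Age, years", NPDR = fmt_age[1],
               PDR = fmt_age[2], NVG = fmt_age[3], p_value = age_p,
               stringsAsFactors = FALSE),
    bin_row("sex", "Sex, male"),
    bin_row("hypertension", "Hypertension"),
    bin_row("me", "Macular edema"),
    bin_row("prp", "Panretinal photocoagulation")
  )
}

#' Association between peptide quantities and a clinical covariate
#'
#' Ordinary least-squares fit of log2 peptide quantity on a clinical
#' covariate, adjusting for disease group and age (the design's known
#' stratifiers). One fit per peptide; p-values for the covariate coefficient
#' are Benjamini-Hochberg adjusted across peptides.
#'
#' @param quantities Matrix of peptide quantities (peptides x samples),
#'   natural scale; log2 is taken internally (zeros/missing dropped per fit).
#' @param clinical Clinical data.frame, one row per sample in matrix column
#'   order, containing `covariate` and the adjustment columns.
#' @param covariate Name of the clinical column of interest.
#' @param adjust_for Character vector of adjustment columns
#'   (default `c("group", "age")`); the covariate itself is excluded.
#' @param min_n Minimum complete observations per fit.
#' @return data.frame with one row per peptide: `estimate`, `se`, `p`,
#'   `p_adj`, `n`, and `flag` (collinear / insufficient data).
#' @export
covariate_regression <- function(quantities, clinical, covariate,
                                 adjust_for = c("group", "age"),
                                 min_n = 10L) {
  stopifnot(ncol(quantities) == nrow(clinical),
            covariate %in% names(clinical))
  if (covariate %in% adjust_for ||
      any(vapply(adjust_for, function(a)
        identical(clinical[[a]], clinical[[covariate]]), logical(1L)))) {
    stop("adjustment covariate identical to the target covariate")
  }
  vars <- c(covariate, adjust_for)
  res <- data.frame(peptide = rownames(quantities),
                    estimate = NA_real_, se = NA_real_, p = NA_real_,
                    n = NA_integer_, flag = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(quantities))) {
    y <- log2(as.numeric(quantities[i, ]))
    dat <- cbind(data.frame(.y = y), clinical[vars])
    dat <- dat[stats::complete.cases(dat) & is.finite(dat$.y), , drop = FALSE]
    res$n[i] <- nrow(dat)
    if (nrow(dat) < min_n) { res$flag[i] <- "insufficient data"; next }
    if (length(unique(dat[[covariate]])) < 2L) {
      res$flag[i] <- "covariate constant"; next
    }
    fit <- stats::lm(stats::reformulate(vars, response = ".y"), data = dat)
    sm <- summary(fit)$coefficients
    hit <- grep(paste0("^", covariate), rownames(sm), value = TRUE)
    if (length(hit) == 0L || any(is.na(stats::coef(fit)))) {
      res$flag[i] <- "collinear design"; next
    }
    res$estimate[i] <- sm[hit[1L], "Estimate"]
    res$se[i] <- sm[hit[1L], "Std. Error"]
    res$p[i] <- sm[hit[1L], "Pr(>|t|)"]
  }
  res$p_adj <- bh_adjust(res$p)
  res
}

#' Stratified re-testing of group contrasts
#'
#' Splits samples into strata of a clinical variable and recomputes the
#' Wilcoxon group contrast for a peptide within each stratum, reporting
#' whether the direction and significance of the pooled result persist.
#'
#' @param quantities Named numeric vector of one peptide's quantities
#'   (names = sample ids) or a 1-row matrix.
#' @param clinical Clinical data.frame with `group` plus the stratifier,
#'   rownames or a `patient_id` column matching quantity names.
#' @param contrast Character vector `c(case_group, control_group)`.
#' @param stratify_by Name of the stratification column (already
#'   discretized, e.g. an age-band factor or cataract grade).
#' @param min_per_arm Minimum samples per group within a stratum for the
#'   stratum to be evaluable.
#' @return data.frame, one row per stratum: `n_case`, `n_control`,
#'   `log2fc`, `p`, `evaluable`.
#' @export
stratified_recheck <- function(quantities, clinical, contrast, stratify_by,
                               min_per_arm = 3L) {
  if (is.matrix(quantities)) quantities <- quantities[1L, ]
  ids <- if (!is.null(clinical$patient_id)) as.character(clinical$patient_id)
         else rownames(clinical)
  stopifnot(!is.null(names(quantities)), all(ids %in% names(quantities)) ||
              all(names(quantities) %in% ids))
  common <- intersect(ids, names(quantities))
  clin <- clinical[match(common, ids), , drop = FALSE]
  q <- quantities[common]
  strata <- unique(as.character(clin[[stratify_by]]))
  out <- lapply(strata, function(s) {
    in_s <- as.character(clin[[stratify_by]]) == s
    x <- q[in_s & clin$group == contrast[1L]]
    y <- q[in_s & clin$group == contrast[2L]]
    evaluable <- length(x) >= min_per_arm && length(y) >= min_per_arm
    data.frame(stratum = s, n_case = length(x), n_control = length(y),
               log2fc = if (evaluable) log2(mean(x) / mean(y)) else NA_real_,
               p = if (evaluable) wilcoxon_rank_sum(x, y)$p_value else NA_real_,
               evaluable = evaluable, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
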