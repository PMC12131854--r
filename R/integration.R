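# Cross-platform integration: parametric empirical-Bayes location/scale
# batch adjustment and integration QC.

#' Empirical-Bayes batch adjustment of an expression matrix
#'
#' Removes additive (location) and multiplicative (scale) batch effects from
#' a proteins x samples log2 matrix by the standard parametric
#' empirical-Bayes scheme: per-protein standardization against the
#' covariate-adjusted grand mean and pooled variance, moment-based priors on
#' the per-batch location (normal) and scale (inverse-gamma) parameters,
#' iterative conditional-expectation shrinkage of both, and back-transform.
#' Biological structure to be preserved (e.g. disease group) is supplied as
#' covariates so it is not absorbed into the batch terms.
#'
#' @param values Numeric matrix, proteins x samples, log2 scale, complete
#'   (proteins not observed in every batch must be excluded beforehand;
#'   see [integrate_platforms()]).
#' @param batch Character/factor batch label per column; >= 2 samples per
#'   batch required.
#' @param covariates Optional data.frame of per-sample covariates (factors
#'   or numerics) whose effects are protected during adjustment.
#' @param tol Convergence tolerance of the shrinkage iteration.
#' @param max_iter Iteration cap.
#' @return Object of class `batch_model`: list with `adjusted` (matrix, same
#'   shape), `gamma_hat`/`delta_hat` (raw per-batch location/scale),
#'   `gamma_star`/`delta_star` (shrunken), `priors` (per-batch
#'   hyperparameters), `dropped` (zero-variance proteins removed), `batch`.
#' @export
combat_adjust <- function(values, batch, covariates = NULL,
                          tol = 1e-6, max_iter = 500L) {
  stopifnot(is.matrix(values), length(batch) == ncol(values))
  if (anyNA(values)) stop("matrix must be complete; filter proteins first")
  batch <- factor(batch)
  n_batches <- nlevels(batch)
  nb <- table(batch)
  if (any(nb < 2L)) stop("every batch needs >= 2 samples")
  dropped <- rownames(values)[apply(values, 1L, stats::sd) == 0]
  if (length(dropped) > 0L) {
    message(length(dropped), " zero-variance protein(s) dropped")
    values <- values[setdiff(rownames(values), dropped), , drop = FALSE]
  }
  if (n_batches == 1L) {
    return(structure(list(adjusted = values, gamma_hat = NULL,
                          delta_hat = NULL, gamma_star = NULL,
                          delta_star = NULL, priors = NULL,
                          dropped = dropped, batch = batch),
                     class = "batch_model"))
  }

  # design: batch indicators (no intercept) + covariates
  bd <- stats::model.matrix(~ batch - 1)
  X <- bd
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cm <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
    X <- cbind(bd, cm)
  }
  if (qr(X)$rank < ncol(X)) stop("confounded design: batch and covariates")

  B_hat <- solve(crossprod(X), crossprod(X, t(values)))   # coef x proteins
  props <- as.numeric(nb) / ncol(values)
  grand_mean <- crossprod(matrix(props, ncol = 1L),
                          B_hat[seq_len(n_batches), , drop = FALSE])
  resid <- values - t(X %*% B_hat)
  var_pooled <- rowMeans(resid^2)
  if (any(var_pooled == 0)) stop("zero pooled variance after model fit")

  stand_mean <- matrix(grand_mean, nrow(values), ncol(values))
  if (ncol(X) > n_batches) {
    extra <- X[, -seq_len(n_batches), drop = FALSE]
    stand_mean <- stand_mean +
      t(extra %*% B_hat[-seq_len(n_batches), , drop = FALSE])
  }
  s_data <- (values - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(NA_real_, n_batches, nrow(values),
                      dimnames = list(levels(batch), rownames(values)))
  delta_hat <- gamma_hat
  for (b in seq_len(n_batches)) {
    cols <- batch == levels(batch)[b]
    gamma_hat[b, ] <- rowMeans(s_data[, cols, drop = FALSE])
    delta_hat[b, ] <- apply(s_data[, cols, drop = FALSE], 1L, stats::var)
  }

  # moment-matched priors: normal on gamma, inverse-gamma on delta
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  a_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 1L, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(n_batches)) {
    cols <- which(batch == levels(batch)[b])
    n <- length(cols)
    sd_b <- s_data[, cols, drop = FALSE]
    g_old <- gamma_hat[b, ]
    d_old <- delta_hat[b, ]
    change <- Inf; iter <- 0L
    while (change > tol && iter < max_iter) {
      g_new <- (n * t2[b] * gamma_hat[b, ] + d_old * gamma_bar[b]) /
               (n * t2[b] + d_old)
      ss <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * ss + b_prior[b]) / (n / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                    abs(d_new - d_old) / abs(d_old + 1e-12))
      g_old <- g_new; d_old <- d_new; iter <- iter + 1L
    }
    gamma_star[b, ] <- g_old
    delta_star[b, ] <- d_old
  }

  adjusted <- s_data
  for (b in seq_len(n_batches)) {
    cols <- which(batch == levels(batch)[b])
    adjusted[, cols] <- (s_data[, cols, drop = FALSE] - gamma_star[b, ]) /
      sqrt(delta_star[b, ])
  }
  adjusted <- adjusted * sqrt(var_pooled) + stand_mean

  structure(list(adjusted = adjusted, gamma_hat = gamma_hat,
                 delta_hat = delta_hat, gamma_star = gamma_star,
                 delta_star = delta_star,
                 priors = list(gamma_bar = gamma_bar, t2 = t2,
                               a_prior = a_prior, b_prior = b_prior),
                 dropped = dropped, batch = batch),
            class = "batch_model")
}

#' @export
print.batch_model <- function(x, ...) {
  cat("Empirical-Bayes batch adjustment\n")
  cat("  proteins:", nrow(x$adjusted), " samples:", ncol(x$adjusted), "\n")
  cat("  batches:", paste(levels(x$batch), collapse = ", "), "\n")
  if (length(x$dropped) > 0L) {
    cat("  zero-variance proteins dropped:", length(x$dropped), "\n")
  }
  invisible(x)
}

#' Integrate two platform matrices into one batch-adjusted matrix
#'
#' Restricts both matrices to their common proteins (the standard model
#' requires complete rows), concatenates the samples with the platform as
#' the batch label, protects the disease group as a covariate, and runs
#' [combat_adjust()].
#'
#' @param lfq,tmt [intensity_matrix()] objects. LFQ proteins with any
#'   missing value are excluded before integration.
#' @param protect_group Supply group labels as a protected covariate
#'   (default TRUE).
#' @return List with `model` (the `batch_model`), `matrix` (adjusted
#'   combined matrix), `batch`, `groups`, `n_excluded` (proteins not
#'   quantified in every batch).
#' @export
integrate_platforms <- function(lfq, tmt, protect_group = TRUE) {
  stopifnot(inherits(lfq, "intensity_matrix"), inherits(tmt, "intensity_matrix"))
  lfq_complete <- lfq$values[stats::complete.cases(lfq$values), , drop = FALSE]
  shared <- intersect(rownames(lfq_complete), rownames(tmt$values))
  n_excluded <- length(union(rownames(lfq$values), rownames(tmt$values))) -
    length(shared)
  if (length(shared) < 2L) stop("fewer than 2 proteins shared across batches")
  combined <- cbind(lfq_complete[shared, , drop = FALSE],
                    tmt$values[shared, , drop = FALSE])
  colnames(combined) <- make.unique(c(colnames(lfq$values),
                                      colnames(tmt$values)))
  batch <- c(rep("LFQ", ncol(lfq$values)), rep("TMT", ncol(tmt$values)))
  groups <- c(lfq$groups, tmt$groups)
  cov <- if (protect_group) data.frame(group = factor(groups)) else NULL
  model <- combat_adjust(combined, batch, covariates = cov)
  list(model = model, matrix = model$adjusted, batch = batch,
       groups = groups, n_excluded = n_excluded)
}

#' Integration quality report
#'
#' Per-protein one-way batch F statistics before and after adjustment, mean
#' within-group Pearson correlation of samples, and the top-2 principal
#' directions (by singular decomposition of the centered matrix) for
#' plotting.
#'
#' @param before,after Complete proteins x samples matrices of equal shape.
#' @param batch,groups Per-sample labels.
#' @return Object of class `integration_qc`: list with `batch_f`
#'   (data.frame before/after per protein), `median_f`, `frac_sig`
#'   (fraction of proteins with batch p < 0.05, before/after),
#'   `within_group_cor`, `pca` (samples x 2 scores on the adjusted data).
#' @export
integration_qc <- function(before, after, batch, groups) {
  stopifnot(all(dim(before) == dim(after)))
  batch_f_one <- function(m) {
    apply(m, 1L, function(v) {
      fit <- stats::anova(stats::lm(v ~ factor(batch)))
      c(f = fit$`F value`[1L], p = fit$`Pr(>F)`[1L])
    })
  }
  fb <- batch_f_one(before); fa <- batch_f_one(after)
  cors <- stats::cor(after)
  wg <- outer(groups, groups, "==") & upper.tri(cors)
  sv <- svd(t(scale(t(after), center = TRUE, scale = FALSE)), nu = 0, nv = 2)
  pca <- sv$v %*% diag(sv$d[1:2], 2L)
  dimnames(pca) <- list(colnames(after), c("PC1", "PC2"))
  structure(list(
    batch_f = data.frame(protein = rownames(before),
                         f_before = fb["f", ], p_before = fb["p", ],
                         f_after = fa["f", ], p_after = fa["p", ],
                         row.names = NULL),
    median_f = c(before = stats::median(fb["f", ]),
                 after = stats::median(fa["f", ])),
    frac_sig = c(before = mean(fb["p", ] < 0.05),
                 after = mean(fa["p", ] < 0.05)),
    within_group_cor = mean(cors[wg]),
    pca = pca, batch = batch, groups = groups
  ), class = "integration_qc")
}

#' @export
print.integration_qc <- function(x, ...) {
  cat("Integration QC\n")
  cat(sprintf("  median batch F: %.2f before -> %.2f after\n",
              x$median_f["before"], x$median_f["after"]))
  cat(sprintf("  proteins with batch p < 0.05: %.1f%% -> %.1f%%\n",
              100 * x$frac_sig["before"], 100 * x$frac_sig["after"]))
  cat(sprintf("  mean within-group correlation: %.3f\n", x$within_group_cor))
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.integration_qc <- function(x, ...) {
  graphics::plot(x$pca, col = factor(x$batch),
                 pch = as.integer(factor(x$groups)),
                 main = "Integrated samples, top-2 principal directions", ...)
  graphics::legend("topright", legend = unique(x$batch),
                   col = seq_along(unique(x$batch)), pch = 1, bty = "n")
  invisible(x)
}
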