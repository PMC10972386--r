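#' @name batchfilter
#' @title Batch-effect feature removal
#' @description Two cohorts run far apart show batch structure that dominates
#'   the lipidome PCA. Rather than model-based correction, features that differ
#'   significantly between the batches are removed. The sham-anchored variant
#'   tests only sham controls (batch 1 vs batch 2) so that genuine injury
#'   signal, which lives in the injured groups, cannot be mistaken for a batch
#'   effect; the all-sample variant is provided for comparison.
NULL

# vectorised Welch t-test over the rows of two matrices.
# Degenerate rows (zero variance in both groups): p = 1 when the means agree,
# p = 0 when they differ -- matching the filter's intent.
welch_p_matrix <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  if (nx < 2 || ny < 2) abort("each group needs at least 2 samples")
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(mx[degenerate] == my[degenerate], 1, 0)
    tstat[degenerate] <- ifelse(mx[degenerate] == my[degenerate], 0, Inf)
    df[degenerate] <- NA_real_
  }
  list(t = tstat, df = df, p = p)
}

#' Welch's two-sample t-test p-value
#'
#' Two-sided p from the unequal-variance t statistic with
#' Welch--Satterthwaite degrees of freedom. Both groups constant and equal
#' gives p = 1 (feature kept by the filter); constant with unequal means gives
#' p = 0 (removed).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return The two-sided p-value.
#' @examples
#' welch_p(c(1, 2, 3), c(1, 2, 3))   # identical groups: p = 1
#' @export
welch_p <- function(x, y) {
  welch_p_matrix(matrix(x, nrow = 1), matrix(y, nrow = 1))$p
}

batch_filter_impl <- function(table, alpha, mode) {
  stopifnot(inherits(table, "feature_tbl"), alpha >= 0, alpha <= 1)
  if (is.null(attr(table, "log_info"))) {
    warn("batch filter is intended for log-transformed intensities")
  }
  sm <- sample_meta(table)
  sel <- if (mode == "sham_only") sm$injury == "sham" else rep(TRUE, nrow(sm))
  g1 <- sm$sample_id[sel & sm$batch == 1L]
  g2 <- sm$sample_id[sel & sm$batch == 2L]
  if (length(g1) < 2 || length(g2) < 2) {
    abort(sprintf("need >= 2 %s samples in each batch",
                  if (mode == "sham_only") "sham" else ""))
  }
  m <- intensity_matrix(table)
  res <- welch_p_matrix(m[, g1, drop = FALSE], m[, g2, drop = FALSE])
  removed <- res$p < alpha
  report <- structure(
    list(
      p_values = tibble(feature_id = table$feature_id, p_value = res$p,
                        removed = removed),
      kept_ids = table$feature_id[!removed],
      removed_ids = table$feature_id[removed],
      mode = mode, alpha = alpha,
      n_in = nrow(table), n_kept = sum(!removed), n_removed = sum(removed)
    ),
    class = "batch_filter_report"
  )
  filtered <- ft_replace(table,
                         features = as_tibble(unclass(table))[!removed, ])
  list(table = filtered, report = report)
}

#' Sham-anchored batch filter
#'
#' Removes every feature whose log intensities differ between sham controls of
#' batch 1 and batch 2 at `p < alpha` by Welch's t-test. Only sham samples are
#' inspected; all samples are retained in the returned table. No
#' multiple-testing correction is applied: removing more features is the
#' conservative direction for a removal filter.
#'
#' @param table A log-transformed `feature_tbl` with sham samples in both
#'   batches.
#' @param alpha Removal significance level (default 0.05).
#' @return A list with `table` (the filtered `feature_tbl`) and `report`
#'   (a `batch_filter_report`; see [tidy.batch_filter_report()]).
#' @export
sham_batch_filter <- function(table, alpha = 0.05) {
  batch_filter_impl(table, alpha, "sham_only")
}

#' All-sample batch filter
#'
#' As [sham_batch_filter()], but the Welch test compares batch 1 vs batch 2
#' over all samples. Injury effects that are batch-balanced inflate neither
#' group mean difference, but any chance imbalance can discard biologically
#' relevant features -- the reason the sham-anchored variant is preferred.
#'
#' @inheritParams sham_batch_filter
#' @export
all_sample_batch_filter <- function(table, alpha = 0.05) {
  batch_filter_impl(table, alpha, "all_samples")
}

#' @export
print.batch_filter_report <- function(x, ...) {
  cat(sprintf("<batch_filter_report> mode=%s alpha=%g: %d in, %d kept, %d removed\n",
              x$mode, x$alpha, x$n_in, x$n_kept, x$n_removed))
  invisible(x)
}

#' Tidy a batch filter report
#' @param x A `batch_filter_report`.
#' @param ... Unused.
#' @return A tibble with `feature_id`, `p_value`, `removed`.
#' @method tidy batch_filter_report
#' @export
tidy.batch_filter_report <- function(x, ...) x$p_values

#' @method glance batch_filter_report
#' @export
glance.batch_filter_report <- function(x, ...) {
  tibble(mode = x$mode, alpha = x$alpha, n_in = x$n_in,
         n_kept = x$n_kept, n_removed = x$n_removed)
}

#' PCA diagnostics of a feature table
#'
#' Principal component analysis of the samples over the (typically
#' log-transformed) feature intensities: samples are observations, features
#' are centred variables. Unit-variance scaling is off by default since
#' log-transformed peak areas are on a comparable scale.
#'
#' @param table A `feature_tbl` with >= 2 samples.
#' @param n_components Number of components to keep (default: all).
#' @param scale. Scale features to unit variance (zero-variance features are
#'   dropped first when `TRUE`).
#' @return A `pca_diag` object: `scores` (tibble of sample metadata plus
#'   `PC1..PCk`), `variance_fraction`, and `sdev`.
#' @export
pca_diagnostics <- function(table, n_components = NULL, scale. = FALSE) {
  stopifnot(inherits(table, "feature_tbl"))
  sm <- sample_meta(table)
  if (nrow(sm) < 2) abort("PCA needs at least 2 samples")
  X <- t(intensity_matrix(table))  # samples x features
  v <- apply(X, 2, var)
  if (all(v == 0)) abort("constant intensity matrix: no variance to analyse")
  if (scale.) X <- X[, v > 0, drop = FALSE]
  fit <- prcomp(X, center = TRUE, scale. = scale.)
  total_var <- sum(fit$sdev^2)
  k <- min(n_components %||% ncol(fit$x), ncol(fit$x))
  scores <- as_tibble(fit$x[, seq_len(k), drop = FALSE])
  structure(
    list(
      scores = bind_cols(sm, scores),
      variance_fraction = fit$sdev[seq_len(k)]^2 / total_var,
      sdev = fit$sdev[seq_len(k)]
    ),
    class = "pca_diag"
  )
}

#' @export
print.pca_diag <- function(x, ...) {
  cat(sprintf("<pca_diag> %d samples, %d components; var fractions: %s\n",
              nrow(x$scores), length(x$variance_fraction),
              paste(sprintf("%.1f%%", 100 * head(x$variance_fraction, 4)),
                    collapse = " ")))
  invisible(x)
}

#' Tidy PCA diagnostics
#' @param x A `pca_diag`.
#' @param ... Unused.
#' @return The score tibble (sample metadata plus component columns).
#' @method tidy pca_diag
#' @export
tidy.pca_diag <- function(x, ...) x$scores

#' @method glance pca_diag
#' @export
glance.pca_diag <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$variance_fraction)),
         variance_fraction = x$variance_fraction)
}

#' Per-component batch (or group) separation score
#'
#' Quantifies separation along each principal component as the absolute
#' standardized mean difference (Cohen's d with pooled SD) of the scores
#' between the two label groups, instead of eyeballing a score plot.
#'
#' @param diag A [pca_diagnostics()] result.
#' @param labels Either the name of a metadata column with exactly two levels
#'   present (default `"batch"`) or a vector of labels aligned with the score
#'   rows.
#' @return A tibble with `component` and `score`.
#' @export
batch_separation_score <- function(diag, labels = "batch") {
  stopifnot(inherits(diag, "pca_diag"))
  lab <- if (is.character(labels) && length(labels) == 1 &&
             labels %in% names(diag$scores)) diag$scores[[labels]] else labels
  if (length(lab) != nrow(diag$scores)) {
    abort("labels do not align with the PCA scores")
  }
  lev <- unique(lab)
  if (length(lev) != 2) abort("separation score needs exactly two label groups")
  pcs <- grep("^PC[0-9]+$", names(diag$scores), value = TRUE)
  sc <- map_dbl(pcs, function(pc) {
    a <- diag$scores[[pc]][lab == lev[1]]
    b <- diag$scores[[pc]][lab == lev[2]]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    if (sp == 0) return(if (mean(a) == mean(b)) 0 else Inf)
    abs(mean(a) - mean(b)) / sp
  })
  tibble(component = pcs, score = sc)
}
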