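#' @name integrate
#' @title Lipid-cytokine integration
#' @description Annotated lipids are correlated with cytokines by Spearman rank
#'   correlation over the animals shared between the two assays, restricted to
#'   an injury group plus its sham reference so that the correlation and the
#'   fold-change criterion describe the same animals. The dual filter keeps
#'   lipids with a fold change beyond the threshold AND at least one
#'   correlation of magnitude >= the rho threshold, and cytokines with at
#'   least one passing lipid partner.
NULL

#' Spearman rank correlation
#'
#' Average ranks for ties; pairs with missing values are dropped. A constant
#' vector has no rank ordering, so the correlation is undefined and `NA` is
#' returned.
#'
#' @param x,y Paired numeric vectors with >= 3 complete pairs.
#' @return Spearman's rho in `[-1, 1]`, or `NA` for a constant input.
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))   # 0.8
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) abort("need >= 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Lipid x cytokine Spearman correlation matrix
#'
#' @param table A `feature_tbl` of (annotated, typically species-level)
#'   lipids. Spearman correlation is rank-based, so raw or log scale give
#'   identical results.
#' @param panel A `cytokine_panel` (after [linear_range_filter()]).
#' @param groups Injury groups defining the animal restriction; the default
#'   `c("sham", "3X")` pairs the repeat-injury animals with their sham
#'   reference. Use all three levels for an unrestricted matrix.
#' @return A `lipid_cytokine_cor`: list with `rho` (lipid x cytokine matrix),
#'   `n` (complete pairs per cell), `groups`, `lipids`, `cytokines`.
#' @export
correlation_matrix <- function(table, panel, groups = c("sham", "3X")) {
  stopifnot(inherits(table, "feature_tbl"), inherits(panel, "cytokine_panel"))
  sm <- sample_meta(table)
  an <- panel_animals(panel)
  shared <- intersect(sm$sample_id[sm$injury %in% groups],
                      an$sample_id[an$injury %in% groups])
  if (length(shared) < 3) abort("fewer than 3 shared animals after restriction")

  L <- t(intensity_matrix(table)[, shared, drop = FALSE])   # animals x lipids
  C <- t(panel_matrix(panel)[, shared, drop = FALSE])       # animals x cytokines
  suppressWarnings(
    rho <- cor(L, C, method = "spearman", use = "pairwise.complete.obs")
  )
  # constant columns give sd 0: undefined rank correlation, reported missing
  n_used <- crossprod(!is.na(L), !is.na(C))
  structure(
    list(rho = rho, n = n_used, groups = groups,
         lipids = colnames(L), cytokines = colnames(C)),
    class = "lipid_cytokine_cor"
  )
}

#' @export
print.lipid_cytokine_cor <- function(x, ...) {
  cat(sprintf("<lipid_cytokine_cor> %d lipids x %d cytokines over groups {%s}\n",
              length(x$lipids), length(x$cytokines),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Tidy a correlation matrix into long form
#' @param x A `lipid_cytokine_cor`.
#' @param ... Unused.
#' @return A tibble with `lipid`, `cytokine`, `rho`, `n`.
#' @method tidy lipid_cytokine_cor
#' @export
tidy.lipid_cytokine_cor <- function(x, ...) {
  tibble(
    lipid = rep(x$lipids, times = length(x$cytokines)),
    cytokine = rep(x$cytokines, each = length(x$lipids)),
    rho = as.vector(x$rho),
    n = as.vector(x$n)
  )
}

#' Dual fold-change / correlation filter
#'
#' @param cmat A [correlation_matrix()] result.
#' @param diff A [volcano()] result (or any frame with `feature_id` and
#'   `fold_change`) for the contrast matching the matrix restriction; every
#'   matrix lipid must appear in it.
#' @param fc_threshold Fold-change magnitude threshold (default 1.25); a lipid
#'   passes with `fold_change >= fc_threshold` or `<= 1/fc_threshold`.
#' @param rho_threshold Correlation magnitude threshold (default 0.4).
#' @return An `integration_selection`: `lipids`, `cytokines`, `pairs` (tibble
#'   of surviving lipid-cytokine pairs with `rho` and `fold_change`) and the
#'   thresholds used.
#' @export
dual_filter <- function(cmat, diff, fc_threshold = 1.25, rho_threshold = 0.4) {
  stopifnot(inherits(cmat, "lipid_cytokine_cor"))
  diff <- as_tibble(diff)
  missing_ids <- setdiff(cmat$lipids, diff$feature_id)
  if (length(missing_ids) > 0) {
    abort(paste0("matrix lipid(s) absent from diff results: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  fc <- diff$fold_change[match(cmat$lipids, diff$feature_id)]
  fc_pass <- fc >= fc_threshold | fc <= 1 / fc_threshold

  abs_rho <- abs(cmat$rho)
  rho_pass <- !is.na(abs_rho) & abs_rho >= rho_threshold
  lipid_pass <- fc_pass & apply(rho_pass, 1, any)

  pair_idx <- which(rho_pass & lipid_pass, arr.ind = TRUE)
  pairs <- tibble(
    lipid = cmat$lipids[pair_idx[, 1]],
    cytokine = cmat$cytokines[pair_idx[, 2]],
    rho = cmat$rho[pair_idx],
    fold_change = fc[pair_idx[, 1]]
  ) |> arrange(.data$lipid, .data$cytokine)

  structure(
    list(
      lipids = cmat$lipids[lipid_pass],
      cytokines = sort(unique(pairs$cytokine)),
      pairs = pairs,
      fc_threshold = fc_threshold,
      rho_threshold = rho_threshold,
      groups = cmat$groups
    ),
    class = "integration_selection"
  )
}

#' @export
print.integration_selection <- function(x, ...) {
  cat(sprintf("<integration_selection> %d lipids, %d cytokines (|FC| >= %g, |rho| >= %g)\n",
              length(x$lipids), length(x$cytokines),
              x$fc_threshold, x$rho_threshold))
  invisible(x)
}

#' @method tidy integration_selection
#' @export
tidy.integration_selection <- function(x, ...) x$pairs

#' @method glance integration_selection
#' @export
glance.integration_selection <- function(x, ...) {
  tibble(n_lipids = length(x$lipids), n_cytokines = length(x$cytokines),
         fc_threshold = x$fc_threshold, rho_threshold = x$rho_threshold)
}

#' PCA over the selected lipid panel
#'
#' @param table A `feature_tbl` (log scale recommended).
#' @param selection An [dual_filter()] result or a character vector of >= 2
#'   feature ids.
#' @return A [pca_diagnostics()] result over the selected lipids only.
#' @export
selected_lipid_pca <- function(table, selection) {
  ids <- if (inherits(selection, "integration_selection")) selection$lipids
         else as.character(selection)
  if (length(ids) < 2) abort("selection must contain at least 2 lipids")
  keep <- table$feature_id %in% ids
  sub <- ft_replace(table, features = as_tibble(unclass(table))[keep, ])
  pca_diagnostics(sub)
}
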