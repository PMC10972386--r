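#' @name diffexpr
#' @title Differential analysis across injury groups
#' @description Per-feature one-way ANOVA on log intensities across the three
#'   injury groups with Tukey HSD post-hoc contrasts; fold changes are ratios
#'   of arithmetic group means on the raw scale. A feature is classified
#'   up/down on the volcano when the Tukey-adjusted p for the plotted contrast
#'   is below `alpha` and the fold change clears the threshold in that
#'   direction.
NULL

# vectorised one-way fixed-effects ANOVA + Tukey HSD over matrix rows.
# X: features x samples; fac: group factor over columns.
# Returns p_anova (vector) and p_tukey (matrix, one column per pair).
anova_tukey_matrix <- function(X, fac) {
  fac <- droplevels(as.factor(fac))
  k <- nlevels(fac)
  if (k < 2) abort("need at least 2 groups")
  ns <- as.vector(base::table(fac))
  if (any(ns < 2)) abort("each group needs at least 2 values")
  N <- ncol(X)

  means <- vapply(levels(fac), function(l) {
    rowMeans(X[, fac == l, drop = FALSE])
  }, numeric(nrow(X)))
  if (nrow(X) == 1) means <- matrix(means, nrow = 1,
                                    dimnames = list(NULL, levels(fac)))
  grand <- rowMeans(X)
  ss_between <- as.vector((means - grand)^2 %*% ns)
  ss_total <- rowSums((X - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1
  df2 <- N - k
  mse <- ss_within / df2
  fstat <- (ss_between / df1) / mse
  p_anova <- stats::pf(fstat, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(levels(fac), 2)
  p_tukey <- matrix(NA_real_, nrow = nrow(X), ncol = ncol(pairs))
  colnames(p_tukey) <- apply(pairs, 2, paste, collapse = " vs ")
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- ns[levels(fac) == a]; nb <- ns[levels(fac) == b]
    se <- sqrt(mse / 2 * (1 / na + 1 / nb))   # Tukey-Kramer
    q <- abs(means[, a] - means[, b]) / se
    p_tukey[, j] <- ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
  }

  # degenerate rows: no within-group variance
  degen <- mse == 0
  if (any(degen)) {
    flat <- degen & ss_between == 0          # all values identical
    p_anova[flat] <- 1
    p_anova[degen & !flat] <- 0
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      same <- means[, a] == means[, b]
      p_tukey[degen, j] <- ifelse(same[degen], 1, 0)
    }
  }
  list(p_anova = p_anova, p_tukey = p_tukey)
}

#' One-way ANOVA with Tukey HSD post-hoc contrasts
#'
#' @param values Numeric vector of (log-scale) observations.
#' @param groups Group labels aligned with `values` (2+ levels, each with >= 2
#'   observations).
#' @return A list with `p_anova` (overall F-test p) and `p_tukey` (named
#'   vector of studentized-range adjusted p per pairwise contrast). All values
#'   identical yields p = 1 by convention.
#' @export
anova_tukey <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  res <- anova_tukey_matrix(matrix(values, nrow = 1), groups)
  list(p_anova = unname(res$p_anova), p_tukey = drop(res$p_tukey))
}

#' Fold change as a ratio of arithmetic means on the raw scale
#'
#' @param a,b Raw-scale intensity vectors (numerator group `a`, reference
#'   group `b`, typically sham).
#' @return `mean(a) / mean(b)`.
#' @export
fold_change <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  if (!is.finite(ma) || !is.finite(mb) || ma <= 0 || mb <= 0) {
    abort("fold change requires positive, finite group means")
  }
  ma / mb
}

#' Volcano classification of a feature table
#'
#' The p used for classification is the Tukey-adjusted pairwise p for the
#' plotted contrast, extracted from the three-group ANOVA on log intensities;
#' the fold change is the ratio of raw-scale arithmetic group means.
#'
#' @param table A log-transformed `feature_tbl` (raw intensities are recovered
#'   from the recorded transform for the fold change).
#' @param contrast Character pair `c(group, reference)`; default `c("3X",
#'   "sham")`.
#' @param alpha Significance threshold (default 0.05).
#' @param fc_threshold Fold-change threshold (default 1.25); `down` means
#'   `fold_change <= 1/fc_threshold`.
#' @param fc_method `"mean_ratio"` (default) or `"log_mean"` (ratio of
#'   geometric means, i.e. back-transformed difference of log means).
#' @return A `volcano_result`: tibble with `feature_id`, `contrast`,
#'   `fold_change`, `p_anova`, `p_tukey`, `volcano_class` plus `n_up`/`n_down`
#'   attributes (also via [glance()]).
#' @export
volcano <- function(table, contrast = c("3X", "sham"), alpha = 0.05,
                    fc_threshold = 1.25, fc_method = c("mean_ratio", "log_mean")) {
  stopifnot(inherits(table, "feature_tbl"), length(contrast) == 2)
  fc_method <- match.arg(fc_method)
  if (is.null(attr(table, "log_info"))) {
    abort("volcano expects a log-transformed table (see log_transform())")
  }
  sm <- sample_meta(table)
  if (!all(contrast %in% sm$injury)) {
    abort("contrast groups not both present in the samples")
  }
  X <- intensity_matrix(table)
  fac <- factor(sm$injury, levels = intersect(INJURY_LEVELS, unique(sm$injury)))
  at <- anova_tukey_matrix(X, fac)
  pair_names <- colnames(at$p_tukey)
  want <- c(paste(contrast[1], "vs", contrast[2]),
            paste(contrast[2], "vs", contrast[1]))
  hit <- pair_names[pair_names %in% want]
  p_contrast <- at$p_tukey[, hit[1]]

  raw <- raw_intensity_matrix(table)
  ga <- rowMeans(raw[, sm$sample_id[sm$injury == contrast[1]], drop = FALSE])
  gb <- rowMeans(raw[, sm$sample_id[sm$injury == contrast[2]], drop = FALSE])
  fc <- if (fc_method == "mean_ratio") {
    ga / gb
  } else {
    li <- attr(table, "log_info")
    la <- rowMeans(X[, sm$sample_id[sm$injury == contrast[1]], drop = FALSE])
    lb <- rowMeans(X[, sm$sample_id[sm$injury == contrast[2]], drop = FALSE])
    li$base^(la - lb)
  }

  cls <- rep("ns", nrow(table))
  cls[p_contrast < alpha & fc >= fc_threshold] <- "up"
  cls[p_contrast < alpha & fc <= 1 / fc_threshold] <- "down"

  out <- tibble(
    feature_id = table$feature_id,
    contrast = paste(contrast[1], "vs", contrast[2]),
    fold_change = fc,
    p_anova = at$p_anova,
    p_tukey = p_contrast,
    volcano_class = cls
  )
  structure(out, n_up = sum(cls == "up"), n_down = sum(cls == "down"),
            alpha = alpha, fc_threshold = fc_threshold,
            class = c("volcano_result", class(out)))
}

#' @method glance volcano_result
#' @export
glance.volcano_result <- function(x, ...) {
  tibble(contrast = x$contrast[1],
         n_up = attr(x, "n_up"), n_down = attr(x, "n_down"),
         n_ns = sum(x$volcano_class == "ns"),
         alpha = attr(x, "alpha"), fc_threshold = attr(x, "fc_threshold"))
}

#' Per-subclass direction tallies of annotated lipids
#'
#' Counts, per lipid subclass, the annotated species whose fold change is
#' above / below 1 (direction regardless of significance). Species at exactly
#' fold change 1 are excluded from the tally and reported in the
#' `n_unchanged` column.
#'
#' @param annotations Annotation tibble from [annotate_table()] (or any frame
#'   with `feature_id` and `subclass`).
#' @param diff A [volcano()] result (or any frame with `feature_id` and
#'   `fold_change`).
#' @return A tibble with `subclass`, `n_increased`, `n_decreased`,
#'   `n_unchanged`, `fraction_decreased`; empty subclasses are omitted.
#' @export
subclass_tally <- function(annotations, diff) {
  joined <- annotations |>
    select("feature_id", "subclass") |>
    dplyr::inner_join(select(as_tibble(diff), "feature_id", "fold_change"),
                      by = "feature_id")
  joined |>
    group_by(.data$subclass) |>
    summarise(
      n_increased = sum(.data$fold_change > 1),
      n_decreased = sum(.data$fold_change < 1),
      n_unchanged = sum(.data$fold_change == 1),
      .groups = "drop"
    ) |>
    mutate(fraction_decreased =
             .data$n_decreased / pmax(.data$n_increased + .data$n_decreased, 1)) |>
    filter(.data$n_increased + .data$n_decreased + .data$n_unchanged > 0)
}
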