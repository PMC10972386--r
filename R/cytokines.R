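#' @name cytokines
#' @title Multiplex cytokine panel analysis
#' @description Panels arrive as analyte x animal concentration tables with a
#'   per-analyte flag marking whether the assay's bead fluorescence was within
#'   its linear range; out-of-range analytes are excluded from all statistics.
#'   Injury effects are modelled per analyte as a fixed-effects linear model
#'   `concentration ~ injury (+ batch)` with Tukey-adjusted pairwise injury
#'   contrasts -- the explicit interpretation of an under-specified
#'   "mixed-effect analysis" for a design with one observation per animal.
NULL

#' Build a cytokine panel
#'
#' @param concentrations A data frame with columns `analyte`,
#'   `in_linear_range` (logical) and one numeric column per animal.
#' @param animals Sample metadata for the animals (`sample_id`, `batch`,
#'   `injury`, `sex`); may omit animals missing from the assay.
#' @return A `cytokine_panel`: a tibble with the animal metadata attached as
#'   the `animals` attribute.
#' @export
cytokine_panel <- function(concentrations, animals) {
  concentrations <- as_tibble(concentrations)
  animals <- as_tibble(animals)
  req <- c("analyte", "in_linear_range")
  if (!all(req %in% names(concentrations))) {
    abort("panel needs columns analyte, in_linear_range")
  }
  if (anyDuplicated(concentrations$analyte)) abort("duplicate analyte names")
  value_cols <- setdiff(names(concentrations), req)
  missing_animals <- setdiff(animals$sample_id, value_cols)
  if (length(missing_animals) > 0) {
    abort(paste0("animal(s) in metadata missing from panel: ",
                 paste(missing_animals, collapse = ", ")))
  }
  concentrations <- concentrations[, c(req, animals$sample_id)]
  m <- as.matrix(concentrations[, animals$sample_id])
  if (any(m < 0, na.rm = TRUE)) abort("negative concentrations")
  out <- concentrations
  attr(out, "animals") <- animals
  class(out) <- c("cytokine_panel", class(tibble()))
  out
}

#' Animal metadata of a cytokine panel
#' @param panel A `cytokine_panel`.
#' @export
panel_animals <- function(panel) {
  stopifnot(inherits(panel, "cytokine_panel"))
  attr(panel, "animals")
}

panel_matrix <- function(panel) {
  an <- panel_animals(panel)
  m <- as.matrix(panel[, an$sample_id, drop = FALSE])
  rownames(m) <- panel$analyte
  m
}

#' Read / write a cytokine panel CSV
#'
#' Dialect: `analyte,in_linear_range,<animal_id>...` plus a metadata CSV
#' `sample_id,batch,injury,sex`.
#'
#' @param path,metadata_path CSV paths.
#' @return A [cytokine_panel()].
#' @export
read_cytokine_panel <- function(path, metadata_path) {
  conc <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  cytokine_panel(conc, meta)
}

#' @rdname read_cytokine_panel
#' @param panel A `cytokine_panel`.
#' @export
write_cytokine_panel <- function(panel, path, metadata_path) {
  readr::write_csv(as_tibble(unclass(panel)), path, progress = FALSE)
  readr::write_csv(panel_animals(panel), metadata_path, progress = FALSE)
  invisible(panel)
}

#' Drop analytes outside the assay's linear range
#'
#' @param panel A `cytokine_panel`.
#' @return The panel restricted to `in_linear_range` analytes; warns when
#'   nothing remains.
#' @export
linear_range_filter <- function(panel) {
  stopifnot(inherits(panel, "cytokine_panel"))
  keep <- panel$in_linear_range
  if (!any(keep)) warn("no analytes within the linear range; panel is empty")
  out <- panel[keep, ]
  attr(out, "animals") <- panel_animals(panel)
  class(out) <- class(panel)
  out
}

#' Per-analyte z-scores across animals
#'
#' `(x - mean) / SD` per analyte row; missing values are ignored in the mean
#' and SD and left missing in the output.
#'
#' @param panel A `cytokine_panel`.
#' @return A tibble `analyte` x animal of z-scores.
#' @export
zscore_by_analyte <- function(panel) {
  m <- panel_matrix(panel)
  z <- t(apply(m, 1, function(x) {
    n_ok <- sum(!is.na(x))
    if (n_ok < 2) abort("each analyte needs >= 2 non-missing values")
    s <- sd(x, na.rm = TRUE)
    if (s == 0) abort("zero SD analyte cannot be z-scored")
    (x - mean(x, na.rm = TRUE)) / s
  }))
  bind_cols(tibble(analyte = panel$analyte), as_tibble(z))
}

#' Injury effects on each cytokine
#'
#' Per analyte (complete cases): fit `concentration ~ injury` -- with batch as
#' an additive covariate when both batches are present and `include_batch` is
#' `TRUE` -- and report Tukey-adjusted pairwise injury contrasts, directions
#' relative to sham, and group means with SEM.
#'
#' @param panel A `cytokine_panel` (typically after [linear_range_filter()]).
#' @param include_batch Adjust for batch when both batches are present.
#' @param alpha Significance level used for the `significant` flag.
#' @return A `cytokine_effects` object; [tidy()] returns the per-contrast
#'   table (`analyte`, `contrast`, `estimate`, `p_adj`, `direction`,
#'   `significant`), `$group_stats` the per-group mean +/- SEM.
#' @export
injury_effect <- function(panel, include_batch = TRUE, alpha = 0.05) {
  stopifnot(inherits(panel, "cytokine_panel"))
  an <- panel_animals(panel)
  m <- panel_matrix(panel)

  contrasts <- list_rbind(lapply(seq_len(nrow(panel)), function(i) {
    df <- tibble(
      conc = m[i, ],
      injury = factor(an$injury, levels = INJURY_LEVELS),
      batch = factor(an$batch)
    )
    df <- df[complete.cases(df), ]
    cnt <- base::table(df$injury)
    if (any(cnt < 2)) {
      abort(sprintf("analyte %s: need >= 2 animals per injury group",
                    panel$analyte[i]))
    }
    with_batch <- include_batch && length(unique(df$batch)) == 2
    fit <- if (with_batch) lm(conc ~ injury + batch, data = df)
           else lm(conc ~ injury, data = df)
    emm <- emmeans::emmeans(fit, "injury")
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "tukey"))
    # emmeans emits "sham - 1X" etc (first minus second); flip so the later
    # level is reported relative to the earlier: "1X vs sham", "3X vs 1X", ...
    parts <- strsplit(as.character(prs$contrast), " - ")
    tibble(
      analyte = panel$analyte[i],
      contrast = map_chr(parts, function(p) paste(p[2], "vs", p[1])),
      estimate = -prs$estimate,
      p_adj = prs$p.value,
      batch_adjusted = with_batch
    )
  }))

  contrasts <- contrasts |>
    mutate(direction = dplyr::case_when(
             .data$estimate > 0 ~ "increased",
             .data$estimate < 0 ~ "decreased",
             TRUE ~ "unchanged"),
           significant = .data$p_adj < alpha)

  group_stats <- list_rbind(lapply(seq_len(nrow(panel)), function(i) {
    tibble(analyte = panel$analyte[i],
           injury = factor(an$injury, levels = INJURY_LEVELS),
           conc = m[i, ]) |>
      filter(!is.na(.data$conc)) |>
      group_by(.data$analyte, .data$injury) |>
      summarise(n = n(), mean = mean(.data$conc),
                sem = sd(.data$conc) / sqrt(n()), .groups = "drop")
  }))

  structure(list(contrasts = contrasts, group_stats = group_stats,
                 alpha = alpha),
            class = "cytokine_effects")
}

#' @export
print.cytokine_effects <- function(x, ...) {
  sig <- x$contrasts |> filter(.data$significant)
  cat(sprintf("<cytokine_effects> %d analytes, %d significant contrasts at alpha=%g\n",
              length(unique(x$contrasts$analyte)), nrow(sig), x$alpha))
  invisible(x)
}

#' Tidy cytokine injury effects
#' @param x A `cytokine_effects`.
#' @param ... Unused.
#' @method tidy cytokine_effects
#' @export
tidy.cytokine_effects <- function(x, ...) x$contrasts

#' @method glance cytokine_effects
#' @export
glance.cytokine_effects <- function(x, ...) {
  x$contrasts |>
    group_by(.data$contrast) |>
    summarise(n_significant = sum(.data$significant),
              n_decreased_sig = sum(.data$significant &
                                      .data$direction == "decreased"),
              .groups = "drop")
}
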