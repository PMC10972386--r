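#' @name pipeline
#' @title End-to-end analysis pipeline
#' @description Fixed stage order: preprocess (retention-time filter, log
#'   transform) -> batch filter -> annotate -> sum sibling features -> volcano
#'   differential analysis -> cytokine injury effects -> lipid-cytokine
#'   integration. Every stage's feature/sample counts are captured in the run
#'   report so the reduction funnel is auditable.
NULL

#' Pipeline configuration
#'
#' Collects every tunable threshold once, with the analysis defaults:
#' 0.75 min retention-time cutoff, log2 transform, sham-anchored batch filter
#' at alpha 0.05, 5/10 ppm annotation tolerances, volcano alpha 0.05 with
#' 1.25-fold threshold, and the dual integration filter at |FC| >= 1.25,
#' |rho| >= 0.4 on the repeat-injury contrast.
#'
#' @param min_rt Retention-time cutoff (minutes).
#' @param log_base,pseudocount Log-transform parameters.
#' @param batch_mode `"sham_only"` or `"all_samples"`.
#' @param alpha Significance level used by the batch filter, volcano and
#'   cytokine contrasts.
#' @param fc_threshold,rho_threshold Dual-filter thresholds.
#' @param contrast Injury contrast for the volcano/integration, `c(group,
#'   reference)`.
#' @param include_batch_covariate Adjust cytokine models for batch.
#' @param default_ion_mode Ion mode for features lacking an `ion_mode` column.
#' @return A `run_config` list.
#' @export
run_config <- function(min_rt = 0.75, log_base = 2, pseudocount = 0,
                       batch_mode = c("sham_only", "all_samples"),
                       alpha = 0.05, fc_threshold = 1.25, rho_threshold = 0.4,
                       contrast = c("3X", "sham"),
                       include_batch_covariate = TRUE,
                       default_ion_mode = "positive") {
  batch_mode <- match.arg(batch_mode)
  stopifnot(min_rt >= 0, log_base > 1, alpha >= 0, alpha <= 1,
            fc_threshold >= 1, rho_threshold >= 0, length(contrast) == 2)
  structure(list(min_rt = min_rt, log_base = log_base,
                 pseudocount = pseudocount, batch_mode = batch_mode,
                 alpha = alpha, fc_threshold = fc_threshold,
                 rho_threshold = rho_threshold, contrast = contrast,
                 include_batch_covariate = include_batch_covariate,
                 default_ion_mode = default_ion_mode),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' @param table A raw-scale [feature_table()] (or path handling via
#'   [read_feature_table()] upstream).
#' @param panel A [cytokine_panel()], or `NULL` to stop after the differential
#'   stage.
#' @param dictionary A [lipid_dictionary()].
#' @param spectra Optional named list of MS2 spectra per feature.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, per-stage CSVs and the JSON
#'   run report are written there.
#' @return A `run_report` list: the count funnel (`funnel`), per-stage objects
#'   (`batch_report`, `annotations`, `diff`, `cytokine_effects`, `selection`,
#'   `pca`), and the configuration echo.
#' @export
run_pipeline <- function(table, panel = NULL, dictionary = NULL,
                         spectra = NULL, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(table, "feature_tbl"), inherits(config, "run_config"))
  funnel <- list(n_detected = nrow(table))

  table_rt <- stage("preprocess", rt_filter(table, min_rt = config$min_rt))
  funnel$n_after_rt <- nrow(table_rt)

  logged <- stage("preprocess",
                  log_transform(table_rt, base = config$log_base,
                                pseudocount = config$pseudocount))
  bf <- stage("batchfilter", {
    if (config$batch_mode == "sham_only") {
      sham_batch_filter(logged, alpha = config$alpha)
    } else {
      all_sample_batch_filter(logged, alpha = config$alpha)
    }
  })
  funnel$n_after_batch <- bf$report$n_kept
  funnel$n_batch_removed <- bf$report$n_removed

  ann <- NULL; species_table <- NULL; diff <- NULL; tally <- NULL
  if (!is.null(dictionary)) {
    kept_raw <- stage("annotate", {
      keep <- table_rt$feature_id %in% bf$report$kept_ids
      ft_replace(table_rt,
                 features = as_tibble(unclass(table_rt))[keep, ])
    })
    ann <- stage("annotate",
                 annotate_table(kept_raw, spectra = spectra, dict = dictionary,
                                default_ion_mode = config$default_ion_mode))
    funnel$n_annotated_features <- nrow(ann$annotations)

    annotated_raw <- stage("sum_siblings", {
      keep <- kept_raw$feature_id %in% ann$annotations$feature_id
      ft_replace(kept_raw,
                 features = as_tibble(unclass(kept_raw))[keep, ])
    })
    groups <- setNames(
      ann$annotations$name[match(annotated_raw$feature_id,
                                 ann$annotations$feature_id)],
      annotated_raw$feature_id
    )
    species_table <- stage("sum_siblings",
                           sum_sibling_features(annotated_raw, groups))
    funnel$n_species <- nrow(species_table)

    species_log <- stage("diffexpr",
                         log_transform(species_table, base = config$log_base,
                                       pseudocount = config$pseudocount))
    diff <- stage("diffexpr",
                  volcano(species_log, contrast = config$contrast,
                          alpha = config$alpha,
                          fc_threshold = config$fc_threshold))
    funnel$n_volcano_up <- attr(diff, "n_up")
    funnel$n_volcano_down <- attr(diff, "n_down")
    # species-level ids are either a lipid name (summed group) or the
    # original feature id (annotated singleton); recover subclass for both
    name_sub <- distinct(ann$annotations, .data$name, .data$subclass)
    species_ann <- tibble(feature_id = species_table$feature_id) |>
      left_join(rename(name_sub, sub_by_name = "subclass"),
                by = c(feature_id = "name")) |>
      left_join(select(ann$annotations, "feature_id",
                       sub_by_id = "subclass"),
                by = "feature_id") |>
      mutate(subclass = dplyr::coalesce(.data$sub_by_name, .data$sub_by_id)) |>
      filter(!is.na(.data$subclass)) |>
      select("feature_id", "subclass")
    tally <- stage("diffexpr", subclass_tally(species_ann, diff))
  }

  cyt <- NULL
  if (!is.null(panel)) {
    panel_in <- stage("cytokines", linear_range_filter(panel))
    funnel$n_analytes_in_range <- nrow(panel_in)
    cyt <- stage("cytokines",
                 injury_effect(panel_in,
                               include_batch = config$include_batch_covariate,
                               alpha = config$alpha))
  }

  selection <- NULL; cmat <- NULL; sel_pca <- NULL
  if (!is.null(panel) && !is.null(dictionary) && nrow(species_table) > 0) {
    restrict <- unique(c(config$contrast[2], config$contrast[1]))
    cmat <- stage("integrate",
                  correlation_matrix(species_table, panel_in,
                                     groups = restrict))
    selection <- stage("integrate",
                       dual_filter(cmat, diff,
                                   fc_threshold = config$fc_threshold,
                                   rho_threshold = config$rho_threshold))
    funnel$n_selected_lipids <- length(selection$lipids)
    funnel$n_selected_cytokines <- length(selection$cytokines)
    if (length(selection$lipids) >= 2) {
      sel_log <- log_transform(species_table, base = config$log_base,
                               pseudocount = config$pseudocount)
      sel_pca <- stage("integrate", selected_lipid_pca(sel_log, selection))
    }
  }

  report <- structure(
    list(funnel = funnel, config = config,
         batch_report = bf$report, annotations = ann,
         species_table = species_table, diff = diff, subclass_tally = tally,
         cytokine_effects = cyt, correlation = cmat, selection = selection,
         selected_pca = sel_pca),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$funnel)) {
    cat(sprintf("  %-24s %s\n", nm, x$funnel[[nm]]))
  }
  invisible(x)
}

#' @method glance run_report
#' @export
glance.run_report <- function(x, ...) as_tibble(x$funnel)

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(report$batch_report),
                   file.path(out_dir, "batch_filter.csv"), progress = FALSE)
  if (!is.null(report$annotations)) {
    readr::write_csv(report$annotations$annotations,
                     file.path(out_dir, "annotations.csv"), progress = FALSE)
  }
  if (!is.null(report$diff)) {
    readr::write_csv(as_tibble(report$diff),
                     file.path(out_dir, "differential.csv"), progress = FALSE)
  }
  if (!is.null(report$selection)) {
    readr::write_csv(report$selection$pairs,
                     file.path(out_dir, "integration_pairs.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(report$funnel, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
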