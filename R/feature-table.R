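#' Build a feature table from intensities and sample metadata
#'
#' The central container of the pipeline: a tibble with one row per LC-MS
#' feature (columns `feature_id`, `mz` in Da, `rt` in minutes, optionally
#' `ion_mode` and `isotope_of`, then one intensity column per sample), carrying
#' the sample metadata and any log-transform provenance as attributes so that
#' fold changes can always be computed on the raw scale.
#'
#' @param features A data frame with columns `feature_id`, `mz`, `rt` and one
#'   numeric intensity column per sample named by `sample_id`.
#' @param samples A data frame of sample metadata with columns `sample_id`,
#'   `batch` (1 or 2), `injury` (`"sham"`, `"1X"`, `"3X"`) and `sex`
#'   (`"M"`/`"F"`).
#' @param allow_missing Keep `NA` intensity cells instead of erroring.
#'
#' @return A `feature_tbl`: a tibble of features with attributes `samples`
#'   (the validated metadata tibble) and `log_info` (`NULL` until
#'   [log_transform()] is applied).
#' @export
feature_table <- function(features, samples, allow_missing = FALSE) {
  features <- as_tibble(features)
  samples <- as_tibble(samples)

  required <- c("feature_id", "mz", "rt")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  meta_req <- c("sample_id", "batch", "injury", "sex")
  missing_meta <- setdiff(meta_req, names(samples))
  if (length(missing_meta) > 0) {
    abort(paste0("sample metadata lacks column(s): ",
                 paste(missing_meta, collapse = ", ")))
  }

  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id)) {
    dup <- unique(features$feature_id[duplicated(features$feature_id)])
    abort(paste0("duplicate feature_id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample_id in metadata")
  }
  samples$batch <- as.integer(samples$batch)
  if (!all(samples$batch %in% c(1L, 2L))) abort("batch must be 1 or 2")
  if (!all(samples$injury %in% INJURY_LEVELS)) {
    abort("injury must be one of sham, 1X, 3X")
  }
  if (!all(samples$sex %in% SEX_LEVELS)) abort("sex must be M or F")

  in_table <- setdiff(names(features), c(required, "ion_mode", "isotope_of"))
  absent <- setdiff(samples$sample_id, in_table)
  if (length(absent) > 0) {
    abort(paste0("sample(s) in metadata missing from feature table: ",
                 paste(absent, collapse = ", ")))
  }
  orphan <- setdiff(in_table, samples$sample_id)
  if (length(orphan) > 0) {
    abort(paste0("intensity column(s) with no metadata: ",
                 paste(orphan, collapse = ", ")))
  }

  keep <- c(required, intersect(c("ion_mode", "isotope_of"), names(features)),
            samples$sample_id)
  features <- features[, keep]

  if (!all(is.finite(features$mz)) || any(features$mz <= 0)) {
    abort("mz must be finite and positive")
  }
  if (!all(is.finite(features$rt)) || any(features$rt < 0)) {
    abort("rt must be finite and non-negative")
  }
  ints <- as.matrix(features[, samples$sample_id, drop = FALSE])
  if (!is.numeric(ints)) abort("non-numeric intensity values")
  if (anyNA(ints) && !allow_missing) {
    abort("missing intensity cells; use allow_missing = TRUE to keep NA")
  }
  if (any(ints < 0, na.rm = TRUE)) abort("negative intensity values")

  new_feature_tbl(features, samples, log_info = NULL)
}

new_feature_tbl <- function(features, samples, log_info = NULL) {
  out <- as_tibble(features)
  attr(out, "samples") <- as_tibble(samples)
  attr(out, "log_info") <- log_info
  class(out) <- c("feature_tbl", class(tibble()))
  out
}

#' Sample metadata of a feature table
#' @param table A `feature_tbl`.
#' @return A tibble of sample metadata.
#' @export
sample_meta <- function(table) {
  stopifnot(inherits(table, "feature_tbl"))
  attr(table, "samples")
}

# features x samples numeric matrix, rownames = feature_id
intensity_matrix <- function(table) {
  sm <- sample_meta(table)
  m <- as.matrix(table[, sm$sample_id, drop = FALSE])
  rownames(m) <- table$feature_id
  m
}

# replace intensity columns / rows, keeping attributes
ft_replace <- function(table, features = NULL, samples = NULL, log_info) {
  new_feature_tbl(
    features %||% as_tibble(unclass(table)),
    samples %||% sample_meta(table),
    if (missing(log_info)) attr(table, "log_info") else log_info
  )
}

#' @export
print.feature_tbl <- function(x, ...) {
  sm <- sample_meta(x)
  li <- attr(x, "log_info")
  cat(sprintf("<feature_tbl> %d features x %d samples (%s scale)\n",
              nrow(x), nrow(sm),
              if (is.null(li)) "raw" else sprintf("log%g", li$base)))
  NextMethod()
}

#' Read a feature table and its sample metadata from CSV
#'
#' The documented dialect is a plain CSV with header
#' `feature_id,mz,rt,<sample_id>...` (optionally `ion_mode` after `rt`) and a
#' metadata CSV `sample_id,batch,injury,sex`.
#'
#' @param path Path to the feature CSV.
#' @param metadata_path Path to the sample metadata CSV.
#' @param allow_missing Map empty/`NA` cells to missing instead of erroring.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, metadata_path, allow_missing = FALSE) {
  feats <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  feature_table(feats, meta, allow_missing = allow_missing)
}

#' Write a feature table and its sample metadata to CSV
#'
#' @param table A `feature_tbl`.
#' @param path,metadata_path Output CSV paths.
#' @return `table`, invisibly.
#' @export
write_feature_table <- function(table, path, metadata_path) {
  readr::write_csv(as_tibble(unclass(table)), path, progress = FALSE)
  readr::write_csv(sample_meta(table), metadata_path, progress = FALSE)
  invisible(table)
}

#' Remove early-eluting features
#'
#' Features eluting with the solvent front suffer ion suppression; everything
#' with a retention time strictly below `min_rt` is dropped. The boundary is
#' kept: a feature at exactly `min_rt` survives.
#'
#' @param table A `feature_tbl`.
#' @param min_rt Minimum retention time in minutes (default 0.75).
#' @return The filtered `feature_tbl`, feature order preserved, with attribute
#'   `n_removed` recording the count dropped.
#' @export
rt_filter <- function(table, min_rt = 0.75) {
  stopifnot(inherits(table, "feature_tbl"), min_rt >= 0)
  keep <- table$rt >= min_rt
  out <- ft_replace(table, features = as_tibble(unclass(table))[keep, ])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Log-transform intensities
#'
#' Records the transform in the table's provenance so downstream fold-change
#' computations can invert it back to the raw scale.
#'
#' @param table A raw-scale `feature_tbl`.
#' @param base Logarithm base (> 1); default 2.
#' @param pseudocount Added to intensities before the log; default 0.
#' @return The transformed `feature_tbl` with `log_info` set.
#' @export
log_transform <- function(table, base = 2, pseudocount = 0) {
  stopifnot(inherits(table, "feature_tbl"), base > 1, pseudocount >= 0)
  if (!is.null(attr(table, "log_info"))) {
    abort("table is already log-transformed")
  }
  m <- intensity_matrix(table)
  if (any(m + pseudocount <= 0, na.rm = TRUE)) {
    abort("zero intensity with zero pseudocount; supply pseudocount > 0")
  }
  feats <- as_tibble(unclass(table))
  sm <- sample_meta(table)
  feats[, sm$sample_id] <- as_tibble(log(m + pseudocount, base = base))
  ft_replace(table, features = feats,
             log_info = list(base = base, pseudocount = pseudocount))
}

# invert log_transform; identity for raw tables
raw_intensity_matrix <- function(table) {
  m <- intensity_matrix(table)
  li <- attr(table, "log_info")
  if (is.null(li)) return(m)
  li$base^m - li$pseudocount
}

#' Sum sibling (isotopologue/adduct) features into species-level features
#'
#' Features arising from the same lipid species -- isotope peaks and alternate
#' adducts grouped by annotation -- are summed per sample on the raw scale.
#' The representative `mz`/`rt` are taken from the most intense member.
#' Summing log values is meaningless, so log-transformed tables are rejected.
#'
#' @param table A raw-scale `feature_tbl`.
#' @param groups A data frame with columns `feature_id` and `group_id`, or a
#'   named character vector `feature_id -> group_id`. Features absent from the
#'   mapping pass through unchanged; a feature may appear in at most one group.
#' @return A `feature_tbl` with one row per group plus the ungrouped features.
#' @export
sum_sibling_features <- function(table, groups) {
  stopifnot(inherits(table, "feature_tbl"))
  if (!is.null(attr(table, "log_info"))) {
    abort("sibling summation must run on raw intensities (before log_transform)")
  }
  if (!is.data.frame(groups)) {
    groups <- tibble(feature_id = names(groups), group_id = unname(groups))
  }
  groups <- as_tibble(groups)[, c("feature_id", "group_id")]
  if (nrow(groups) == 0) return(table)
  if (anyDuplicated(groups$feature_id)) {
    abort("a feature is assigned to more than one sibling group")
  }
  unknown <- setdiff(groups$feature_id, table$feature_id)
  if (length(unknown) > 0) {
    abort(paste0("grouped feature_id(s) not in table: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }

  sm <- sample_meta(table)
  feats <- as_tibble(unclass(table))
  idx <- match(groups$feature_id, feats$feature_id)

  grouped <- feats[idx, ]
  grouped$group_id <- groups$group_id
  summed <- grouped |>
    group_by(.data$group_id) |>
    summarise(
      .rep = {
        tot <- rowSums(across(all_of(sm$sample_id)))
        which.max(tot)
      },
      feature_id = .data$group_id[1],
      mz = .data$mz[.data$.rep[1]],
      rt = .data$rt[.data$.rep[1]],
      across(all_of(sm$sample_id), sum),
      .groups = "drop"
    ) |>
    select(-".rep", -"group_id")

  passthrough <- feats[-idx, setdiff(names(feats), c("ion_mode", "isotope_of"))]
  out <- bind_rows(summed, passthrough)
  ft_replace(table, features = out)
}
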