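#' @name annotate
#' @title Exact-mass annotation with fragment confirmation
#' @description Features are matched to dictionary species by precursor exact
#'   mass within a ppm tolerance over the allowed adducts; a candidate is
#'   promoted to identification-confidence level 2 when at least one diagnostic
#'   MS2 fragment is found within the fragment tolerance, and stays at level 3
#'   (precursor-only) otherwise.
NULL

# expanded (entry x adduct) theoretical m/z table for a dictionary
dictionary_ion_table <- function(dict) {
  ent <- dict$entries
  if (nrow(ent) == 0) {
    return(tibble(name = character(), subclass = character(),
                  adduct = character(), theoretical_mz = numeric(),
                  ion_mode = character()))
  }
  rows <- lapply(seq_len(nrow(ent)), function(i) {
    adds <- strsplit(ent$adducts[i], ";")[[1]]
    tibble(
      name = ent$name[i],
      subclass = ent$subclass[i],
      adduct = adds,
      theoretical_mz = vapply(adds, function(a) {
        adduct_mz(ent$monoisotopic_mass[i], a, dict$adduct_table)
      }, numeric(1), USE.NAMES = FALSE)
    )
  })
  out <- list_rbind(rows)
  out$ion_mode <- dict$adduct_table$ion_mode[
    match(out$adduct, dict$adduct_table$label)]
  out
}

# fragment m/z values (already charged formulas) for one entry + ion mode
entry_fragment_mz <- function(dict, name, ion_mode) {
  ent <- dict$entries[dict$entries$name == name, ]
  if (nrow(ent) != 1) abort(paste0("no dictionary entry named: ", name))
  frags <- strsplit(ent$fragment_formulas, ";")[[1]]
  frags <- frags[!is.na(frags) & frags != "NA" & frags != ""]
  if (length(frags) == 0) return(numeric(0))
  sign <- ifelse(grepl("-$", frags), "negative", "positive")
  unname(formula_mass(frags)[sign == ion_mode])
}

#' Match a feature m/z against the dictionary precursors
#'
#' @param mz Observed m/z (> 0).
#' @param ion_mode `"positive"` or `"negative"`; only adducts of that mode are
#'   considered.
#' @param dict A [lipid_dictionary()].
#' @return A tibble of candidates (`name`, `subclass`, `adduct`,
#'   `theoretical_mz`, `ppm`) with `|ppm| <=` the precursor tolerance, sorted
#'   by `|ppm|`; zero rows when nothing matches.
#' @export
match_precursor <- function(mz, ion_mode = c("positive", "negative"), dict) {
  stopifnot(is.numeric(mz), length(mz) == 1, mz > 0)
  ion_mode <- match.arg(ion_mode)
  ions <- dictionary_ion_table(dict)
  ions <- ions[ions$ion_mode == ion_mode, ]
  ions$ppm <- ppm_error(mz, ions$theoretical_mz)
  out <- ions[abs(ions$ppm) <= dict$tolerance_ppm_precursor, ]
  out[order(abs(out$ppm)), c("name", "subclass", "adduct", "theoretical_mz", "ppm")]
}

#' Confirm a precursor candidate against an MS2 spectrum
#'
#' @param spectrum A data frame of fragment peaks with columns `mz` and
#'   `intensity`, or `NULL` when no spectrum was acquired.
#' @param candidate A dictionary entry name.
#' @param dict A [lipid_dictionary()].
#' @param ion_mode Ion mode of the spectrum.
#' @return A list with `n_matched` (diagnostic fragments found within the
#'   fragment ppm tolerance) and `msi_level` (`2` when `n_matched >= 1`, else
#'   `3`), plus `precursor_only = TRUE` when no spectrum is available.
#' @export
confirm_fragments <- function(spectrum, candidate, dict,
                              ion_mode = c("positive", "negative")) {
  ion_mode <- match.arg(ion_mode)
  frag_mz <- entry_fragment_mz(dict, candidate, ion_mode)
  if (is.null(spectrum) || nrow(spectrum) == 0 || length(frag_mz) == 0) {
    return(list(n_matched = 0L, msi_level = 3L,
                precursor_only = is.null(spectrum)))
  }
  tol <- dict$tolerance_ppm_fragment
  n <- sum(vapply(frag_mz, function(fm) {
    any(abs(ppm_error(spectrum$mz, fm)) <= tol)
  }, logical(1)))
  list(n_matched = as.integer(n),
       msi_level = if (n >= 1) 2L else 3L,
       precursor_only = FALSE)
}

#' Annotate a feature table against a lipid dictionary
#'
#' One best annotation per feature: the candidate with the smallest absolute
#' precursor ppm error; exact ties are broken by the number of matched
#' diagnostic fragments, then lexicographic name. Features grouped upstream as
#' isotopologues (an `isotope_of` column) inherit their parent's annotation.
#' Features annotated to the same species form a sibling group for
#' [sum_sibling_features()].
#'
#' @param table A `feature_tbl` (raw or log scale; only `mz` is used).
#' @param spectra Optional named list of MS2 spectra (per `feature_id`), each a
#'   data frame with `mz` and `intensity`.
#' @param dict A [lipid_dictionary()].
#' @param default_ion_mode Used for features without an `ion_mode` column.
#' @return A list with `annotations` (tibble: `feature_id`, `name`, `subclass`,
#'   `lipid_class`, `adduct`, `precursor_ppm`, `n_fragments_matched`,
#'   `msi_level`, `precursor_only`), `sibling_groups` (tibble: `feature_id`,
#'   `group_id`) and `subclass_counts` (species per subclass).
#' @export
annotate_table <- function(table, spectra = NULL, dict,
                           default_ion_mode = "positive") {
  stopifnot(inherits(table, "feature_tbl"), inherits(dict, "lipid_dictionary"))
  ions <- dictionary_ion_table(dict)
  modes <- if ("ion_mode" %in% names(table)) table$ion_mode
           else rep(default_ion_mode, nrow(table))
  iso_parent <- if ("isotope_of" %in% names(table)) table$isotope_of
                else rep(NA_character_, nrow(table))

  annotate_one <- function(mz, mode, fid) {
    cand <- ions[ions$ion_mode == mode, ]
    cand$ppm <- ppm_error(mz, cand$theoretical_mz)
    cand <- cand[abs(cand$ppm) <= dict$tolerance_ppm_precursor, ]
    if (nrow(cand) == 0) return(NULL)
    spec <- spectra[[fid]]
    conf <- lapply(cand$name, function(nm) {
      confirm_fragments(spec, nm, dict, ion_mode = mode)
    })
    cand$n_matched <- vapply(conf, `[[`, integer(1), "n_matched")
    cand$precursor_only <- vapply(conf, `[[`, logical(1), "precursor_only")
    ord <- order(abs(cand$ppm), -cand$n_matched, cand$name)
    best <- cand[ord[1], ]
    tibble(
      feature_id = fid, name = best$name, subclass = best$subclass,
      adduct = best$adduct, precursor_ppm = best$ppm,
      n_fragments_matched = best$n_matched,
      msi_level = if (best$n_matched >= 1) 2L else 3L,
      precursor_only = best$precursor_only
    )
  }

  direct <- which(is.na(iso_parent))
  ann <- list_rbind(lapply(direct, function(i) {
    annotate_one(table$mz[i], modes[i], table$feature_id[i])
  }))

  # isotopologue children inherit the parent annotation
  children <- which(!is.na(iso_parent))
  if (length(children) > 0 && !is.null(ann) && nrow(ann) > 0) {
    inherited <- list_rbind(lapply(children, function(i) {
      par <- ann[ann$feature_id == iso_parent[i], ]
      if (nrow(par) == 0) return(NULL)
      mutate(par, feature_id = table$feature_id[i])
    }))
    ann <- bind_rows(ann, inherited)
  }

  if (is.null(ann) || nrow(ann) == 0) {
    ann <- tibble(feature_id = character(), name = character(),
                  subclass = character(), adduct = character(),
                  precursor_ppm = numeric(), n_fragments_matched = integer(),
                  msi_level = integer(), precursor_only = logical())
  }
  ann$lipid_class <- SUBCLASS_CLASS[ann$subclass]
  ann <- ann[, c("feature_id", "name", "subclass", "lipid_class", "adduct",
                 "precursor_ppm", "n_fragments_matched", "msi_level",
                 "precursor_only")]

  # only multi-member groups need summing; singletons pass through untouched
  keep_groups <- ann |>
    dplyr::count(.data$name) |>
    filter(.data$n > 1) |>
    pull("name")
  sibling_groups <- ann |>
    filter(.data$name %in% keep_groups) |>
    select("feature_id", group_id = "name")

  subclass_counts <- ann |>
    distinct(.data$name, .data$subclass) |>
    dplyr::count(.data$subclass, name = "n_species") |>
    arrange(desc(.data$n_species))

  list(annotations = ann, sibling_groups = sibling_groups,
       subclass_counts = subclass_counts)
}
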