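#' @name synth
#' @title Synthetic lipidomics / cytokine data with known ground truth
#' @description Generates feature tables, MS2 spectra and cytokine panels that
#'   emulate the statistical structure of a two-batch, three-injury-group
#'   (sham / single impact 1X / repeat impact 3X), mixed-sex rodent cortex
#'   study: log-normal baseline intensities, a batch-shifted feature subset,
#'   injury effects that predominantly decrease in the repeat-injury group,
#'   exact-mass features drawn from a lipid dictionary, and rank-copula
#'   couplings between planted lipids and cytokines. Every planted effect is
#'   returned as ground truth so downstream stages have a recoverable answer.
NULL

# analyte roster of a 27-plex rodent cytokine/chemokine bead panel; the
# flagged analytes fall outside the assay's linear range and are excluded
# from statistics, leaving the 15 detectable markers.
PANEL_ANALYTES <- tibble::tibble(
  analyte = c("EGF", "Eotaxin", "Fractalkine", "G-CSF", "GM-CSF", "GRO/KC",
              "IFN-gamma", "IL-1alpha", "IL-1beta", "IL-2", "IL-4", "IL-5",
              "IL-6", "IL-10", "IL-12p70", "IL-13", "IL-17A", "IL-18",
              "IP-10", "Leptin", "LIX", "MCP-1", "MIP-1alpha", "MIP-2",
              "RANTES", "TNF-alpha", "VEGF"),
  in_linear_range = !c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE,
                       TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
                       FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                       FALSE, TRUE, FALSE, TRUE, TRUE, FALSE,
                       FALSE, FALSE, FALSE)
)

#' Synthetic-data generator configuration
#'
#' Defaults are the study conditions the generator emulates: a 2-batch x
#' 3-injury-group x 2-sex grid, ~10^3 features with log-normal baselines,
#' a 10% batch-shifted subset at 3 standard deviations, sparse injury effects
#' that decrease in 90% of affected repeat-injury features, 2 ppm mass error,
#' and planted lipid-cytokine couplings at Spearman 0.8.
#'
#' @param n_features Number of base features (isotopologue rows are extra).
#' @param n_per_cell Animals per batch x injury cell; sexes alternate within a
#'   cell, so odd sizes split as evenly as possible.
#' @param frac_batch Fraction of features given a batch shift.
#' @param batch_shift Batch effect size in log2-intensity units.
#' @param frac_injury_3x,frac_injury_1x Fractions of features with injury
#'   effects in the 3X / 1X groups.
#' @param injury_log_fc Signed injury effect in log2 units (negative =
#'   decrease in injured animals); the magnitude is used for every affected
#'   feature, the sign for the planted integration lipids.
#' @param frac_decrease_3x Fraction of injury-affected 3X features that
#'   decrease (1X effects split 50/50).
#' @param noise_sd Residual log2-intensity standard deviation.
#' @param ppm_noise Mass-measurement error scale (ppm, 1 SD).
#' @param rho_target Planted lipid-cytokine Spearman magnitude, in (-1, 1).
#' @param n_dict_lipids Dictionary species planted as true lipid features
#'   (0 when no dictionary is supplied).
#' @param n_planted_pairs Injury-affected dictionary lipids coupled to
#'   cytokines.
#' @param coupled_cytokines Analytes receiving the couplings (round-robin).
#' @param decreased_analytes Pro-inflammatory analytes given a direct decrease
#'   in 3X animals.
#' @param cytokine_effect_sd Size of that decrease in within-analyte SD units.
#' @param frac_low_rt Fraction of decoy features eluting before 0.75 min.
#' @param frac_isotope Fraction of dictionary features given a +1 isotopologue
#'   sibling row.
#' @param n_noise_peaks Uniform noise peaks per MS2 spectrum.
#' @param drop_one_animal Mark one animal missing from the cytokine panel.
#' @param baseline_log2 Range of mean log2 baseline intensities.
#' @param seed Integer seed fixing all outputs bit-for-bit.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_features = 1000,
                         n_per_cell = 5,
                         frac_batch = 0.1,
                         batch_shift = 1.5,
                         frac_injury_3x = 0.02,
                         frac_injury_1x = 0.01,
                         injury_log_fc = -1,
                         frac_decrease_3x = 0.9,
                         noise_sd = 0.5,
                         ppm_noise = 2,
                         rho_target = 0.8,
                         n_dict_lipids = 60,
                         n_planted_pairs = 12,
                         coupled_cytokines = c("TNF-alpha", "IP-10", "Eotaxin"),
                         decreased_analytes = c("IL-1beta", "IP-10",
                                                "TNF-alpha", "RANTES"),
                         cytokine_effect_sd = 1.5,
                         frac_low_rt = 0.05,
                         frac_isotope = 0.1,
                         n_noise_peaks = 5,
                         drop_one_animal = TRUE,
                         baseline_log2 = c(10, 20),
                         seed = 1L) {
  cfg <- list(
    n_features = n_features, n_per_cell = n_per_cell, frac_batch = frac_batch,
    batch_shift = batch_shift, frac_injury_3x = frac_injury_3x,
    frac_injury_1x = frac_injury_1x, injury_log_fc = injury_log_fc,
    frac_decrease_3x = frac_decrease_3x, noise_sd = noise_sd,
    ppm_noise = ppm_noise, rho_target = rho_target,
    n_dict_lipids = n_dict_lipids, n_planted_pairs = n_planted_pairs,
    coupled_cytokines = coupled_cytokines,
    decreased_analytes = decreased_analytes,
    cytokine_effect_sd = cytokine_effect_sd, frac_low_rt = frac_low_rt,
    frac_isotope = frac_isotope, n_noise_peaks = n_noise_peaks,
    drop_one_animal = drop_one_animal, baseline_log2 = baseline_log2,
    seed = as.integer(seed)
  )
  nums <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (!all(is.finite(nums))) abort("non-finite value in synth_config")
  fracs <- c(cfg$frac_batch, cfg$frac_injury_3x, cfg$frac_injury_1x,
             cfg$frac_decrease_3x, cfg$frac_low_rt, cfg$frac_isotope)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (cfg$n_features < 1 || cfg$n_per_cell < 1) abort("counts must be >= 1")
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0")
  if (abs(cfg$rho_target) >= 1) abort("rho_target must lie in (-1, 1)")
  structure(cfg, class = "synth_config")
}

# 2 batches x 3 injury groups x n_per_cell animals, sexes alternating
synth_samples <- function(n_per_cell) {
  grid <- tidyr::expand_grid(batch = 1:2, injury = INJURY_LEVELS,
                             idx = seq_len(n_per_cell))
  grid |>
    mutate(
      sample_id = sprintf("B%d_%s_%02d", .data$batch, .data$injury, .data$idx),
      sex = SEX_LEVELS[(.data$idx - 1) %% 2 + 1]
    ) |>
    select("sample_id", "batch", "injury", "sex")
}

#' Generate a synthetic feature table with ground truth
#'
#' @param config A [synth_config()].
#' @param dictionary Optional [lipid_dictionary()]; when supplied, the first
#'   `n_dict_lipids` planted features carry dictionary-derived adduct m/z
#'   values (perturbed by `ppm_noise`) and the rest are uniform decoys.
#' @return A list with `table` (a raw-scale [feature_table()]) and `truth`
#'   (`batch_affected`, `injury_affected`, `planted_pairs`,
#'   `dictionary_truth`, `isotopes`, `low_rt`).
#' @export
generate_feature_table <- function(config, dictionary = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  samples <- synth_samples(config$n_per_cell)
  S <- nrow(samples)
  n <- config$n_features

  n_dict <- if (is.null(dictionary)) 0L else
    min(config$n_dict_lipids, nrow(dictionary$entries), n)
  feature_id <- sprintf("F%05d", seq_len(n))

  mz <- runif(n, 150, 2000)
  ion_mode <- sample(c("positive", "negative"), n, replace = TRUE)
  dictionary_truth <- tibble(feature_id = character(), name = character(),
                             adduct = character(), ion_mode = character())
  if (n_dict > 0) {
    ent <- dictionary$entries[sample(nrow(dictionary$entries), n_dict), ]
    adduct <- map_chr(strsplit(ent$adducts, ";"), 1)
    theo <- map_dbl(seq_len(n_dict), function(i) {
      adduct_mz(ent$monoisotopic_mass[i], adduct[i], dictionary$adduct_table)
    })
    mz[seq_len(n_dict)] <- theo *
      (1 + rnorm(n_dict, 0, config$ppm_noise) * 1e-6)
    ion_mode[seq_len(n_dict)] <- dictionary$adduct_table$ion_mode[
      match(adduct, dictionary$adduct_table$label)]
    dictionary_truth <- tibble(feature_id = feature_id[seq_len(n_dict)],
                               name = ent$name, adduct = adduct,
                               ion_mode = ion_mode[seq_len(n_dict)])
  }

  rt <- runif(n, 0.75, 25)
  decoys <- setdiff(seq_len(n), seq_len(n_dict))
  n_low <- min(floor(config$frac_low_rt * n), length(decoys))
  low_idx <- if (n_low > 0) sample(decoys, n_low) else integer(0)
  rt[low_idx] <- runif(n_low, 0.05, 0.749)

  eligible <- setdiff(decoys, low_idx)
  n_batch <- min(floor(config$frac_batch * n), length(eligible))
  batch_idx <- if (n_batch > 0) sample(eligible, n_batch) else integer(0)
  batch_sign <- sample(c(-1, 1), n_batch, replace = TRUE)

  pick_injury <- function(frac, force = integer(0)) {
    pool <- setdiff(seq_len(n), c(low_idx, force))
    n_want <- max(floor(frac * n) - length(force), 0)
    c(force, if (n_want > 0) sample(pool, min(n_want, length(pool)))
      else integer(0))
  }
  planted <- seq_len(min(config$n_planted_pairs, n_dict))
  idx_3x <- pick_injury(config$frac_injury_3x, force = planted)
  sign_3x <- ifelse(runif(length(idx_3x)) < config$frac_decrease_3x, -1, 1)
  sign_3x[seq_along(planted)] <- sign(config$injury_log_fc)
  idx_1x <- pick_injury(config$frac_injury_1x)
  sign_1x <- sample(c(-1, 1), length(idx_1x), replace = TRUE)

  mu <- runif(n, config$baseline_log2[1], config$baseline_log2[2])
  X <- matrix(rnorm(n * S, 0, config$noise_sd), n, S) + mu
  b2 <- samples$batch == 2L
  X[batch_idx, b2] <- X[batch_idx, b2] + batch_sign * config$batch_shift
  eff <- abs(config$injury_log_fc)
  in_3x <- samples$injury == "3X"
  in_1x <- samples$injury == "1X"
  X[idx_3x, in_3x] <- X[idx_3x, in_3x] + sign_3x * eff
  X[idx_1x, in_1x] <- X[idx_1x, in_1x] + sign_1x * eff

  feats <- tibble(feature_id = feature_id, mz = mz, rt = rt,
                  ion_mode = ion_mode,
                  isotope_of = NA_character_)
  raw <- 2^X
  colnames(raw) <- samples$sample_id
  feats <- bind_cols(feats, as_tibble(raw))

  # +1 isotopologue siblings for a fraction of the dictionary features
  isotopes <- tibble(feature_id = character(), parent = character())
  n_iso <- floor(config$frac_isotope * n_dict)
  if (n_iso > 0) {
    iso_parent <- sample(seq_len(n_dict), n_iso)
    frac_int <- runif(n_iso, 0.15, 0.4)
    iso_rows <- feats[iso_parent, ]
    iso_rows$feature_id <- paste0(feature_id[iso_parent], "_i1")
    iso_rows$mz <- (mz[iso_parent] + 1.0033548) *
      (1 + rnorm(n_iso, 0, config$ppm_noise) * 1e-6)
    iso_rows$isotope_of <- feature_id[iso_parent]
    iso_rows[, samples$sample_id] <-
      iso_rows[, samples$sample_id] * frac_int
    feats <- bind_rows(feats, iso_rows)
    isotopes <- tibble(feature_id = iso_rows$feature_id,
                       parent = iso_rows$isotope_of)
  }

  coupled <- config$coupled_cytokines
  planted_pairs <- if (length(planted) > 0 && length(coupled) > 0) {
    tibble(
      feature_id = feature_id[planted],
      cytokine = coupled[(seq_along(planted) - 1) %% length(coupled) + 1],
      rho_sign = 1
    )
  } else {
    tibble(feature_id = character(), cytokine = character(),
           rho_sign = numeric())
  }

  truth <- list(
    batch_affected = feature_id[batch_idx],
    injury_affected = bind_rows(
      tibble(feature_id = feature_id[idx_3x], group = "3X",
             log2_effect = sign_3x * eff),
      tibble(feature_id = feature_id[idx_1x], group = "1X",
             log2_effect = sign_1x * eff)
    ),
    planted_pairs = planted_pairs,
    dictionary_truth = dictionary_truth,
    isotopes = isotopes,
    low_rt = feature_id[low_idx]
  )
  list(table = feature_table(feats, samples), truth = truth)
}

#' Generate MS2 spectra for synthetic features
#'
#' Dictionary-truth features receive their entry's diagnostic fragment masses
#' perturbed by `ppm_noise`, plus uniform noise peaks; all other features of
#' the supplied table receive noise-only spectra.
#'
#' @param truth Ground truth from [generate_feature_table()].
#' @param dictionary The [lipid_dictionary()] the truth was drawn from.
#' @param config The same [synth_config()].
#' @param table Optional `feature_tbl`; when given, decoy features get
#'   noise-only spectra too.
#' @return A named list (by `feature_id`) of spectra tibbles (`mz`,
#'   `intensity`).
#' @export
generate_ms2 <- function(truth, dictionary, config, table = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  dt <- truth$dictionary_truth
  missing_entries <- setdiff(dt$name, dictionary$entries$name)
  if (length(missing_entries) > 0) {
    abort(paste0("truth feature(s) missing from dictionary: ",
                 paste(missing_entries, collapse = ", ")))
  }
  noise_spec <- function(precursor) {
    k <- config$n_noise_peaks
    tibble(mz = runif(k, 50, max(precursor, 60)),
           intensity = runif(k, 0.01, 0.3))
  }
  spectra <- list()
  if (nrow(dt) > 0) {
    mzs <- if (!is.null(table)) {
      table$mz[match(dt$feature_id, table$feature_id)]
    } else {
      rep(1000, nrow(dt))
    }
    for (i in seq_len(nrow(dt))) {
      frag <- entry_fragment_mz(dictionary, dt$name[i], dt$ion_mode[i])
      peaks <- tibble(
        mz = frag * (1 + rnorm(length(frag), 0, config$ppm_noise) * 1e-6),
        intensity = runif(length(frag), 0.5, 1)
      )
      spectra[[dt$feature_id[i]]] <- bind_rows(peaks, noise_spec(mzs[i]))
    }
  }
  if (!is.null(table)) {
    rest <- setdiff(table$feature_id, dt$feature_id)
    for (fid in rest) {
      spectra[[fid]] <- noise_spec(table$mz[match(fid, table$feature_id)])
    }
  }
  spectra
}

#' Generate a synthetic cytokine panel
#'
#' Concentrations are Gaussian per analyte on the assay scale (baseline mean
#' drawn once per analyte, 15% coefficient of variation), so planted effects
#' are exact multiples of the within-analyte SD on the scale the injury-effect
#' model analyses. Designated pro-inflammatory analytes receive a direct
#' decrease in the repeat-injury animals; analytes named in the planted pairs
#' are instead coupled to their partner lipids through a Gaussian rank copula
#' whose latent correlation `2 sin(pi rho / 6)` realizes the target Spearman
#' (a cytokine with several partner lipids is coupled to the standardized
#' mean of their log intensities, inheriting the lipids' injury effect).
#'
#' @param table The synthetic `feature_tbl`.
#' @param truth Its ground truth.
#' @param config The same [synth_config()].
#' @return A [cytokine_panel()]; one animal is omitted when
#'   `drop_one_animal` is set.
#' @export
generate_cytokines <- function(table, truth, config) {
  stopifnot(inherits(config, "synth_config"), inherits(table, "feature_tbl"))
  if (abs(config$rho_target) >= 1) abort("rho_target must lie in (-1, 1)")
  set.seed(config$seed + 2L)
  animals <- sample_meta(table)
  if (config$drop_one_animal && nrow(animals) > 1) {
    animals <- animals[-sample(nrow(animals), 1), ]
  }
  nA <- nrow(animals)
  roster <- PANEL_ANALYTES
  logX <- log2(raw_intensity_matrix(table)[, animals$sample_id, drop = FALSE])

  r_latent <- 2 * sin(pi * config$rho_target / 6)
  conc <- matrix(NA_real_, nrow(roster), nA,
                 dimnames = list(roster$analyte, animals$sample_id))
  for (i in seq_len(nrow(roster))) {
    a <- roster$analyte[i]
    base_mean <- runif(1, 20, 500)   # assay units, e.g. pg per mg protein
    base_sd <- 0.15 * base_mean
    partners <- truth$planted_pairs$feature_id[truth$planted_pairs$cytokine == a]
    if (length(partners) > 0) {
      zl <- scale(t(logX[partners, , drop = FALSE]))   # animals x partners
      zbar <- rowMeans(zl)
      zbar <- zbar / sd(zbar)
      z <- r_latent * zbar + sqrt(1 - r_latent^2) * rnorm(nA)
    } else {
      z <- rnorm(nA)
      if (a %in% config$decreased_analytes) {
        z[animals$injury == "3X"] <- z[animals$injury == "3X"] -
          config$cytokine_effect_sd
      }
    }
    conc[i, ] <- pmax(base_mean + base_sd * z, 0)
  }
  cytokine_panel(bind_cols(roster, as_tibble(conc)), animals)
}

#' Generate the full synthetic bundle
#'
#' Convenience wrapper: feature table + ground truth, MS2 spectra and
#' cytokine panel from one configuration.
#'
#' @param config A [synth_config()].
#' @param dictionary A [lipid_dictionary()] (default the built-in one); `NULL`
#'   for a dictionary-free table.
#' @return A list with `table`, `truth`, `spectra`, `panel`, `dictionary`.
#' @export
generate_bundle <- function(config, dictionary = default_lipid_dictionary()) {
  ft <- generate_feature_table(config, dictionary)
  spectra <- if (is.null(dictionary)) list()
             else generate_ms2(ft$truth, dictionary, config, table = ft$table)
  panel <- generate_cytokines(ft$table, ft$truth, config)
  list(table = ft$table, truth = ft$truth, spectra = spectra, panel = panel,
       dictionary = dictionary)
}
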