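test_that("synth_config validates its fields", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(frac_batch = 1.2), "fractions")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(rho_target = 1), "rho_target")
  expect_error(synth_config(n_features = 0), "counts")
  expect_error(synth_config(batch_shift = Inf), "non-finite")
})

test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- synth_config(n_features = 200, n_per_cell = 3, seed = 7)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$table, b2$table)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$spectra, b2$spectra)
  expect_identical(b1$panel, b2$panel)
  # a different seed gives different data
  b3 <- generate_bundle(synth_config(n_features = 200, n_per_cell = 3,
                                     seed = 8))
  expect_false(identical(b1$table, b3$table))
})

test_that("the sample grid and planted structure match the configuration", {
  cfg <- synth_config(n_features = 500, n_per_cell = 5, frac_batch = 0.1,
                      frac_low_rt = 0.08, n_dict_lipids = 40, seed = 3)
  ft <- generate_feature_table(cfg, default_lipid_dictionary())
  sm <- sample_meta(ft$table)
  expect_equal(nrow(sm), 2 * 3 * 5)
  expect_equal(unname(base::table(sm$batch, sm$injury)["1", ]), rep(5, 3))
  # sexes split as evenly as an odd cell size allows
  expect_true(all(base::table(sm$sex) %in% c(12, 18)))

  expect_equal(nrow(ft$truth$dictionary_truth), 40)
  expect_equal(length(ft$truth$batch_affected), 50)
  expect_equal(sum(ft$table$rt < 0.75), 40)
  # planted integration lipids are never batch-confounded
  expect_false(any(ft$truth$dictionary_truth$feature_id %in%
                     ft$truth$batch_affected))
  # planted pairs reference injury-affected lipids
  expect_true(all(ft$truth$planted_pairs$feature_id %in%
                    ft$truth$injury_affected$feature_id))
})

test_that("planted m/z values sit within ppm noise of their dictionary ions", {
  dict <- default_lipid_dictionary()
  cfg <- synth_config(n_features = 200, n_per_cell = 2, n_dict_lipids = 50,
                      ppm_noise = 2, seed = 11)
  ft <- generate_feature_table(cfg, dict)
  dt <- ft$truth$dictionary_truth
  theo <- sapply(seq_len(nrow(dt)), function(i) {
    adduct_mz(dict$entries$monoisotopic_mass[
      match(dt$name[i], dict$entries$name)], dt$adduct[i])
  })
  obs <- ft$table$mz[match(dt$feature_id, ft$table$feature_id)]
  ppm <- 1e6 * (obs - theo) / theo
  expect_lt(max(abs(ppm)), 10)          # ~5 sigma
  expect_lt(abs(mean(ppm)), 1)          # centred
})

test_that("MS2 spectra contain diagnostic fragments for truth features only", {
  dict <- default_lipid_dictionary()
  cfg <- synth_config(n_features = 120, n_per_cell = 2, n_dict_lipids = 30,
                      seed = 9)
  ft <- generate_feature_table(cfg, dict)
  spectra <- generate_ms2(ft$truth, dict, cfg, table = ft$table)
  expect_setequal(names(spectra), ft$table$feature_id)

  dt <- ft$truth$dictionary_truth
  frag_hit <- sapply(seq_len(nrow(dt)), function(i) {
    res <- confirm_fragments(spectra[[dt$feature_id[i]]], dt$name[i], dict,
                             dt$ion_mode[i])
    res$n_matched >= 1
  })
  expect_true(all(frag_hit))

  # decoys carry only uniform noise: diagnostic hits are rare
  decoys <- setdiff(ft$table$feature_id, dt$feature_id)
  decoy_hits <- sapply(head(decoys, 40), function(fid) {
    res <- confirm_fragments(spectra[[fid]], "PC(34:1)", dict, "positive")
    res$n_matched
  })
  expect_lte(mean(decoy_hits >= 1), 0.1)

  # empty truth set: no fragment-bearing spectra are produced
  empty_truth <- ft$truth
  empty_truth$dictionary_truth <- dt[0, ]
  expect_equal(length(generate_ms2(empty_truth, dict, cfg)), 0)

  # a truth feature missing from the dictionary is an error
  bad <- ft$truth
  bad$dictionary_truth$name[1] <- "XX(1:0)"
  expect_error(generate_ms2(bad, dict, cfg), "missing from dictionary")
})

test_that("planted cytokine couplings realize the target Spearman at high rho", {
  cfg <- synth_config(n_features = 60, n_per_cell = 9, n_dict_lipids = 10,
                      n_planted_pairs = 3, rho_target = 0.95,
                      drop_one_animal = FALSE, seed = 15)
  b <- generate_bundle(cfg)
  an <- panel_animals(b$panel)
  logx <- log2(as.matrix(b$table[, an$sample_id]))
  rownames(logx) <- b$table$feature_id
  pm <- as.matrix(b$panel[, an$sample_id])
  rownames(pm) <- b$panel$analyte
  rhos <- sapply(seq_len(nrow(b$truth$planted_pairs)), function(i) {
    pp <- b$truth$planted_pairs[i, ]
    spearman_rho(logx[pp$feature_id, ], pm[pp$cytokine, ])
  })
  expect_true(all(rhos >= 0.8))
})

test_that("uncoupled cytokines show null correlations with planted lipids", {
  cfg <- synth_config(n_features = 60, n_per_cell = 9, n_dict_lipids = 10,
                      n_planted_pairs = 0, frac_injury_3x = 0,
                      frac_injury_1x = 0, drop_one_animal = FALSE, seed = 25)
  b <- generate_bundle(cfg)
  an <- panel_animals(b$panel)
  logx <- log2(as.matrix(b$table[, an$sample_id]))
  pm <- as.matrix(b$panel[, an$sample_id])
  rhos <- as.vector(cor(t(logx[1:10, ]), t(pm), method = "spearman"))
  # n = 54 animals: null |rho| above 0.4 is a ~0.3% event per cell
  expect_lt(mean(abs(rhos) >= 0.4), 0.05)
})
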