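make_panel <- function(seed = 1, n_per_cell = 4, effect = 0,
                       targets = character(0)) {
  set.seed(seed)
  animals <- sample_meta(tiny_table(n_per_cell = n_per_cell, seed = seed))
  conc <- t(sapply(1:6, function(i) {
    z <- rnorm(nrow(animals))
    if (paste0("A", i) %in% targets) {
      z[animals$injury == "3X"] <- z[animals$injury == "3X"] - effect
    }
    100 + 15 * z
  }))
  colnames(conc) <- animals$sample_id
  cytokine_panel(
    cbind(data.frame(analyte = paste0("A", 1:6),
                     in_linear_range = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)),
          conc),
    animals
  )
}

test_that("linear_range_filter is driven entirely by the flags", {
  panel <- make_panel()
  kept <- linear_range_filter(panel)
  expect_equal(nrow(kept), 4)
  expect_true(all(kept$in_linear_range))

  all_in <- panel
  all_in$in_linear_range <- TRUE
  expect_equal(nrow(linear_range_filter(all_in)), 6)
  none <- panel
  none$in_linear_range <- FALSE
  expect_warning(out <- linear_range_filter(none), "empty")
  expect_equal(nrow(out), 0)
})

test_that("the default synthetic roster leaves the detectable analytes after flag filtering", {
  cfg <- synth_config(n_features = 5, n_per_cell = 2, n_dict_lipids = 0,
                      drop_one_animal = FALSE, seed = 2)
  ft <- generate_feature_table(cfg)
  panel <- generate_cytokines(ft$table, ft$truth, cfg)
  expect_equal(nrow(panel), 27)
  kept <- linear_range_filter(panel)
  expect_equal(nrow(kept), 15)
  expect_true(all(c("IL-1beta", "IP-10", "TNF-alpha", "RANTES", "Eotaxin")
                  %in% kept$analyte))
  expect_false(any(c("EGF", "Leptin", "MCP-1") %in% kept$analyte))
})

test_that("zscore_by_analyte normalizes rows and is idempotent and shift-invariant", {
  panel <- make_panel(seed = 6)
  an <- panel_animals(panel)
  feats <- as.data.frame(panel)
  feats[1, an$sample_id] <- as.list(c(1, 2, 3, rep(2, nrow(an) - 3)))
  panel2 <- cytokine_panel(feats, an)
  z <- zscore_by_analyte(panel2)
  zm <- as.matrix(z[, an$sample_id])
  expect_equal(unname(rowMeans(zm)), rep(0, nrow(zm)), tolerance = 1e-12)
  expect_equal(unname(apply(zm, 1, sd)), rep(1, nrow(zm)), tolerance = 1e-12)
  # (1, 2, 3) with the rest at 2: symmetric, so z1 = -z3 and z2 = 0
  expect_equal(unname(zm[1, 2]), 0, tolerance = 1e-12)
  expect_equal(unname(zm[1, 1]), unname(-zm[1, 3]), tolerance = 1e-12)

  # shifting an analyte by a constant changes nothing
  feats2 <- as.data.frame(panel)
  feats2[2, an$sample_id] <- feats2[2, an$sample_id] + 500
  z2 <- zscore_by_analyte(cytokine_panel(feats2, an))
  expect_equal(as.matrix(z2[, an$sample_id])[2, ],
               as.matrix(zscore_by_analyte(panel)[, an$sample_id])[2, ],
               tolerance = 1e-12)

  # z of (z + constant) equals z: idempotence up to the location shift that
  # keeps concentrations non-negative
  zz <- cytokine_panel(cbind(data.frame(analyte = z$analyte,
                                        in_linear_range = TRUE),
                             as.data.frame(zm + 10)), an)
  expect_equal(as.matrix(zscore_by_analyte(zz)[, an$sample_id]), zm,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("injury_effect reduces to anova_tukey without the batch covariate", {
  panel <- make_panel(seed = 11, effect = 2, targets = c("A1", "A2"))
  eff <- injury_effect(panel, include_batch = FALSE)
  td <- tidy(eff)
  an <- panel_animals(panel)
  m <- as.matrix(panel[, an$sample_id])
  for (i in seq_len(nrow(panel))) {
    ref <- anova_tukey(m[i, ], factor(an$injury, c("sham", "1X", "3X")))
    ours <- td[td$analyte == panel$analyte[i], ]
    expect_equal(ours$p_adj[ours$contrast == "3X vs sham"],
                 unname(ref$p_tukey["sham vs 3X"]), tolerance = 1e-6)
    expect_equal(ours$p_adj[ours$contrast == "1X vs sham"],
                 unname(ref$p_tukey["sham vs 1X"]), tolerance = 1e-6)
  }
})

test_that("injury_effect flags planted decreases and is label-exchangeable", {
  panel <- make_panel(seed = 21, n_per_cell = 6, effect = 2.5,
                      targets = c("A1", "A3"))
  td <- tidy(injury_effect(panel))
  dec <- td$analyte[td$contrast == "3X vs sham" & td$significant &
                      td$direction == "decreased"]
  expect_setequal(dec, c("A1", "A3"))

  # permuting animal columns (metadata follows) leaves results unchanged
  an <- panel_animals(panel)
  perm <- sample(nrow(an))
  panel_p <- cytokine_panel(as.data.frame(panel)[, c("analyte",
                                                     "in_linear_range",
                                                     an$sample_id[perm])],
                            an[perm, ])
  td_p <- tidy(injury_effect(panel_p))
  expect_equal(td_p$p_adj, td$p_adj, tolerance = 1e-10)
})

test_that("a missing animal is handled by complete-case analysis", {
  panel <- make_panel(seed = 31, n_per_cell = 5, effect = 2.5, targets = "A1")
  an <- panel_animals(panel)
  feats <- as.data.frame(panel)
  feats[[an$sample_id[1]]][2] <- NA   # one missing cell in analyte A2
  panel_na <- cytokine_panel(feats, an)
  td <- tidy(injury_effect(panel_na))
  expect_true(all(is.finite(td$p_adj)))
  # analyte A1 (complete) is unaffected by A2's missing cell
  td_full <- tidy(injury_effect(panel))
  expect_equal(td$p_adj[td$analyte == "A1"],
               td_full$p_adj[td_full$analyte == "A1"], tolerance = 1e-12)

  panel_csv <- withr::local_tempfile(fileext = ".csv")
  meta_csv <- withr::local_tempfile(fileext = ".csv")
  write_cytokine_panel(panel, panel_csv, meta_csv)
  back <- read_cytokine_panel(panel_csv, meta_csv)
  expect_equal(as.data.frame(back), as.data.frame(panel), tolerance = 1e-12)
})
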