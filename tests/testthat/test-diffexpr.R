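test_that("anova_tukey matches aov + TukeyHSD across random datasets", {
  set.seed(14)
  for (i in 1:15) {
    g <- factor(rep(c("sham", "1X", "3X"), each = sample(3:8, 1)),
                levels = c("sham", "1X", "3X"))
    v <- rnorm(length(g), mean = as.integer(g) * runif(1, 0, 1))
    ours <- anova_tukey(v, g)
    fit <- aov(v ~ g)
    expect_equal(ours$p_anova, summary(fit)[[1]]$`Pr(>F)`[1],
                 tolerance = 1e-10)
    ref <- TukeyHSD(fit)$g
    # our pair labels are "a vs b" in level order; TukeyHSD uses "b-a"
    for (pair in rownames(ref)) {
      lv <- rev(strsplit(pair, "-")[[1]])
      ok <- ours$p_tukey[paste(lv[1], "vs", lv[2])]
      if (is.na(ok)) ok <- ours$p_tukey[paste(lv[2], "vs", lv[1])]
      expect_equal(unname(ok), ref[pair, "p adj"], tolerance = 1e-8)
    }
  }
})

test_that("anova_tukey handles degenerate and near-degenerate groups", {
  g <- rep(c("a", "b", "c"), each = 4)
  expect_equal(anova_tukey(rep(1, 12), g)$p_anova, 1)
  expect_true(all(anova_tukey(rep(1, 12), g)$p_tukey == 1))

  set.seed(1)
  v <- c(rep(0, 8), rep(5, 4)) + rnorm(12, 0, 1e-6)
  res <- anova_tukey(v, g)
  expect_lt(res$p_anova, 1e-6)
  expect_lt(res$p_tukey["a vs c"], 1e-6)
  expect_lt(res$p_tukey["b vs c"], 1e-6)
  expect_gt(res$p_tukey["a vs b"], 0.9)
})

test_that("Tukey-adjusted p is never smaller than the unadjusted pairwise p", {
  set.seed(3)
  for (i in 1:20) {
    g <- rep(c("a", "b", "c"), each = 5)
    v <- rnorm(15)
    res <- anova_tukey(v, g)
    # unadjusted pairwise p from the same model MSE: t = q / sqrt(2)
    fit <- aov(v ~ factor(g))
    mse <- sum(residuals(fit)^2) / fit$df.residual
    tt <- abs(mean(v[g == "a"]) - mean(v[g == "b"])) /
      sqrt(mse * (1 / 5 + 1 / 5))
    p_unadj <- 2 * pt(-tt, fit$df.residual)
    expect_gte(res$p_tukey["a vs b"] + 1e-10, p_unadj)
  }
})

test_that("anova_tukey agrees with a permutation ANOVA oracle", {
  set.seed(9)
  diffs <- replicate(8, {
    g <- rep(c("a", "b", "c"), each = 4)
    v <- rnorm(12, mean = rep(c(0, 0.5, 1), each = 4))
    abs(anova_tukey(v, g)$p_anova -
          perm_p_anova(v, g, n_perm = 2000, seed = sample(1e6, 1)))
  })
  expect_lt(max(diffs), 0.1)
})

test_that("fold_change is a ratio of means with reciprocal duality", {
  expect_equal(fold_change(c(120, 130), c(95, 105)), 1.25)
  expect_equal(fold_change(c(75, 85), c(95, 105)), 0.8)
  expect_equal(fold_change(c(7, 8, 9), c(7, 8, 9)), 1)
  expect_equal(fold_change(c(2, 4), c(5, 5)) * fold_change(c(5, 5), c(2, 4)), 1)
  expect_error(fold_change(c(0, 0), c(1, 2)), "positive")
})

test_that("volcano recovers planted decreases and respects alpha", {
  cfg <- synth_config(n_features = 500, n_per_cell = 9, frac_batch = 0,
                      frac_injury_3x = 0.1, injury_log_fc = -1,
                      frac_decrease_3x = 1, frac_low_rt = 0,
                      n_dict_lipids = 0, seed = 17)
  ft <- generate_feature_table(cfg)
  v <- volcano(log_transform(ft$table))
  planted <- ft$truth$injury_affected$feature_id[
    ft$truth$injury_affected$group == "3X"]
  cls <- v$volcano_class[match(planted, v$feature_id)]
  expect_gte(mean(cls == "down"), 0.9)
  nulls <- setdiff(v$feature_id, planted)
  expect_lte(mean(v$volcano_class[match(nulls, v$feature_id)] != "ns"), 0.05)

  # alpha = 0: everything ns
  v0 <- volcano(log_transform(ft$table), alpha = 0)
  expect_true(all(v0$volcano_class == "ns"))

  # relabelling the contrast maps up <-> down and inverts FC
  vr <- volcano(log_transform(ft$table), contrast = c("sham", "3X"))
  expect_equal(vr$fold_change, 1 / v$fold_change, tolerance = 1e-12)
  expect_equal(attr(vr, "n_up"), attr(v, "n_down"))
  expect_equal(attr(vr, "n_down"), attr(v, "n_up"))
  expect_equal(vr$p_tukey, v$p_tukey)
})

test_that("volcano classification matches its defining thresholds exactly", {
  cfg <- synth_config(n_features = 300, n_per_cell = 5, frac_injury_3x = 0.1,
                      frac_low_rt = 0, n_dict_lipids = 0, seed = 23)
  v <- volcano(log_transform(generate_feature_table(cfg)$table))
  up <- v$volcano_class == "up"
  dn <- v$volcano_class == "down"
  expect_true(all(v$fold_change[up] >= 1.25 & v$p_tukey[up] < 0.05))
  expect_true(all(v$fold_change[dn] <= 1 / 1.25 & v$p_tukey[dn] < 0.05))
  expect_true(all(v$fold_change[!up & !dn] > 1 / 1.25 &
                    v$fold_change[!up & !dn] < 1.25 |
                    v$p_tukey[!up & !dn] >= 0.05))
})

test_that("subclass_tally mirrors the increase/decrease bookkeeping", {
  ann <- tibble::tibble(feature_id = sprintf("f%d", 1:6),
                        subclass = c(rep("Car", 4), "FFA", "FFA"))
  diff <- tibble::tibble(feature_id = sprintf("f%d", 1:6),
                         fold_change = c(1.2, 1.3, 1.1, 0.9, 0.5, 1))
  tal <- subclass_tally(ann, diff)
  car <- tal[tal$subclass == "Car", ]
  expect_equal(car$n_increased, 3)
  expect_equal(car$n_decreased, 1)
  expect_equal(car$fraction_decreased, 0.25)
  ffa <- tal[tal$subclass == "FFA", ]
  expect_equal(ffa$n_unchanged, 1)
  expect_equal(ffa$fraction_decreased, 1)
  # empty subclasses are absent
  expect_false("PC" %in% tal$subclass)
})
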