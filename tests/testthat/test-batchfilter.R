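test_that("welch_p matches stats::t.test and handles degenerate features", {
  x <- c(10, 11, 12, 13); y <- c(20, 21, 22, 23)
  ref <- t.test(x, y)
  expect_equal(welch_p(x, y), ref$p.value, tolerance = 1e-12)
  # hand computation: mean diff -10, s^2 = 5/3 each, se = 0.91287,
  # t = -10.954, Welch-Satterthwaite df = 6
  expect_equal(unname(ref$statistic), -10.9545, tolerance = 1e-4)
  expect_equal(unname(ref$parameter), 6)
  expect_lt(welch_p(x, y), 0.001)

  expect_equal(welch_p(c(1, 2, 3), c(1, 2, 3)), 1)
  # degenerate conventions: both constant
  expect_equal(welch_p(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(welch_p(c(5, 5, 5), c(7, 7, 7)), 0)
  expect_error(welch_p(1, c(1, 2)), "at least 2")

  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 2))
    expect_equal(welch_p(a, b), t.test(a, b)$p.value, tolerance = 1e-12)
  }
})

test_that("welch_p agrees with a permutation oracle on small normal samples", {
  set.seed(10)
  diffs <- replicate(12, {
    a <- rnorm(6); b <- rnorm(6, mean = runif(1, 0, 1.5))
    abs(welch_p(a, b) - perm_p_two_sample(a, b, n_perm = 4000,
                                          seed = sample(1e6, 1)))
  })
  expect_lt(max(diffs), 0.1)
  expect_lt(mean(diffs), 0.04)
})

test_that("sham filter removes shifted features, spares injury-only features", {
  cfg <- synth_config(n_features = 1000, n_per_cell = 5, frac_batch = 0.1,
                      batch_shift = 1.5, noise_sd = 0.5, frac_injury_3x = 0.05,
                      frac_low_rt = 0, n_dict_lipids = 0, seed = 7)
  ft <- generate_feature_table(cfg)
  bf <- sham_batch_filter(log_transform(ft$table))
  shifted <- ft$truth$batch_affected
  injury_only <- setdiff(ft$truth$injury_affected$feature_id, shifted)
  expect_gte(mean(shifted %in% bf$report$removed_ids), 0.80)
  expect_lte(mean(injury_only %in% bf$report$removed_ids), 0.10)
  # funnel bookkeeping
  expect_equal(sort(c(bf$report$kept_ids, bf$report$removed_ids)),
               sort(ft$table$feature_id))
  expect_equal(nrow(bf$table), bf$report$n_kept)
})

test_that("sham filter never inspects non-sham samples", {
  cfg <- synth_config(n_features = 300, n_per_cell = 4, frac_batch = 0.1,
                      n_dict_lipids = 0, frac_low_rt = 0, seed = 3)
  raw <- generate_feature_table(cfg)$table
  bf1 <- sham_batch_filter(log_transform(raw))
  # perturb every injured sample wildly (on the raw scale)
  sm <- sample_meta(raw)
  feats <- tibble::as_tibble(unclass(raw))
  injured <- sm$sample_id[sm$injury != "sham"]
  set.seed(1)
  feats[, injured] <- feats[, injured] *
    matrix(2^rnorm(nrow(feats) * length(injured), 0, 5), nrow(feats))
  bf2 <- sham_batch_filter(log_transform(feature_table(feats, sm)))
  expect_identical(bf1$report$removed_ids, bf2$report$removed_ids)
})

test_that("alpha = 0 and byte-identical sham batches remove nothing", {
  expect_equal(
    sham_batch_filter(log_transform(tiny_table(n_feat = 20, seed = 5)),
                      alpha = 0)$report$n_removed, 0)
  tab <- tiny_table(n_feat = 20, seed = 5)
  sm <- sample_meta(tab)
  feats <- tibble::as_tibble(unclass(tab))
  sham1 <- sm$sample_id[sm$injury == "sham" & sm$batch == 1]
  sham2 <- sm$sample_id[sm$injury == "sham" & sm$batch == 2]
  feats[, sham2] <- feats[, sham1]
  bf <- sham_batch_filter(log_transform(feature_table(feats, sm)))
  expect_equal(bf$report$n_removed, 0)
})

test_that("all-sample filter is calibrated under the null and catches strong shifts", {
  removed <- sapply(1:30, function(s) {
    cfg <- synth_config(n_features = 500, n_per_cell = 4, frac_batch = 0,
                        frac_injury_3x = 0, frac_injury_1x = 0,
                        frac_low_rt = 0, n_dict_lipids = 0, seed = s)
    tab <- log_transform(generate_feature_table(cfg)$table)
    all_sample_batch_filter(tab)$report$n_removed / 500
  })
  expect_equal(mean(removed), 0.05, tolerance = 0.3)

  # single feature with a strong batch shift is removed
  tab <- tiny_table(n_feat = 1, seed = 2)
  sm <- sample_meta(tab)
  feats <- tibble::as_tibble(unclass(tab))
  feats[, sm$sample_id[sm$batch == 2]] <-
    feats[, sm$sample_id[sm$batch == 2]] * 64
  bf <- all_sample_batch_filter(log_transform(feature_table(feats, sm)))
  expect_equal(bf$report$n_removed, 1)
})

test_that("batch-balanced injury effects are not preferentially removed by the all-sample filter", {
  hit_inj <- c(); hit_null <- c()
  for (s in 1:10) {
    cfg <- synth_config(n_features = 500, n_per_cell = 4, frac_batch = 0,
                        frac_injury_3x = 0.2, injury_log_fc = -1,
                        frac_low_rt = 0, n_dict_lipids = 0, seed = s)
    ft <- generate_feature_table(cfg)
    bf <- all_sample_batch_filter(log_transform(ft$table))
    inj <- unique(ft$truth$injury_affected$feature_id)
    nul <- setdiff(ft$table$feature_id, inj)
    hit_inj <- c(hit_inj, mean(inj %in% bf$report$removed_ids))
    hit_null <- c(hit_null, mean(nul %in% bf$report$removed_ids))
  }
  # balanced injury effects inflate the within-batch variance, so the Welch
  # filter is conservative (not aggressive) on them: never removed more often
  # than null features
  expect_lte(mean(hit_inj), mean(hit_null) + 0.01)
})

test_that("PCA diagnostics expose cluster structure and obey variance invariants", {
  set.seed(6)
  tab <- tiny_table(n_feat = 40, seed = 6)
  sm <- sample_meta(tab)
  feats <- tibble::as_tibble(unclass(tab))
  # plant a strong batch shift on all features: PC1 must separate batches
  b2 <- sm$sample_id[sm$batch == 2]
  feats[, b2] <- feats[, b2] * 2^3
  tab2 <- log_transform(feature_table(feats, sm))
  diag <- pca_diagnostics(tab2)
  expect_true(all(diff(diag$variance_fraction) <= 1e-12))
  expect_lte(sum(diag$variance_fraction), 1 + 1e-8)
  sep <- batch_separation_score(diag, "batch")
  expect_equal(which.max(sep$score), 1L)
  expect_gt(sep$score[1], 3)

  # orthonormal rotation of the feature space leaves variance fractions alone
  X <- t(as.matrix(tab2[, sm$sample_id]))
  Q <- qr.Q(qr(matrix(rnorm(40 * 40), 40)))
  feats_rot <- feats
  feats_rot[, sm$sample_id] <- t(2^(X %*% Q))
  dr <- pca_diagnostics(log_transform(feature_table(feats_rot, sm)))
  expect_equal(dr$variance_fraction, diag$variance_fraction, tolerance = 1e-8)
})

test_that("separation score is zero for identical groups and sign-flip invariant", {
  tab <- log_transform(tiny_table(n_feat = 30, seed = 12))
  diag <- pca_diagnostics(tab)
  sep1 <- batch_separation_score(diag, "batch")
  # flipping a component's sign changes nothing
  diag2 <- diag
  diag2$scores$PC1 <- -diag2$scores$PC1
  sep2 <- batch_separation_score(diag2, "batch")
  expect_equal(sep1$score, sep2$score)
  # same scores in both groups: exact zero
  d0 <- diag
  sm <- sample_meta(tab)
  d0$scores$batch <- rep(1:2, length.out = nrow(d0$scores))
  d0$scores[d0$scores$batch == 2, grep("^PC", names(d0$scores))] <-
    d0$scores[d0$scores$batch == 1, grep("^PC", names(d0$scores))]
  expect_true(all(batch_separation_score(d0, "batch")$score < 1e-12))
  expect_error(batch_separation_score(diag, rep(1, nrow(diag$scores))),
               "two label groups")
})

test_that("filtering reduces the dominant batch separation on shifted tables", {
  cfg <- synth_config(n_features = 400, n_per_cell = 5, frac_batch = 0.25,
                      batch_shift = 2, frac_low_rt = 0, n_dict_lipids = 0,
                      seed = 21)
  tab <- log_transform(generate_feature_table(cfg)$table)
  before <- max(batch_separation_score(pca_diagnostics(tab), "batch")$score)
  bf <- sham_batch_filter(tab)
  after <- max(batch_separation_score(pca_diagnostics(bf$table), "batch")$score)
  expect_lt(after, before)
})
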