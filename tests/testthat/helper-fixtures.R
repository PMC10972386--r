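# small hand-built fixtures used across the suite

# a tiny feature table with explicit values; intensities filled column-major
tiny_table <- function(n_feat = 4, n_per_cell = 2, seed = 1,
                       rt = NULL, mz = NULL) {
  set.seed(seed)
  samples <- expand.grid(batch = 1:2, injury = c("sham", "1X", "3X"),
                         idx = seq_len(n_per_cell),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("S%02d", seq_len(nrow(samples)))
  samples$sex <- rep(c("M", "F"), length.out = nrow(samples))
  feats <- data.frame(
    feature_id = sprintf("f%02d", seq_len(n_feat)),
    mz = if (is.null(mz)) runif(n_feat, 200, 900) else mz,
    rt = if (is.null(rt)) runif(n_feat, 1, 20) else rt
  )
  ints <- matrix(2^rnorm(n_feat * nrow(samples), 15, 1), n_feat)
  colnames(ints) <- samples$sample_id
  feature_table(cbind(feats, ints),
                samples[, c("sample_id", "batch", "injury", "sex")])
}

# exact permutation p for a two-sample difference-of-means test
perm_p_two_sample <- function(x, y, n_perm = 4000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  nx <- length(x)
  stats <- replicate(n_perm, {
    idx <- sample(length(pooled), nx)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1)
}

# permutation one-way ANOVA p (F statistic under label shuffles)
perm_p_anova <- function(values, groups, n_perm = 2000, seed = 1) {
  set.seed(seed)
  fstat <- function(v, g) {
    m <- tapply(v, g, mean); n <- tapply(v, g, length)
    ssb <- sum(n * (m - mean(v))^2)
    ssw <- sum((v - ave(v, g))^2)
    (ssb / (length(m) - 1)) / (ssw / (length(v) - length(m)))
  }
  obs <- fstat(values, groups)
  stats <- replicate(n_perm, fstat(values, sample(groups)))
  (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1)
}
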