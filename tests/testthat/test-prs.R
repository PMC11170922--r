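# LD computation, greedy clumping, individual scoring and cross-validated
# threshold selection.

test_that("pairwise LD matches its definition and the generator's closed form", {
  panel <- make_panel(n = 5000, m = 40, ld_rho = 0.9, block_size = 20,
                      seed = 7)
  expect_equal(ld_r2(panel, 1, 1), 1.0)

  # independent variants (different blocks)
  expect_lt(ld_r2(panel, 1, 21), 0.01)

  # adjacent variants vs the closed-form expectation of the latent model
  p <- panel$variants$eaf
  expected <- latent_dosage_cor(0.9, p[1], p[2])^2
  expect_lt(abs(ld_r2(panel, 1, 2) - expected), 0.05)

  # zero-variance variant reports missing LD as 0 with a warning
  panel$dosage[, 3] <- 2
  expect_warning(r <- ld_r2(panel, 3, 4), "variance")
  expect_identical(r, 0)
})

test_that("clumping applies the window/LD/P rule", {
  # two correlated variants 100 kb apart: keep only the more significant
  cfg2 <- ancestry_config("EAS", n_samples = 500, fst = 0, ld_rho = 0.9,
                          block_size = 2)
  dosage <- simulate_genotype_panel(cfg2, c(0.5, 0.5), seed = 3)$dosage
  panel <- list(
    sample_ids = rownames(dosage),
    variants = data.table::data.table(
      variant_id = c("a", "b"), chr = c(1L, 1L),
      pos = c(1000000L, 1100000L), effect_allele = "A", other_allele = "G",
      eaf = colMeans(dosage) / 2),
    dosage = dosage, ancestry = "EAS")
  colnames(panel$dosage) <- c("a", "b")
  class(panel) <- "genotype_panel"
  meta <- data.table::data.table(
    variant_id = c("a", "b"), chr = 1L, pos = c(1000000L, 1100000L),
    effect_allele = "A", beta_meta = c(0.2, 0.1),
    pval_meta = c(1e-10, 1e-8))
  stopifnot(ld_r2(panel, 1, 2) > 0.1)
  wt <- clump(meta, panel, ct_grid_spec(), r2_cut = 0.1, p_cut = 1)
  expect_identical(wt$variant_id, "a")

  # 300 kb apart: outside the window, both kept regardless of LD
  meta$pos <- panel$variants$pos <- c(1000000L, 1300000L)
  wt2 <- clump(meta, panel, ct_grid_spec(), r2_cut = 0.1, p_cut = 1)
  expect_setequal(wt2$variant_id, c("a", "b"))

  # P threshold removes candidates before clumping
  wt3 <- clump(meta, panel, ct_grid_spec(), r2_cut = 0.1, p_cut = 1e-9)
  expect_identical(wt3$variant_id, "a")

  # variants absent from the LD panel are excluded with a log
  meta2 <- rbind(meta, data.table::data.table(
    variant_id = "ghost", chr = 1L, pos = 5000000L, effect_allele = "A",
    beta_meta = 0.3, pval_meta = 1e-12))
  wt4 <- clump(meta2, panel, ct_grid_spec(), r2_cut = 0.1, p_cut = 1)
  expect_identical(attr(wt4, "excluded"), "ghost")
})

test_that("clumping agrees with the brute-force greedy reference", {
  for (i in 1:15) {
    panel <- make_panel(n = 120, m = 200, ld_rho = 0.7, block_size = 25,
                        seed = 1000 + i, fst = 0, freq_range = c(0.15, 0.85))
    meta <- random_meta_instance(panel, seed = 2000 + i)
    r2c <- sample(c(0.05, 0.1, 0.3), 1)
    pc <- sample(c(0.05, 0.2, 1), 1)
    wt <- clump(meta, panel, ct_grid_spec(window_bp = 250000),
                r2_cut = r2c, p_cut = pc)
    ref <- brute_clump(meta, panel$dosage, 250000, r2c, pc)
    expect_identical(sort(wt$variant_id), ref)
  }
})

test_that("retained clumped variants are pairwise independent by construction", {
  panel <- make_panel(n = 400, m = 200, ld_rho = 0.8, block_size = 50,
                      seed = 5)
  meta <- random_meta_instance(panel, seed = 6)
  wt <- clump(meta, panel, ct_grid_spec(), r2_cut = 0.1, p_cut = 1)
  idx <- match(wt$variant_id, panel$variants$variant_id)
  for (a in seq_along(idx)) {
    for (b in seq_len(a - 1)) {
      if (wt$chr[a] == wt$chr[b] && abs(wt$pos[a] - wt$pos[b]) < 250000) {
        expect_lte(ld_r2(panel, idx[a], idx[b]), 0.1)
      }
    }
  }
})

test_that("scoring sums aligned weighted dosages with EAF imputation", {
  panel <- structure(list(
    sample_ids = "s1",
    variants = data.table::data.table(
      variant_id = c("v1", "v2", "v3"), chr = 1L, pos = c(1L, 2L, 3L),
      effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
      eaf = c(0.5, 0.5, 0.25)),
    dosage = matrix(c(0, 1, 2), 1, dimnames = list("s1", c("v1", "v2", "v3"))),
    ancestry = "EAS"), class = "genotype_panel")
  wt <- weight_table(data.table::data.table(
    variant_id = c("v1", "v2", "v3"), effect_allele = c("A", "C", "G"),
    weight = c(0.1, 0.2, 0.3)))
  # single sample: standardize against itself is degenerate; check raw only
  big <- panel
  big$sample_ids <- c("s1", "s2")
  big$dosage <- rbind(big$dosage, c(1, 1, 1))
  rownames(big$dosage) <- big$sample_ids
  sc <- score_panel(big, wt)
  expect_equal(sc$raw[1], 0.8)

  # all-zero weights give all-zero scores
  wt0 <- weight_table(data.table::data.table(
    variant_id = c("v1", "v2"), effect_allele = c("A", "C"),
    weight = c(0, 0)))
  sc0 <- score_panel(big, wt0)
  expect_identical(sc0$raw, c(0, 0))
  expect_identical(sc0$z, c(0, 0))

  # missing dosage imputed as 2 * EAF
  miss <- big
  miss$dosage[1, 3] <- NA
  scm <- score_panel(miss, wt)
  expect_equal(scm$raw[1], 0 * 0.1 + 1 * 0.2 + 2 * 0.25 * 0.3)
  expect_identical(attr(scm, "n_missing_imputed"), 1L)

  expect_error(score_panel(big, weight_table(data.table::data.table(
    variant_id = "nope", effect_allele = "A", weight = 1))), "no weight")
})

test_that("scoring is invariant to variant order and allele representation", {
  panel <- make_panel(n = 300, m = 40, ld_rho = 0.4, block_size = 20,
                      seed = 31)
  v <- panel$variants
  wt <- weight_table(data.table::data.table(
    variant_id = v$variant_id[1:20], effect_allele = v$effect_allele[1:20],
    weight = rnorm(20, 0, 0.1)))
  base <- score_panel(panel, wt)

  perm <- wt[sample(nrow(wt)), ]
  expect_equal(score_panel(panel, weight_table(perm))$raw, base$raw)

  # representing each weight on the opposite allele with flipped sign
  # shifts every raw score by a constant (2 * sum w) and leaves z intact
  flipped <- data.table::copy(wt)
  flipped$effect_allele <- v$other_allele[1:20]
  flipped$weight <- -flipped$weight
  fs <- score_panel(panel, weight_table(flipped))
  expect_equal(fs$raw, base$raw - 2 * sum(wt$weight), tolerance = 1e-12)
  expect_equal(fs$z, base$z, tolerance = 1e-10)
})

test_that("cross-validated threshold selection finds the informative cell", {
  # panel with 50 strongly associated variants among noise
  cfg <- ancestry_config("EAS", n_samples = 2000, fst = 0, ld_rho = 0.3,
                         block_size = 25)
  freqs <- runif(500, 0.2, 0.8)
  panel <- simulate_genotype_panel(cfg, freqs, seed = 41)
  betas <- numeric(500)
  causal <- seq(5, 500, by = 10)
  betas[causal] <- 0.25
  model <- true_model(causal_weights = betas, stage_thresholds = c(0, 1))
  model$stage_thresholds <- liability_thresholds(panel, model, p_naa = 0.1,
                                                 p_adv = 0.25)
  cohort <- simulate_outcomes(panel, model, seed = 42)
  stats <- simulate_summary_stats(freqs, betas, 20000, 200000, seed = 43,
                                  ancestry = "EAS", variants = panel$variants)
  data.table::setnames(stats, c("beta", "pval"), c("beta_meta", "pval_meta"))

  grid <- ct_grid_spec(p_cuts = c(1e-6, 1e-4, 0.5), r2_cuts = c(0.1, 0.5))
  cv <- cv_select_threshold(panel, cohort$advanced_neoplasm, stats,
                            spec = grid, repeats = 20, folds = 5, seed = 44)
  expect_lte(cv$best$p_cut, 1e-4)
  expect_identical(nrow(cv$auc_table), 6L)

  cv2 <- cv_select_threshold(panel, cohort$advanced_neoplasm, stats,
                             spec = grid, repeats = 20, folds = 5, seed = 44)
  expect_identical(cv$auc_table, cv2$auc_table)

  # informative weights beat permuted weights out of fold
  wt <- clump(stats, panel, grid, r2_cut = 0.1, p_cut = 1e-4)
  perm <- data.table::copy(wt)
  set.seed(45)
  perm$weight <- sample(perm$weight)
  perm$variant_id <- sample(panel$variants$variant_id, nrow(perm))
  auc_true <- empirical_auc(score_panel(panel, wt)$raw,
                            cohort$advanced_neoplasm)
  auc_perm <- empirical_auc(score_panel(panel, weight_table(perm))$raw,
                            cohort$advanced_neoplasm)
  expect_gt(auc_true, auc_perm)

  # degenerate single-cell grid returns that cell
  g1 <- ct_grid_spec(p_cuts = 1e-4, r2_cuts = 0.1)
  cv1 <- cv_select_threshold(panel, cohort$advanced_neoplasm, stats,
                             spec = g1, repeats = 2, folds = 5, seed = 1)
  expect_equal(cv1$best, list(p_cut = 1e-4, r2_cut = 0.1))
})
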