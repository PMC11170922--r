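# Cohort simulator: allele-frequency divergence, LD structure, staged
# liability outcomes, summary statistics and follow-up.

test_that("allele frequency divergence behaves like Balding-Nichols", {
  base <- runif(50, 0.1, 0.9)
  f0 <- simulate_allele_freqs(50, fst_by_ancestry = c(EAS = 0, EUR = 0),
                              seed = 1, base_freqs = base)
  expect_identical(f0$EAS, base)
  expect_identical(f0$EUR, base)

  # mean preservation: one variant at base 0.5, fst 0.1, many replicates
  reps <- vapply(1:10000, function(s) {
    simulate_allele_freqs(1, fst_by_ancestry = c(EAS = 0.1), seed = s,
                          base_freqs = 0.5)$EAS
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.5), 0.02)
  expect_true(all(reps > 0 & reps < 1))

  # higher fst means lower cross-ancestry EAF correlation
  fr <- simulate_allele_freqs(2000, fst_by_ancestry = c(a = 0.01, b = 0.3),
                              seed = 7)
  expect_gt(cor(fr$base, fr$a), cor(fr$base, fr$b))

  expect_error(simulate_allele_freqs(1, fst_by_ancestry = c(EAS = 0.1),
                                     seed = 1, base_freqs = 0.005),
               "0.01")
  expect_error(simulate_allele_freqs(10, fst_by_ancestry = c(EAS = 1)),
               "fst")
})

test_that("genotype panel has block-AR(1) LD and is seed-deterministic", {
  cfg0 <- ancestry_config("EAS", n_samples = 5000, fst = 0, ld_rho = 0,
                          block_size = 10)
  freqs <- rep(0.3, 20)
  p0 <- simulate_genotype_panel(cfg0, freqs, seed = 3)
  expect_true(all(p0$dosage %in% 0:2))
  expect_lt(abs(cor(p0$dosage[, 1], p0$dosage[, 2])), 0.05)

  cfg9 <- ancestry_config("EAS", n_samples = 5000, fst = 0, ld_rho = 0.9,
                          block_size = 10)
  p9 <- simulate_genotype_panel(cfg9, freqs, seed = 3)
  r2_adj <- cor(p9$dosage[, 1], p9$dosage[, 2])^2
  r2_far <- cor(p9$dosage[, 1], p9$dosage[, 6])^2
  expect_gt(r2_adj, r2_far)

  # no LD across block boundaries
  expect_lt(abs(cor(p9$dosage[, 10], p9$dosage[, 11])), 0.05)

  # empirical EAF tracks the target
  expect_lt(max(abs(colMeans(p9$dosage) / 2 - freqs)), 0.03)

  p9b <- simulate_genotype_panel(cfg9, freqs, seed = 3)
  expect_identical(p9, p9b)

  # positions nondecreasing within chromosome, ids unique
  v <- p9$variants
  expect_false(anyDuplicated(v$variant_id) > 0)
  expect_true(all(unlist(tapply(v$pos, v$chr, function(x) diff(x) >= 0))))
})

test_that("null liability model reproduces Gaussian stage tail probabilities", {
  cfg <- ancestry_config("EAS", n_samples = 20000, fst = 0, ld_rho = 0,
                         block_size = 10)
  panel <- simulate_genotype_panel(cfg, rep(0.3, 10), seed = 5)
  th <- c(1.0, 1.6)
  model <- true_model(causal_weights = numeric(10), stage_thresholds = th,
                      noise_sd = 1)
  cohort <- simulate_outcomes(panel, model, seed = 6)
  p_exp <- c(normal = pnorm(th[1]),
             NAA = pnorm(th[2]) - pnorm(th[1]),
             advanced = pnorm(th[2], lower.tail = FALSE))
  p_obs <- c(normal = mean(cohort$stage == "normal"),
             NAA = mean(cohort$stage == "NAA"),
             advanced = mean(cohort$advanced_neoplasm))
  expect_true(all(abs(p_obs - p_exp) < 0.015))
  expect_false(anyNA(cohort$bmi))  # missingness rate 0 by default

  # advanced split into adenoma vs CRC by the configured proportion
  adv <- cohort[cohort$advanced_neoplasm == 1, ]
  expect_lt(abs(mean(adv$stage == "advanced_adenoma") - 0.9), 0.05)
})

test_that("nonzero causal weights order mean PRS across stages", {
  cfg <- ancestry_config("EAS", n_samples = 20000, fst = 0, ld_rho = 0.5,
                         block_size = 10)
  freqs <- runif(50, 0.1, 0.9)
  panel <- simulate_genotype_panel(cfg, freqs, seed = 11)
  model <- true_model(causal_weights = rep(0.12, 50),
                      stage_thresholds = c(0, 1), noise_sd = 1)
  model$stage_thresholds <- liability_thresholds(panel, model)
  cohort <- simulate_outcomes(panel, model, seed = 12)
  grp <- ifelse(cohort$advanced_neoplasm == 1, "advanced", cohort$stage)
  means <- tapply(cohort$true_score, grp, mean)
  expect_lt(means[["normal"]], means[["NAA"]])
  expect_lt(means[["NAA"]], means[["advanced"]])

  expect_error(
    simulate_outcomes(panel, true_model(causal_weights = numeric(3),
                                        stage_thresholds = c(0, 1)),
                      seed = 1),
    "align")
})

test_that("logistic regression recovers the population log-OR per SD", {
  # oracle: the population per-SD log-OR of the true-weight score, estimated
  # from an independent 100k-sample replicate of the same generative model
  per_sd_logor <- function(n, seed_panel, seed_out) {
    cfg <- ancestry_config("EAS", n_samples = n, fst = 0, ld_rho = 0.3,
                           block_size = 20)
    set.seed(20)
    freqs <- runif(100, 0.2, 0.8)
    panel <- simulate_genotype_panel(cfg, freqs, seed = seed_panel)
    model <- true_model(causal_weights = rep(0.08, 100),
                        stage_thresholds = c(0, 1), noise_sd = 1)
    model$stage_thresholds <- liability_thresholds(panel, model, p_naa = 0.2,
                                                   p_adv = 0.3)
    cohort <- simulate_outcomes(panel, model, seed = seed_out)
    y <- cohort$advanced_neoplasm
    z <- scale(cohort$true_score)[, 1]
    unname(coef(glm(y ~ z, family = binomial()))["z"])
  }
  fitted <- per_sd_logor(20000, seed_panel = 21, seed_out = 22)
  population <- per_sd_logor(100000, seed_panel = 23, seed_out = 24)
  expect_lt(abs(fitted - population) / population, 0.10)
})

test_that("simulated summary statistics follow the stated Wald model", {
  # SE arithmetic at p = 0.5, 10k/10k
  st <- simulate_summary_stats(0.5, 0, 10000, 10000, seed = 1)
  expect_equal(st$se, sqrt((2 / 10000) / 0.5), tolerance = 1e-12)

  # type-I error of the Wald test across null variants
  set.seed(14)
  null_freqs <- runif(1000, 0.1, 0.9)
  st2 <- simulate_summary_stats(null_freqs, numeric(1000), 5000, 5000,
                                seed = 2)
  expect_lt(abs(mean(st2$pval < 0.05) - 0.05), 0.02)

  st3 <- simulate_summary_stats(null_freqs, numeric(1000), 5000, 5000,
                                seed = 2)
  expect_identical(st2, st3)

  expect_error(simulate_summary_stats(1.2, 0, 100, 100, seed = 1), "0, 1")
  expect_error(simulate_summary_stats(0.5, 0, 0, 100, seed = 1), "positive")
})

test_that("follow-up times are exponential with group hazard ratios", {
  n <- 20000
  cohort <- data.table::data.table(sample_id = seq_len(n),
                                   risk_group = rep(c("a", "b"), n / 2))
  fu <- simulate_followup(cohort, c(a = 1, b = 1), baseline_hazard = 0.01,
                          max_years = 10, seed = 31)
  expect_lt(abs(mean(fu$event) - (1 - exp(-0.1))), 0.01)
  expect_true(all(fu$follow_up_years >= 0 & fu$follow_up_years <= 10))
  expect_true(all(fu$follow_up_years[fu$event == 1] > 0))

  fu0 <- simulate_followup(cohort, c(a = 1, b = 1), baseline_hazard = 0,
                           max_years = 10, seed = 31)
  expect_identical(sum(fu0$event), 0L)

  # stochastic ordering of cumulative incidence under HR = 4
  fu4 <- simulate_followup(cohort, c(a = 1, b = 4), baseline_hazard = 0.01,
                           max_years = 10, seed = 32)
  km <- followup_analysis(fu4, factor(fu4$risk_group))$km
  for (tt in 1:9) {
    ci_a <- max(km$cum_incidence[km$group == "a" & km$time <= tt], 0)
    ci_b <- max(km$cum_incidence[km$group == "b" & km$time <= tt], 0)
    expect_gt(ci_b, ci_a)
  }

  expect_error(simulate_followup(cohort, c(a = -1, b = 1)), "positive")
})
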