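# Two-ancestry synthetic cohort generator: LD-blocked genotypes with
# allele-frequency divergence, liability-threshold staged outcomes
# (normal / non-advanced adenoma / advanced neoplasm), lifestyle factors,
# GWAS summary statistics, and censored follow-up.

#' Ancestry configuration for the cohort simulator
#'
#' @param label ancestry tag, e.g. `"EAS"` or `"EUR"`.
#' @param n_samples number of individuals to simulate genotypes for.
#' @param n_cases,n_controls case/control counts used when simulating GWAS
#'   summary statistics for this ancestry.
#' @param fst allele-frequency divergence from the shared base frequencies,
#'   in `[0, 1)` (Balding–Nichols model; 0 means identical frequencies).
#' @param ld_rho latent adjacent-variant correlation within an LD block,
#'   in `[0, 1)`.
#' @param block_size number of variants per LD block.
#' @return an object of class `ancestry_config`.
#' @export
ancestry_config <- function(label, n_samples, n_cases = 1000L,
                            n_controls = 1000L, fst = 0.05, ld_rho = 0.8,
                            block_size = 50L) {
  if (n_samples < 1 || n_cases < 1 || n_controls < 1) {
    stop_invalid("sample and case/control counts must be positive")
  }
  if (fst < 0 || fst >= 1) stop_invalid("`fst` must lie in [0, 1)")
  if (ld_rho < 0 || ld_rho >= 1) stop_invalid("`ld_rho` must lie in [0, 1)")
  if (block_size < 1) stop_invalid("`block_size` must be positive")
  structure(list(label = label, n_samples = as.integer(n_samples),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 fst = fst, ld_rho = ld_rho,
                 block_size = as.integer(block_size)),
            class = "ancestry_config")
}

#' Generative truth underlying a simulated cohort
#'
#' Houses the per-variant causal log-ORs, the per-factor lifestyle log-ORs,
#' the two liability cutoffs separating normal / non-advanced adenoma (NAA) /
#' advanced neoplasm, the baseline event hazard, and the residual liability
#' SD.
#'
#' @param causal_weights numeric vector, per-allele log-OR for each variant.
#' @param lifestyle_logors named numeric vector of length 5 (smoking,
#'   alcohol, activity, diet, bmi): log-OR per unhealthy flag.
#' @param stage_thresholds strictly increasing numeric length 2: liability
#'   cutoffs for NAA and advanced neoplasm.
#' @param baseline_hazard events per person-year for follow-up simulation.
#' @param noise_sd residual (environment + polygenic background) liability SD.
#' @param adenoma_prop proportion of advanced-neoplasm individuals labelled
#'   advanced adenoma rather than CRC.
#' @return an object of class `true_model`.
#' @export
true_model <- function(causal_weights, lifestyle_logors = NULL,
                       stage_thresholds, baseline_hazard = 0.01,
                       noise_sd = 1, adenoma_prop = 0.9) {
  if (is.null(lifestyle_logors)) {
    lifestyle_logors <- setNames(numeric(5), lifestyle_factors())
  }
  if (length(lifestyle_logors) != 5L) {
    stop_invalid("`lifestyle_logors` must have 5 entries")
  }
  if (is.null(names(lifestyle_logors))) {
    names(lifestyle_logors) <- lifestyle_factors()
  }
  if (length(stage_thresholds) != 2L ||
      !(stage_thresholds[1] < stage_thresholds[2])) {
    stop_invalid("`stage_thresholds` must be two strictly increasing values")
  }
  if (baseline_hazard < 0) stop_invalid("`baseline_hazard` must be >= 0")
  if (noise_sd <= 0) stop_invalid("`noise_sd` must be > 0")
  structure(list(causal_weights = causal_weights,
                 lifestyle_logors = lifestyle_logors,
                 stage_thresholds = stage_thresholds,
                 baseline_hazard = baseline_hazard,
                 noise_sd = noise_sd, adenoma_prop = adenoma_prop),
            class = "true_model")
}

lifestyle_factors <- function() {
  c("smoking", "alcohol", "activity", "diet", "bmi")
}

#' Simulate per-ancestry effect-allele frequencies
#'
#' Base frequencies are drawn uniformly from `base_freq_range` (or supplied
#' directly), then diverged per ancestry under the Balding–Nichols model:
#' `p_anc ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, whose mean is the base
#' frequency. `fst = 0` returns the base frequencies unchanged.
#'
#' @param m number of variants.
#' @param base_freq_range length-2 range for the shared base frequencies;
#'   must lie within (0.01, 0.99).
#' @param fst_by_ancestry named numeric vector of F_ST values in `[0, 1)`.
#' @param seed integer seed.
#' @param base_freqs optional explicit base frequencies (length `m`).
#' @return list with `base` and one EAF vector per ancestry.
#' @export
simulate_allele_freqs <- function(m, base_freq_range = c(0.05, 0.95),
                                  fst_by_ancestry, seed,
                                  base_freqs = NULL) {
  if (m < 1) stop_invalid("`m` must be >= 1")
  if (any(fst_by_ancestry < 0 | fst_by_ancestry >= 1)) {
    stop_invalid("each fst must lie in [0, 1)")
  }
  if (is.null(names(fst_by_ancestry))) {
    stop_invalid("`fst_by_ancestry` must be named by ancestry")
  }
  with_seed(seed, {
    if (is.null(base_freqs)) {
      if (any(base_freq_range <= 0.01) || any(base_freq_range >= 0.99)) {
        stop_invalid("`base_freq_range` must lie within (0.01, 0.99)")
      }
      base_freqs <- runif(m, base_freq_range[1], base_freq_range[2])
    } else {
      if (length(base_freqs) != m) stop_invalid("`base_freqs` length != m")
      if (any(base_freqs <= 0.01 | base_freqs >= 0.99)) {
        stop_invalid("base frequencies must lie within (0.01, 0.99)")
      }
    }
    out <- list(base = base_freqs)
    for (anc in names(fst_by_ancestry)) {
      f <- fst_by_ancestry[[anc]]
      if (f == 0) {
        out[[anc]] <- base_freqs
      } else {
        shape <- (1 - f) / f
        p <- stats::rbeta(m, base_freqs * shape, (1 - base_freqs) * shape)
        # keep frequencies usable downstream (nonzero variance, finite SE)
        out[[anc]] <- pmin(pmax(p, 1e-4), 1 - 1e-4)
      }
    }
    out
  })
}

#' Simulate a genotype dosage panel with block-AR(1) LD
#'
#' Each individual's two allele draws per variant come from thresholding a
#' latent Gaussian vector that follows an AR(1) process within each LD block
#' (adjacent latent correlation `ld_rho`), independent across blocks.
#' Dosages are the 0/1/2 sums of the two haplotypes. Blocks are laid out
#' round-robin over 22 chromosomes with positions increasing within each
#' chromosome.
#'
#' @param config an [ancestry_config()].
#' @param freqs per-variant effect-allele frequencies for this ancestry.
#' @param seed integer seed.
#' @param missing_rate fraction of dosages set missing at random.
#' @param spacing_bp base-pair distance between adjacent variants in a block.
#' @return an object of class `genotype_panel`: list with `sample_ids`,
#'   `variants` (data.table: variant_id, chr, pos, effect_allele,
#'   other_allele, eaf), `dosage` (n x m matrix, NA = missing), `ancestry`.
#' @export
simulate_genotype_panel <- function(config, freqs, seed, missing_rate = 0,
                                    spacing_bp = 20000L) {
  stopifnot(inherits(config, "ancestry_config"))
  m <- length(freqs)
  if (m %% config$block_size != 0L) {
    stop_invalid("length(freqs) must be a multiple of block_size")
  }
  assert_prob(freqs, "freqs")
  n <- config$n_samples
  n_blocks <- m %/% config$block_size
  with_seed(seed, {
    dosage <- draw_haplotypes(n, freqs, config$ld_rho, config$block_size) +
      draw_haplotypes(n, freqs, config$ld_rho, config$block_size)
    if (missing_rate > 0) {
      miss <- runif(length(dosage)) < missing_rate
      dosage[miss] <- NA_real_
    }
    variants <- layout_variants(m, n_blocks, config$block_size, spacing_bp,
                                freqs)
    sample_ids <- sprintf("%s_%05d", config$label, seq_len(n))
    rownames(dosage) <- sample_ids
    colnames(dosage) <- variants$variant_id
    structure(list(sample_ids = sample_ids, variants = variants,
                   dosage = dosage, ancestry = config$label),
              class = "genotype_panel")
  })
}

# One haplotype draw: latent AR(1) Gaussian per block, allele = indicator
# that the latent value falls below the frequency quantile.
draw_haplotypes <- function(n, freqs, rho, block_size) {
  m <- length(freqs)
  z <- matrix(rnorm(n * m), n, m)
  if (rho > 0) {
    w <- sqrt(1 - rho^2)
    for (j in seq_len(m)) {
      if ((j - 1L) %% block_size != 0L) {
        z[, j] <- rho * z[, j - 1L] + w * z[, j]
      }
    }
  }
  h <- sweep(z, 2, qnorm(freqs), "<")
  storage.mode(h) <- "double"
  h
}

layout_variants <- function(m, n_blocks, block_size, spacing_bp, freqs) {
  block <- rep(seq_len(n_blocks), each = block_size)
  chr <- ((block - 1L) %% 22L) + 1L
  chr_block_idx <- stats::ave(block, chr, FUN = function(b) {
    match(b, unique(b))
  })
  within <- rep(seq_len(block_size), n_blocks)
  pos <- (chr_block_idx - 1L) * 10000000L + within * as.integer(spacing_bp)
  pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  al <- pairs[(seq_len(m) - 1L) %% 4L + 1L]
  data.table::data.table(
    variant_id = sprintf("rs%07d", seq_len(m)),
    chr = chr, pos = as.integer(pos),
    effect_allele = vapply(al, `[`, "", 1L),
    other_allele = vapply(al, `[`, "", 2L),
    eaf = freqs, block = block
  )
}

default_lifestyle_prev <- function() {
  # prevalence of the *unhealthy* level of each factor, typical of an
  # average-risk East Asian screening population
  c(smoking = 0.30, alcohol = 0.25, activity = 0.60, diet = 0.40, bmi = 0.45)
}

#' Simulate staged outcomes, covariates and lifestyle from a liability model
#'
#' Latent liability = sum(causal_weight * dosage) + sum(lifestyle_logor *
#' unhealthy flag) + Gaussian noise with SD `noise_sd`. Stage is assigned by
#' the two thresholds: below the first is normal, between the two is
#' non-advanced adenoma (NAA), above the second is advanced neoplasm, which
#' is split into advanced adenoma vs CRC by `adenoma_prop`. Raw lifestyle
#' values are generated so their binarized unhealthy flags have the
#' configured prevalences; missing dosages contribute their expected value
#' `2 * EAF * weight` to the liability.
#'
#' @param panel a `genotype_panel`.
#' @param model a [true_model()]; `causal_weights` must align with the
#'   panel's variants.
#' @param seed integer seed.
#' @param lifestyle_prev named prevalences of the unhealthy level per factor.
#' @param missing_rate MCAR missingness rate applied to raw lifestyle values.
#' @return a `data.table` cohort: sample_id, age, sex, family_history,
#'   pc1..pc3, platform, raw lifestyle fields, stage, advanced_neoplasm,
#'   true_score (the true-weight genetic score), liability.
#' @export
simulate_outcomes <- function(panel, model, seed,
                              lifestyle_prev = default_lifestyle_prev(),
                              missing_rate = 0) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(model, "true_model"))
  m <- nrow(panel$variants)
  if (length(model$causal_weights) != m) {
    stop_invalid("causal_weights (%d) do not align with panel variants (%d)",
                 length(model$causal_weights), m)
  }
  lifestyle_prev <- lifestyle_prev[lifestyle_factors()]
  if (anyNA(lifestyle_prev)) {
    stop_invalid("`lifestyle_prev` must name all five factors")
  }
  n <- length(panel$sample_ids)
  with_seed(seed, {
    dos <- panel$dosage
    if (anyNA(dos)) {
      for (j in seq_len(ncol(dos))) {
        jna <- is.na(dos[, j])
        if (any(jna)) dos[jna, j] <- 2 * panel$variants$eaf[j]
      }
    }
    true_score <- as.vector(dos %*% model$causal_weights)

    flags <- vapply(lifestyle_prev, function(p) as.numeric(runif(n) < p),
                    numeric(n))
    raw <- lifestyle_raw_from_flags(flags, n)
    liab <- true_score + as.vector(flags %*% model$lifestyle_logors) +
      rnorm(n, 0, model$noise_sd)
    th <- model$stage_thresholds
    stage <- ifelse(liab < th[1], "normal",
                    ifelse(liab < th[2], "NAA", "advanced"))
    adv <- stage == "advanced"
    stage[adv] <- ifelse(runif(sum(adv)) < model$adenoma_prop,
                         "advanced_adenoma", "CRC")
    if (missing_rate > 0) {
      for (f in lifestyle_factors()) {
        raw[[f]][runif(n) < missing_rate] <- NA
      }
    }
    cohort <- data.table::data.table(
      sample_id = panel$sample_ids,
      age = round(rnorm(n, 55, 8)),
      sex = rbinom(n, 1, 0.5),
      family_history = rbinom(n, 1, 0.1),
      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
      platform = sample(c("chipA", "chipB"), n, replace = TRUE),
      smoking = raw$smoking, alcohol = raw$alcohol,
      activity = raw$activity, diet = raw$diet, bmi = raw$bmi,
      stage = stage,
      advanced_neoplasm = as.integer(stage %in% c("advanced_adenoma", "CRC")),
      true_score = true_score, liability = liab
    )
    cohort
  })
}

# Raw lifestyle values consistent with pre-drawn unhealthy flags:
# smoking/alcohol status, activity sessions/week, 0-8 diet score, BMI.
lifestyle_raw_from_flags <- function(flags, n) {
  ever <- function(f) {
    out <- rep("never", n)
    out[f == 1] <- sample(c("former", "current"), sum(f == 1),
                          replace = TRUE, prob = c(0.35, 0.65))
    out
  }
  activity <- ifelse(flags[, "activity"] == 1, sample(0:4, n, TRUE),
                     sample(5:10, n, TRUE))
  diet <- ifelse(flags[, "diet"] == 1, sample(0:4, n, TRUE),
                 sample(5:8, n, TRUE))
  bmi_h <- 20 + 3.9 * stats::rbeta(n, 2, 2)          # healthy: [20, 23.9]
  bmi_u <- 24 + 6 * stats::rbeta(n, 1.5, 2.5)        # unhealthy: >= 24
  bmi <- round(ifelse(flags[, "bmi"] == 1, bmi_u, bmi_h), 1)
  list(smoking = ever(flags[, "smoking"]), alcohol = ever(flags[, "alcohol"]),
       activity = as.integer(activity), diet = as.integer(diet), bmi = bmi)
}

#' Choose liability thresholds hitting target stage proportions
#'
#' Uses the analytic mean and variance of the liability (independent-variant
#' approximation for the genetic part, ignoring LD) to place the two cutoffs
#' so that expected stage proportions are approximately
#' `(1 - p_naa - p_adv, p_naa, p_adv)`.
#'
#' @param panel a `genotype_panel`.
#' @param model a [true_model()] (thresholds ignored).
#' @param lifestyle_prev unhealthy-flag prevalences.
#' @param p_naa,p_adv target NAA and advanced-neoplasm proportions.
#' @return numeric length 2.
#' @export
liability_thresholds <- function(panel, model,
                                 lifestyle_prev = default_lifestyle_prev(),
                                 p_naa = 0.15, p_adv = 0.05) {
  p <- panel$variants$eaf
  w <- model$causal_weights
  lw <- model$lifestyle_logors
  pr <- lifestyle_prev[lifestyle_factors()]
  mu <- sum(w * 2 * p) + sum(lw * pr)
  v <- sum(w^2 * 2 * p * (1 - p)) + sum(lw^2 * pr * (1 - pr)) +
    model$noise_sd^2
  mu + sqrt(v) * qnorm(c(1 - p_naa - p_adv, 1 - p_adv))
}

#' Simulate per-ancestry GWAS summary statistics
#'
#' Per variant, the estimated log-OR is drawn `Normal(true_beta, se^2)` with
#' `se = sqrt((1/n_cases + 1/n_controls) / (2 p (1 - p)))`; the two-sided
#' P comes from the Wald statistic, and the reported EAF is perturbed by
#' binomial sampling of `2 (n_cases + n_controls)` alleles.
#'
#' @param freqs per-variant EAFs in (0, 1).
#' @param true_betas per-variant true log-ORs.
#' @param n_cases,n_controls study counts.
#' @param seed integer seed.
#' @param ancestry ancestry label stamped on the records.
#' @param variants optional variant metadata table (as in `genotype_panel`);
#'   synthesized when omitted.
#' @return data.table with columns variant_id, chr, pos, effect_allele,
#'   other_allele, eaf, beta, se, pval, n_cases, n_controls, ancestry.
#' @export
simulate_summary_stats <- function(freqs, true_betas, n_cases, n_controls,
                                   seed, ancestry = "EAS", variants = NULL) {
  if (n_cases <= 0 || n_controls <= 0) stop_invalid("counts must be positive")
  assert_prob(freqs, "freqs")
  m <- length(freqs)
  if (length(true_betas) != m) stop_invalid("true_betas length mismatch")
  if (is.null(variants)) {
    variants <- layout_variants(m, 1L, m, 20000L, freqs)
  }
  with_seed(seed, {
    se <- sqrt((1 / n_cases + 1 / n_controls) / (2 * freqs * (1 - freqs)))
    beta <- rnorm(m, true_betas, se)
    pval <- 2 * pnorm(-abs(beta / se))
    n2 <- 2 * (n_cases + n_controls)
    eaf_hat <- rbinom(m, n2, freqs) / n2
    data.table::data.table(
      variant_id = variants$variant_id, chr = variants$chr,
      pos = variants$pos, effect_allele = variants$effect_allele,
      other_allele = variants$other_allele,
      eaf = pmin(pmax(eaf_hat, 1e-6), 1 - 1e-6),
      beta = beta, se = se, pval = pmax(pval, .Machine$double.xmin),
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      ancestry = ancestry
    )
  })
}

#' Simulate censored follow-up on top of a cohort
#'
#' Event times are exponential with rate `baseline_hazard * HR(group)`,
#' administratively censored at `max_years`.
#'
#' @param cohort a cohort `data.table`.
#' @param risk_group_hr named numeric of hazard ratios, indexed by the
#'   values of `group_col`.
#' @param group_col cohort column naming each sample's risk group.
#' @param baseline_hazard events per person-year in the HR = 1 group.
#' @param max_years administrative censoring time.
#' @param seed integer seed.
#' @return the cohort with `follow_up_years` and `event` columns added.
#' @export
simulate_followup <- function(cohort, risk_group_hr, group_col = "risk_group",
                              baseline_hazard = 0.01, max_years = 10,
                              seed = 1L) {
  if (any(risk_group_hr <= 0)) stop_invalid("hazard ratios must be positive")
  if (baseline_hazard < 0) stop_invalid("`baseline_hazard` must be >= 0")
  grp <- as.character(cohort[[group_col]])
  if (anyNA(risk_group_hr[grp])) {
    stop_invalid("`risk_group_hr` missing an HR for some group")
  }
  n <- nrow(cohort)
  out <- data.table::copy(cohort)
  with_seed(seed, {
    rate <- baseline_hazard * unname(risk_group_hr[grp])
    t_event <- ifelse(rate > 0, rexp(n, pmax(rate, 1e-300)), Inf)
    out[, `:=`(follow_up_years = pmin(t_event, max_years),
               event = as.integer(t_event <= max_years))]
  })
  out[]
}
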