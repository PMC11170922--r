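# Independent reference implementations used as test oracles. These stay
# deliberately separate from the package's code paths: matrix-based greedy
# clumping, a double-loop Mann-Whitney count, and closed-form expectations
# for the latent-Gaussian haplotype model.

# Brute-force greedy clumping over a precomputed r2 matrix: visit variants
# in ascending P (ties by chr, pos, id), reject when within the window of an
# accepted variant on the same chromosome with r2 above the cutoff.
brute_clump <- function(meta, dosage, window_bp, r2_cut, p_cut) {
  keep <- meta$pval_meta <= p_cut
  cand <- meta[keep, ]
  ord <- order(cand$pval_meta, cand$chr, cand$pos, cand$variant_id)
  cand <- cand[ord, ]
  d <- dosage[, match(cand$variant_id, colnames(dosage)), drop = FALSE]
  r2 <- suppressWarnings(cor(d)^2)
  r2[is.na(r2)] <- 0
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    conflict <- FALSE
    for (a in accepted) {
      if (cand$chr[i] == cand$chr[a] &&
          abs(cand$pos[i] - cand$pos[a]) < window_bp &&
          r2[i, a] > r2_cut) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) accepted <- c(accepted, i)
  }
  sort(cand$variant_id[accepted])
}

# Mann-Whitney AUC by exhaustive pair counting (ties = 1/2).
brute_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Expected dosage correlation between two variants of the latent-Gaussian
# haplotype model with latent correlation rho and frequencies p1, p2:
# haplotype indicators are thresholded bivariate normals, and the dosage
# correlation equals the haplotype correlation (sum of two iid draws).
latent_dosage_cor <- function(rho, p1, p2) {
  t1 <- qnorm(p1)
  t2 <- qnorm(p2)
  # P(Z1 < t1, Z2 < t2) via one-dimensional integration
  joint <- integrate(function(x) {
    dnorm(x) * pnorm((t2 - rho * x) / sqrt(1 - rho^2))
  }, -Inf, t1, rel.tol = 1e-10)$value
  (joint - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Small random meta table over a panel, for clumping equivalence tests.
random_meta_instance <- function(panel, seed) {
  set.seed(seed)
  v <- panel$variants
  data.table::data.table(
    variant_id = v$variant_id, chr = v$chr, pos = v$pos,
    effect_allele = v$effect_allele,
    beta_meta = rnorm(nrow(v), 0, 0.1),
    pval_meta = runif(nrow(v))^3
  )
}

make_panel <- function(n = 200, m = 200, ld_rho = 0.6, block_size = 20,
                       seed = 1, label = "EAS", fst = 0.05,
                       freq_range = c(0.1, 0.9)) {
  cfg <- ancestry_config(label, n_samples = n, fst = fst, ld_rho = ld_rho,
                         block_size = block_size)
  freqs <- simulate_allele_freqs(m, base_freq_range = freq_range,
                                 fst_by_ancestry = setNames(fst, label),
                                 seed = seed)[[label]]
  simulate_genotype_panel(cfg, freqs, seed = seed + 1)
}

sumstat_row <- function(variant_id, ea, oa, eaf, beta, ancestry,
                        se = 0.05, chr = 1L, pos = 1000L) {
  data.table::data.table(
    variant_id = variant_id, chr = chr, pos = pos, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n_cases = 1000L,
    n_controls = 1000L, ancestry = ancestry)
}
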