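# Clumping-and-thresholding PRS construction and individual-level scoring.
#
# The clumping rule follows the standard greedy scheme: walk variants in
# ascending P; a variant is rejected when it lies within the physical window
# of an already-accepted variant on the same chromosome AND is in LD with it
# above the r2 cutoff. Accepted variants carry their meta-analysis log-OR as
# the PRS weight.

#' Pairwise LD between two variants of a panel
#'
#' Squared Pearson correlation of dosages over samples non-missing at both
#' variants. Zero-variance pairs are reported as `r2 = 0` with a warning
#' (missing LD treated as absence of LD).
#'
#' @param panel a `genotype_panel`.
#' @param i,j variant indices or variant ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(panel, i, j) {
  if (is.character(i)) i <- match(i, panel$variants$variant_id)
  if (is.character(j)) j <- match(j, panel$variants$variant_id)
  x <- panel$dosage[, i]
  y <- panel$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) {
    warning("fewer than 2 complete pairs; LD treated as 0")
    return(0)
  }
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    warning("zero dosage variance; LD treated as 0")
    return(0)
  }
  cor(x[ok], y[ok])^2
}

#' Clumping-and-thresholding grid specification
#'
#' @param window_bp physical clumping window (same-chromosome distance
#'   strictly below this is "within window"); default 250 kb.
#' @param r2_cuts candidate LD r-squared cutoffs.
#' @param p_cuts candidate P-value thresholds.
#' @return a `ct_grid_spec`.
#' @export
ct_grid_spec <- function(window_bp = 250000L,
                         r2_cuts = c(0.1, 0.2, 0.5),
                         p_cuts = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01)) {
  if (window_bp <= 0) stop_invalid("`window_bp` must be positive")
  if (any(r2_cuts < 0 | r2_cuts > 1)) stop_invalid("r2 cuts must be in [0,1]")
  if (any(p_cuts <= 0 | p_cuts > 1)) stop_invalid("p cuts must be in (0,1]")
  structure(list(window_bp = as.integer(window_bp), r2_cuts = r2_cuts,
                 p_cuts = p_cuts), class = "ct_grid_spec")
}

#' Greedy LD clumping + P thresholding of meta-analysis results
#'
#' Variants with `pval_meta <= p_cut` are visited in ascending P (ties broken
#' by chromosome, position, then variant id); each is accepted unless it lies
#' within `window_bp` of an already-accepted variant on the same chromosome
#' and has `r2 > r2_cut` with it in the LD panel. Accepted variants form a
#' weight table with `weight = beta_meta`. Variants absent from the panel are
#' excluded and reported.
#'
#' @param meta meta-analysis records (needs variant_id, chr, pos,
#'   effect_allele, pval_meta, beta_meta).
#' @param panel LD reference `genotype_panel`.
#' @param spec a [ct_grid_spec()] (its `window_bp` is used).
#' @param r2_cut,p_cut the grid cell to apply.
#' @return a `weight_table`; attribute `excluded` lists variants missing
#'   from the LD panel.
#' @export
clump <- function(meta, panel, spec = ct_grid_spec(), r2_cut = 0.1,
                  p_cut = 1e-4) {
  meta <- data.table::as.data.table(meta)
  cand <- meta[meta$pval_meta <= p_cut, ]
  excluded <- cand$variant_id[!cand$variant_id %in%
                                panel$variants$variant_id]
  cand <- cand[!cand$variant_id %in% excluded, ]
  data.table::setorder(cand, pval_meta, chr, pos, variant_id)
  idx <- match(cand$variant_id, panel$variants$variant_id)
  accepted <- integer(0)
  for (r in seq_len(nrow(cand))) {
    ok <- TRUE
    for (a in accepted) {
      if (cand$chr[r] == cand$chr[a] &&
          abs(cand$pos[r] - cand$pos[a]) < spec$window_bp &&
          ld_r2(panel, idx[r], idx[a]) > r2_cut) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, r)
  }
  wt <- weight_table(
    data.table::data.table(variant_id = cand$variant_id[accepted],
                           effect_allele = cand$effect_allele[accepted],
                           weight = cand$beta_meta[accepted],
                           chr = cand$chr[accepted],
                           pos = cand$pos[accepted],
                           pval = cand$pval_meta[accepted]),
    provenance = sprintf("ct_grid(p_cut=%g, r2_cut=%g)", p_cut, r2_cut))
  attr(wt, "excluded") <- excluded
  wt
}

#' Score individuals against a PRS weight table
#'
#' Raw score = sum over matched variants of `weight * aligned dosage`. When
#' the panel counts the opposite allele the dosage is reflected (`2 - d`);
#' missing dosages are imputed as `2 * EAF` of the variant in the panel.
#' The z-score standardizes against `reference_ids` (default: all scored
#' samples).
#'
#' @param panel a `genotype_panel`.
#' @param weights a `weight_table`.
#' @param reference_ids sample ids defining the standardization population.
#' @return a `score_result`: data.table (sample_id, raw, z) with attributes
#'   `mean`, `sd`, `n_variants_used`, `n_missing_imputed`.
#' @export
score_panel <- function(panel, weights, reference_ids = NULL) {
  v <- panel$variants
  hit <- match(weights$variant_id, v$variant_id)
  used <- !is.na(hit)
  if (!any(used)) {
    stop_invalid("no weight variants found in panel (e.g. %s)",
                 paste(head(weights$variant_id, 3), collapse = ", "))
  }
  w <- weights$weight[used]
  cols <- hit[used]
  d <- panel$dosage[, cols, drop = FALSE]
  # align panel dosage (counting panel effect allele) to the weight's allele
  flip <- v$effect_allele[cols] != weights$effect_allele[used]
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  n_imputed <- sum(is.na(d))
  if (n_imputed > 0) {
    eaf <- ifelse(flip, 1 - v$eaf[cols], v$eaf[cols])
    for (j in which(colSums(is.na(d)) > 0)) {
      jna <- is.na(d[, j])
      d[jna, j] <- 2 * eaf[j]
    }
  }
  raw <- as.vector(d %*% w)
  ref <- if (is.null(reference_ids)) seq_along(raw) else {
    match(reference_ids, panel$sample_ids)
  }
  mu <- mean(raw[ref])
  sg <- sd(raw[ref])
  z <- if (is.na(sg) || sg == 0) rep(0, length(raw)) else (raw - mu) / sg
  out <- data.table::data.table(sample_id = panel$sample_ids, raw = raw,
                                z = z)
  data.table::setattr(out, "mean", mu)
  data.table::setattr(out, "sd", sg)
  data.table::setattr(out, "n_variants_used", sum(used))
  data.table::setattr(out, "n_missing_imputed", n_imputed)
  data.table::setattr(out, "class", c("score_result", class(out)))
  out
}

#' Stratified repeated k-fold assignment
#'
#' @param labels binary outcome vector.
#' @param folds number of folds.
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @return integer matrix (n x repeats) of fold memberships.
#' @keywords internal
stratified_folds <- function(labels, folds, repeats, seed) {
  with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      fold <- integer(length(labels))
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      fold
    }, integer(length(labels)))
  })
}

#' Select the clumping-and-thresholding cell by repeated cross-validation
#'
#' For every `(p_cut, r2_cut)` grid cell the meta statistics are clumped,
#' the panel scored, and the mean out-of-fold AUC computed over
#' `repeats x folds` stratified splits of the binary outcome (advanced
#' neoplasm vs normal by default). Returns the cell with the highest mean
#' AUC; ties prefer the smaller `p_cut`, then the larger `r2_cut`.
#'
#' @param panel a `genotype_panel`.
#' @param outcome binary vector aligned with the panel's samples.
#' @param meta meta-analysis records.
#' @param spec a [ct_grid_spec()].
#' @param repeats,folds cross-validation design (the full design is 400 x 5;
#'   reduce for desk-scale runs).
#' @param seed integer seed.
#' @return list: `best` (p_cut, r2_cut), `auc_table` (data.table with one
#'   row per grid cell: p_cut, r2_cut, n_variants, mean_auc).
#' @export
cv_select_threshold <- function(panel, outcome, meta, spec = ct_grid_spec(),
                                repeats = 400L, folds = 5L, seed = 1L) {
  if (length(outcome) != length(panel$sample_ids)) {
    stop_invalid("outcome must align with panel samples")
  }
  if (length(unique(outcome)) != 2L) {
    stop_invalid("outcome must be binary with both classes present")
  }
  grid <- expand.grid(p_cut = spec$p_cuts, r2_cut = spec$r2_cuts,
                      KEEP.OUT.ATTRS = FALSE)
  fold_mat <- stratified_folds(outcome, folds, repeats, seed)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    wt <- clump(meta, panel, spec, r2_cut = grid$r2_cut[g],
                p_cut = grid$p_cut[g])
    if (nrow(wt) == 0L) {
      return(data.table::data.table(p_cut = grid$p_cut[g],
                                    r2_cut = grid$r2_cut[g],
                                    n_variants = 0L, mean_auc = NA_real_))
    }
    sc <- score_panel(panel, wt)
    aucs <- c()
    for (r in seq_len(repeats)) {
      for (f in seq_len(folds)) {
        test <- fold_mat[, r] == f
        if (length(unique(outcome[test])) < 2L) {
          warning("fold with a single class skipped")
          next
        }
        aucs <- c(aucs, empirical_auc(sc$raw[test], outcome[test]))
      }
    }
    data.table::data.table(p_cut = grid$p_cut[g], r2_cut = grid$r2_cut[g],
                           n_variants = nrow(wt), mean_auc = mean(aucs))
  })
  tab <- data.table::rbindlist(rows)
  ord <- order(-tab$mean_auc, tab$p_cut, -tab$r2_cut)
  best <- tab[ord[1], ]
  list(best = list(p_cut = best$p_cut, r2_cut = best$r2_cut),
       auc_table = tab)
}
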