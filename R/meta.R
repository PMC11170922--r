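# Trans-ancestry GWAS meta-analysis: allele harmonization across studies,
# per-study genomic control, inverse-variance fixed-effects pooling with
# Cochran's Q, and heterogeneity / presence filtering.

VALID_ALLELES <- c("A", "C", "G", "T")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize per-study summary statistics to a common effect allele
#'
#' The reference study's effect allele defines the common allele per
#' variant. A study whose effect/other alleles are swapped relative to the
#' reference has its beta sign flipped and its EAF replaced by `1 - eaf`;
#' variants with incompatible allele pairs are dropped, as are
#' strand-ambiguous (A/T, C/G) variants whose EAF falls in `[0.4, 0.6]` in
#' any study.
#'
#' @param records stacked summary statistics for all studies (`data.table`
#'   with an `ancestry` column).
#' @param reference ancestry label of the reference study.
#' @return list: `records` (harmonized data.table) and `dropped`
#'   (data.table of variant_id, reason).
#' @export
harmonize <- function(records, reference) {
  records <- data.table::as.data.table(records)
  studies <- unique(records$ancestry)
  if (!reference %in% studies) {
    stop_invalid("reference ancestry '%s' not present", reference)
  }
  for (s in studies) {
    ids <- records$variant_id[records$ancestry == s]
    if (anyDuplicated(ids)) {
      stop_invalid("duplicate variant_id within study '%s'", s)
    }
  }
  ref <- records[records$ancestry == reference,
                 c("variant_id", "effect_allele", "other_allele")]
  data.table::setnames(ref, c("effect_allele", "other_allele"),
                       c("ref_ea", "ref_oa"))
  out <- merge(records, ref, by = "variant_id", all.x = TRUE)

  dropped <- list()
  # strand-ambiguous: A/T or C/G pair with eaf in [0.4, 0.6] in ANY study
  pal <- is_palindromic(out$effect_allele, out$other_allele)
  amb_ids <- unique(out$variant_id[pal & out$eaf >= 0.4 & out$eaf <= 0.6])
  if (length(amb_ids)) {
    dropped$ambiguous <- data.table::data.table(
      variant_id = amb_ids, reason = "strand-ambiguous")
    out <- out[!out$variant_id %in% amb_ids, ]
  }

  classify <- function(d) {
    no_ref <- is.na(d$ref_ea)
    same <- !no_ref & d$effect_allele == d$ref_ea &
      d$other_allele == d$ref_oa
    swapped <- !no_ref & d$effect_allele == d$ref_oa &
      d$other_allele == d$ref_ea
    list(incompatible = !no_ref & !same & !swapped, swapped = swapped)
  }
  cls <- classify(out)
  if (any(cls$incompatible)) {
    bad <- unique(out$variant_id[cls$incompatible])
    dropped$incompatible <- data.table::data.table(
      variant_id = bad, reason = "incompatible-alleles")
    out <- out[!out$variant_id %in% bad, ]
    cls <- classify(out)
  }
  flip <- which(cls$swapped)
  if (length(flip)) {
    out$beta[flip] <- -out$beta[flip]
    out$eaf[flip] <- 1 - out$eaf[flip]
    tmp <- out$effect_allele[flip]
    out$effect_allele[flip] <- out$other_allele[flip]
    out$other_allele[flip] <- tmp
  }
  out[, c("ref_ea", "ref_oa") := NULL]
  list(records = out[],
       dropped = if (length(dropped)) data.table::rbindlist(dropped)
                 else data.table::data.table(variant_id = character(),
                                             reason = character()))
}

#' Inverse-variance fixed-effects meta-analysis of one variant
#'
#' Weights are `1/se^2`; the pooled effect is the weighted mean, Cochran's Q
#' is the weighted sum of squared deviations, and the heterogeneity P comes
#' from a chi-square with K - 1 degrees of freedom. With a single study the
#' inputs are returned and the heterogeneity P is `NA`.
#'
#' @param betas,ses study-level log-ORs and standard errors.
#' @return list: beta_meta, se_meta, pval_meta, q_stat, pval_het, n_studies.
#' @export
ivw_meta <- function(betas, ses) {
  k <- length(betas)
  if (k == 0L) stop_invalid("no studies supplied")
  if (length(ses) != k || any(ses <= 0)) {
    stop_invalid("`ses` must match `betas` and be positive")
  }
  w <- 1 / ses^2
  beta_meta <- sum(w * betas) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  q <- sum(w * (betas - beta_meta)^2)
  list(beta_meta = beta_meta, se_meta = se_meta,
       pval_meta = 2 * pnorm(-abs(beta_meta / se_meta)),
       q_stat = q,
       pval_het = if (k > 1) pchisq(q, k - 1, lower.tail = FALSE) else NA_real_,
       n_studies = k)
}

#' Genomic-control correction of one study's summary statistics
#'
#' `lambda = median(chi^2) / 0.4549` with `chi^2 = (beta/se)^2`. When
#' `lambda > 1` every SE is inflated by `sqrt(lambda)` and P-values are
#' recomputed; statistics are never deflated.
#'
#' @param stats one study's summary-statistic `data.table`.
#' @return list: `stats` (corrected data.table), `lambda`.
#' @export
genomic_control <- function(stats) {
  stats <- data.table::copy(data.table::as.data.table(stats))
  chisq <- (stats$beta / stats$se)^2
  lambda <- median(chisq) / qchisq(0.5, df = 1)
  if (lambda > 1) {
    stats[, se := se * sqrt(lambda)]
    stats[, pval := 2 * pnorm(-abs(beta / se))]
  }
  list(stats = stats[], lambda = lambda)
}

#' Meta-analyse harmonized multi-study summary statistics
#'
#' Applies per-study genomic control (optional), harmonizes alleles to the
#' reference study, then pools each variant across studies by
#' inverse-variance fixed effects.
#'
#' @param records stacked per-study summary statistics.
#' @param reference reference ancestry for harmonization.
#' @param gc_correct apply per-study genomic control first.
#' @return list: `meta` (data.table with variant metadata, beta_meta,
#'   se_meta, pval_meta, q_stat, pval_het, n_studies, present_in),
#'   `lambdas` (named per-study), `dropped` (harmonization log).
#' @export
meta_analyse <- function(records, reference, gc_correct = TRUE) {
  records <- data.table::as.data.table(records)
  lambdas <- numeric(0)
  if (gc_correct) {
    parts <- lapply(split(records, records$ancestry), function(st) {
      gc <- genomic_control(st)
      lambdas[[st$ancestry[1]]] <<- gc$lambda
      gc$stats
    })
    records <- data.table::rbindlist(parts)
  }
  h <- harmonize(records, reference)
  rec <- h$records
  meta <- rec[, {
    r <- ivw_meta(beta, se)
    list(chr = chr[1], pos = pos[1], effect_allele = effect_allele[1],
         other_allele = other_allele[1],
         eaf = sum(eaf * (n_cases + n_controls)) / sum(n_cases + n_controls),
         beta_meta = r$beta_meta, se_meta = r$se_meta,
         pval_meta = r$pval_meta, q_stat = r$q_stat,
         pval_het = r$pval_het, n_studies = r$n_studies,
         present_in = paste(sort(ancestry), collapse = ","))
  }, by = "variant_id"]
  list(meta = meta, lambdas = lambdas, dropped = h$dropped)
}

#' Filter meta-analysis records on heterogeneity and ancestry presence
#'
#' Removes variants with heterogeneity P below `het_p_cut` and, when
#' `require_all` is set, variants absent from any required ancestry.
#' An optional minor-allele-frequency floor mirrors per-study QC.
#'
#' @param meta meta-analysis `data.table` (see [meta_analyse()]).
#' @param het_p_cut heterogeneity P-value cutoff.
#' @param required_ancestries ancestries each variant must be present in.
#' @param require_all enforce presence in every required ancestry.
#' @param maf_cut minimum minor allele frequency (default 0.001).
#' @return list: `meta` (filtered), `removed` (counts by reason).
#' @export
filter_meta <- function(meta, het_p_cut = 0.001,
                        required_ancestries = NULL, require_all = TRUE,
                        maf_cut = 0.001) {
  meta <- data.table::as.data.table(meta)
  het <- !is.na(meta$pval_het) & meta$pval_het < het_p_cut
  absent <- rep(FALSE, nrow(meta))
  if (require_all && length(required_ancestries)) {
    present <- strsplit(meta$present_in, ",", fixed = TRUE)
    absent <- !vapply(present, function(p) {
      all(required_ancestries %in% p)
    }, logical(1))
  }
  maf <- pmin(meta$eaf, 1 - meta$eaf)
  rare <- maf < maf_cut
  keep <- !het & !absent & !rare
  list(meta = meta[keep],
       removed = c(heterogeneity = sum(het),
                   missing_ancestry = sum(absent & !het),
                   maf = sum(rare & !het & !absent)))
}
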