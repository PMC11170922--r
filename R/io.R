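# Plain-text interchange formats: summary-statistic TSV, dosage VCF/TSV,
# cohort CSV, PGS-Catalog-style scoring files.

sumstat_cols <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n_cases", "n_controls")

#' Write / read GWAS summary statistics as tab-separated text
#'
#' Columns: variant_id, chr, pos, effect_allele, other_allele, eaf, beta,
#' se, pval, n_cases, n_controls, plus any extra columns present (ancestry,
#' meta-analysis fields).
#'
#' @param stats summary-statistic `data.table`.
#' @param path output file.
#' @return `path`, invisibly (writer); a `data.table` (reader).
#' @export
write_sumstats <- function(stats, path) {
  missing_cols <- setdiff(sumstat_cols, names(stats))
  if (length(missing_cols)) {
    stop_invalid("summary stats missing columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  data.table::fwrite(stats, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  st <- data.table::fread(path, sep = "\t")
  missing_cols <- setdiff(sumstat_cols, names(st))
  if (length(missing_cols)) {
    stop_invalid("%s is not a summary-stat file (missing %s)", path,
                 paste(missing_cols, collapse = ", "))
  }
  st
}

#' Write a genotype panel as a dosage VCF
#'
#' Minimal VCF 4.2 with a single `DS` FORMAT field carrying the effect-allele
#' dosage (REF = other allele, ALT = effect allele); missing dosages are
#' written as `.`.
#'
#' @param panel a `genotype_panel`.
#' @param path output file (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=transprs ancestry=%s", panel$ancestry),
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  ), con)
  ds <- t(panel$dosage)  # variants x samples
  body <- vapply(seq_len(nrow(v)), function(i) {
    val <- ifelse(is.na(ds[i, ]), ".", formatC(ds[i, ], format = "g"))
    paste(c(v$chr[i], v$pos[i], v$variant_id[i], v$other_allele[i],
            v$effect_allele[i], ".", "PASS", ".", "DS", val), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write / read a genotype panel as a plain dosage matrix
#'
#' Tab-separated: variant metadata columns followed by one dosage column per
#' sample; missing dosages are empty fields.
#'
#' @param panel a `genotype_panel`.
#' @param path file path.
#' @param ancestry ancestry label to stamp on the panel read back.
#' @return `path`, invisibly (writer); a `genotype_panel` (reader).
#' @export
write_dosage_matrix <- function(panel, path) {
  tab <- cbind(panel$variants[, c("variant_id", "chr", "pos", "effect_allele",
                                  "other_allele", "eaf")],
               data.table::as.data.table(t(panel$dosage)))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dosage_matrix
#' @export
read_dosage_matrix <- function(path, ancestry = "NA") {
  tab <- data.table::fread(path, sep = "\t")
  meta_cols <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
                 "eaf")
  sample_ids <- setdiff(names(tab), meta_cols)
  dosage <- t(as.matrix(tab[, sample_ids, with = FALSE]))
  colnames(dosage) <- tab$variant_id
  rownames(dosage) <- sample_ids
  structure(list(sample_ids = sample_ids,
                 variants = tab[, meta_cols, with = FALSE],
                 dosage = dosage, ancestry = ancestry),
            class = "genotype_panel")
}

#' Write / read a PGS-Catalog-style scoring file
#'
#' Tab-separated columns `rsID`, `effect_allele`, `effect_weight`; leading
#' `#` comment lines are tolerated on read and a provenance comment is
#' written.
#'
#' @param weights a `weight_table` (see [clump()]) or a data.table with
#'   columns variant_id, effect_allele, weight.
#' @param path file path.
#' @return `path`, invisibly (writer); a `weight_table` (reader).
#' @export
write_scorefile <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#provenance=%s", attr(weights, "provenance") %||%
                       "external"), con)
  writeLines("rsID\teffect_allele\teffect_weight", con)
  writeLines(sprintf("%s\t%s\t%.10g", weights$variant_id,
                     weights$effect_allele, weights$weight), con)
  invisible(path)
}

#' @rdname write_scorefile
#' @export
read_scorefile <- function(path) {
  lines <- readLines(path)
  comments <- grepl("^#", lines)
  tab <- data.table::fread(text = paste(lines[!comments], collapse = "\n"),
                           sep = "\t")
  names(tab) <- sub("^rsID$", "variant_id", names(tab))
  names(tab) <- sub("^effect_weight$", "weight", names(tab))
  if (anyDuplicated(tab$variant_id)) {
    stop_invalid("duplicate variant ids in scoring file %s", path)
  }
  prov <- sub("^#provenance=", "",
              grep("^#provenance=", lines, value = TRUE))
  weight_table(tab, provenance = if (length(prov)) prov[1] else "external")
}

#' Construct a PRS weight table
#'
#' @param tab data.table with columns variant_id, effect_allele, weight.
#' @param provenance `"external"` or a clumping-grid tag.
#' @return a `weight_table`.
#' @export
weight_table <- function(tab, provenance = "external") {
  tab <- data.table::as.data.table(tab)
  need <- c("variant_id", "effect_allele", "weight")
  if (!all(need %in% names(tab))) {
    stop_invalid("weight table needs columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$variant_id)) stop_invalid("duplicate variant ids")
  if (any(!is.finite(tab$weight))) stop_invalid("weights must be finite")
  structure(tab, class = c("weight_table", class(tab)),
            provenance = provenance)
}
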