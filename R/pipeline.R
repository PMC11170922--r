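# End-to-end orchestration: simulate a two-ancestry scenario, meta-analyse,
# build and score the clumping-and-thresholding PRS, build the ERS, and run
# the full screening evaluation and follow-up analysis, writing every table
# plus a manifest (seed + file hashes) to an output directory.

#' Default demo pipeline configuration
#'
#' A desk-scale two-ancestry scenario: 2,000 variants in 40-variant LD
#' blocks, 5,000 target-ancestry individuals, 40 causal variants, lifestyle
#' effects on, cross-validation reduced to 20 x 5.
#'
#' @param outdir output directory.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @return a `pipeline_config` list.
#' @export
default_config <- function(outdir = tempfile("transprs_run_"), seed = 1L) {
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    stages = c("simulate", "meta", "ct", "score", "ers", "evaluate",
               "followup"),
    sim = list(
      m = 2000L, block_size = 40L, n_causal = 40L, causal_beta = 0.15,
      target = ancestry_config("EAS", n_samples = 5000L, n_cases = 20000L,
                               n_controls = 200000L, fst = 0.05,
                               ld_rho = 0.8, block_size = 40L),
      other = ancestry_config("EUR", n_samples = 1000L, n_cases = 15000L,
                              n_controls = 600000L, fst = 0.10,
                              ld_rho = 0.8, block_size = 40L),
      lifestyle_logors = c(smoking = 0.35, alcohol = 0.25, activity = 0.20,
                           diet = 0.25, bmi = 0.30),
      lifestyle_missing = 0.05,
      p_naa = 0.15, p_adv = 0.06, noise_sd = 1, adenoma_prop = 0.9
    ),
    grid = ct_grid_spec(p_cuts = c(1e-6, 1e-4, 1e-3, 0.01),
                        r2_cuts = c(0.1, 0.5)),
    cv = list(repeats = 20L, folds = 5L),
    eval = list(k = c(0.02, 0.05, 0.10)),
    followup = list(baseline_hazard = 0.004, max_years = 10,
                    hr_ladder = 1.45)
  ), class = "pipeline_config")
}

pipeline_covariates <- function(cohort) {
  data.frame(age = cohort$age, sex = cohort$sex,
             family_history = cohort$family_history,
             pc1 = cohort$pc1, pc2 = cohort$pc2, pc3 = cohort$pc3,
             platform = cohort$platform)
}

# The four stage comparisons evaluated throughout: case definition vs
# control definition over the stage column.
stage_comparisons <- function() {
  list(
    adv_vs_normal = list(case = c("advanced_adenoma", "CRC"),
                         control = "normal"),
    naa_vs_normal = list(case = "NAA", control = "normal"),
    adv_vs_naa = list(case = c("advanced_adenoma", "CRC"), control = "NAA"),
    adv_vs_naa_normal = list(case = c("advanced_adenoma", "CRC"),
                             control = c("NAA", "normal"))
  )
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order, writes tables under
#' `config$outdir`, and records every output with its MD5 hash plus the
#' master seed in `manifest.json`. Re-running with the same config and seed
#' reproduces identical tables.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @return invisibly, a list with the in-memory stage products (panels,
#'   meta table, weight table, scores, ERS, evaluation report, follow-up
#'   report, manifest path).
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  sim <- config$sim
  st <- config$stages
  res <- list()
  outputs <- character(0)
  emit <- function(obj, name, writer) {
    path <- file.path(config$outdir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
  }

  ## -- simulate ------------------------------------------------------------
  if (!"simulate" %in% st) stop_invalid("pipeline requires the simulate stage")
  fst <- setNames(c(sim$target$fst, sim$other$fst),
                  c(sim$target$label, sim$other$label))
  freqs <- simulate_allele_freqs(sim$m, fst_by_ancestry = fst,
                                 seed = derive_seed(seed, 1))
  panel <- simulate_genotype_panel(sim$target, freqs[[sim$target$label]],
                                   seed = derive_seed(seed, 2))
  causal_idx <- round(seq(1, sim$m, length.out = sim$n_causal))
  betas <- numeric(sim$m)
  betas[causal_idx] <- sim$causal_beta
  model <- true_model(causal_weights = betas,
                      lifestyle_logors = sim$lifestyle_logors,
                      stage_thresholds = c(0, 1), noise_sd = sim$noise_sd,
                      adenoma_prop = sim$adenoma_prop)
  model$stage_thresholds <- liability_thresholds(panel, model,
                                                 p_naa = sim$p_naa,
                                                 p_adv = sim$p_adv)
  cohort <- simulate_outcomes(panel, model, seed = derive_seed(seed, 3),
                              missing_rate = sim$lifestyle_missing)
  stats <- data.table::rbindlist(list(
    simulate_summary_stats(freqs[[sim$target$label]], betas,
                           sim$target$n_cases, sim$target$n_controls,
                           seed = derive_seed(seed, 4),
                           ancestry = sim$target$label,
                           variants = panel$variants),
    simulate_summary_stats(freqs[[sim$other$label]], betas,
                           sim$other$n_cases, sim$other$n_controls,
                           seed = derive_seed(seed, 5),
                           ancestry = sim$other$label,
                           variants = panel$variants)
  ))
  emit(cohort, "cohort.csv", function(x, p) data.table::fwrite(x, p))
  emit(stats, "sumstats.tsv", write_sumstats)
  emit(panel, "panel.vcf", write_panel_vcf)
  res$panel <- panel; res$cohort <- cohort; res$model <- model

  ## -- meta ----------------------------------------------------------------
  if ("meta" %in% st) {
    ma <- meta_analyse(stats, reference = sim$target$label)
    flt <- filter_meta(ma$meta,
                       required_ancestries = c(sim$target$label,
                                               sim$other$label))
    res$meta <- flt$meta
    res$lambdas <- ma$lambdas
    res$meta_removed <- flt$removed
    emit(flt$meta, "meta.tsv",
         function(x, p) data.table::fwrite(x, p, sep = "\t"))
  }

  ## -- ct: CV threshold selection + final clump ---------------------------
  comparisons <- stage_comparisons()
  covars <- pipeline_covariates(cohort)
  adv <- cohort$advanced_neoplasm
  if ("ct" %in% st) {
    sel_idx <- cohort$stage %in% c("normal", "advanced_adenoma", "CRC")
    sub_panel <- panel
    sub_panel$sample_ids <- panel$sample_ids[sel_idx]
    sub_panel$dosage <- panel$dosage[sel_idx, , drop = FALSE]
    cv <- cv_select_threshold(sub_panel, adv[sel_idx], res$meta,
                              spec = config$grid,
                              repeats = config$cv$repeats,
                              folds = config$cv$folds,
                              seed = derive_seed(seed, 6))
    weights <- clump(res$meta, panel, config$grid,
                     r2_cut = cv$best$r2_cut, p_cut = cv$best$p_cut)
    res$cv <- cv
    res$weights <- weights
    emit(cv$auc_table, "cv_auc_grid.csv",
         function(x, p) data.table::fwrite(x, p))
    emit(weights, "prs_weights.txt", write_scorefile)
  }

  ## -- score ---------------------------------------------------------------
  if ("score" %in% st) {
    if (is.null(res$weights)) stop_invalid("score stage needs ct output")
    scores <- score_panel(panel, res$weights)
    res$scores <- scores
    emit(scores, "prs_scores.csv", function(x, p) data.table::fwrite(x, p))
  }

  ## -- ers -----------------------------------------------------------------
  if ("ers" %in% st) {
    completed <- pmm_impute(cohort, seed = derive_seed(seed, 7))
    flags <- binarize_lifestyle(completed)
    ers_w <- fit_ers_weights(flags, adv, covars)
    ers <- compute_ers(flags, ers_w)
    res$ers_weights <- ers_w
    res$ers <- ers
    emit(ers_w, "ers_weights.tsv", write_ers_weights)
    emit(ers, "ers_scores.csv", function(x, p) data.table::fwrite(x, p))
  }

  ## -- evaluate ------------------------------------------------------------
  if ("evaluate" %in% st) {
    if (is.null(res$scores)) stop_invalid("evaluate stage needs scores")
    report <- evaluate_stratification(cohort, res$scores, res$ers, covars,
                                      k_list = config$eval$k)
    res$report <- report
    emit(report$associations, "eval_associations.csv",
         function(x, p) data.table::fwrite(x, p))
    emit(report$screening, "eval_screening.csv",
         function(x, p) data.table::fwrite(x, p))
    emit(report$deciles, "eval_deciles.csv",
         function(x, p) data.table::fwrite(x, p))
    if (!is.null(report$joint)) {
      emit(report$joint, "eval_joint.csv",
           function(x, p) data.table::fwrite(x, p))
    }
  }

  ## -- followup ------------------------------------------------------------
  if ("followup" %in% st) {
    if (is.null(res$ers)) stop_invalid("followup stage needs ERS categories")
    prs_cat <- percentile_category(res$scores$z)
    grp <- paste(prs_cat, res$ers$category, sep = "/")
    ladder <- config$followup$hr_ladder
    lv <- c("low", "middle", "top")
    hr <- setNames(ladder^(as.vector(outer(0:2, 0:2, "+"))),
                   as.vector(outer(lv, lv, function(a, b)
                     paste(a, b, sep = "/"))))
    fu_cohort <- data.table::copy(cohort)[, risk_group := grp]
    fu_cohort <- simulate_followup(fu_cohort, hr,
                                   baseline_hazard =
                                     config$followup$baseline_hazard,
                                   max_years = config$followup$max_years,
                                   seed = derive_seed(seed, 8))
    fu <- followup_analysis(fu_cohort,
                            factor(grp, levels = names(hr)), covars)
    res$followup <- fu
    emit(fu$incidence, "followup_incidence.csv",
         function(x, p) data.table::fwrite(x, p))
    emit(fu$cox, "followup_cox.csv", function(x, p) data.table::fwrite(x, p))
  }

  ## -- manifest ------------------------------------------------------------
  manifest <- list(
    seed = seed,
    stages = st,
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  res$manifest <- manifest_path
  invisible(res)
}

#' Full stratification evaluation over the four stage comparisons
#'
#' For each comparison (advanced neoplasm vs normal, NAA vs normal,
#' advanced vs NAA, advanced vs NAA + normal): crude and adjusted AUC and
#' per-SD OR of the PRS (and ERS when supplied), top-k screening metrics at
#' each `k`, decile ORs for the main comparison, the joint 3x3 PRS x ERS
#' grid, and additive interaction statistics.
#'
#' @param cohort cohort `data.table` with `stage`.
#' @param scores PRS `score_result` aligned with the cohort.
#' @param ers ERS table from [compute_ers()] (or NULL to skip ERS parts).
#' @param covariates adjustment covariate data.frame.
#' @param k_list top-k fractions for screening metrics.
#' @return list of tables: `associations`, `screening`, `deciles`,
#'   `joint`, `interaction`.
#' @export
evaluate_stratification <- function(cohort, scores, ers = NULL, covariates,
                                    k_list = c(0.02, 0.05, 0.10)) {
  comparisons <- stage_comparisons()
  assoc <- list(); screen <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    idx <- cohort$stage %in% c(cmp$case, cmp$control)
    y <- as.integer(cohort$stage[idx] %in% cmp$case)
    if (length(unique(y)) < 2L) next
    cv <- covariates[idx, , drop = FALSE]
    sub_scores <- list(prs = scores$z[idx])
    if (!is.null(ers)) sub_scores$ers <- ers$z[idx]
    for (sc in names(sub_scores)) {
      z <- scale(sub_scores[[sc]])[, 1]  # re-standardize within comparison
      o <- per_sd_or(z, y, cv)
      assoc[[paste(nm, sc)]] <- data.table::data.table(
        comparison = nm, score = sc, n_cases = o$n_cases,
        n_controls = o$n_controls,
        auc_crude = empirical_auc(z, y),
        auc_adjusted = adjusted_auc(z, y, cv),
        or_per_sd = o$or, ci_lo = o$ci[1], ci_hi = o$ci[2], p = o$p)
      for (k in k_list) {
        tm <- topk_metrics(z, y, k, cv)
        screen[[paste(nm, sc, k)]] <- data.table::data.table(
          comparison = nm, score = sc, k = k,
          sensitivity = tm$sensitivity, specificity = tm$specificity,
          ppv = tm$ppv, npv = tm$npv, or = tm$or, ci_lo = tm$ci[1],
          ci_hi = tm$ci[2], p = tm$p)
      }
    }
  }
  main <- comparisons$adv_vs_normal
  idx <- cohort$stage %in% c(main$case, main$control)
  y <- as.integer(cohort$stage[idx] %in% main$case)
  dec <- decile_ors(scores$z[idx], y, covariates[idx, , drop = FALSE])
  dec_tab <- data.table::copy(dec$table)[, p_trend := dec$p_trend]
  joint <- NULL; inter <- NULL
  if (!is.null(ers)) {
    prs_cat <- percentile_category(scores$z)
    joint <- joint_stratify(prs_cat[idx], ers$category[idx], y,
                            covariates[idx, , drop = FALSE])
    inter <- interaction_analysis(prs_cat[idx] == "top",
                                  (ers$category == "top")[idx], y,
                                  covariates[idx, , drop = FALSE])
  }
  list(associations = data.table::rbindlist(assoc),
       screening = data.table::rbindlist(screen),
       deciles = dec_tab, joint = joint, interaction = inter)
}
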