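# Environmental risk score: lifestyle binarization, sex/age-stratified
# predictive-mean-matching imputation, covariate-adjusted weight estimation,
# and per-participant scoring with 20/60/20 risk categories.

#' Binarize raw lifestyle factors into unhealthy flags
#'
#' A factor is healthy (flag 0) only when: never smoker; never drinker;
#' physical activity > 4 sessions/week; diet quality score >= 5 (of 8);
#' BMI < 24 kg/m^2. Former and current smokers/drinkers are both unhealthy.
#' Missing raw values yield missing flags (impute first, see
#' [pmm_impute()]).
#'
#' @param cohort cohort `data.table` with raw fields `smoking`, `alcohol`,
#'   `activity`, `diet`, `bmi`.
#' @param factors factor subset to use (4-factor mode drops `activity` when
#'   its collection is too sparse).
#' @return data.table of 0/1 unhealthy flags, one column per factor, with
#'   attribute `factors`.
#' @export
binarize_lifestyle <- function(cohort, factors = lifestyle_factors()) {
  factors <- match.arg(factors, lifestyle_factors(), several.ok = TRUE)
  if (any(!is.na(cohort$diet) & (cohort$diet < 0 | cohort$diet > 8))) {
    stop_invalid("diet score out of [0, 8]")
  }
  if (any(!is.na(cohort$bmi) & cohort$bmi <= 0)) {
    stop_invalid("nonpositive BMI")
  }
  bad_status <- function(x) {
    !is.na(x) & !x %in% c("never", "former", "current")
  }
  if (any(bad_status(cohort$smoking)) || any(bad_status(cohort$alcohol))) {
    stop_invalid("smoking/alcohol status must be never/former/current")
  }
  all_flags <- list(
    smoking = as.integer(cohort$smoking != "never"),
    alcohol = as.integer(cohort$alcohol != "never"),
    activity = as.integer(!(cohort$activity > 4)),
    diet = as.integer(!(cohort$diet >= 5)),
    bmi = as.integer(!(cohort$bmi < 24))
  )
  out <- data.table::as.data.table(all_flags[factors])
  data.table::setattr(out, "factors", factors)
  out
}

age_band <- function(age, width = 5) {
  floor(age / width) * width
}

#' Sex- and age-stratified predictive mean matching imputation
#'
#' For each lifestyle variable with missing values, a linear predictor
#' (variable ~ age + sex, fit on complete cases) supplies predicted means;
#' each missing value is replaced by the observed value of one of the
#' `donors_k` donors with nearest predicted mean inside the recipient's
#' sex x 5-year-age-band stratum, falling back to the whole cohort when the
#' stratum holds no donors. Categorical smoking/alcohol are matched on the
#' predicted mean of an ever-indicator and the donor's raw status is copied.
#'
#' @param cohort cohort `data.table` (raw lifestyle fields with NAs).
#' @param donors_k number of nearest donors to draw from.
#' @param seed integer seed (donor draws).
#' @param band_width age-band width in years.
#' @return the cohort with lifestyle fields completed.
#' @export
pmm_impute <- function(cohort, donors_k = 5L, seed = 1L, band_width = 5) {
  out <- data.table::copy(data.table::as.data.table(cohort))
  strata <- paste(out$sex, age_band(out$age, band_width), sep = ":")
  with_seed(seed, {
    for (f in lifestyle_factors()) {
      x <- out[[f]]
      if (!anyNA(x)) next
      categorical <- is.character(x) || is.factor(x)
      y <- if (categorical) as.numeric(x != "never") else as.numeric(x)
      obs <- !is.na(y)
      if (!any(obs)) stop_invalid("'%s' is missing for every sample", f)
      fit <- lm(y ~ age + sex, data = out, subset = obs)
      pred <- as.vector(predict(fit, newdata = out))
      for (i in which(!obs)) {
        pool <- which(obs & strata == strata[i])
        if (!length(pool)) pool <- which(obs)
        k <- min(donors_k, length(pool))
        donors <- pool[order(abs(pred[pool] - pred[i]))[seq_len(k)]]
        pick <- donors[sample.int(k, 1L)]
        x[i] <- x[pick]
      }
      out[[f]] <- x
    }
  })
  out
}

#' Estimate ERS factor weights by adjusted logistic regression
#'
#' Fits one maximum-likelihood logistic model of the binary outcome on all
#' unhealthy flags jointly plus covariates; the flag coefficients (log-ORs)
#' are the factor weights.
#'
#' @param flags unhealthy-flag table from [binarize_lifestyle()].
#' @param outcome binary outcome (advanced neoplasm indicator).
#' @param covariates data.frame of adjustment covariates (age, sex, family
#'   history, ...), or NULL for a crude fit.
#' @return an `ers_weights` object: named numeric weights with fitting
#'   metadata attributes (`covariates`, `n`, `vcov`).
#' @export
fit_ers_weights <- function(flags, outcome, covariates = NULL) {
  if (length(unique(outcome)) != 2L) {
    stop_invalid("outcome must be binary with both classes present")
  }
  df <- data.frame(.y = outcome, flags)
  if (!is.null(covariates)) df <- data.frame(df, covariates)
  fit <- glm(.y ~ ., data = df, family = binomial())
  fnames <- names(flags)
  co <- coef(fit)[fnames]
  if (!fit$converged || any(!is.finite(co)) || any(abs(co) > 10)) {
    off <- fnames[!is.finite(co) | abs(co) > 10]
    stop_invalid("logistic fit unstable (separation?) for factor(s): %s",
                 paste(if (length(off)) off else "model", collapse = ", "))
  }
  structure(co, class = "ers_weights",
            covariates = if (is.null(covariates)) character(0)
                         else names(covariates),
            n = nrow(df), vcov = vcov(fit)[fnames, fnames, drop = FALSE])
}

#' Compute per-participant environmental risk scores
#'
#' ERS = sum over available factors of `weight * unhealthy flag`; the
#' z-score standardizes over the analysis sample and the category splits at
#' the 20th/80th percentiles (low / middle / top).
#'
#' @param flags unhealthy-flag table.
#' @param weights an `ers_weights` (or named numeric) covering the flag
#'   columns.
#' @return data.table: ers, z, category (factor low/middle/top).
#' @export
compute_ers <- function(flags, weights) {
  fnames <- names(flags)
  if (!all(fnames %in% names(weights))) {
    stop_invalid("weights missing for factor(s): %s",
                 paste(setdiff(fnames, names(weights)), collapse = ", "))
  }
  w <- unclass(weights)[fnames]
  ers <- as.vector(as.matrix(flags) %*% w)
  z <- if (sd(ers) > 0) (ers - mean(ers)) / sd(ers) else ers * 0
  data.table::data.table(ers = ers, z = z,
                         category = percentile_category(ers))
}

#' 20/60/20 percentile risk categories
#'
#' @param x numeric score.
#' @param probs lower/upper percentile boundaries (default 0.2 and 0.8).
#' @return factor with levels low / middle / top.
#' @export
percentile_category <- function(x, probs = c(0.2, 0.8)) {
  qs <- quantile(x, probs, names = FALSE, type = 7)
  cut(x, breaks = c(-Inf, qs, Inf), labels = c("low", "middle", "top"),
      right = FALSE)
}

#' Write / read ERS factor weights as two-column TSV
#'
#' @param weights an `ers_weights` or named numeric.
#' @param path file path.
#' @return `path` invisibly (writer); named numeric (reader).
#' @export
write_ers_weights <- function(weights, path) {
  data.table::fwrite(data.table::data.table(factor = names(weights),
                                            weight = as.numeric(weights)),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_ers_weights
#' @export
read_ers_weights <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  setNames(tab$weight, tab$factor)
}
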