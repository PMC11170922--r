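# Risk-model evaluation: discrimination (AUC), per-SD and decile ORs,
# top-percentile screening metrics, joint PRS x ERS stratification, additive
# interaction (RERI / AP / synergy index) with delta-method CIs, follow-up
# incidence analysis, and the closed-form equal-variance Gaussian liability
# oracles that link a per-SD OR to its crude AUC and screening metrics.

#' Tie-aware empirical AUC (Mann–Whitney)
#'
#' Midrank formulation of the Mann–Whitney statistic: the probability that a
#' random case outscores a random control, counting ties as 1/2.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- as.numeric(sum(labels == 1))
  n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) stop_invalid("both classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a covariate-adjusted model's linear predictor
#'
#' Fits `labels ~ scores + covariates` by logistic regression and returns
#' the empirical AUC of the fitted linear predictor.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome.
#' @param covariates data.frame of adjustment covariates.
#' @return AUC in `[0, 1]`.
#' @export
adjusted_auc <- function(scores, labels, covariates = NULL) {
  df <- data.frame(.y = labels, .s = scores)
  if (!is.null(covariates)) df <- data.frame(df, covariates)
  fit <- glm(.y ~ ., data = df, family = binomial())
  empirical_auc(predict(fit, type = "link"), labels)
}

wald_or <- function(fit, term) {
  est <- coef(fit)[term]
  se <- sqrt(diag(vcov(fit))[term])
  list(or = exp(est), ci = exp(est + c(-1, 1) * qnorm(0.975) * se),
       p = 2 * pnorm(-abs(est / se)), log_or = unname(est),
       se = unname(se))
}

#' Per-SD odds ratio of a z-scored risk score
#'
#' Logistic regression of the outcome on the z-transformed score plus
#' covariates; OR per SD with Wald 95% CI and P.
#'
#' @param z z-scored risk score (unit SD).
#' @param labels binary outcome.
#' @param covariates adjustment covariates (data.frame) or NULL.
#' @return list: or, ci (length 2), p, log_or, se, n_cases, n_controls.
#' @export
per_sd_or <- function(z, labels, covariates = NULL) {
  if (sd(z) == 0) stop_invalid("score has zero variance")
  df <- data.frame(.y = labels, z = z)
  if (!is.null(covariates)) df <- data.frame(df, covariates)
  fit <- glm(.y ~ ., data = df, family = binomial())
  if (!fit$converged) stop_invalid("logistic model did not converge")
  out <- wald_or(fit, "z")
  out$n_cases <- sum(labels == 1)
  out$n_controls <- sum(labels == 0)
  out
}

#' Decile odds ratios with trend test
#'
#' Scores are cut into deciles on the combined sample; each decile's OR vs
#' the lowest decile comes from an adjusted logistic model with decile as a
#' factor, and the trend P from the same model with the decile index
#' continuous.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome.
#' @param covariates adjustment covariates or NULL.
#' @return list: `table` (data.table decile, or, lo, hi, p, n_cases,
#'   n_controls; decile 1 is the reference with OR 1), `p_trend`.
#' @export
decile_ors <- function(scores, labels, covariates = NULL) {
  qs <- quantile(scores, seq(0.1, 0.9, 0.1), names = FALSE)
  dec <- findInterval(scores, vec = qs) + 1L
  df <- data.frame(.y = labels, dec = factor(dec, levels = 1:10))
  if (!is.null(covariates)) df <- data.frame(df, covariates)
  fit <- glm(.y ~ ., data = df, family = binomial())
  rows <- lapply(2:10, function(d) {
    term <- paste0("dec", d)
    cell_cases <- sum(labels == 1 & dec == d)
    cell_ctrls <- sum(labels == 0 & dec == d)
    if (!term %in% names(coef(fit)) || is.na(coef(fit)[term]) ||
        cell_cases == 0 || cell_ctrls == 0) {
      return(data.table::data.table(decile = d, or = NA_real_, lo = NA_real_,
                                    hi = NA_real_, p = NA_real_,
                                    n_cases = cell_cases,
                                    n_controls = cell_ctrls))
    }
    w <- wald_or(fit, term)
    data.table::data.table(decile = d, or = unname(w$or), lo = w$ci[1],
                           hi = w$ci[2], p = unname(w$p),
                           n_cases = cell_cases, n_controls = cell_ctrls)
  })
  tab <- rbind(data.table::data.table(decile = 1L, or = 1, lo = NA_real_,
                                      hi = NA_real_, p = NA_real_,
                                      n_cases = sum(labels == 1 & dec == 1),
                                      n_controls = sum(labels == 0 & dec == 1)),
               data.table::rbindlist(rows))
  df$dec <- dec
  trend <- glm(.y ~ ., data = df, family = binomial())
  list(table = tab, p_trend = unname(wald_or(trend, "dec")$p))
}

#' Screening metrics at a top-percentile cutoff
#'
#' The high-risk group is the top `k` fraction of the combined score
#' distribution (threshold at the `1 - k` quantile). Sensitivity,
#' specificity, PPV and NPV come from the resulting 2x2 table; the OR of
#' high-risk vs rest comes from the covariate-adjusted logistic model.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome.
#' @param k top fraction in (0, 1) (e.g. 0.02, 0.05, 0.10).
#' @param covariates adjustment covariates or NULL.
#' @param high optional explicit high-risk indicator overriding the
#'   percentile rule (e.g. joint PRS & ERS high-risk definitions).
#' @return list: k, threshold, sensitivity, specificity, ppv, npv, or, ci,
#'   p, counts (tp, fp, fn, tn).
#' @export
topk_metrics <- function(scores, labels, k = 0.05, covariates = NULL,
                         high = NULL) {
  if (k <= 0 || k >= 1) stop_invalid("`k` must lie in (0, 1)")
  if (length(unique(labels)) != 2L) stop_invalid("both classes required")
  if (is.null(high)) {
    thr <- quantile(scores, 1 - k, names = FALSE)
    high <- scores >= thr
  } else {
    thr <- NA_real_
    high <- as.logical(high)
  }
  tp <- sum(high & labels == 1); fp <- sum(high & labels == 0)
  fn <- sum(!high & labels == 1); tn <- sum(!high & labels == 0)
  df <- data.frame(.y = labels, high = as.integer(high))
  if (!is.null(covariates)) df <- data.frame(df, covariates)
  orw <- tryCatch({
    fit <- glm(.y ~ ., data = df, family = binomial())
    wald_or(fit, "high")
  }, error = function(e) list(or = NA_real_, ci = c(NA_real_, NA_real_),
                              p = NA_real_))
  list(k = k, threshold = thr,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       or = unname(orw$or), ci = unname(orw$ci), p = unname(orw$p),
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Joint PRS x ERS 3x3 stratification
#'
#' ORs of each (PRS category, ERS category) cell against the
#' (low, low) reference, from one adjusted logistic model with the 9-level
#' cell factor.
#'
#' @param prs_category,ers_category factors with levels low/middle/top.
#' @param labels binary outcome.
#' @param covariates adjustment covariates or NULL.
#' @return data.table: prs, ers, or, lo, hi, p, n_cases, n_controls
#'   (reference row has OR 1; empty cells flagged non-estimable with NA).
#' @export
joint_stratify <- function(prs_category, ers_category, labels,
                           covariates = NULL) {
  lv <- c("low", "middle", "top")
  cell <- factor(paste(prs_category, ers_category, sep = "."),
                 levels = as.vector(outer(lv, lv, paste, sep = ".")))
  df <- data.frame(.y = labels, cell = cell)
  if (!is.null(covariates)) df <- data.frame(df, covariates)
  fit <- glm(.y ~ ., data = df, family = binomial())
  grid <- expand.grid(ers = lv, prs = lv, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, c("prs", "ers")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lab <- paste(grid$prs[i], grid$ers[i], sep = ".")
    nc <- sum(labels == 1 & cell == lab)
    n0 <- sum(labels == 0 & cell == lab)
    base <- data.table::data.table(prs = grid$prs[i], ers = grid$ers[i],
                                   or = NA_real_, lo = NA_real_,
                                   hi = NA_real_, p = NA_real_,
                                   n_cases = nc, n_controls = n0)
    if (lab == "low.low") {
      base$or <- 1
    } else {
      term <- paste0("cell", lab)
      if (term %in% names(coef(fit)) && !is.na(coef(fit)[term]) &&
          nc > 0 && n0 > 0) {
        w <- wald_or(fit, term)
        base$or <- unname(w$or); base$lo <- w$ci[1]; base$hi <- w$ci[2]
        base$p <- unname(w$p)
      }
    }
    base
  })
  data.table::rbindlist(rows)
}

#' Additive interaction statistics from a joint 2x2 exposure model
#'
#' Given the ORs of the three non-reference cells of a double-dichotomy
#' (exposure A only, exposure B only, both) and the covariance of their
#' log-ORs, computes the relative excess risk due to interaction
#' `RERI = OR11 - OR10 - OR01 + 1`, the attributable proportion
#' `AP = RERI / OR11`, the synergy index
#' `S = (OR11 - 1) / (OR10 + OR01 - 2)`, and the multiplicative interaction
#' ratio `OR11 / (OR10 * OR01)`, each with delta-method 95% CIs on the
#' appropriate scale (S and the multiplicative ratio on the log scale).
#'
#' @param or10,or01,or11 cell odds ratios (A-only, B-only, both) vs the
#'   doubly-unexposed reference.
#' @param vcov_log 3x3 covariance matrix of (log OR10, log OR01, log OR11);
#'   defaults to independence with `se_log` variances.
#' @param se_log optional length-3 SEs of the log-ORs (used when
#'   `vcov_log` is NULL).
#' @return list of lists: reri, ap, s, mult — each with `est`, `lo`, `hi`
#'   (S is NA with a warning when `OR10 + OR01 <= 2`).
#' @export
additive_interaction <- function(or10, or01, or11, vcov_log = NULL,
                                 se_log = c(0, 0, 0)) {
  or10 <- unname(or10); or01 <- unname(or01); or11 <- unname(or11)
  if (any(c(or10, or01, or11) <= 0)) stop_invalid("ORs must be positive")
  if (is.null(vcov_log)) vcov_log <- diag(se_log^2, 3)
  l <- log(c(or10, or01, or11))
  zq <- qnorm(0.975)
  dm <- function(est, grad) {
    se <- sqrt(as.vector(t(grad) %*% vcov_log %*% grad))
    c(est = est, lo = est - zq * se, hi = est + zq * se)
  }
  reri <- or11 - or10 - or01 + 1
  reri_ci <- dm(reri, c(-or10, -or01, or11))
  ap <- reri / or11
  ap_ci <- dm(ap, c(-or10 / or11, -or01 / or11,
                    (or10 + or01) / or11 - exp(-l[3])))
  if (or10 + or01 > 2 && or11 > 1) {
    den <- or10 + or01 - 2
    ls <- log((or11 - 1) / den)
    ls_ci <- dm(ls, c(-or10 / den, -or01 / den, or11 / (or11 - 1)))
    s <- list(est = exp(ls), lo = exp(ls_ci["lo"]), hi = exp(ls_ci["hi"]))
  } else {
    warning("synergy index undefined (OR10 + OR01 <= 2 or OR11 <= 1)")
    s <- list(est = NA_real_, lo = NA_real_, hi = NA_real_)
  }
  lm_ <- l[3] - l[1] - l[2]
  lm_ci <- dm(lm_, c(-1, -1, 1))
  list(reri = list(est = reri, lo = unname(reri_ci["lo"]),
                   hi = unname(reri_ci["hi"])),
       ap = list(est = ap, lo = unname(ap_ci["lo"]), hi = unname(ap_ci["hi"])),
       s = lapply(s, unname),
       mult = list(est = exp(lm_), lo = exp(unname(lm_ci["lo"])),
                   hi = exp(unname(lm_ci["hi"]))))
}

#' Fit the double-dichotomy model behind the additive interaction measures
#'
#' Dichotomizes PRS and ERS as high vs rest (top 20% by default), fits one
#' adjusted logistic model with the three indicator cells, and feeds the
#' fitted log-ORs and their covariance to [additive_interaction()].
#'
#' @param prs_high,ers_high logical high-exposure indicators.
#' @param labels binary outcome.
#' @param covariates adjustment covariates or NULL.
#' @return as [additive_interaction()], plus `or10`, `or01`, `or11`.
#' @export
interaction_analysis <- function(prs_high, ers_high, labels,
                                 covariates = NULL) {
  g10 <- as.integer(prs_high & !ers_high)
  g01 <- as.integer(!prs_high & ers_high)
  g11 <- as.integer(prs_high & ers_high)
  df <- data.frame(.y = labels, g10 = g10, g01 = g01, g11 = g11)
  if (!is.null(covariates)) df <- data.frame(df, covariates)
  fit <- glm(.y ~ ., data = df, family = binomial())
  terms <- c("g10", "g01", "g11")
  ors <- exp(coef(fit)[terms])
  res <- additive_interaction(ors[1], ors[2], ors[3],
                              vcov_log = vcov(fit)[terms, terms])
  res$or10 <- unname(ors[1]); res$or01 <- unname(ors[2])
  res$or11 <- unname(ors[3])
  res
}

#' Kaplan–Meier / Cox follow-up analysis by risk group
#'
#' Cumulative incidence per group by Kaplan–Meier, events and person-years
#' with rates per 100,000 person-years, and Cox hazard ratios (Breslow ties)
#' per group against the first level.
#'
#' @param cohort data.table with `follow_up_years` and `event`.
#' @param group factor of risk-group labels (first level = reference).
#' @param covariates adjustment covariates or NULL.
#' @return list: `incidence` (data.table: group, n, events, person_years,
#'   rate_per_1e5), `km` (data.table: group, time, cum_incidence),
#'   `cox` (data.table: group, hr, lo, hi, p; reference HR 1).
#' @export
followup_analysis <- function(cohort, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  time <- cohort$follow_up_years
  event <- cohort$event
  inc <- data.table::data.table(group = levels(group))
  inc$n <- as.vector(table(group))
  inc$events <- as.vector(tapply(event, group, sum))
  inc$person_years <- as.vector(tapply(time, group, sum))
  inc$rate_per_1e5 <- ifelse(inc$person_years > 0,
                             1e5 * inc$events / inc$person_years, NA_real_)
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  km <- data.table::data.table(
    group = rep(sub("^group=", "", names(sf$strata) %||% levels(group)),
                sf$strata %||% length(sf$time)),
    time = sf$time, cum_incidence = 1 - sf$surv)
  if (nlevels(group) > 1L) {
    df <- data.frame(time = time, event = event, group = group)
    if (!is.null(covariates)) df <- data.frame(df, covariates)
    cx <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                          ties = "breslow")
    terms <- paste0("group", levels(group)[-1])
    est <- coef(cx)[terms]
    se <- sqrt(diag(vcov(cx))[terms])
    cox <- data.table::data.table(
      group = levels(group),
      hr = c(1, exp(unname(est))),
      lo = c(NA, exp(unname(est - qnorm(0.975) * se))),
      hi = c(NA, exp(unname(est + qnorm(0.975) * se))),
      p = c(NA, unname(2 * pnorm(-abs(est / se)))))
  } else {
    cox <- data.table::data.table(group = levels(group), hr = 1,
                                  lo = NA_real_, hi = NA_real_,
                                  p = NA_real_)
  }
  list(incidence = inc, km = km, cox = cox)
}

#' Crude AUC implied by a per-SD OR under the Gaussian liability model
#'
#' Equal-variance binormal model: case and control scores are unit-variance
#' Gaussians whose means differ by `ln(OR per SD)`, giving
#' `AUC = Phi(ln(OR) / sqrt(2))`.
#'
#' @param or_per_sd odds ratio per SD of the score (> 0).
#' @return AUC in (0, 1).
#' @export
binormal_auc_from_or <- function(or_per_sd) {
  if (any(or_per_sd <= 0)) stop_invalid("`or_per_sd` must be positive")
  pnorm(log(or_per_sd) / sqrt(2))
}

#' Analytic top-k screening metrics under the Gaussian mixture model
#'
#' Controls score as N(0,1) and cases as N(mu, 1) with `mu = ln(OR per SD)`;
#' the case fraction is `n_cases / (n_cases + n_controls)`. The threshold t
#' solving `(1 - pi) P(N(0,1) > t) + pi P(N(mu,1) > t) = k` is found by a
#' bracketing root-finder (tolerance 1e-8); sensitivity, specificity, PPV
#' and NPV follow from the mixture and Bayes' rule.
#'
#' @param or_per_sd odds ratio per SD.
#' @param n_cases,n_controls population composition.
#' @param k top fraction flagged high-risk.
#' @return list: threshold, sensitivity, specificity, ppv, npv, prevalence.
#' @export
gaussian_topk_oracle <- function(or_per_sd, n_cases, n_controls, k) {
  if (or_per_sd <= 0 || n_cases <= 0 || n_controls <= 0) {
    stop_invalid("inputs must be positive")
  }
  if (k <= 0 || k >= 1) stop_invalid("`k` must lie in (0, 1)")
  mu <- log(or_per_sd)
  pi1 <- n_cases / (n_cases + n_controls)
  f <- function(t) {
    (1 - pi1) * pnorm(t, lower.tail = FALSE) +
      pi1 * pnorm(t - mu, lower.tail = FALSE) - k
  }
  t <- uniroot(f, lower = -20, upper = 20 + abs(mu), tol = 1e-8)$root
  sens <- pnorm(t - mu, lower.tail = FALSE)
  spec <- pnorm(t)
  ppv <- pi1 * sens / (pi1 * sens + (1 - pi1) * (1 - spec))
  npv <- (1 - pi1) * spec / ((1 - pi1) * spec + pi1 * (1 - sens))
  list(threshold = t, sensitivity = sens, specificity = spec,
       ppv = ppv, npv = npv, prevalence = pi1)
}
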