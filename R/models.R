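# Longitudinal mixed-effects machinery: the shared covariate model
# (age + age^2 + sex + education + English proficiency + log stroke severity
# + time since stroke, with a per-subject random intercept and time slope),
# Gaussian fits on Yeo-Johnson-transformed outcomes, aggregated binomial fits
# for accuracy counts, Benjamini-Hochberg control, the hand-impairment
# confound analysis and criterion validity against clinical scales.

#' Benjamini-Hochberg false discovery control
#'
#' Step-up q-values via [stats::p.adjust()] (valid under positive regression
#' dependency) and the rejection set at level `alpha`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `q` (monotone q-values) and `reject` (logical).
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) {
    return(list(q = numeric(0), reject = logical(0)))
  }
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    stopf("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Build the standardized analysis table for the patient cohort
#'
#' One row per patient session. Continuous covariates (age, age squared, time
#' since stroke) are z-scored once here, so every downstream model sees the
#' same standardisation; stroke severity is `log(1 + NIHSS)` and never
#' z-scored (its range includes 0 and the log already tames the skew).
#' Education enters as a factor with the lowest level as reference.
#'
#' @param meta participant-session metadata.
#' @return data.frame of model covariates keyed by `participant_id` and
#'   `session_index`.
#' @export
prepare_analysis_table <- function(meta) {
  m <- meta[meta$cohort == "patient", , drop = FALSE]
  if (nrow(m) == 0) stopf("no patient rows in metadata")
  data.frame(
    participant_id = m$participant_id,
    session_index = m$session_index,
    subject = factor(m$participant_id),
    age_z = zscore(m$age),
    age2_z = zscore(m$age^2),
    sex = factor(m$sex, levels = c("female", "male")),
    education = factor(m$education, levels = 1:4),
    esl = as.numeric(m$english_second_language),
    log_nihss = log1p(m$nihss_baseline),
    time_z = zscore(m$days_since_stroke),
    impaired = as.numeric(m$impaired_hand),
    phase = m$phase,
    moca = m$moca,
    iadl = m$iadl,
    stringsAsFactors = FALSE
  )
}

model_formula <- function(lhs, include_impaired) {
  rhs <- "age_z + age2_z + sex + education + esl + log_nihss + time_z"
  if (include_impaired) rhs <- paste(rhs, "+ impaired")
  stats::as.formula(paste(lhs, "~", rhs, "+ (1 + time_z | subject)"))
}

tidy_fixed <- function(coefs, p_col) {
  z <- stats::qnorm(0.975)
  data.frame(
    term = rownames(coefs),
    estimate = coefs[, "Estimate"],
    se = coefs[, "Std. Error"],
    ci_lo = coefs[, "Estimate"] - z * coefs[, "Std. Error"],
    ci_hi = coefs[, "Estimate"] + z * coefs[, "Std. Error"],
    p = coefs[, p_col],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Linear mixed model with random time slopes on a transformed outcome
#'
#' Yeo-Johnson-transforms and z-scores the outcome (so estimates are
#' standardized betas), then fits
#' `y ~ age + age^2 + sex + education + esl + log(1 + NIHSS) + time (+ impaired)`
#' with a per-subject random intercept and time slope via
#' [lmerTest::lmer()]. Singular random-slope fits are refitted with a random
#' intercept only and flagged. Wald 95% confidence intervals;
#' Satterthwaite p-values; a Shapiro-Wilk residual-normality p-value is
#' attached.
#'
#' @param outcome numeric outcome aligned with `data` rows.
#' @param data analysis table from [prepare_analysis_table()].
#' @param include_impaired add the impaired-hand predictor.
#' @param transform Yeo-Johnson the outcome before standardising (disable for
#'   already well-behaved simulation outcomes).
#' @return Object of class `regression_result`: data.frame of fixed terms
#'   (`term`, `estimate`, `se`, `ci_lo`, `ci_hi`, `p`) with attributes
#'   `family`, `singular`, `converged`, `shapiro_p`, `lambda`, `n`.
#' @export
fit_lmm <- function(outcome, data, include_impaired = FALSE, transform = TRUE) {
  keep <- is.finite(outcome)
  d <- data[keep, , drop = FALSE]
  y <- outcome[keep]
  lambda <- NA_real_
  if (transform && stats::sd(y) > 0) {
    tf <- fit_transform(y)
    lambda <- tf$lambda
    y <- yeo_johnson(y, lambda)
  }
  d$.y <- zscore(y)
  fm <- model_formula(".y", include_impaired)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- suppressMessages(lmerTest::lmer(fm, data = d, REML = TRUE,
                                         control = ctrl))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    fm2 <- stats::update.formula(fm, . ~ . - (1 + time_z | subject) +
                                   (1 | subject))
    fit <- suppressMessages(lmerTest::lmer(fm2, data = d, REML = TRUE,
                                           control = ctrl))
  }
  res <- stats::residuals(fit)
  if (length(res) > 4999) res <- res[seq(1, length(res), length.out = 4999)]
  shapiro_p <- tryCatch(stats::shapiro.test(res)$p.value,
                        error = function(e) NA_real_)
  out <- tidy_fixed(summary(fit)$coefficients, "Pr(>|t|)")
  structure(out, class = c("regression_result", "data.frame"),
            family = "gaussian", singular = singular,
            converged = length(fit@optinfo$conv$lme4$messages) == 0,
            shapiro_p = shapiro_p, lambda = lambda, n = nrow(d))
}

#' Aggregated binomial mixed model for accuracy counts
#'
#' Models per-session correct counts out of totals with a logit link and the
#' same fixed and random structure as [fit_lmm()], via [lme4::glmer()].
#' Estimates are standardized log-odds (covariates are z-scored upstream).
#' Sessions with zero total trials are dropped with a message; complete
#' separation (all-zero or all-maximal outcomes) raises an error. Singular or
#' non-converging random-slope fits fall back to a random intercept.
#'
#' @param correct,total integer vectors, `0 <= correct <= total`.
#' @param data analysis table from [prepare_analysis_table()].
#' @param include_impaired add the impaired-hand predictor.
#' @return `regression_result` (Wald z p-values), as in [fit_lmm()].
#' @export
fit_binomial_glmm <- function(correct, total, data, include_impaired = FALSE) {
  if (any(correct < 0 | correct > total, na.rm = TRUE)) {
    stopf("correct counts must lie in [0, total]")
  }
  keep <- is.finite(correct) & is.finite(total) & total > 0
  if (any(is.finite(total) & total == 0)) {
    message(sum(is.finite(total) & total == 0),
            " session(s) with zero trials dropped")
  }
  d <- data[keep, , drop = FALSE]
  k <- correct[keep]
  n <- total[keep]
  if (all(k == 0) || all(k == n)) {
    stopf("degenerate accuracy outcome (complete separation)")
  }
  d$.k <- k
  d$.nk <- n - k
  fm <- model_formula("cbind(.k, .nk)", include_impaired)
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             check.conv.grad = "ignore",
                             check.nobs.vs.nRE = "ignore")
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(fm, data = d, family = stats::binomial(), control = ctrl)))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  bad <- length(fit@optinfo$conv$lme4$messages) > 0
  if (singular || bad) {
    fm2 <- stats::update.formula(fm, . ~ . - (1 + time_z | subject) +
                                   (1 | subject))
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(fm2, data = d, family = stats::binomial(), control = ctrl)))
  }
  out <- tidy_fixed(summary(fit)$coefficients, "Pr(>|z|)")
  structure(out, class = c("regression_result", "data.frame"),
            family = "binomial", singular = singular,
            converged = length(fit@optinfo$conv$lme4$messages) == 0,
            shapiro_p = NA_real_, lambda = NA_real_, n = nrow(d))
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s family, n = %d%s\n",
              attr(x, "family"), attr(x, "n"),
              if (isTRUE(attr(x, "singular"))) " (random slope dropped)" else ""))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

# metric -> (source table, extractor, model family)
impairment_metrics <- function() {
  list(
    cognitive_index = list(src = "decomposition",
                           value = function(d) d$cognitive_index,
                           family = "gaussian"),
    delay_time = list(src = "decomposition",
                      value = function(d) d$delay_time,
                      family = "gaussian"),
    accuracy = list(src = "standard", value = NULL, family = "binomial"),
    median_rt = list(src = "standard",
                     value = function(d) d$median_rt,
                     family = "gaussian")
  )
}

#' Task-by-metric hand-impairment confound analysis
#'
#' For every task, fits the covariate-adjusted mixed model with the
#' impaired-hand predictor on four outcomes: the modelled Cognitive Index and
#' Response Delay Time (Gaussian on Yeo-Johnson-transformed values) and the
#' standard accuracy counts (aggregated binomial) and median reaction time
#' (Gaussian). The impaired-hand coefficient of each fit is collected and two
#' Benjamini-Hochberg families are reported: within each task across its four
#' metrics (`q_within_task`) and across tasks within each metric
#' (`q_across_tasks`). A task-metric cell is flagged `confounded` when its
#' across-task q-value falls below `alpha` - the family behind "how many of
#' the battery's tasks does impairment reach" statements; the within-task
#' q-values support per-task four-measure displays.
#'
#' @param decomposition output of [decompose_all()].
#' @param std_metrics output of [standard_metrics()].
#' @param meta participant-session metadata (patients are analysed).
#' @param alpha FDR level for the confounded verdict.
#' @return data.frame with one row per task x metric: the impaired-hand
#'   coefficient (`estimate`, `se`, `ci_lo`, `ci_hi`, `p`), `q_within_task`,
#'   `q_across_tasks`, `confounded`, `family`, `singular`, `n`.
#' @export
hand_impairment_analysis <- function(decomposition, std_metrics, meta,
                                     alpha = 0.05) {
  tab <- prepare_analysis_table(meta)
  key_tab <- paste(tab$participant_id, tab$session_index)
  metrics <- impairment_metrics()
  tasks <- sort(intersect(unique(decomposition$task_id),
                          unique(std_metrics$task_id)))
  skipped <- setdiff(union(unique(decomposition$task_id),
                           unique(std_metrics$task_id)), tasks)
  if (length(skipped)) {
    message("task(s) absent from one metric family excluded: ",
            paste(skipped, collapse = ", "))
  }

  rows <- list()
  for (task in tasks) {
    dec <- decomposition[decomposition$task_id == task, , drop = FALSE]
    std <- std_metrics[std_metrics$task_id == task, , drop = FALSE]
    for (metric in names(metrics)) {
      mm <- metrics[[metric]]
      src <- if (mm$src == "decomposition") dec else std
      idx <- match(key_tab, paste(src$participant_id, src$session_index))
      fit <- if (mm$family == "binomial") {
        fit_binomial_glmm(src$accuracy_count[idx], src$trial_count[idx],
                          tab, include_impaired = TRUE)
      } else {
        fit_lmm(mm$value(src)[idx], tab, include_impaired = TRUE)
      }
      imp <- fit[fit$term == "impaired", , drop = FALSE]
      rows[[paste(task, metric)]] <- data.frame(
        task_id = task, metric = metric, family = mm$family,
        estimate = imp$estimate, se = imp$se,
        ci_lo = imp$ci_lo, ci_hi = imp$ci_hi, p = imp$p,
        singular = attr(fit, "singular"), n = attr(fit, "n"),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q_within_task <- stats::ave(res$p, res$task_id,
                                  FUN = function(p) bh_fdr(p)$q)
  res$q_across_tasks <- stats::ave(res$p, res$metric,
                                   FUN = function(p) bh_fdr(p)$q)
  res$confounded <- res$q_across_tasks < alpha
  res
}

#' Criterion validity of global factors against clinical scales
#'
#' Ordinary least-squares of a clinical criterion (MoCA-like or IADL-like
#' score) on the global factor score, per phase and metric family. R-squared,
#' slope and the slope's p-value are reported uncorrected (these are three
#' phase-wise confirmatory regressions, not a screening family).
#'
#' @param gfactors a [extract_g()] result or list of them.
#' @param meta participant-session metadata.
#' @param criterion `"moca"` or `"iadl"`.
#' @param min_pairs skip a factor with fewer matched pairs than this.
#' @return data.frame: `phase`, `metric_family`, `criterion`, `n`,
#'   `r_squared`, `slope`, `p`.
#' @export
criterion_validity <- function(gfactors, meta, criterion = c("moca", "iadl"),
                               min_pairs = 10L) {
  criterion <- match.arg(criterion)
  if (inherits(gfactors, "global_factor")) gfactors <- list(gfactors)
  out <- list()
  for (gf in gfactors) {
    sel <- select_phase_sessions(meta, gf$phase)
    crit <- sel[[criterion]][match(names(gf$scores), sel$participant_id)]
    keep <- is.finite(crit)
    if (sum(keep) < min_pairs) {
      message("phase ", gf$phase, " / ", gf$metric_family, ": only ",
              sum(keep), " matched pairs; skipped")
      next
    }
    fit <- stats::lm(crit[keep] ~ gf$scores[keep])
    sm <- summary(fit)
    out[[paste(gf$phase, gf$metric_family)]] <- data.frame(
      phase = gf$phase, metric_family = gf$metric_family,
      criterion = criterion, n = sum(keep),
      r_squared = sm$r.squared,
      slope = stats::coef(fit)[2],
      p = sm$coefficients[2, 4],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
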