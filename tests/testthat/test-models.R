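test_that("BH control matches the step-up definition on canonical cases", {
  expect_equal(bh_fdr(0.03)$q, 0.03)
  expect_equal(bh_fdr(rep(0.04, 10))$q, rep(0.04, 10))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.05, 0.20))$q,
               c(0.04, 0.04, 0.2 / 3, 0.20), tolerance = 1e-12)
  expect_length(bh_fdr(numeric(0))$q, 0)
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
  # q-values never fall below their p-values and rejections respect alpha
  withr::with_seed(8, {
    p <- runif(40)^2
  })
  out <- bh_fdr(p, alpha = 0.05)
  expect_true(all(out$q >= p - 1e-12))
  expect_identical(out$reject, out$q <= 0.05)
})

test_that("BH q-values are permutation invariant and match brute force on random draws", {
  withr::with_seed(12, {
    for (i in 1:20) {
      p <- round(runif(7), 3)
      expect_equal(bh_fdr(p)$q, bh_bruteforce(p), tolerance = 1e-12)
      perm <- sample(length(p))
      expect_equal(bh_fdr(p[perm])$q, bh_fdr(p)$q[perm], tolerance = 1e-12)
    }
  })
})

test_that("the linear mixed model recovers a known standardized effect with nominal coverage", {
  n_rep <- 100
  covered <- logical(n_rep)
  withr::with_seed(11, {
    for (r in seq_len(n_rep)) {
      tab <- simulate_patient_table(300, n_sessions = 2)
      # variance budget sums to 1 so the effect is -0.3 on the standardized
      # outcome scale the model estimates
      y <- -0.3 * tab$age_z +
        null_outcome(tab, 0.5, 0.2, sqrt(1 - 0.09 - 0.25 - 0.04))
      fit <- fit_lmm(y, tab, transform = FALSE)
      row <- fit[fit$term == "age_z", ]
      covered[r] <- row$ci_lo <= -0.3 && row$ci_hi >= -0.3
    }
  })
  expect_gte(mean(covered), 0.93)
})

test_that("singular random slopes fall back to a random intercept, flagged", {
  withr::with_seed(15, {
    tab <- simulate_patient_table(60, n_sessions = 2)
    y <- null_outcome(tab, 0.5, 0, 1)  # no slope variance: singular by design
  })
  fit <- fit_lmm(y, tab, transform = FALSE)
  expect_true(attr(fit, "singular"))
  expect_true(all(c("estimate", "se", "ci_lo", "ci_hi", "p") %in% names(fit)))
  expect_true(all(fit$ci_lo <= fit$estimate & fit$estimate <= fit$ci_hi))
})

test_that("the aggregated binomial model is unbiased at chance performance", {
  withr::with_seed(13, {
    tab <- simulate_patient_table(140, n_sessions = 3)
    k <- rbinom(nrow(tab), 40, 0.5)
  })
  fit <- fit_binomial_glmm(k, rep(40L, nrow(tab)), tab,
                           include_impaired = TRUE)
  expect_lt(abs(fit$estimate[fit$term == "(Intercept)"]), 0.1)
  expect_true(all(abs(fit$estimate[fit$term != "(Intercept)"]) < 0.1))
  expect_equal(attr(fit, "family"), "binomial")
})

test_that("binomial degenerate rows and separation are handled explicitly", {
  withr::with_seed(14, {
    tab <- simulate_patient_table(40, n_sessions = 2)
    k <- rbinom(nrow(tab), 30, 0.6)
  })
  tot <- rep(30L, nrow(tab))
  tot[1:3] <- 0L
  k[1:3] <- 0L
  expect_message(fit <- fit_binomial_glmm(k, tot, tab), "zero trials")
  expect_equal(attr(fit, "n"), nrow(tab) - 3)
  expect_error(fit_binomial_glmm(rep(0L, nrow(tab)), rep(30L, nrow(tab)),
                                 tab), "separation")
  expect_error(fit_binomial_glmm(c(31L, k[-1]), rep(30L, nrow(tab)), tab),
               "correct counts")
})

test_that("criterion validity spans its extremes", {
  withr::with_seed(17, {
    scores <- rnorm(200)
    ids <- sprintf("pat%04d", 1:200)
    meta <- data.frame(participant_id = ids, session_index = 1L,
                       cohort = "patient", phase = "chronic",
                       days_since_stroke = 371,
                       moca = scores, iadl = rnorm(200),
                       stringsAsFactors = FALSE)
    gf <- structure(list(phase = "chronic", metric_family = "cognitive_index",
                         scores = stats::setNames(scores, ids),
                         loadings = NULL, variance_explained = 0.5),
                    class = "global_factor")
    cv_perfect <- suppressWarnings(criterion_validity(gf, meta, "moca"))
    expect_equal(cv_perfect$r_squared, 1, tolerance = 1e-12)
    cv_null <- criterion_validity(gf, meta, "iadl")
    expect_lt(cv_null$r_squared, 0.05)
  })
})

test_that("hand-impairment analysis reports both FDR families coherently", {
  coh <- generate_cohort(60, 50, seed = 23, registry = small_registry())
  est <- suppressWarnings(
    run_idoct(coh$trials, coh$participants, default_config()))
  res <- suppressMessages(hand_impairment_analysis(
    est$decomposition, est$standard, coh$participants))
  expect_equal(nrow(res), 4 * 4)  # 4 tasks x 4 metrics
  expect_true(all(res$q_within_task >= res$p - 1e-12))
  expect_true(all(res$q_across_tasks >= res$p - 1e-12))
  for (task in unique(res$task_id)) {
    sub <- res[res$task_id == task, ]
    expect_equal(sub$q_within_task, bh_fdr(sub$p)$q, tolerance = 1e-12)
  }
  for (metric in unique(res$metric)) {
    sub <- res[res$metric == metric, ]
    expect_equal(sub$q_across_tasks, bh_fdr(sub$p)$q, tolerance = 1e-12)
  }
  expect_identical(res$confounded, res$q_across_tasks < 0.05)
  expect_identical(unique(res$family[res$metric == "accuracy"]), "binomial")
})
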