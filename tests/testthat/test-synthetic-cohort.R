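test_that("empty cohorts are handled and generation is reproducible", {
  p0 <- generate_participants(10, 0, seed = 1)
  expect_true(all(p0$cohort == "normative"))
  expect_equal(nrow(generate_participants(0, 0, seed = 1)), 0)
  expect_error(generate_participants(-1, 5), "nonnegative")

  a <- generate_participants(50, 30, seed = 42)
  b <- generate_participants(50, 30, seed = 42)
  expect_identical(a, b)
  reg <- default_task_registry()
  ta <- generate_trials(a, reg$trail_making, seed = 9)
  tb <- generate_trials(b, reg$trail_making, seed = 9)
  expect_identical(ta, tb)
})

test_that("marginal moments track the configured cohort characteristics", {
  p <- generate_participants(600, 500, seed = 3)
  pat <- p[p$cohort == "patient" & !duplicated(p$participant_id), ]
  nrm <- p[p$cohort == "normative", ]
  n <- nrow(pat)

  # age: mean within 3 SE of 63.01 (truncation to [24, 97] barely bites)
  expect_lt(abs(mean(pat$age) - 63.01), 3 * 14.1 / sqrt(n))
  expect_true(all(pat$age >= 24 & pat$age <= 97))
  expect_lt(abs(mean(nrm$age) - 60.8), 3 * 10.1 / sqrt(nrow(nrm)))

  # NIHSS: 3 SE band plus a small rounding/clipping allowance
  expect_lt(abs(mean(pat$nihss_baseline) - 4.93),
            3 * 4.66 / sqrt(n) + 0.2)
  expect_lt(abs(sd(pat$nihss_baseline) - 4.66), 0.7)
  expect_gt(sample_skewness(pat$nihss_baseline), 0.5)
  expect_true(all(pat$nihss_baseline >= 0 & pat$nihss_baseline <= 26))

  rate <- 47 / 171
  expect_lt(abs(mean(pat$impaired_hand) - rate),
            3 * sqrt(rate * (1 - rate) / n))
  expect_false(any(nrm$impaired_hand))
  expect_true(all(is.na(nrm$nihss_baseline)))
  expect_true(all(is.na(nrm$days_since_stroke)))

  # phase banding is deterministic in days
  expect_identical(pat_phase <- phase_from_days(c(1, 14, 15, 180, 181, 500)),
                   c("acute", "acute", "subacute", "subacute",
                     "chronic", "chronic"))
})

test_that("criterion scores are monotone in ability, exactly so without noise", {
  params <- default_generator_params()
  params$criterion$moca_sd <- 0
  params$criterion$iadl_sd <- 0
  p <- generate_participants(0, 500, seed = 1, params = params)
  expect_equal(cor(p$moca, p$latent_ability), 1, tolerance = 1e-12)
  expect_equal(cor(p$iadl, p$latent_ability), 1, tolerance = 1e-12)

  # with default noise the association stays strongly positive, and imaging
  # burden decreases in ability
  pd <- generate_participants(0, 500, seed = 1)
  expect_gt(cor(pd$moca, pd$latent_ability), 0.7)
  expect_gt(cor(pd$iadl, pd$latent_ability), 0.5)
  base <- pd[!duplicated(pd$participant_id), ]
  expect_lt(cor(log(base$lesion_volume), base$latent_ability,
                use = "complete.obs"), -0.3)
  expect_lt(cor(log(base$wmh_volume), base$latent_ability,
                use = "complete.obs"), -0.3)
})

test_that("with motor effects disabled, impairment does not touch accuracy", {
  params <- null_motor_params()
  reg <- strip_motor_effects(default_task_registry())
  p <- generate_participants(0, 400, seed = 7, params = params)
  tr <- generate_trials(p, reg$trail_making, seed = 7, params = params)
  imp <- p$impaired_hand[match(tr$participant_id, p$participant_id)]
  acc_by <- tapply(tr$accuracy, interaction(tr$participant_id, imp,
                                            drop = TRUE), mean)
  grp <- sub(".*\\.", "", names(acc_by))
  tt <- t.test(acc_by[grp == "TRUE"], acc_by[grp == "FALSE"])
  expect_gt(tt$p.value, 0.01)
})

test_that("the trial model honours its closed forms and saturation limits", {
  params <- default_generator_params()
  reg <- default_task_registry()

  # sigmoid saturation: overwhelming ability => every trial correct
  p <- generate_participants(0, 30, seed = 2, params = params)
  p$latent_ability <- 12
  params0 <- params
  params0$ability$task_session_sd <- 0
  params0$criterion$kappa_wmh <- 0
  tr <- generate_trials(p[!p$impaired_hand, ], reg$semantic_judgement,
                        seed = 2, params = params0)
  expect_true(all(tr$accuracy[!tr$timed_out] == 1L))

  # zero-noise reaction time equals the closed form exactly
  pz <- generate_participants(0, 1, seed = 5, params = params)
  pz <- pz[1, ]
  pz$impaired_hand <- FALSE
  pz$latent_caution <- 0
  paramsz <- params
  paramsz$trial$rt_noise_sdlog <- 0
  paramsz$ability$task_session_sd <- 0
  paramsz$criterion$kappa_wmh <- 0
  paramsz$sessions$task_completion_rate <- 1
  task <- reg$semantic_judgement
  trz <- generate_trials(pz, task, seed = 5, params = paramsz)
  b <- task$condition_difficulties[match(trz$condition_label,
                                         task$condition_labels)]
  expected <- pz$latent_motor_delay +
    task$base_answer_time * (1 + task$difficulty_rt_slope * b) *
      exp(-paramsz$trial$eta * pz$latent_ability)
  expect_equal(trz$rt[!trz$timed_out], expected[!trz$timed_out],
               tolerance = 1e-12)

  # timeout contract: rt clamped to the window and accuracy zeroed
  expect_true(all(trz$rt <= task$response_window))
  tall <- generate_trials(generate_participants(0, 100, seed = 8),
                          reg$simple_reaction_time, seed = 8)
  to <- tall[tall$timed_out, ]
  if (nrow(to) > 0) {
    expect_true(all(to$accuracy == 0L))
    expect_true(all(to$rt == reg$simple_reaction_time$response_window))
  }
})

test_that("the motor confound is present by construction in high-motor tasks", {
  coh <- generate_cohort(0, 400, seed = 11,
                         registry = default_task_registry()[
                           c("motor_control", "trail_making")])
  p <- coh$participants
  tr <- coh$trials
  imp <- p$impaired_hand[match(tr$participant_id, p$participant_id)]
  expect_lt(mean(tr$accuracy[imp]), mean(tr$accuracy[!imp]))
  expect_gt(median(tr$rt[imp]), median(tr$rt[!imp]))
})

test_that("cohort files round-trip losslessly and ground truth is quarantined", {
  coh <- generate_cohort(15, 10, seed = 4,
                         registry = default_task_registry()[1:3])
  dir <- withr::local_tempdir()
  write_cohort(coh$participants, coh$trials, dir)

  pub <- read_cohort(dir)
  expect_false(any(grepl("^latent_", names(pub$participants))))
  expect_null(pub$truth)

  full <- read_cohort(dir, with_truth = TRUE)
  lat <- grep("^latent_", names(coh$participants), value = TRUE)
  for (col in setdiff(names(coh$participants), lat)) {
    expect_identical(full$participants[[col]], coh$participants[[col]],
                     info = col)
  }
  for (col in lat) {
    expect_identical(full$truth[[col]], coh$participants[[col]], info = col)
  }
  for (col in names(coh$trials)) {
    expect_identical(full$trials[[col]], coh$trials[[col]], info = col)
  }
})

test_that("the default registry matches the battery contract", {
  reg <- default_task_registry()
  expect_length(reg, 18)
  expect_setequal(vapply(reg, `[[`, character(1), "task_id"), names(reg))
  for (sp in reg) {
    expect_true(all(diff(sp$condition_difficulties) > 0))
    expect_true(sp$slip_rate_impaired == 0 || sp$motor_demand == "high")
  }
  # exactly one task is designed to measure hand-motor ability itself
  pure <- names(Filter(function(s) s$impaired_ability_penalty > 0, reg))
  expect_identical(pure, "motor_control")
  expect_error(task_spec("bad", "x", "low", "low", numeric(0)),
               "at least one condition")
  expect_error(task_spec("bad", "x", "low", "low", c(1, 1)),
               "strictly increasing")
})
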