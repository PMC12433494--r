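test_that("clean_trials enforces bounds, preserves order and reports fractions", {
  tr <- session_trials("p1", "t", rep("A", 10),
                       rt = c(50, 400, 500, 50, 600, 700, 50, 800, 900, 1000),
                       accuracy = rep(1, 10))
  out <- clean_trials(tr, rt_min = 200)
  expect_equal(nrow(out$kept), 7)
  expect_equal(out$report$fraction, 0.3)
  expect_identical(out$kept$rt, tr$rt[tr$rt >= 200])

  # all in bounds -> identity
  ok <- clean_trials(tr[tr$rt >= 200, ], rt_min = 200)
  expect_identical(ok$kept, tr[tr$rt >= 200, ])
  expect_equal(ok$report$fraction, 0)

  # timeouts are never removed even when the clamped rt exceeds rt_max
  to <- tr
  to$timed_out <- TRUE
  expect_equal(nrow(clean_trials(to, rt_min = 200, rt_max = 900)$kept), 10)

  empty <- clean_trials(tr[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$report), 0)
  expect_error(clean_trials(tr, rt_min = 500, rt_max = 400), "below")
})

test_that("raw difficulty hits its boundary cases", {
  # condition A always correct at maximal speed score, B always wrong
  tr <- rbind(
    session_trials("p1", "t", rep(c("A", "B"), each = 5),
                   rt = rep(c(100, 1000), each = 5),
                   accuracy = rep(c(1, 0), each = 5)),
    session_trials("p2", "t", rep(c("A", "B"), each = 5),
                   rt = rep(c(100, 1000), each = 5),
                   accuracy = rep(c(1, 0), each = 5))
  )
  tab <- idoct_calibrate(tr, min_obs = 5)
  expect_equal(tab$conditions$d_raw,  c(0, 1), tolerance = 1e-12)
  expect_true(all(tab$conditions$d_scaled >= 0 & tab$conditions$d_scaled <= 1))
  expect_lt(tab$calibration$rt_floor, tab$calibration$rt_ceiling)
})

test_that("ability correction raises difficulty of selectively-attempted conditions", {
  # A attempted by everyone (pooled pass rate 1/2), B only by the two
  # above-average participants (pass rate also 1/2): B must scale harder
  rt4 <- c(400, 500, 600, 700)
  tr <- rbind(
    session_trials("w1", "t", rep("A", 4), rt4, c(1, 0, 0, 0)),
    session_trials("w2", "t", rep("A", 4), rt4, c(1, 0, 0, 0)),
    session_trials("s1", "t", c(rep("A", 4), rep("B", 4)), c(rt4, rt4),
                   c(1, 1, 1, 0, 1, 1, 0, 0)),
    session_trials("s2", "t", c(rep("A", 4), rep("B", 4)), c(rt4, rt4),
                   c(1, 1, 1, 0, 1, 1, 0, 0))
  )
  tab <- idoct_calibrate(tr, min_obs = 4)
  expect_equal(mean(tr$accuracy[tr$condition_label == "A"]), 0.5)
  expect_equal(mean(tr$accuracy[tr$condition_label == "B"]), 0.5)
  expect_gt(tab$conditions$d_scaled[tab$conditions$condition_label == "B"],
            tab$conditions$d_scaled[tab$conditions$condition_label == "A"])
})

test_that("calibration validates its inputs", {
  tr <- toy_trials()
  expect_error(idoct_calibrate(tr[tr$participant_id == "p1", ]),
               "at least 2 participants")
  expect_error(idoct_calibrate(tr, min_obs = 10), "fewer than 10")
  two <- tr
  two$task_id[1] <- "other"
  expect_error(idoct_calibrate(two), "exactly one task")
})

test_that("decomposition recovers a noise-free delay exactly and reconstructs rt", {
  at <- c(600, 800, 1000, 1200)
  tab <- manual_table("t", c("c1", "c2", "c3", "c4"), at,
                      d_scaled = c(0.2, 0.4, 0.6, 0.8))
  labs <- rep(c("c1", "c2", "c3", "c4"), each = 3)
  rt <- 350 + at[match(labs, c("c1", "c2", "c3", "c4"))]
  tr <- session_trials("p1", "t", labs, rt, accuracy = rep(1, 12))
  dec <- idoct_decompose(tr, tab)
  expect_equal(dec$delay_time, 350, tolerance = 1e-10)
  expect_equal(tr$rt - dec$answer_times, rep(dec$delay_time, 12),
               tolerance = 1e-6)
  expect_false(dec$low_confidence)

  # delay can never be negative, even for unrealistically fast sessions
  fast <- session_trials("p2", "t", labs, rt - 1000, accuracy = rep(1, 12))
  expect_gte(idoct_decompose(fast, tab)$delay_time, 0)
})

test_that("the Cognitive Index behaves as a cognition score, not a speed artefact", {
  at <- c(600, 800, 1000, 1200)
  labs <- rep(c("c1", "c2", "c3", "c4"), each = 3)
  tab <- manual_table("t", c("c1", "c2", "c3", "c4"), at,
                      d_scaled = c(0.2, 0.4, 0.6, 0.8))
  atv <- at[match(labs, c("c1", "c2", "c3", "c4"))]

  # all-incorrect session scores zero regardless of reaction times
  wrong <- session_trials("p1", "t", labs, 300 + atv, accuracy = rep(0, 12))
  expect_equal(idoct_decompose(wrong, tab)$cognitive_index, 0)

  # identical accuracy, uniformly (multiplicatively) slower answer times ->
  # strictly lower index; an additive delay shift -> same index
  acc <- rep(c(1, 1, 0), 4)
  fastr <- session_trials("pf", "t", labs, 300 + atv, acc)
  slowr <- session_trials("ps", "t", labs, 300 + 1.4 * atv, acc)
  shifted <- session_trials("pd", "t", labs, 700 + atv, acc)
  as_fast <- idoct_decompose(fastr, tab)$cognitive_index
  as_slow <- idoct_decompose(slowr, tab)$cognitive_index
  as_shift <- idoct_decompose(shifted, tab)$cognitive_index
  expect_lt(as_slow, as_fast)
  expect_equal(as_shift, as_fast, tolerance = 1e-8)

  # single-trial sessions are decomposed but flagged
  one <- session_trials("p1", "t", "c1", 900, 1)
  expect_true(idoct_decompose(one, tab)$low_confidence)

  # unknown condition labels are a hard error naming the label
  bad <- session_trials("p1", "t", c("c1", "zz"), c(900, 950), c(1, 1))
  expect_error(idoct_decompose(bad, tab), "zz")
})

test_that("batch decomposition agrees with single-session decomposition", {
  coh <- generate_cohort(40, 20, seed = 6,
                         registry = default_task_registry()["trail_making"])
  est <- suppressWarnings(
    run_idoct(coh$trials, coh$participants, default_config()))
  d <- est$decomposition
  expect_true(all(d$converged))
  pick <- d[c(3, 17, 29), ]
  for (i in seq_len(nrow(pick))) {
    tr1 <- coh$trials[coh$trials$participant_id == pick$participant_id[i] &
                        coh$trials$session_index == pick$session_index[i], ]
    tr1 <- clean_trials(tr1)$kept
    one <- idoct_decompose(tr1, est$tables$trail_making)
    expect_equal(one$cognitive_index, pick$cognitive_index[i],
                 tolerance = 1e-12)
    expect_equal(one$delay_time, pick$delay_time[i], tolerance = 1e-12)
  }
  # the whole path is seed-free: repeated runs are identical
  est2 <- suppressWarnings(
    run_idoct(coh$trials, coh$participants, default_config()))
  expect_identical(est$decomposition, est2$decomposition)
  expect_identical(est$tables$trail_making$conditions,
                   est2$tables$trail_making$conditions)
})

test_that("standard metrics count, median and degrade gracefully", {
  tr <- session_trials("p1", "t", rep("A", 5),
                       rt = c(400, 500, 600, 700, 800),
                       accuracy = c(1, 1, 1, 0, 0))
  sm <- standard_metrics(tr)
  expect_equal(sm$accuracy_count, 3L)
  expect_equal(sm$trial_count, 5L)
  expect_equal(sm$median_rt, 600)
  expect_equal(nrow(standard_metrics(tr[0, ])), 0)
})

test_that("impaired responders are slower on high-motor tasks by standard metrics", {
  coh <- generate_cohort(0, 400, seed = 400,
                         registry = default_task_registry()["trail_making"])
  sm <- standard_metrics(coh$trials)
  p <- coh$participants
  imp <- p$impaired_hand[match(sm$participant_id, p$participant_id)]
  per_part <- tapply(sm$median_rt, sm$participant_id, mean)
  imp_part <- p$impaired_hand[match(names(per_part), p$participant_id)]
  tt <- t.test(per_part[imp_part], per_part[!imp_part], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})
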