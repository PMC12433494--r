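# Shared fixtures: tiny hand-checkable trial tables and reduced cohorts used
# across test files. Everything is built in code at test time.

# Toy 3-participant x 2-condition table. Participant p3 attempts only
# condition A, so the ability correction of the scaled difficulty is
# exercised, not just the raw pass rates.
toy_trials <- function() {
  data.frame(
    participant_id = rep(c("p1", "p1", "p2", "p2", "p3"), each = 2),
    task_id = "toy",
    session_index = 1L,
    trial_index = rep(1:2, 5),
    condition_label = c("A", "A", "B", "B", "A", "A", "B", "B", "A", "A"),
    accuracy = c(1L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 1L),
    rt = c(800, 900, 1400, 1500, 1000, 1100, 1600, 1700, 1200, 1300),
    timed_out = FALSE,
    stringsAsFactors = FALSE
  )
}

# Hand-build a difficulty table without running calibration, for decompose
# tests that need a known answer-time curve.
manual_table <- function(task_id, labels, at, d_scaled,
                         rt_floor = 500, rt_ceiling = 2500,
                         dt_reference_mean = 300, w = 0.5) {
  structure(list(
    task_id = task_id,
    conditions = data.frame(condition_label = labels,
                            d_raw = d_scaled, d_scaled = d_scaled,
                            n_obs = 100L, at = at, stringsAsFactors = FALSE),
    calibration = list(rt_floor = rt_floor, rt_ceiling = rt_ceiling,
                       dt_reference_mean = dt_reference_mean, w = w),
    converged = TRUE,
    n_iterations = c(difficulty = 1L, answer_time = 1L)
  ), class = "difficulty_table")
}

session_trials <- function(pid, task_id, labels, rt, accuracy,
                           session = 1L) {
  data.frame(participant_id = pid, task_id = task_id,
             session_index = session,
             trial_index = seq_along(rt), condition_label = labels,
             accuracy = as.integer(accuracy), rt = rt, timed_out = FALSE,
             stringsAsFactors = FALSE)
}

# Reduced 4-task registry (one per motor/cognitive quadrant) with fewer
# trials, for replicate simulations that must stay fast.
small_registry <- function(n_trials = 24L) {
  reg <- default_task_registry()
  reg <- reg[c("motor_control", "trail_making", "semantic_judgement",
               "simple_reaction_time")]
  lapply(reg, function(sp) {
    sp$n_trials <- as.integer(n_trials)
    sp
  })
}

# Covariate table with genuine longitudinal random-effect structure and a
# null outcome generator, for mixed-model calibration tests.
simulate_patient_table <- function(n_subj, n_sessions = 3) {
  n <- n_subj * n_sessions
  subj <- rep(sprintf("s%03d", seq_len(n_subj)), each = n_sessions)
  data.frame(
    participant_id = subj,
    session_index = rep(seq_len(n_sessions), n_subj),
    subject = factor(subj),
    age_z = rep(stats::rnorm(n_subj), each = n_sessions),
    age2_z = rep(stats::rnorm(n_subj), each = n_sessions),
    sex = factor(rep(sample(c("female", "male"), n_subj, TRUE),
                     each = n_sessions), levels = c("female", "male")),
    education = factor(rep(sample(1:4, n_subj, TRUE), each = n_sessions),
                       levels = 1:4),
    esl = rep(stats::rbinom(n_subj, 1, 0.3), each = n_sessions),
    log_nihss = rep(log1p(stats::rpois(n_subj, 4)), each = n_sessions),
    time_z = as.numeric(scale(rep(c(4, 94, 371)[seq_len(n_sessions)],
                                  n_subj) + stats::rnorm(n, 0, 10))),
    impaired = rep(stats::rbinom(n_subj, 1, 0.3), each = n_sessions),
    stringsAsFactors = FALSE
  )
}

# Outcome with subject random intercept + time slope and no covariate effects
null_outcome <- function(tab, intercept_sd = 0.5, slope_sd = 0.2,
                         resid_sd = 1) {
  n_subj <- nlevels(tab$subject)
  b0 <- stats::rnorm(n_subj, 0, intercept_sd)[as.integer(tab$subject)]
  b1 <- stats::rnorm(n_subj, 0, slope_sd)[as.integer(tab$subject)]
  b0 + b1 * tab$time_z + stats::rnorm(nrow(tab), 0, resid_sd)
}

# Brute-force Benjamini-Hochberg q-values straight from the step-up
# definition: q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j.
bh_bruteforce <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  qs <- vapply(seq_len(m), function(i) min(m * ps[i:m] / (i:m)), numeric(1))
  qs <- pmin(qs, 1)
  q <- numeric(m)
  q[ord] <- qs
  q
}
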