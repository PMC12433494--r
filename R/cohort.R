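#' Default generator configuration
#'
#' Returns the full parameter set of the synthetic cohort simulator. Cohort
#' demographics (age, sex, education, English-as-second-language, stroke
#' severity, impaired-hand prevalence, recovery-phase timing and follow-up
#' rates) are anchored to the published characteristics of a large normative
#' cohort (N = 6364) and a longitudinal stroke cohort (N = 171). The latent
#' behavioural parameters (ability effects, response-delay distribution,
#' mis-tap rates, reaction-time noise) are simulation conventions, chosen once
#' and documented in the methods vignette.
#'
#' @return Nested named list of generator parameters.
#' @export
default_generator_params <- function() {
  list(
    normative = list(
      age_mean = 60.8, age_sd = 10.1, age_range = c(40, 95),
      p_male = 0.427,
      edu_probs = c(0.155, 0.372, 0.288, 0.185),
      p_esl = 0.036
    ),
    patient = list(
      age_mean = 63.01, age_sd = 14.1, age_range = c(24, 97),
      p_male = 0.696,
      edu_probs = c(0.082, 0.503, 0.228, 0.187),
      p_esl = 0.345,
      nihss_mean = 4.93, nihss_sd = 4.66, nihss_range = c(0, 26),
      impairment_rate = 47 / 171
    ),
    ability = list(
      beta_age = -0.30,          # per SD of age (anchored at 60.8 / 10.1)
      beta_edu = 0.18,           # per ordinal education level, centred at 2.5
      beta_nihss = -0.25,        # per unit log(1 + NIHSS)
      patient_deficit = 0.6,     # mean stroke-related ability loss (SD units)
      resid_sd = 0.8,
      recovery_slope_mean = 0.085,  # ability gain per unit log(1 + days)
      recovery_slope_sd = 0.04,
      task_session_sd = 0.55,    # task-specific ability variance (battery tasks intercorrelate ~0.6)
      caution_sd = 1          # speed-accuracy trade-off trait (standardized)
    ),
    motor = list(
      delay_meanlog = log(300),  # median response delay, ms
      delay_sdlog = 0.55,
      patient_delay_mult = 1.15, # stroke cohort is slower at the median
      impaired_delta = 150,      # extra delay (ms) when the impaired hand responds
      motor_boost = 0.75         # multiplier bonus of the delta in high-motor tasks
    ),
    trial = list(
      alpha = 1.3,               # item-response discrimination
      eta = 0.10,                # relative answer-time reduction per SD ability
      caution_acc = 1.0,         # accuracy logit gain per SD of response caution
      caution_rt = 0.10,         # relative answer-time cost per SD of caution
      rt_noise_sdlog = 0.2
    ),
    sessions = list(
      presence = c(acute = 0.77, subacute = 0.42, chronic = 0.77),
      acute_meanlog = log(4.5), acute_sdlog = 0.5, acute_range = c(1, 14),
      subacute_mean = 94, subacute_sd = 10, subacute_range = c(15, 180),
      chronic_mean = 371, chronic_sd = 80, chronic_range = c(181, 730),
      task_completion_rate = 0.96
    ),
    criterion = list(
      moca_intercept = 21, moca_slope = 3.5, moca_sd = 1.5,
      iadl_intercept = 5.5, iadl_slope = 1.1, iadl_sd = 1.1,
      lesion_log_intercept = 3.0, lesion_log_slope = -0.55, lesion_log_sd = 0.7,
      wmh_log_intercept = 2.1, wmh_log_slope = -0.5, wmh_log_sd = 0.7,
      imaging_rate = 0.7,
      kappa_wmh = 0.35           # chronic-phase WMH loading on sensitive domains
    )
  )
}

#' Null-motor generator configuration
#'
#' Copy of a parameter set with every impaired-hand effect removed (zero extra
#' response delay). Pair with [strip_motor_effects()] on the task registry to
#' simulate the global null in which hand impairment has no behavioural
#' consequence at all.
#'
#' @param params generator parameters, see [default_generator_params()].
#' @return Modified parameter list.
#' @export
null_motor_params <- function(params = default_generator_params()) {
  params$motor$impaired_delta <- 0
  params$motor$motor_boost <- 0
  params
}

#' Map days since stroke to recovery phase
#'
#' Deterministic banding: acute for 0-14 days, subacute for 15-180 days,
#' chronic beyond 180 days. The bands bracket the cohort's median assessment
#' days of 4 (acute), 94 (subacute) and 371 (chronic).
#'
#' @param days numeric vector of days since stroke (NA allowed).
#' @return Character vector in `{"acute","subacute","chronic"}` (NA for NA).
#' @export
phase_from_days <- function(days) {
  out <- rep(NA_character_, length(days))
  out[!is.na(days) & days <= 14] <- "acute"
  out[!is.na(days) & days > 14 & days <= 180] <- "subacute"
  out[!is.na(days) & days > 180] <- "chronic"
  out
}

# Reference assessment day of each phase (cohort medians), used when one
# session per participant per phase must be selected.
phase_reference_days <- c(acute = 4, subacute = 94, chronic = 371)

check_probability <- function(p, what) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("invalid probability for %s", what)
  }
}

#' Generate participant metadata for normative and patient cohorts
#'
#' Draws demographics, clinical covariates, latent cognitive ability and
#' latent motor response delay for a normative (single-session) and a
#' longitudinal patient cohort. Latent ability combines additive demographic
#' effects (age negative, education positive, stroke severity negative), a
#' stroke-related deficit, and a subject-specific recovery slope on
#' log(1 + days since stroke). MoCA and IADL criterion scores are noisy
#' increasing functions of session-level ability; lesion and white-matter
#' hyperintensity volumes are noisy decreasing functions of baseline ability.
#' Impaired-hand status is assigned independently of latent ability: the
#' impairment harms performance only through response delay, mis-taps and
#' timeouts downstream, which is exactly the confound the decomposition is
#' meant to remove.
#'
#' @param n_normative,n_patient cohort sizes (>= 0).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param params generator configuration, see [default_generator_params()].
#' @return data.frame with one row per participant-session. Ground-truth
#'   columns are prefixed `latent_` and are stripped into a separate file by
#'   [write_cohort()]; estimation functions never read them.
#' @export
generate_participants <- function(n_normative, n_patient, seed = 1,
                                  params = default_generator_params()) {
  if (n_normative < 0 || n_patient < 0) {
    stopf("cohort sizes must be nonnegative")
  }
  check_probability(params$patient$impairment_rate, "impairment_rate")
  check_probability(params$sessions$presence, "session presence")
  check_probability(params$normative$p_male, "p_male")
  check_probability(params$patient$p_esl, "p_esl")

  with_seed(seed, {
    rows <- list()
    if (n_normative > 0) {
      rows[[length(rows) + 1L]] <- draw_cohort("normative", n_normative, params)
    }
    if (n_patient > 0) {
      rows[[length(rows) + 1L]] <- draw_cohort("patient", n_patient, params)
    }
    if (length(rows) == 0) {
      return(empty_participants())
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

empty_participants <- function() {
  data.frame(participant_id = character(), cohort = character(),
             session_index = integer(), age = numeric(), sex = character(),
             education = integer(), english_second_language = logical(),
             nihss_baseline = numeric(), impaired_hand = logical(),
             days_since_stroke = numeric(), phase = character(),
             moca = numeric(), iadl = numeric(), lesion_volume = numeric(),
             wmh_volume = numeric(), latent_ability = numeric(),
             latent_motor_delay = numeric(), latent_wmh_load = numeric(),
             latent_caution = numeric(), stringsAsFactors = FALSE)
}

draw_cohort <- function(cohort, n, params) {
  cp <- if (cohort == "normative") params$normative else params$patient
  ab <- params$ability
  mo <- params$motor
  cr <- params$criterion

  id <- sprintf("%s%04d", if (cohort == "normative") "norm" else "pat",
                seq_len(n))
  age <- rnorm_trunc(n, cp$age_mean, cp$age_sd, cp$age_range[1], cp$age_range[2])
  sex <- ifelse(stats::runif(n) < cp$p_male, "male", "female")
  education <- sample(1:4, n, replace = TRUE, prob = cp$edu_probs)
  esl <- stats::runif(n) < cp$p_esl

  if (cohort == "patient") {
    # gamma with the published mean and SD: nonnegative and right-skewed,
    # as stroke-severity scores are (a 0-truncated normal would inflate the
    # configured mean by ~25%)
    shape <- (cp$nihss_mean / cp$nihss_sd)^2
    nihss <- clip(round(stats::rgamma(n, shape = shape,
                                      scale = cp$nihss_sd^2 / cp$nihss_mean)),
                  cp$nihss_range[1], cp$nihss_range[2])
    impaired <- stats::runif(n) < cp$impairment_rate
  } else {
    nihss <- rep(NA_real_, n)
    impaired <- rep(FALSE, n)
  }

  theta_base <- ab$beta_age * (age - 60.8) / 10.1 +
    ab$beta_edu * (education - 2.5) +
    stats::rnorm(n, 0, ab$resid_sd)
  if (cohort == "patient") {
    theta_base <- theta_base + ab$beta_nihss * log1p(nihss) - ab$patient_deficit
  }

  delay_meanlog <- mo$delay_meanlog +
    if (cohort == "patient") log(mo$patient_delay_mult) else 0
  motor_delay <- exp(stats::rnorm(n, delay_meanlog, mo$delay_sdlog))

  # imaging burden: decreasing in baseline ability, with an independent noise
  # component whose standardized value is carried as latent_wmh_load (it
  # drives the chronic-phase domain-specific association structure)
  wmh_noise <- stats::rnorm(n, 0, cr$wmh_log_sd)
  wmh <- exp(cr$wmh_log_intercept + cr$wmh_log_slope * theta_base + wmh_noise)
  lesion <- exp(cr$lesion_log_intercept + cr$lesion_log_slope * theta_base +
                  stats::rnorm(n, 0, cr$lesion_log_sd))
  wmh_load <- if (cr$wmh_log_sd > 0) wmh_noise / cr$wmh_log_sd else wmh_noise
  has_imaging <- stats::runif(n) < cr$imaging_rate
  caution <- stats::rnorm(n, 0, ab$caution_sd)

  if (cohort == "normative") {
    return(data.frame(
      participant_id = id, cohort = cohort, session_index = 1L,
      age = age, sex = sex, education = as.integer(education),
      english_second_language = esl, nihss_baseline = NA_real_,
      impaired_hand = FALSE, days_since_stroke = NA_real_,
      phase = NA_character_, moca = NA_real_, iadl = NA_real_,
      lesion_volume = NA_real_, wmh_volume = NA_real_,
      latent_ability = theta_base, latent_motor_delay = motor_delay,
      latent_wmh_load = wmh_load, latent_caution = caution,
      stringsAsFactors = FALSE))
  }

  slope <- stats::rnorm(n, ab$recovery_slope_mean, ab$recovery_slope_sd)
  se <- params$sessions
  out <- vector("list", n)
  for (i in seq_len(n)) {
    present <- stats::runif(3) < se$presence
    if (!any(present)) present[1] <- TRUE  # everyone has a baseline visit
    days <- c(
      round(clip(exp(stats::rnorm(1, se$acute_meanlog, se$acute_sdlog)),
                 se$acute_range[1], se$acute_range[2])),
      round(clip(stats::rnorm(1, se$subacute_mean, se$subacute_sd),
                 se$subacute_range[1], se$subacute_range[2])),
      round(clip(stats::rnorm(1, se$chronic_mean, se$chronic_sd),
                 se$chronic_range[1], se$chronic_range[2]))
    )[present]
    theta_s <- theta_base[i] + slope[i] * log1p(days)
    moca <- criterion_score(theta_s, cr$moca_intercept, cr$moca_slope,
                            cr$moca_sd, c(0, 30))
    iadl <- criterion_score(theta_s, cr$iadl_intercept, cr$iadl_slope,
                            cr$iadl_sd, c(0, 8))
    k <- length(days)
    out[[i]] <- data.frame(
      participant_id = id[i], cohort = cohort, session_index = seq_len(k),
      age = age[i], sex = sex[i], education = as.integer(education[i]),
      english_second_language = esl[i], nihss_baseline = nihss[i],
      impaired_hand = impaired[i], days_since_stroke = days,
      phase = phase_from_days(days), moca = moca, iadl = iadl,
      lesion_volume = if (has_imaging[i]) lesion[i] else NA_real_,
      wmh_volume = if (has_imaging[i]) wmh[i] else NA_real_,
      latent_ability = theta_s, latent_motor_delay = motor_delay[i],
      latent_wmh_load = wmh_load[i], latent_caution = caution[i],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Noisy monotone criterion mapping. With noise sd 0 the unrounded linear
# mapping is returned (rounding and clipping are treated as part of the
# measurement noise), so the noiseless diagnostic correlation is exactly 1.
criterion_score <- function(theta, intercept, slope, sd, range) {
  raw <- intercept + slope * theta + stats::rnorm(length(theta), 0, sd)
  if (sd == 0) return(raw)
  clip(round(raw), range[1], range[2])
}

#' Generate trial-level records for one task
#'
#' Simulates every trial of `task` for each participant-session. Accuracy
#' follows a one-parameter item-response model, Bernoulli with success
#' probability `plogis(alpha * (ability - b_c))` for condition difficulty
#' `b_c`; correct responses are then spoiled with the task's mis-tap
#' probability when an impaired hand is used in a high motor-demand task.
#' Reaction time is the sum of the participant's motor response delay and a
#' lognormal-noise cognitive answer time
#' `base_answer_time * (1 + slope * b_c) * exp(-eta * ability + caution_rt * caution)`.
#' The caution trait models the speed-accuracy trade-off: it also adds
#' `caution_acc * caution` to the accuracy logit, so cautious responders are
#' more accurate but slower for reasons unrelated to ability. Using an
#' impaired hand adds `impaired_delta * (1 + motor_boost)` ms of delay in high
#' motor-demand tasks and `impaired_delta` elsewhere. Responses slower than
#' the task's response window time out: accuracy 0 and reaction time clamped
#' to the window.
#'
#' @param participants participant-session table from
#'   [generate_participants()] (latent columns required).
#' @param task a [task_spec()].
#' @param seed integer seed.
#' @param params generator configuration.
#' @return data.frame of trial records: `participant_id`, `task_id`,
#'   `session_index`, `trial_index`, `condition_label`, `accuracy`, `rt`,
#'   `timed_out`.
#' @export
generate_trials <- function(participants, task, seed = 1,
                            params = default_generator_params()) {
  if (!inherits(task, "task_spec")) stopf("task must be a task_spec")
  if (task$n_conditions == 0) stopf("task has no conditions")
  needed <- c("latent_ability", "latent_motor_delay", "latent_wmh_load")
  if (!all(needed %in% names(participants))) {
    stopf("participants table lacks latent ground-truth fields; pass the generator output, not the estimation-facing table")
  }
  if (nrow(participants) == 0) return(empty_trials())

  tr <- params$trial
  mo <- params$motor
  cr <- params$criterion
  ab <- params$ability

  with_seed(seed, {
    ns <- nrow(participants)
    keep <- stats::runif(ns) < params$sessions$task_completion_rate
    pp <- participants[keep, , drop = FALSE]
    if (nrow(pp) == 0) return(empty_trials())
    ns <- nrow(pp)

    wmh_hit <- !is.na(pp$phase) & pp$phase == "chronic" &
      task$domain %in% wmh_sensitive_domains
    theta <- pp$latent_ability +
      stats::rnorm(ns, 0, ab$task_session_sd) -
      cr$kappa_wmh * pp$latent_wmh_load * wmh_hit -
      task$impaired_ability_penalty * pp$impaired_hand

    caution <- pp$latent_caution
    boost <- if (task$motor_demand == "high") 1 + mo$motor_boost else 1
    delay <- pp$latent_motor_delay +
      mo$impaired_delta * boost * pp$impaired_hand

    nt <- task$n_trials
    # graded progression: conditions administered in increasing difficulty
    cond_idx <- sort(rep_len(seq_len(task$n_conditions), nt))
    b <- task$condition_difficulties[cond_idx]

    n_all <- ns * nt
    theta_t <- rep(theta, each = nt)
    delay_t <- rep(delay, each = nt)
    b_t <- rep(b, times = ns)

    caution_t <- rep(caution, each = nt)
    acc <- stats::rbinom(n_all, 1, stats::plogis(tr$alpha * (theta_t - b_t) +
                                                   tr$caution_acc * caution_t))
    slip_ok <- task$motor_demand == "high" && task$slip_rate_impaired > 0
    if (slip_ok) {
      slips <- stats::runif(n_all) < task$slip_rate_impaired
      acc[slips & rep(pp$impaired_hand, each = nt)] <- 0L
    }

    at <- task$base_answer_time * (1 + task$difficulty_rt_slope * b_t) *
      exp(-tr$eta * theta_t + tr$caution_rt * caution_t) *
      exp(stats::rnorm(n_all, 0, tr$rt_noise_sdlog))
    rt <- delay_t + at
    timed_out <- rt > task$response_window
    acc[timed_out] <- 0L
    rt[timed_out] <- task$response_window

    data.frame(
      participant_id = rep(pp$participant_id, each = nt),
      task_id = task$task_id,
      session_index = rep(pp$session_index, each = nt),
      trial_index = rep(seq_len(nt), times = ns),
      condition_label = rep(task$condition_labels[cond_idx], times = ns),
      accuracy = as.integer(acc),
      rt = rt,
      timed_out = timed_out,
      stringsAsFactors = FALSE
    )
  })
}

empty_trials <- function() {
  data.frame(participant_id = character(), task_id = character(),
             session_index = integer(), trial_index = integer(),
             condition_label = character(), accuracy = integer(),
             rt = numeric(), timed_out = logical(), stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort across a task battery
#'
#' Convenience wrapper: draws participants once, then trials for every task in
#' the registry (each task on its own derived seed stream).
#'
#' @inheritParams generate_participants
#' @param registry list of [task_spec()]s, see [default_task_registry()].
#' @return list with elements `participants` (incl. latent columns) and
#'   `trials` (single long table across tasks).
#' @export
generate_cohort <- function(n_normative, n_patient, seed = 1,
                            registry = default_task_registry(),
                            params = default_generator_params()) {
  participants <- generate_participants(n_normative, n_patient, seed, params)
  trials <- vector("list", length(registry))
  for (i in seq_along(registry)) {
    trials[[i]] <- generate_trials(participants, registry[[i]],
                                   seed = seed + 101L * i, params = params)
  }
  list(participants = participants, trials = do.call(rbind, trials))
}

latent_columns <- c("latent_ability", "latent_motor_delay",
                    "latent_wmh_load", "latent_caution")

#' Write a cohort to disk
#'
#' Emits `participants.csv`, `trials.csv` and `truth.csv` (UTF-8, header row,
#' missing values as empty fields) into `out_dir`. Ground-truth latent fields
#' live only in `truth.csv`, which estimation stages never consume. Numeric
#' fields are written at full precision so tables round-trip losslessly
#' through [read_cohort()].
#'
#' @param participants participant-session table (latent columns allowed).
#' @param trials trial table.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(participants, trials, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lat <- intersect(latent_columns, names(participants))
  pub <- participants[, setdiff(names(participants), lat), drop = FALSE]
  truth <- participants[, c("participant_id", "session_index", lat),
                        drop = FALSE]
  paths <- file.path(out_dir, c("participants.csv", "trials.csv", "truth.csv"))
  write_csv_exact(pub, paths[1])
  write_csv_exact(trials, paths[2])
  write_csv_exact(truth, paths[3])
  invisible(paths)
}

#' Read a cohort from disk
#'
#' @param dir directory holding `participants.csv` and `trials.csv` (and
#'   optionally `truth.csv`, read only if `with_truth = TRUE`).
#' @param with_truth also read the ground-truth file; default FALSE so the
#'   estimation path never touches latent fields.
#' @return list with `participants`, `trials` and (optionally) `truth`.
#' @export
read_cohort <- function(dir, with_truth = FALSE) {
  read1 <- function(f) {
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                    na.strings = "")
  }
  out <- list(participants = read1("participants.csv"),
              trials = read1("trials.csv"))
  out$participants$impaired_hand <- as.logical(out$participants$impaired_hand)
  out$participants$english_second_language <-
    as.logical(out$participants$english_second_language)
  # columns that are double in the schema but may read back as integer
  for (col in c("age", "nihss_baseline", "days_since_stroke", "moca",
                "iadl", "lesion_volume", "wmh_volume")) {
    if (col %in% names(out$participants)) {
      out$participants[[col]] <- as.numeric(out$participants[[col]])
    }
  }
  out$trials$timed_out <- as.logical(out$trials$timed_out)
  out$trials$rt <- as.numeric(out$trials$rt)
  if (with_truth) {
    out$truth <- read1("truth.csv")
    for (col in grep("^latent_", names(out$truth), value = TRUE)) {
      out$truth[[col]] <- as.numeric(out$truth[[col]])
    }
  }
  out
}
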