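# Iterative decomposition of trial-level accuracy / reaction-time data into
# condition difficulty, answer time, response delay time and a Cognitive
# Index. Difficulty and the condition-level answer-time curve are calibrated
# on a normative cohort and frozen; sessions (patient or normative) are then
# decomposed against the frozen calibration, which pins down the additive
# split between answer time and delay.

#' Remove physiologically implausible trials
#'
#' Drops non-timeout trials with reaction times outside `[rt_min, rt_max]`.
#' Timed-out trials are kept: their clamped reaction time equals the response
#' window by construction and they carry real (incorrect) responses. Original
#' order is preserved among kept trials.
#'
#' @param records trial table (see [generate_trials()] for the schema).
#' @param rt_min lower bound in ms; 200 ms is the conventional physiological
#'   floor for a deliberate response.
#' @param rt_max upper bound in ms; defaults to `Inf` so that per-task
#'   response windows (already enforced at capture) are the effective ceiling.
#' @param meta optional participant table used to split the exclusion report
#'   by cohort.
#' @return list with `kept` (filtered trials) and `report` (per task, and per
#'   task-by-cohort when `meta` is given: trials seen, removed, fraction).
#' @export
clean_trials <- function(records, rt_min = 200, rt_max = Inf, meta = NULL) {
  if (rt_min >= rt_max) stopf("rt_min must be below rt_max")
  if (nrow(records) == 0) {
    return(list(kept = records,
                report = data.frame(task_id = character(), n_total = integer(),
                                    n_removed = integer(), fraction = numeric(),
                                    stringsAsFactors = FALSE)))
  }
  bad <- !records$timed_out & (records$rt < rt_min | records$rt > rt_max)
  grp <- records$task_id
  if (!is.null(meta)) {
    cohort <- meta$cohort[match(records$participant_id, meta$participant_id)]
    grp <- paste(records$task_id, cohort, sep = ":")
  }
  tot <- table(grp)
  rem <- table(factor(grp[bad], levels = names(tot)))
  report <- data.frame(task_id = names(tot),
                       n_total = as.integer(tot),
                       n_removed = as.integer(rem),
                       fraction = as.numeric(rem) / as.numeric(tot),
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(kept = records[!bad, , drop = FALSE], report = report)
}

# speed score: linear position of rt between the calibrated ceiling (s = 0)
# and floor (s = 1), clipped to [0, 1]
speed_score <- function(rt, rt_floor, rt_ceiling) {
  clip01((rt_ceiling - rt) / (rt_ceiling - rt_floor))
}

# Per-group response delay: intercept of the within-group regression of rt
# on at (the frozen condition answer-time curve), floored at zero. The
# difficulty gradient identifies the split: cognitive slowing scales the
# condition curve (slope), while motor/device delay shifts it additively
# (intercept). The slope is ridge-shrunk towards 1 with prior weight
# n * tau^2, so tasks whose answer-time spread is small against `tau` (ms)
# fall back smoothly to the unit-slope mean residual - for a flat curve the
# session carries no slope information and the least-squares slope would be
# pure noise. A [0.2, 5] clamp guards degenerate sessions.
group_delay_raw <- function(rt, at, g, tau = 100) {
  n <- as.numeric(table(g))
  sx <- as.numeric(tapply(at, g, sum))
  sy <- as.numeric(tapply(rt, g, sum))
  sxx <- as.numeric(tapply(at * at, g, sum))
  sxy <- as.numeric(tapply(at * rt, g, sum))
  vx <- sxx - sx^2 / n
  cxy <- sxy - sx * sy / n
  lambda <- n * tau^2
  slope <- clip((cxy + lambda) / (vx + lambda), 0.2, 5)
  (sy - slope * sx) / n
}

group_delay <- function(rt, at, g, tau = 100) {
  pmax(0, group_delay_raw(rt, at, g, tau))
}

#' Calibrate condition difficulties and the answer-time curve on a normative cohort
#'
#' Runs the two fixed-point procedures of the decomposition on one task's
#' normative trials.
#'
#' Stage 1 (difficulty): each trial gets a speed score
#' `s = clip((ceiling - rt) / (ceiling - floor), 0, 1)` using the cohort's 5th
#' and 95th reaction-time percentiles, and a trial performance
#' `p = accuracy * (w + (1 - w) * s)`. Raw condition difficulty is
#' `D_raw(c) = 1 - mean(p)` over trials with label `c`. Difficulty-weighted
#' provisional abilities `A_i = sum(p * D') / sum(D')` and the ability-scaled
#' difficulty `D'(c) = clip(D_raw(c) + (mean ability of attempters of c -
#' grand mean ability), 0, 1)` are then alternated to convergence. The
#' correction compensates progression bias: when only stronger participants
#' reach a condition, its raw pass rate understates its difficulty.
#'
#' Stage 2 (answer time): alternates a monotone (in `D'`) condition-level
#' answer-time curve, fitted by isotonic regression on per-condition means of
#' `rt - DT` (means, not medians: the delays are mean-based intercepts, and a
#' moment-inconsistent curve re-injects a skew offset every iteration and
#' never settles), with per-participant delays (the floored intercept of each
#' participant's reaction times regressed on the current curve, see
#' [idoct_decompose()]), until the curve stabilises. Because the additive split between the curve's
#' level and the delays is otherwise unidentified, the delay scale is
#' anchored so the fastest (5th-percentile) normative participants carry zero
#' delay. The curve, the reaction-time percentiles and the normative mean
#' delay are frozen into the returned table.
#'
#' @param trials normative trial table for a single task (cleaned).
#' @param w accuracy floor weight of the performance score; a fully correct
#'   but maximally slow trial scores `w`.
#' @param tol convergence tolerance for both fixed points (max absolute
#'   change in `D'`; max relative change in the answer-time curve).
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param min_obs minimum observations required per condition label.
#' @param keep_intermediates retain per-trial scores and per-participant
#'   abilities/delays for diagnostics and verification.
#' @return Object of class `difficulty_table`: `task_id`, a `conditions`
#'   data.frame (`condition_label`, `d_raw`, `d_scaled`, `n_obs`, `at`), a
#'   `calibration` list (`rt_floor`, `rt_ceiling`, `dt_reference_mean`, `w`),
#'   convergence flags and iteration counts.
#' @export
idoct_calibrate <- function(trials, w = 0.5, tol = 1e-4, max_iter = 200L,
                            min_obs = 10L, keep_intermediates = FALSE) {
  if (length(unique(trials$task_id)) != 1) {
    stopf("calibrate expects trials from exactly one task")
  }
  if (length(unique(trials$participant_id)) < 2) {
    stopf("calibration needs at least 2 participants")
  }
  labels <- sort(unique(trials$condition_label))
  n_obs <- as.integer(table(factor(trials$condition_label, levels = labels)))
  if (any(n_obs < min_obs)) {
    stopf("condition(s) %s observed fewer than %d times",
          paste(labels[n_obs < min_obs], collapse = ", "), min_obs)
  }

  rt <- trials$rt
  rt_floor <- unname(stats::quantile(rt, 0.05))
  rt_ceiling <- unname(stats::quantile(rt, 0.95))
  s <- speed_score(rt, rt_floor, rt_ceiling)
  p <- trials$accuracy * (w + (1 - w) * s)

  lab_f <- factor(trials$condition_label, levels = labels)
  lab_i <- as.integer(lab_f)
  d_raw <- 1 - as.numeric(tapply(p, lab_f, mean))

  pid <- factor(trials$participant_id)
  # participant x condition attempt structure (fixed over iterations)
  attempted <- table(pid, lab_f) > 0

  d_scaled <- clip01(d_raw)
  converged_d <- FALSE
  iter_d <- 0L
  ability <- NULL
  for (it in seq_len(max_iter)) {
    iter_d <- it
    wtrial <- d_scaled[lab_i]
    num <- tapply(p * wtrial, pid, sum)
    den <- tapply(wtrial, pid, sum)
    ability <- as.numeric(ifelse(den > 0, num / den, tapply(p, pid, mean)))
    grand <- mean(ability)
    cond_ability <- vapply(seq_along(labels), function(j) {
      mean(ability[attempted[, j]])
    }, numeric(1))
    d_new <- clip01(d_raw + (cond_ability - grand))
    delta <- max(abs(d_new - d_scaled))
    d_scaled <- d_new
    if (delta < tol) {
      converged_d <- TRUE
      break
    }
  }

  # stage 2: monotone answer-time curve vs per-participant delay. The
  # additive split between the curve's level and the delays is not identified
  # by the data alone, so the delay scale is anchored each iteration: the
  # 5th-percentile (fastest) normative participants are assigned zero delay.
  dt_i <- rep(0, nlevels(pid))
  at_c <- rep(0, length(labels))
  converged_at <- FALSE
  iter_at <- 0L
  ord <- order(d_scaled)
  for (it in seq_len(max_iter)) {
    iter_at <- it
    resid <- rt - dt_i[as.integer(pid)]
    cm <- as.numeric(tapply(resid, lab_f, mean))
    cand <- cm
    cand[ord] <- stats::isoreg(seq_along(ord), cm[ord])$yf
    anchor <- unname(stats::quantile(group_delay_raw(rt, cand[lab_i], pid),
                                     0.05))
    cand <- cand + anchor
    # half-step damping: the median/isotonic/clamp composition is not a
    # contraction and can limit-cycle at the millisecond scale without it
    at_new <- if (it == 1) cand else at_c + 0.5 * (cand - at_c)
    dt_i <- group_delay(rt, at_new[lab_i], pid)
    delta <- max(abs(at_new - at_c)) / max(1, max(abs(at_c)))
    at_c <- at_new
    if (delta < tol) {
      converged_at <- TRUE
      break
    }
  }

  out <- structure(list(
    task_id = trials$task_id[1],
    conditions = data.frame(condition_label = labels, d_raw = d_raw,
                            d_scaled = d_scaled, n_obs = n_obs, at = at_c,
                            stringsAsFactors = FALSE),
    calibration = list(rt_floor = rt_floor, rt_ceiling = rt_ceiling,
                       dt_reference_mean = mean(dt_i), w = w),
    converged = converged_d && converged_at,
    n_iterations = c(difficulty = iter_d, answer_time = iter_at)
  ), class = "difficulty_table")
  if (!out$converged) {
    warning(sprintf("calibration for task '%s' did not converge in %d iterations",
                    out$task_id, max_iter))
  }
  if (keep_intermediates) {
    out$intermediates <- list(s = s, p = p,
                              ability = stats::setNames(ability, levels(pid)),
                              dt = stats::setNames(as.numeric(dt_i), levels(pid)))
  }
  out
}

#' @export
print.difficulty_table <- function(x, ...) {
  cat(sprintf("<difficulty_table> task %s: %d conditions, rt window [%.0f, %.0f] ms, reference delay %.0f ms%s\n",
              x$task_id, nrow(x$conditions), x$calibration$rt_floor,
              x$calibration$rt_ceiling, x$calibration$dt_reference_mean,
              if (x$converged) "" else " (NOT converged)"))
  print(x$conditions, ...)
  invisible(x)
}

check_labels <- function(labels, table) {
  idx <- match(labels, table$conditions$condition_label)
  if (anyNA(idx)) {
    stopf("condition label(s) %s unknown to the calibrated table for task '%s'",
          paste(unique(labels[is.na(idx)]), collapse = ", "), table$task_id)
  }
  idx
}

#' Decompose one session against a frozen calibration
#'
#' Splits a single participant-session-task block of trials into a response
#' delay time, per-trial answer times and a Cognitive Index. The delay is the
#' floor-at-zero intercept of the session's reaction times regressed on the
#' frozen condition answer-time curve: the difficulty gradient identifies the
#' split, because cognitive slowing scales the curve while motor and device
#' delay shift it additively. Answer times are `rt - DT`, so `rt = AT + DT`
#' holds exactly per trial and a noise-free session with
#' `rt = DT_true + AT_c` recovers `DT_true` exactly. The Cognitive Index is the
#' difficulty-weighted performance over the session's trials,
#' `AS = sum(accuracy * D' * (w + (1 - w) * s*)) / sum(D')`, where the speed
#' score `s*` is computed on answer times against the calibrated percentiles
#' shifted by the normative mean delay. An all-incorrect session therefore
#' scores 0 regardless of its reaction times, and of two sessions with the
#' same accuracy pattern the one with uniformly slower answer times scores
#' strictly lower.
#'
#' @param trials trials of one participant-session for the table's task.
#' @param table a calibrated [idoct_calibrate()] result for the same task.
#' @return Object of class `idoct_decomposition`: `cognitive_index`,
#'   `delay_time`, per-trial `answer_times`, `n_trials_used`,
#'   `low_confidence` (fewer than 3 usable trials), `converged`,
#'   `n_iterations`.
#' @export
idoct_decompose <- function(trials, table) {
  if (nrow(trials) == 0) stopf("no trials to decompose")
  if (length(unique(paste(trials$participant_id, trials$session_index))) != 1) {
    stopf("decompose expects a single participant-session; use decompose_all for batches")
  }
  if (any(trials$task_id != table$task_id)) {
    stopf("trials belong to task '%s' but table was calibrated for '%s'",
          trials$task_id[1], table$task_id)
  }
  idx <- check_labels(trials$condition_label, table)
  cal <- table$calibration
  at_c <- table$conditions$at[idx]
  dsc <- table$conditions$d_scaled[idx]

  dt <- group_delay(trials$rt, at_c, rep(1L, nrow(trials)))
  answer <- trials$rt - dt
  s_star <- speed_score(answer, cal$rt_floor - cal$dt_reference_mean,
                        cal$rt_ceiling - cal$dt_reference_mean)
  num <- trials$accuracy * dsc * (cal$w + (1 - cal$w) * s_star)
  den <- sum(dsc)
  as_score <- if (den > 0) sum(num) / den else mean(num)

  structure(list(
    participant_id = trials$participant_id[1],
    task_id = table$task_id,
    session_index = trials$session_index[1],
    cognitive_index = as_score,
    delay_time = dt,
    answer_times = answer,
    n_trials_used = nrow(trials),
    low_confidence = nrow(trials) < 3,
    converged = TRUE,
    n_iterations = 1L
  ), class = "idoct_decomposition")
}

#' @export
print.idoct_decomposition <- function(x, ...) {
  cat(sprintf("<idoct_decomposition> %s / %s session %s: AS %.3f, DT %.0f ms (%d trials%s)\n",
              x$participant_id, x$task_id, x$session_index, x$cognitive_index,
              x$delay_time, x$n_trials_used,
              if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}

#' Decompose every participant-session against calibrated tables
#'
#' Vectorised batch version of [idoct_decompose()] across tasks and sessions.
#' Tasks without a calibrated table are skipped with a message.
#'
#' @param trials cleaned trial table (any number of tasks and sessions).
#' @param tables named list of `difficulty_table`s, keyed by task id.
#' @return data.frame with one row per participant-session-task:
#'   `participant_id`, `task_id`, `session_index`, `cognitive_index`,
#'   `delay_time`, `n_trials`, `low_confidence`, `converged`.
#' @export
decompose_all <- function(trials, tables) {
  out <- list()
  for (task_id in unique(trials$task_id)) {
    tab <- tables[[task_id]]
    if (is.null(tab)) {
      message("no calibrated table for task '", task_id, "'; skipped")
      next
    }
    tt <- trials[trials$task_id == task_id, , drop = FALSE]
    idx <- check_labels(tt$condition_label, tab)
    cal <- tab$calibration
    at_c <- tab$conditions$at[idx]
    dsc <- tab$conditions$d_scaled[idx]

    g <- interaction(tt$participant_id, tt$session_index, drop = TRUE)
    dt_g <- group_delay(tt$rt, at_c, g)
    dt_t <- dt_g[as.integer(g)]
    answer <- tt$rt - dt_t
    s_star <- speed_score(answer, cal$rt_floor - cal$dt_reference_mean,
                          cal$rt_ceiling - cal$dt_reference_mean)
    num <- tt$accuracy * dsc * (cal$w + (1 - cal$w) * s_star)
    num_g <- as.numeric(tapply(num, g, sum))
    den_g <- as.numeric(tapply(dsc, g, sum))
    as_g <- ifelse(den_g > 0, num_g / den_g,
                   as.numeric(tapply(num, g, mean)))
    n_g <- as.integer(table(g))
    first <- !duplicated(g)
    out[[task_id]] <- data.frame(
      participant_id = tt$participant_id[first][order(unique(as.integer(g)))],
      task_id = task_id,
      session_index = tt$session_index[first][order(unique(as.integer(g)))],
      cognitive_index = as_g,
      delay_time = dt_g,
      n_trials = n_g,
      low_confidence = n_g < 3,
      converged = TRUE,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standard per-session performance metrics
#'
#' The conventional outcome measures a task reports without any modelling:
#' number of correct responses and the median reaction time over all trials
#' (correct and incorrect; the all-trial median is the conservative
#' motor-confounded baseline the decomposition is compared against).
#'
#' @param trials trial table (any number of tasks/sessions).
#' @return data.frame with `participant_id`, `task_id`, `session_index`,
#'   `accuracy_count`, `trial_count`, `median_rt` (NA for empty groups).
#' @export
standard_metrics <- function(trials) {
  if (nrow(trials) == 0) {
    return(data.frame(participant_id = character(), task_id = character(),
                      session_index = integer(), accuracy_count = integer(),
                      trial_count = integer(), median_rt = numeric(),
                      stringsAsFactors = FALSE))
  }
  g <- interaction(trials$participant_id, trials$task_id,
                   trials$session_index, drop = TRUE)
  first <- !duplicated(g)
  ord <- order(unique(as.integer(g)))
  data.frame(
    participant_id = trials$participant_id[first][ord],
    task_id = trials$task_id[first][ord],
    session_index = trials$session_index[first][ord],
    accuracy_count = as.integer(tapply(trials$accuracy, g, sum)),
    trial_count = as.integer(table(g)),
    median_rt = as.numeric(tapply(trials$rt, g, stats::median)),
    stringsAsFactors = FALSE
  )
}
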