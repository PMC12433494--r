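#' Define a digital cognitive task
#'
#' A `task_spec` describes one self-administered task of the battery: how
#' strongly it loads on hand-motor versus cognitive ability, its graded
#' condition difficulties, trial count, response window and reaction-time
#' parameters. The specs drive both the synthetic trial generator and the
#' decomposition (condition labels and response windows are read from them).
#'
#' @param task_id short unique token naming the task.
#' @param domain cognitive domain tag (e.g. `"memory"`, `"attention"`,
#'   `"speed"`, `"language"`); used only for interpretation and for the
#'   imaging-association structure of the simulator.
#' @param motor_demand `"low"` or `"high"`: whether responding requires
#'   complex hand movements across the screen.
#' @param cognitive_demand `"low"` or `"high"`: low-demand tasks are easy
#'   screening tasks on which healthy adults perform near ceiling.
#' @param condition_difficulties strictly increasing numeric vector of latent
#'   condition difficulties on the ability scale (logit units).
#' @param n_trials total trials per session, spread evenly over conditions.
#' @param response_window maximum allowed reaction time in ms; slower
#'   responses time out.
#' @param base_answer_time baseline cognitive answer time in ms for a trial of
#'   difficulty 0 answered by an average participant.
#' @param difficulty_rt_slope relative increase in answer time per unit of
#'   condition difficulty.
#' @param slip_rate_impaired probability that a correct response is spoiled by
#'   a mis-tap when an impaired hand is used; only applied in high
#'   motor-demand tasks.
#' @param impaired_ability_penalty ability-scale penalty applied to users of
#'   an impaired hand; nonzero only for tasks explicitly designed to measure
#'   fine hand-motor ability (their score *should* reflect the impairment).
#'
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(task_id, domain,
                      motor_demand = c("low", "high"),
                      cognitive_demand = c("low", "high"),
                      condition_difficulties,
                      n_trials = 40L,
                      response_window = 5000,
                      base_answer_time = 800,
                      difficulty_rt_slope = 0.3,
                      slip_rate_impaired = 0,
                      impaired_ability_penalty = 0) {
  motor_demand <- match.arg(motor_demand)
  cognitive_demand <- match.arg(cognitive_demand)
  if (length(condition_difficulties) < 1) {
    stopf("task '%s': at least one condition is required", task_id)
  }
  if (length(condition_difficulties) > 1 &&
      any(diff(condition_difficulties) <= 0)) {
    stopf("task '%s': condition_difficulties must be strictly increasing",
          task_id)
  }
  if (slip_rate_impaired < 0 || slip_rate_impaired > 1) {
    stopf("task '%s': slip_rate_impaired must be a probability", task_id)
  }
  if (n_trials < length(condition_difficulties)) {
    stopf("task '%s': fewer trials than conditions", task_id)
  }
  if (any(1 + difficulty_rt_slope * condition_difficulties <= 0)) {
    stopf("task '%s': difficulty_rt_slope implies nonpositive answer times",
          task_id)
  }
  structure(list(
    task_id = task_id,
    domain = domain,
    motor_demand = motor_demand,
    cognitive_demand = cognitive_demand,
    n_conditions = length(condition_difficulties),
    condition_difficulties = as.numeric(condition_difficulties),
    condition_labels = sprintf("%s_c%02d", task_id,
                               seq_along(condition_difficulties)),
    n_trials = as.integer(n_trials),
    response_window = as.numeric(response_window),
    base_answer_time = as.numeric(base_answer_time),
    difficulty_rt_slope = as.numeric(difficulty_rt_slope),
    slip_rate_impaired = as.numeric(slip_rate_impaired),
    impaired_ability_penalty = as.numeric(impaired_ability_penalty)
  ), class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s (%s; motor %s, cognitive %s; %d conditions, %d trials)\n",
              x$task_id, x$domain, x$motor_demand, x$cognitive_demand,
              x$n_conditions, x$n_trials))
  invisible(x)
}

#' Default 18-task battery registry
#'
#' A registry of 18 synthetic task specifications covering memory, language,
#' executive function, attention, numeracy, reasoning, processing speed and
#' praxis, with opposing levels of motor and cognitive demand. Four archetypes
#' anchor the grid: a pure motor-control task (high motor / low cognitive,
#' explicitly designed to index fine hand-motor ability), trail-making (high /
#' high), semantic judgement (low / high) and a simple reaction-time task
#' (low / low). Low cognitive-demand tasks have condition difficulties well
#' below typical ability, so accuracy sits near ceiling and the graded signal
#' lives mostly in response speed.
#'
#' @return Named list of [task_spec()] objects.
#' @export
default_task_registry <- function() {
  easy <- seq(-4.0, -2.4, length.out = 5)
  hard <- seq(-1.5, 1.5, length.out = 5)
  specs <- list(
    task_spec("motor_control", "praxis", "high", "low",
              seq(-3.6, -2.2, length.out = 5), base_answer_time = 550,
              difficulty_rt_slope = 0.12, response_window = 3500,
              slip_rate_impaired = 0.03, impaired_ability_penalty = 1.0),
    task_spec("trail_making", "executive", "high", "high", hard,
              base_answer_time = 1000, response_window = 6000,
              slip_rate_impaired = 0.03),
    task_spec("semantic_judgement", "language", "low", "high", hard,
              base_answer_time = 950, response_window = 6000),
    task_spec("simple_reaction_time", "speed", "low", "low",
              seq(-4.2, -3.0, length.out = 5), base_answer_time = 350,
              difficulty_rt_slope = 0.08, response_window = 2000),
    task_spec("choice_reaction_time", "speed", "high", "low", easy,
              base_answer_time = 500, difficulty_rt_slope = 0.12,
              response_window = 3000, slip_rate_impaired = 0.03),
    task_spec("target_cancellation", "attention", "high", "high", hard,
              base_answer_time = 800, response_window = 5000,
              slip_rate_impaired = 0.03),
    task_spec("sustained_attention", "attention", "low", "high", hard,
              base_answer_time = 700, response_window = 4500),
    task_spec("auditory_attention", "attention", "low", "high", hard,
              base_answer_time = 750, response_window = 5000),
    task_spec("digit_span", "memory", "low", "high", hard,
              base_answer_time = 900, response_window = 6000),
    task_spec("spatial_span", "memory", "high", "high", hard,
              base_answer_time = 950, response_window = 6000,
              slip_rate_impaired = 0.03),
    task_spec("paired_associates", "memory", "low", "high", hard,
              base_answer_time = 1000, response_window = 6000),
    task_spec("word_recognition", "memory", "low", "low", easy,
              base_answer_time = 650, difficulty_rt_slope = 0.12,
              response_window = 4000),
    task_spec("task_recall", "memory", "low", "low", easy,
              base_answer_time = 600, difficulty_rt_slope = 0.12,
              response_window = 4000),
    task_spec("orientation", "screening", "low", "low", easy,
              base_answer_time = 700, difficulty_rt_slope = 0.12,
              response_window = 5000),
    task_spec("calculation", "numeracy", "low", "high", hard,
              base_answer_time = 1100, response_window = 6000),
    task_spec("number_problems", "numeracy", "low", "high", hard,
              base_answer_time = 1150, response_window = 6500),
    task_spec("odd_one_out", "reasoning", "low", "high", hard,
              base_answer_time = 1050, response_window = 6000),
    task_spec("rule_learning", "reasoning", "high", "high", hard,
              base_answer_time = 1000, response_window = 6000,
              slip_rate_impaired = 0.03)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "task_id")
  specs
}

#' Remove all motor effects from a task registry
#'
#' Returns a copy of the registry with mis-tap slip rates and the
#' impaired-hand ability penalty set to zero. Combined with a zero
#' impaired-hand delay in the generator parameters this yields the null
#' condition in which hand impairment has no effect on any trial, used for
#' false-positive calibration of the confound analysis.
#'
#' @param registry list of [task_spec()] objects.
#' @return Modified registry.
#' @export
strip_motor_effects <- function(registry) {
  lapply(registry, function(sp) {
    sp$slip_rate_impaired <- 0
    sp$impaired_ability_penalty <- 0
    sp
  })
}

# domains whose chronic-phase performance carries the extra white-matter
# burden loading in the simulator
wmh_sensitive_domains <- c("attention", "speed", "memory")
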