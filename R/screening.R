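#' Screening test characteristics
#'
#' Describes a screening programme: diagnostic accuracy (sensitivity and
#' specificity against the clinical reference standard), the variable cost
#' of one screen, the fixed annual programme cost, and annual patient
#' capacity. The per-patient screening cost charged by the decision tree is
#' `cost_per_screen + fixed_program_cost / capacity`.
#'
#' @param sensitivity Probability a diseased patient screens positive.
#' @param specificity Probability a disease-free patient screens negative.
#' @param cost_per_screen Variable cost of one screen (CAD).
#' @param fixed_program_cost Fixed programme cost per year (CAD).
#' @param capacity Patients screened per year (>= 1).
#' @return An object of class `screening_test`.
#' @export
#' @examples
#' screening_test(0.865, 0.786, cost_per_screen = 133)
screening_test <- function(sensitivity, specificity, cost_per_screen = 0,
                           fixed_program_cost = 0, capacity = 1) {
  for (p in c(sensitivity, specificity)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 ||
        p > 1) {
      stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cost_per_screen < 0 || fixed_program_cost < 0) {
    stop("screening costs must be non-negative", call. = FALSE)
  }
  if (capacity < 1) stop("capacity must be >= 1", call. = FALSE)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 cost_per_screen = cost_per_screen,
                 fixed_program_cost = fixed_program_cost,
                 capacity = capacity),
            class = "screening_test")
}

#' A screening strategy or the standard-of-care comparator
#'
#' A strategy couples a screening test (or `NULL` for the no-screening /
#' in-person comparator) with the transition models governing treated and
#' untreated disease, a per-patient service cost, and the one-off
#' confirmatory examination cost incurred by false positives.
#'
#' Both strategies in a comparison share the same [state_rewards] and
#' natural-history inputs; they differ in how patients are routed into the
#' treated versus untreated Markov arms and in programme costs.
#'
#' @param name Strategy label.
#' @param treated_transitions,untreated_transitions [transition_model]s for
#'   patients whose glaucoma is detected and treated, versus undetected
#'   (natural history under usual care).
#' @param test A [screening_test], or `NULL` for the comparator.
#' @param per_patient_service_cost Per-patient programme/service cost
#'   (CAD), e.g. annual in-person examination costs divided by patients
#'   serviced.
#' @param confirmatory_cost One-off in-person confirmatory examination
#'   cost (CAD) charged to false positives.
#' @return An object of class `cea_strategy`.
#' @export
strategy <- function(name, treated_transitions, untreated_transitions,
                     test = NULL, per_patient_service_cost = 0,
                     confirmatory_cost = 0) {
  stopifnot(inherits(treated_transitions, "transition_model"),
            inherits(untreated_transitions, "transition_model"))
  if (!is.null(test)) stopifnot(inherits(test, "screening_test"))
  if (per_patient_service_cost < 0 || confirmatory_cost < 0) {
    stop("strategy costs must be non-negative", call. = FALSE)
  }
  structure(list(name = name, test = test,
                 treated_transitions = treated_transitions,
                 untreated_transitions = untreated_transitions,
                 per_patient_service_cost = per_patient_service_cost,
                 confirmatory_cost = confirmatory_cost),
            class = "cea_strategy")
}

#' Joint classification probabilities of a screening test
#'
#' Expands prevalence, sensitivity and specificity into the four joint
#' probabilities of the screening decision tree.
#'
#' @param prevalence Disease prevalence in the screened population.
#' @param test A [screening_test].
#' @return An object of class `classification_result` with fields
#'   `p_true_positive`, `p_false_negative`, `p_false_positive`,
#'   `p_true_negative` (summing to 1).
#' @export
#' @examples
#' classify(0.03, screening_test(0.865, 0.786))
classify <- function(prevalence, test) {
  stopifnot(inherits(test, "screening_test"))
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      !is.finite(prevalence) || prevalence < 0 || prevalence > 1) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    p_true_positive = prevalence * test$sensitivity,
    p_false_negative = prevalence * (1 - test$sensitivity),
    p_false_positive = (1 - prevalence) * (1 - test$specificity),
    p_true_negative = (1 - prevalence) * test$specificity
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>\n")
  print(round(unlist(unclass(x)), 6))
  invisible(x)
}

# at-risk branch: disease-free patients stay in the at_risk state, accruing
# its utility and annual cost (no incidence is modelled after entry)
at_risk_branch <- function(rewards, n_cycles, discount_rate, timing) {
  run_cohort(c(1, 0, 0, 0, 0),
             transition_model(diag(N_STATES), arm = "at_risk"),
             rewards, n_cycles, discount_rate, timing)
}

#' Expected cost and effectiveness of a strategy
#'
#' Runs the screening decision tree: disease-positive patients detected by
#' the test (true positives) enter the treated Markov arm, missed cases
#' (false negatives) the untreated arm; disease-free patients follow the
#' at-risk branch, with false positives additionally incurring one
#' confirmatory examination. The comparator (no test) routes all diseased
#' patients to the untreated arm. Branch traces are probability-weighted
#' into per-patient expected discounted cost and QALYs.
#'
#' @param strat A [strategy].
#' @param prevalence Disease prevalence at entry.
#' @param rewards A [state_rewards] shared by all branches.
#' @param n_cycles,discount_rate,timing Passed to [run_cohort].
#' @param entry_dist Initial state distribution for disease-positive
#'   entrants; default all mass in `at_risk` (diagnosed suspects enter
#'   under monitoring/treatment before converting to a mild diagnosis).
#' @return A list with `expected_cost`, `expected_qaly`,
#'   `screening_cost` (per-patient programme + screen cost charged at
#'   entry), `branch_weights`, and `traces` (per-branch [run_cohort]
#'   results).
#' @export
evaluate_strategy <- function(strat, prevalence, rewards, n_cycles = 30L,
                              discount_rate = 0.03,
                              timing = c("start", "end", "half"),
                              entry_dist = c(1, 0, 0, 0, 0)) {
  stopifnot(inherits(strat, "cea_strategy"))
  timing <- match.arg(timing)
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }

  run_arm <- function(tm) {
    if (is.null(tm)) {
      stop("strategy '", strat$name, "' lacks a transition model for a ",
           "branch the decision tree needs", call. = FALSE)
    }
    run_cohort(entry_dist, tm, rewards, n_cycles, discount_rate, timing)
  }
  ar <- at_risk_branch(rewards, n_cycles, discount_rate, timing)

  if (is.null(strat$test)) {
    weights <- c(diseased = prevalence, disease_free = 1 - prevalence)
    traces <- list(diseased = run_arm(strat$untreated_transitions),
                   disease_free = ar)
    extra_cost <- 0
    screening_cost <- 0
  } else {
    cl <- classify(prevalence, strat$test)
    weights <- c(true_positive = cl$p_true_positive,
                 false_negative = cl$p_false_negative,
                 false_positive = cl$p_false_positive,
                 true_negative = cl$p_true_negative)
    traces <- list(true_positive = run_arm(strat$treated_transitions),
                   false_negative = run_arm(strat$untreated_transitions),
                   false_positive = ar,
                   true_negative = ar)
    extra_cost <- cl$p_false_positive * strat$confirmatory_cost
    screening_cost <- strat$test$cost_per_screen +
      strat$test$fixed_program_cost / strat$test$capacity
  }

  branch_cost <- sum(weights *
                       vapply(traces, `[[`, 0, "discounted_cost_cum"))
  branch_qaly <- sum(weights *
                       vapply(traces, `[[`, 0, "discounted_qaly_cum"))

  list(
    strategy = strat$name,
    expected_cost = screening_cost + strat$per_patient_service_cost +
      extra_cost + branch_cost,
    expected_qaly = branch_qaly,
    screening_cost = screening_cost,
    branch_weights = weights,
    traces = traces
  )
}

#' Per-patient cost from a programme total
#'
#' Programme costs are divided by the number of patients serviced per year
#' (300 for the teleglaucoma programme, 1379 in-person glaucoma visits in
#' the reference setting).
#'
#' @param total_program_cost Total programme cost (CAD).
#' @param patients_served Number of patients serviced (>= 1).
#' @return Cost per patient (CAD).
#' @export
#' @examples
#' per_patient_cost(39904.68, 300)
per_patient_cost <- function(total_program_cost, patients_served) {
  if (!is.numeric(total_program_cost) || any(total_program_cost < 0)) {
    stop("total_program_cost must be non-negative", call. = FALSE)
  }
  if (!is.numeric(patients_served) || any(patients_served < 1)) {
    stop("patients_served must be >= 1", call. = FALSE)
  }
  total_program_cost / patients_served
}

#' Visit-time savings of remote screening
#'
#' @param tele_minutes Minutes per remote screening visit (> 0).
#' @param inperson_minutes Minutes per in-person visit (> 0).
#' @return A list with `absolute` (minutes saved) and `relative`
#'   (percentage reduction relative to the in-person visit).
#' @export
#' @examples
#' time_savings_report(78, 115)
time_savings_report <- function(tele_minutes, inperson_minutes) {
  if (!is.numeric(tele_minutes) || !is.numeric(inperson_minutes) ||
      tele_minutes <= 0 || inperson_minutes <= 0) {
    stop("visit times must be positive", call. = FALSE)
  }
  absolute <- inperson_minutes - tele_minutes
  list(absolute = absolute,
       relative = 100 * absolute / inperson_minutes)
}
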