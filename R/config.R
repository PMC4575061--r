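PARAM_NAMES <- c(
  "prevalence", "sensitivity", "specificity",
  "utility_at_risk", "utility_mild", "utility_moderate", "utility_severe",
  "utility_blind",
  "cost_at_risk", "cost_mild", "cost_moderate", "cost_severe", "cost_blind",
  "cost_screen_tele", "cost_service_inperson", "cost_confirmatory",
  "tp_treated_at_risk_mild", "tp_treated_mild_moderate",
  "tp_treated_moderate_severe", "tp_treated_severe_blind",
  "tp_untreated_at_risk_mild", "tp_untreated_mild_moderate",
  "tp_untreated_moderate_severe", "tp_untreated_severe_blind"
)

# parameter names that are probabilities or utilities (beta-compatible,
# bounded in [0, 1]); everything else is a cost (gamma-compatible)
prob_like <- function(name) {
  !startsWith(name, "cost_")
}

#' Define one model parameter
#'
#' @param value Base-case value.
#' @param dist Second-order uncertainty distribution for probabilistic
#'   sensitivity analysis: `"gamma"` (costs), `"beta"` (probabilities and
#'   utilities) or `"fixed"`.
#' @param se Standard error of the distribution (ignored for `"fixed"`;
#'   an `se` of 0 degenerates to fixed).
#' @param source Provenance tag, e.g. `"paper"`, `"calibrated"`,
#'   `"assumption"`.
#' @return A list with class `cea_param`.
#' @export
param <- function(value, dist = "fixed", se = 0, source = "assumption") {
  structure(list(value = as.numeric(value), dist = dist,
                 se = as.numeric(se), source = source),
            class = "cea_param")
}

#' Assemble and validate a model configuration
#'
#' A `model_config` bundles everything needed to evaluate both strategies:
#' the 24 named model parameters (with their PSA distributions and
#' provenance tags) and the run settings (horizon, discount rate,
#' willingness to pay, reward-accrual timing, entry state, PSA defaults).
#'
#' @param parameters Named list of [param] entries covering every name in
#'   the canonical parameter set.
#' @param settings List with elements `horizon`, `discount_rate`, `wtp`,
#'   `timing`, `entry_state`, and `psa` (`n_samples`, `seed`).
#' @param meta Optional metadata list (currency, price year, notes).
#' @return A validated object of class `model_config`.
#' @export
model_config <- function(parameters, settings = NULL, meta = NULL) {
  defaults <- list(horizon = 30L, discount_rate = 0.03, wtp = 40000,
                   timing = "start", entry_state = "at_risk",
                   psa = list(n_samples = 1000L, seed = 42L))
  settings <- utils::modifyList(defaults, settings %||% list())
  cfg <- structure(list(meta = meta %||% list(currency = "CAD"),
                        settings = settings, parameters = parameters),
                   class = "model_config")
  validate_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a model configuration
#'
#' Checks the parameter set for completeness, ranges, distribution
#' compatibility (gamma only for costs, beta only for quantities in
#' \[0, 1\] with a feasible variance), the utility ordering, and the run
#' settings; transition matrices implied by the parameters are built and
#' validated. Errors name the offending field.
#'
#' @param config A `model_config` (or plain list with the same shape).
#' @return `config`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  p <- config$parameters
  missing <- setdiff(PARAM_NAMES, names(p))
  if (length(missing)) {
    stop("config$parameters: missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(p), PARAM_NAMES)
  if (length(extra)) {
    stop("config$parameters: unknown parameter(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(p))) {
    stop("config$parameters: duplicated parameter names", call. = FALSE)
  }
  for (nm in PARAM_NAMES) {
    e <- p[[nm]]
    where <- paste0("config$parameters$", nm)
    if (!is.numeric(e$value) || !is.finite(e$value)) {
      stop(where, ": value must be a finite number", call. = FALSE)
    }
    if (!e$dist %in% c("gamma", "beta", "fixed")) {
      stop(where, ": dist must be gamma, beta or fixed", call. = FALSE)
    }
    if (!is.numeric(e$se) || !is.finite(e$se) || e$se < 0) {
      stop(where, ": se must be a non-negative number", call. = FALSE)
    }
    if (prob_like(nm)) {
      if (e$value < 0 || e$value > 1) {
        stop(where, ": probabilities and utilities must lie in [0, 1]",
             call. = FALSE)
      }
      if (e$dist == "gamma") {
        stop(where, ": gamma distributions are reserved for costs; ",
             "use beta for probabilities and utilities", call. = FALSE)
      }
      if (e$dist == "beta" && e$se > 0) {
        moments_to_beta(e$value, e$se)  # feasibility check
      }
    } else {
      if (e$value < 0) {
        stop(where, ": costs must be non-negative", call. = FALSE)
      }
      if (e$dist == "beta") {
        stop(where, ": beta distributions are reserved for quantities in ",
             "[0, 1]; use gamma for costs", call. = FALSE)
      }
      if (e$dist == "gamma" && e$se > 0 && e$value <= 0) {
        stop(where, ": gamma requires a positive mean", call. = FALSE)
      }
    }
  }
  # structural checks (these constructors validate ranges and ordering)
  config_rewards(config)
  config_transitions(config, "treated")
  config_transitions(config, "untreated")
  s <- config$settings
  if (!is.numeric(s$horizon) || s$horizon < 1) {
    stop("config$settings$horizon: must be >= 1", call. = FALSE)
  }
  if (!is.numeric(s$discount_rate) || s$discount_rate < 0) {
    stop("config$settings$discount_rate: must be >= 0", call. = FALSE)
  }
  if (!is.numeric(s$wtp) || s$wtp < 0) {
    stop("config$settings$wtp: must be >= 0", call. = FALSE)
  }
  if (!s$timing %in% c("start", "end", "half")) {
    stop("config$settings$timing: must be start, end or half",
         call. = FALSE)
  }
  if (!s$entry_state %in% health_states()) {
    stop("config$settings$entry_state: unknown state", call. = FALSE)
  }
  invisible(config)
}

#' @export
print.model_config <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<model_config> horizon %d y, discount %.3g, WTP %s, timing '%s'\n",
    s$horizon, s$discount_rate, format(s$wtp, big.mark = ","), s$timing))
  df <- config_parameter_table(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Parameter table of a configuration
#'
#' @param config A [model_config].
#' @return data.frame with columns `parameter`, `value`, `dist`, `se`,
#'   `source`.
#' @export
config_parameter_table <- function(config) {
  p <- config$parameters[PARAM_NAMES]
  data.frame(
    parameter = PARAM_NAMES,
    value = vapply(p, `[[`, 0, "value"),
    dist = vapply(p, `[[`, "", "dist"),
    se = vapply(p, `[[`, 0, "se"),
    source = vapply(p, `[[`, "", "source"),
    row.names = NULL
  )
}

param_value <- function(config, name) {
  config$parameters[[name]]$value
}

#' Replace a parameter's base-case value
#'
#' @param config A [model_config].
#' @param name Parameter name (see [config_parameter_table]).
#' @param value New value.
#' @return The modified config (not re-validated; sensitivity analyses may
#'   legitimately push values to bounds).
#' @export
set_param <- function(config, name, value) {
  if (!name %in% PARAM_NAMES) {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  config$parameters[[name]]$value <- as.numeric(value)
  config
}

#' Build the shared state rewards / transition models of a configuration
#'
#' @param config A [model_config].
#' @return `config_rewards` returns the [state_rewards]; 
#'   `config_transitions` the [transition_model] of one arm.
#' @export
config_rewards <- function(config) {
  v <- function(nm) param_value(config, nm)
  state_rewards(
    utilities = c(v("utility_at_risk"), v("utility_mild"),
                  v("utility_moderate"), v("utility_severe"),
                  v("utility_blind")),
    annual_costs = c(v("cost_at_risk"), v("cost_mild"),
                     v("cost_moderate"), v("cost_severe"), v("cost_blind"))
  )
}

#' @rdname config_rewards
#' @param arm `"treated"` or `"untreated"`.
#' @export
config_transitions <- function(config, arm = c("treated", "untreated")) {
  arm <- match.arg(arm)
  v <- function(nm) param_value(config, paste0("tp_", arm, "_", nm))
  q <- c(v("at_risk_mild"), v("mild_moderate"), v("moderate_severe"),
         v("severe_blind"))
  transition_model(progression_matrix(q), arm = arm)
}

config_strategies <- function(config) {
  v <- function(nm) param_value(config, nm)
  treated <- config_transitions(config, "treated")
  untreated <- config_transitions(config, "untreated")
  list(
    teleglaucoma = strategy(
      name = "teleglaucoma",
      treated_transitions = treated,
      untreated_transitions = untreated,
      test = screening_test(v("sensitivity"), v("specificity"),
                            cost_per_screen = v("cost_screen_tele")),
      per_patient_service_cost = 0,
      confirmatory_cost = v("cost_confirmatory")
    ),
    in_person = strategy(
      name = "in_person",
      treated_transitions = treated,
      untreated_transitions = untreated,
      test = NULL,
      per_patient_service_cost = v("cost_service_inperson")
    )
  )
}

config_entry_dist <- function(config) {
  d <- numeric(N_STATES)
  d[match(config$settings$entry_state, health_states())] <- 1
  d
}

#' Evaluate both strategies of a configuration
#'
#' Runs the full decision tree + Markov model for the teleglaucoma
#' screening strategy and the in-person (no-screening) comparator, and
#' compares them.
#'
#' @param config A [model_config].
#' @return A list of class `cea_evaluation`: `strategies` (per-strategy
#'   [evaluate_strategy] results), `cea` (the [icer] comparison with
#'   teleglaucoma as reference), `nmb` (per-strategy net monetary benefit
#'   at the configured willingness to pay), and `wtp`.
#' @export
#' @examples
#' ev <- evaluate_config(reference_config())
#' ev$cea
evaluate_config <- function(config) {
  s <- config$settings
  rewards <- config_rewards(config)
  strategies <- config_strategies(config)
  entry <- config_entry_dist(config)
  res <- lapply(strategies, evaluate_strategy,
                prevalence = param_value(config, "prevalence"),
                rewards = rewards, n_cycles = s$horizon,
                discount_rate = s$discount_rate, timing = s$timing,
                entry_dist = entry)
  cea <- icer(res$teleglaucoma$expected_cost,
              res$teleglaucoma$expected_qaly,
              res$in_person$expected_cost, res$in_person$expected_qaly,
              ref_name = "teleglaucoma", comp_name = "in_person")
  structure(list(
    strategies = res,
    cea = cea,
    nmb = vapply(res, function(r) nmb(r$expected_cost, r$expected_qaly,
                                      s$wtp), 0),
    wtp = s$wtp
  ), class = "cea_evaluation")
}

#' @export
print.cea_evaluation <- function(x, ...) {
  print(x$cea)
  cat(sprintf("NMB at WTP %s: %s\n", format(x$wtp, big.mark = ","),
              paste(sprintf("%s %.2f", names(x$nmb), x$nmb),
                    collapse = ", ")))
  invisible(x)
}

#' Read a model configuration from YAML
#'
#' Parses and schema-validates a configuration file. YAML syntax errors
#' carry the parser's line reference; semantic errors name the offending
#' field.
#'
#' @param path Path to a YAML file written by [write_config] (or by hand
#'   in the same layout).
#' @return A validated [model_config].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$parameters)) {
    stop("config file '", path, "': no 'parameters' block", call. = FALSE)
  }
  params <- lapply(raw$parameters, function(e) {
    param(value = e$value, dist = e$dist %||% "fixed", se = e$se %||% 0,
          source = e$source %||% "unspecified")
  })
  model_config(parameters = params, settings = raw$settings,
               meta = raw$meta)
}

#' Write a model configuration to YAML
#'
#' The round trip `read_config(write_config(cfg, f))` reproduces `cfg`
#' (numeric values are serialised at full double precision).
#'
#' @param config A [model_config].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  out <- list(
    meta = config$meta,
    settings = config$settings,
    parameters = lapply(config$parameters[PARAM_NAMES], unclass)
  )
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}
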