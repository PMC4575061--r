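#' Calibrate adjacent-progression transition probabilities
#'
#' Back-solves the four per-cycle progression probabilities of an
#' adjacent-progression arm so that the cohort trace reproduces a target
#' cycle-`n` state occupancy (and, optionally, a target cumulative
#' discounted QALY). The fit is a bounded least-squares minimisation
#' (L-BFGS-B over \[1e-6, 0.999\]^4) of the squared occupancy error plus
#' `qaly_weight` times the squared QALY error, run from a small fixed set
#' of deterministic starting points, so the result is reproducible.
#'
#' The occupancy target need not sum to exactly 1 (published tables are
#' rounded); the residual then reflects the best compromise.
#'
#' @param target_occupancy Numeric vector of length 5: target occupancy
#'   over [health_states()] at cycle `n_cycles`.
#' @param n_cycles Horizon used for the trace; default 30.
#' @param entry_dist Initial distribution; default all mass in `at_risk`.
#' @param arm Arm label for the returned [transition_model].
#' @param occupancy_weights Per-state weights in the occupancy residual.
#' @param target_trace Optional full occupancy trajectory (an
#'   `(n_cycles+1) x 5` matrix): when supplied, the least squares runs
#'   over every cycle, which makes the progression probabilities
#'   identifiable (a single end-point occupancy can be reproduced by more
#'   than one progression vector). Self-consistency recovery of known
#'   probabilities uses this form.
#' @param target_disc_qaly Optional target cumulative discounted QALY of
#'   the trace (requires `utilities`).
#' @param utilities,discount_rate,timing Reward inputs used only when
#'   `target_disc_qaly` is given.
#' @param qaly_weight Weight of the squared QALY error in the objective.
#' @param tol Maximum acceptable occupancy residual (sum of squared
#'   per-state errors); above it, calibration fails with diagnostics.
#' @return A list of class `calibration_result`: `model` (the fitted
#'   [transition_model]), `probs`, `fitted_occupancy`, `residual`
#'   (occupancy sum of squares), `fitted_disc_qaly`, `objective`,
#'   `convergence`.
#' @export
#' @examples
#' q <- c(0.25, 0.08, 0.15, 0.2)
#' tr <- run_cohort(c(1, 0, 0, 0, 0),
#'                  transition_model(progression_matrix(q)),
#'                  state_rewards(c(1, .87, .79, .64, .5), rep(0, 5)))
#' fit <- calibrate_transitions(tr$occupancy[31, ])
#' round(fit$probs - q, 6)
calibrate_transitions <- function(target_occupancy, n_cycles = 30L,
                                  entry_dist = c(1, 0, 0, 0, 0),
                                  arm = "untreated",
                                  occupancy_weights = rep(1, 5),
                                  target_trace = NULL,
                                  target_disc_qaly = NULL,
                                  utilities = NULL, discount_rate = 0.03,
                                  timing = "start", qaly_weight = 25,
                                  tol = 1e-3) {
  tgt <- as.numeric(target_occupancy)
  if (length(tgt) != N_STATES || any(!is.finite(tgt)) || any(tgt < 0) ||
      any(tgt > 1)) {
    stop("target_occupancy must be 5 probabilities", call. = FALSE)
  }
  if (!is.null(target_disc_qaly) && is.null(utilities)) {
    stop("a QALY target needs 'utilities'", call. = FALSE)
  }
  w <- cycle_weights(n_cycles, discount_rate, timing)

  trace_from <- function(q) {
    # L-BFGS-B finite-difference steps can poke marginally past the box
    q <- pmin(pmax(q, 0), 1)
    m <- progression_matrix(q)
    occ <- matrix(0, n_cycles + 1L, N_STATES)
    occ[1L, ] <- entry_dist
    for (t in seq_len(n_cycles)) occ[t + 1L, ] <- occ[t, ] %*% m
    occ
  }
  objective <- function(q) {
    occ <- trace_from(q)
    val <- sum(occupancy_weights * (occ[n_cycles + 1L, ] - tgt)^2)
    if (!is.null(target_trace)) {
      val <- val + sum((occ - target_trace)^2)
    }
    if (!is.null(target_disc_qaly)) {
      qq <- sum((occ %*% utilities) * w)
      val <- val + qaly_weight * (qq - target_disc_qaly)^2
    }
    # minute ridge toward zero progression: breaks the ties left by
    # unidentified downstream probabilities (e.g. an all-at-risk target)
    val + 1e-8 * sum(q^2)
  }

  starts <- list(rep(0.1, 4), rep(0.3, 4), c(0.3, 0.1, 0.15, 0.2),
                 c(0.05, 0.2, 0.3, 0.4), rep(0.5, 4))
  best <- NULL
  for (s0 in starts) {
    fit <- stats::optim(s0, objective, method = "L-BFGS-B",
                        lower = 0, upper = 1,
                        control = list(factr = 1e3, maxit = 500L))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  occ <- trace_from(best$par)
  resid <- sum((occ[n_cycles + 1L, ] - tgt)^2)
  fitted_q <- if (!is.null(utilities)) {
    sum((occ %*% utilities) * w)
  } else {
    NA_real_
  }
  if (resid > tol) {
    stop(sprintf(
      paste0("calibration failed: occupancy residual %.3g exceeds ",
             "tolerance %.3g\n  fitted occupancy: %s\n  target:          %s"),
      resid, tol,
      paste(signif(occ[n_cycles + 1L, ], 4), collapse = " "),
      paste(signif(tgt, 4), collapse = " ")), call. = FALSE)
  }
  structure(list(
    model = transition_model(progression_matrix(best$par), arm = arm),
    probs = best$par,
    fitted_occupancy = occ[n_cycles + 1L, ],
    residual = resid,
    fitted_disc_qaly = fitted_q,
    objective = best$value,
    convergence = best$convergence
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n  probs:",
      paste(signif(x$probs, 6), collapse = " "),
      sprintf("\n  occupancy residual (SSQ): %.3g\n", x$residual))
  invisible(x)
}
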