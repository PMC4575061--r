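#' Glaucoma health states
#'
#' The model uses five ordered, progressive health states: `at_risk`
#' (glaucoma suspect, no clinical diagnosis), `mild`, `moderate`, `severe`
#' glaucoma, and `blind` (end-stage, visual acuity 20/200 or worse,
#' glaucoma-attributable). Disease only progresses: there is no recovery to
#' a healthier state, and blindness is absorbing.
#'
#' @return Character vector of the five state labels, in severity order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("at_risk", "mild", "moderate", "severe", "blind")
}

N_STATES <- 5L
BLIND <- 5L

#' Per-cycle transition probabilities for one treatment arm
#'
#' Builds and validates a row-stochastic transition matrix over the five
#' health states. The matrix must be upper triangular (no recovery) with an
#' absorbing blind state. The usual progressive structure -- self-loop plus
#' one-step progression to the adjacent state -- is a special case; any
#' upper-triangular row-stochastic matrix is accepted.
#'
#' @param matrix 5x5 numeric matrix of per-cycle (per-year) transition
#'   probabilities; rows index the current state, columns the next state.
#' @param arm Label for the arm, typically `"treated"` or `"untreated"`.
#' @param tol Absolute tolerance for the row-sum check.
#' @return An object of class `transition_model`.
#' @export
#' @examples
#' transition_model(progression_matrix(c(0.29, 0.07, 0.17, 0.24)), "treated")
transition_model <- function(matrix, arm = "untreated", tol = 1e-9) {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || any(dim(m) != N_STATES)) {
    stop("transition matrix must be a numeric ", N_STATES, "x", N_STATES,
         " matrix", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    bad <- which(abs(rs - 1) > tol)[1]
    stop(sprintf(
      "transition matrix row %d ('%s') sums to %.12f, not 1 (tol %g)",
      bad, health_states()[bad], rs[bad], tol), call. = FALSE)
  }
  if (any(m[lower.tri(m)] != 0)) {
    stop("moves to a strictly less severe state are not allowed ",
         "(lower-triangular entries must be 0)", call. = FALSE)
  }
  if (any(m[BLIND, ] != c(0, 0, 0, 0, 1))) {
    stop("blind state must be absorbing (identity row)", call. = FALSE)
  }
  dimnames(m) <- list(health_states(), health_states())
  structure(list(matrix = m, arm = as.character(arm)),
            class = "transition_model")
}

#' Adjacent-progression transition matrix
#'
#' Convenience constructor for the progressive structure used throughout:
#' each pre-blind state either stays put or advances one step, so the model
#' is fully described by four per-cycle progression probabilities.
#'
#' @param q Numeric vector of length 4: per-cycle probabilities of moving
#'   at_risk->mild, mild->moderate, moderate->severe, severe->blind.
#' @return A 5x5 numeric matrix.
#' @export
progression_matrix <- function(q) {
  stopifnot(length(q) == N_STATES - 1L, is.numeric(q))
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("progression probabilities must lie in [0, 1]", call. = FALSE)
  }
  m <- diag(N_STATES)
  for (i in seq_len(N_STATES - 1L)) {
    m[i, i] <- 1 - q[i]
    m[i, i + 1L] <- q[i]
  }
  dimnames(m) <- list(health_states(), health_states())
  m
}

#' Extract adjacent progression probabilities from a transition model
#'
#' @param tm A `transition_model` whose matrix has self-loop +
#'   one-step-progression structure.
#' @return Numeric vector of length 4 of per-cycle progression
#'   probabilities.
#' @export
progression_probs <- function(tm) {
  stopifnot(inherits(tm, "transition_model"))
  m <- tm$matrix
  q <- m[cbind(1:4, 2:5)]
  if (max(abs(progression_matrix(q) - m)) > 1e-12) {
    stop("transition matrix is not of adjacent-progression form",
         call. = FALSE)
  }
  q
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> arm:", x$arm, "\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Per-state utilities and annual costs
#'
#' A utility is the preference weight for one year lived in a state
#' (1 = perfect health, 0 = worst); it must be non-increasing with disease
#' severity. Annual costs are the glaucoma-attributable payer costs of one
#' year in each state, in CAD, and must be non-negative.
#'
#' @param utilities Named or ordered numeric vector of length 5 of
#'   QALY-weights in \[0, 1\], ordered as [health_states()].
#' @param annual_costs Numeric vector of length 5 of annual state costs
#'   (CAD/year), same order.
#' @return An object of class `state_rewards`.
#' @export
#' @examples
#' state_rewards(c(1, 0.87, 0.79, 0.64, 0.5), c(20, 100, 150, 220, 400))
state_rewards <- function(utilities, annual_costs) {
  u <- unname(as.numeric(utilities))
  co <- unname(as.numeric(annual_costs))
  stopifnot(length(u) == N_STATES, length(co) == N_STATES)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(u) > 0)) {
    stop("utilities must be non-increasing with severity", call. = FALSE)
  }
  if (any(!is.finite(co)) || any(co < 0)) {
    stop("annual state costs must be non-negative", call. = FALSE)
  }
  names(u) <- names(co) <- health_states()
  structure(list(utilities = u, annual_costs = co), class = "state_rewards")
}

#' @export
print.state_rewards <- function(x, ...) {
  cat("<state_rewards>\n")
  print(data.frame(state = health_states(), utility = unname(x$utilities),
                   annual_cost = unname(x$annual_costs)))
  invisible(x)
}
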