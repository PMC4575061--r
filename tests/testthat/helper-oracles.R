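# Independent oracles used across tests.

# Per-individual Monte Carlo microsimulation of a Markov chain: each
# individual samples its next state from the transition matrix row every
# cycle. Independent of the cohort engine (categorical sampling, no matrix
# products).
microsim_occupancy <- function(m, n_ind, n_cycles, seed, init_state = 1L) {
  set.seed(seed)
  states <- rep.int(init_state, n_ind)
  occ <- matrix(0, n_cycles + 1L, 5L)
  occ[1L, ] <- tabulate(states, 5L) / n_ind
  for (t in seq_len(n_cycles)) {
    nxt <- states
    for (s in 1:5) {
      idx <- which(states == s)
      if (length(idx)) {
        nxt[idx] <- sample.int(5L, length(idx), replace = TRUE,
                               prob = m[s, ])
      }
    }
    states <- nxt
    occ[t + 1L, ] <- tabulate(states, 5L) / n_ind
  }
  occ
}

# elementwise check of cohort occupancy against a microsimulation: cells
# must sit within 3 binomial standard errors, allowing the handful of
# chance exceedances a 3-SE band produces over hundreds of cells (~0.3%
# expected), and never beyond 5 SE
expect_matches_microsim <- function(cohort_occ, msim_occ, n_ind) {
  se <- sqrt(cohort_occ * (1 - cohort_occ) / n_ind)
  dev <- abs(cohort_occ - msim_occ)
  expect_gte(mean(dev <= 3 * se + 3 / n_ind), 0.98)
  expect_true(all(dev <= 5 * se + 5 / n_ind))
}

# the ICER-vs-threshold decision rule, stated independently of NMB algebra
icer_rule_prefers_comparator <- function(ref_cost, ref_effect,
                                         comp_cost, comp_effect, wtp) {
  d_cost <- comp_cost - ref_cost
  d_eff <- comp_effect - ref_effect
  if (d_eff > 0) {
    d_cost / d_eff < wtp      # pay less than WTP per QALY gained
  } else if (d_eff < 0) {
    d_cost / d_eff > wtp      # save more than WTP per QALY forgone
  } else {
    d_cost < 0
  }
}

ref_rewards <- function() {
  state_rewards(c(1, 0.87, 0.79, 0.64, 0.5), c(20, 100, 150, 220, 400))
}
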