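test_that("discount factors follow 1/(1+r)^t and reject bad input", {
  expect_identical(discount_factor(0.03, 0), 1)
  expect_identical(discount_factor(0, 17), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.05, 0:3), 1.05^-(0:3))
  expect_error(discount_factor(-0.01, 1), "non-negative")
  expect_error(discount_factor(0.03, -1), "non-negative integer")
  expect_error(discount_factor(0.03, 1.5), "integer")
})

test_that("QALYs are utility times years, bounded to valid utilities", {
  expect_identical(qaly(0.5, 1), 0.5)
  expect_identical(qaly(1.0, 7), 7)
  expect_equal(qaly(0.87, 2), 1.74)
  expect_error(qaly(1.2, 1), "\\[0, 1\\]")
  expect_error(qaly(-0.1, 1), "\\[0, 1\\]")
  expect_error(qaly(0.5, -1), "non-negative")
})

test_that("transition model validation enforces the progressive structure", {
  m <- progression_matrix(c(0.3, 0.1, 0.15, 0.2))
  tm <- transition_model(m, "treated")
  expect_s3_class(tm, "transition_model")
  expect_equal(progression_probs(tm), c(0.3, 0.1, 0.15, 0.2))

  bad <- m; bad[1, 1] <- 0.9           # row no longer sums to 1
  expect_error(transition_model(bad), "sums to")
  bad <- m; bad[2, 1] <- bad[2, 2]; bad[2, 2] <- 0   # recovery move
  expect_error(transition_model(bad), "less severe")
  bad <- m; bad[5, 5] <- 0.9; bad[5, 4] <- 0.1       # leaky absorbing state
  expect_error(transition_model(bad), "less severe|absorbing")
  expect_error(progression_matrix(c(0.3, 1.2, 0, 0)), "\\[0, 1\\]")
})

test_that("a frozen cohort accrues exactly its state utility each cycle", {
  # all-mild cohort, identity transitions, no discounting:
  # 31 accrual points x utility 0.87
  tm <- transition_model(diag(5))
  rw <- state_rewards(c(1, 0.87, 0.79, 0.64, 0.5), rep(0, 5))
  tr <- run_cohort(c(0, 1, 0, 0, 0), tm, rw, n_cycles = 30,
                   discount_rate = 0, timing = "start")
  expect_equal(tr$discounted_qaly_cum, 31 * 0.87)
})

test_that("a single-step chain reaches blindness at the closed-form rate", {
  rw <- ref_rewards()
  for (p in c(0.05, 0.3, 0.7)) {
    tm <- transition_model(progression_matrix(c(0, 0, 0, p)))
    tr <- run_cohort(c(0, 0, 0, 1, 0), tm, rw, n_cycles = 20)
    expect_equal(unname(tr$occupancy[, "blind"]), 1 - (1 - p)^(0:20),
                 tolerance = 1e-12)
  }
})

test_that("an invalid matrix is rejected before any cycle runs", {
  rw <- ref_rewards()
  tm <- transition_model(progression_matrix(c(0.2, 0.2, 0.2, 0.2)))
  tm$matrix[1, 1] <- 0.5  # mutate after construction
  expect_error(run_cohort(c(1, 0, 0, 0, 0), tm, rw), "sums to")
  expect_error(run_cohort(c(0.5, 0, 0, 0, 0.4),
                          transition_model(diag(5)), rw),
               "probability vector")
})

test_that("occupancy rows stay stochastic and blindness never recedes", {
  for (seed in c(11, 12, 13, 14, 15)) {
    cfg <- random_scenario(seed)
    for (arm in c("treated", "untreated")) {
      tr <- run_cohort(c(1, 0, 0, 0, 0), config_transitions(cfg, arm),
                       config_rewards(cfg), n_cycles = 30)
      expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
      expect_true(all(diff(tr$occupancy[, "blind"]) >= -1e-12))
      # progression-only: cumulative occupancy of states <= k never grows
      for (k in 1:4) {
        cum_k <- rowSums(tr$occupancy[, 1:k, drop = FALSE])
        expect_true(all(diff(cum_k) <= 1e-12))
      }
    }
  }
})

test_that("with strictly positive progression, blindness absorbs the cohort", {
  tm <- transition_model(progression_matrix(c(0.4, 0.4, 0.4, 0.4)))
  tr <- run_cohort(c(1, 0, 0, 0, 0), tm, ref_rewards(), n_cycles = 100)
  expect_gt(tr$occupancy[101, "blind"], 0.999)
})

test_that("discounted cumulative reward is non-increasing in the rate", {
  cfg <- random_scenario(21)
  tm <- config_transitions(cfg, "untreated")
  rw <- config_rewards(cfg)
  q <- vapply(c(0, 0.01, 0.03, 0.05, 0.1),
              function(r) run_cohort(c(1, 0, 0, 0, 0), tm, rw,
                                     discount_rate = r)$discounted_qaly_cum,
              0)
  expect_true(all(diff(q) < 0))
  # and discounted <= undiscounted <= (n+1) * max utility
  expect_lte(q[3], q[1])
  expect_lte(q[1], 31 * max(rw$utilities))
})

test_that("reward-timing conventions differ exactly by the cycle-0 share", {
  cfg <- random_scenario(33)
  tm <- config_transitions(cfg, "treated")
  rw <- config_rewards(cfg)
  r0 <- sum(c(1, 0, 0, 0, 0) * rw$utilities)
  q <- vapply(c("start", "end", "half"),
              function(tmg) run_cohort(c(1, 0, 0, 0, 0), tm, rw,
                                       timing = tmg)$discounted_qaly_cum, 0)
  expect_equal(q[["end"]], q[["start"]] - r0)
  expect_equal(q[["half"]], q[["start"]] - 0.5 * r0)
})

test_that("cohort occupancy matches a per-individual microsimulation", {
  n_ind <- 20000L
  for (seed in c(101, 102, 103)) {
    cfg <- random_scenario(seed)
    tm <- config_transitions(cfg, "untreated")
    tr <- run_cohort(c(1, 0, 0, 0, 0), tm, config_rewards(cfg),
                     n_cycles = 15)
    ms <- microsim_occupancy(tm$matrix, n_ind, 15L, seed = seed + 1000L)
    expect_matches_microsim(tr$occupancy, ms, n_ind)
  }
})

test_that("the trace exports with the standard CSV header", {
  tr <- run_cohort(c(1, 0, 0, 0, 0),
                   transition_model(progression_matrix(rep(0.2, 4))),
                   ref_rewards(), n_cycles = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  expect_identical(
    readLines(path, n = 1),
    paste0("cycle,at_risk,mild,moderate,severe,blind,",
           "cycle_cost,cycle_qaly,cum_disc_cost,cum_disc_qaly"))
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 6)
  expect_equal(df$cum_disc_qaly[6], tr$discounted_qaly_cum)
})
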