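test_that("classification expands prevalence and accuracy into joint probabilities", {
  perfect <- classify(0.03, screening_test(1, 1))
  expect_equal(perfect$p_true_positive, 0.03)
  expect_equal(perfect$p_true_negative, 0.97)
  expect_identical(perfect$p_false_positive, 0)
  expect_identical(perfect$p_false_negative, 0)

  cl <- classify(0.03, screening_test(0.865, 0.786))
  expect_equal(cl$p_true_positive, 0.025950)
  expect_equal(cl$p_false_negative, 0.004050)
  expect_equal(cl$p_false_positive, 0.207580)
  expect_equal(cl$p_true_negative, 0.762420)

  none <- classify(0, screening_test(0.9, 0.8))
  expect_identical(none$p_true_positive, 0)
  expect_identical(none$p_false_negative, 0)
  expect_equal(none$p_false_positive + none$p_true_negative, 1)

  expect_error(classify(1.2, screening_test(0.9, 0.8)), "\\[0, 1\\]")
  expect_error(screening_test(1.2, 0.8), "\\[0, 1\\]")
})

test_that("classification probabilities always sum to one", {
  set.seed(404)
  for (i in 1:50) {
    cl <- classify(runif(1), screening_test(runif(1), runif(1)))
    expect_equal(cl$p_true_positive + cl$p_false_negative +
                   cl$p_false_positive + cl$p_true_negative, 1,
                 tolerance = 1e-12)
  }
})

test_that("per-patient cost divides programme totals by patients served", {
  expect_identical(per_patient_cost(0, 300), 0)
  expect_identical(per_patient_cost(1000, 4), 250)
  tgt <- reference_targets()
  expect_equal(per_patient_cost(39904.68, tgt$capacity$teleglaucoma),
               133.0156)
  expect_error(per_patient_cost(100, 0), ">= 1")
  expect_error(per_patient_cost(-5, 10), "non-negative")
})

test_that("visit-time savings report absolute and relative reductions", {
  ts <- time_savings_report(78, 115)
  expect_equal(ts$absolute, 37)
  expect_equal(ts$relative, 100 * 37 / 115, tolerance = 1e-12)
  expect_equal(time_savings_report(60, 60)$relative, 0)
  expect_equal(time_savings_report(115, 115)$absolute, 0)
  expect_error(time_savings_report(0, 60), "positive")
})

test_that("with no disease and free screening the tree collapses to the at-risk branch", {
  cfg <- random_scenario(51)
  rw <- config_rewards(cfg)
  st <- strategy("tele", config_transitions(cfg, "treated"),
                 config_transitions(cfg, "untreated"),
                 test = screening_test(0.9, 0.8, cost_per_screen = 0),
                 confirmatory_cost = 0)
  ev <- evaluate_strategy(st, prevalence = 0, rw)
  ar <- ev$traces$true_negative
  expect_identical(ev$expected_cost, ar$discounted_cost_cum)
  expect_identical(ev$expected_qaly, ar$discounted_qaly_cum)
})

test_that("a blind, free test is exactly the no-screening comparator", {
  cfg <- random_scenario(52)
  rw <- config_rewards(cfg)
  tr_t <- config_transitions(cfg, "treated")
  tr_u <- config_transitions(cfg, "untreated")
  prev <- 0.3
  blind_test <- strategy("zero-sens", tr_t, tr_u,
                         test = screening_test(0, 0.8, cost_per_screen = 0),
                         confirmatory_cost = 0)
  comparator <- strategy("none", tr_t, tr_u, test = NULL)
  a <- evaluate_strategy(blind_test, prev, rw)
  b <- evaluate_strategy(comparator, prev, rw)
  expect_equal(a$expected_cost, b$expected_cost, tolerance = 1e-12)
  expect_equal(a$expected_qaly, b$expected_qaly, tolerance = 1e-12)
})

test_that("expected QALYs never fall as sensitivity rises (treated no faster arm)", {
  for (seed in c(61, 62, 63)) {
    cfg <- random_scenario(seed)    # generator enforces treated <= untreated
    rw <- config_rewards(cfg)
    tr_t <- config_transitions(cfg, "treated")
    tr_u <- config_transitions(cfg, "untreated")
    prev <- 0.35
    q <- vapply(seq(0, 1, by = 0.1), function(s) {
      st <- strategy("s", tr_t, tr_u, test = screening_test(s, 0.8))
      evaluate_strategy(st, prev, rw)$expected_qaly
    }, 0)
    expect_true(all(diff(q) >= -1e-12))
  }
})

test_that("strategies require transition models for both arms", {
  cfg <- random_scenario(64)
  tm <- config_transitions(cfg, "treated")
  expect_error(strategy("broken", tm, NULL), "transition_model")
  expect_error(strategy("broken", NULL, tm), "transition_model")
})
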