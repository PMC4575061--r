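test_that("method-of-moments recovers gamma and beta parameters", {
  g <- moments_to_gamma(100, 10)
  expect_equal(g$shape, 100)
  expect_equal(g$scale, 1)
  b <- moments_to_beta(0.5, 0.1)
  expect_equal(b$alpha, 12)
  expect_equal(b$beta, 12)
  # declared moments are reproduced by the distribution's formulae
  for (i in 1:20) {
    set.seed(i)
    m <- runif(1, 10, 500); se <- runif(1, 1, 50)
    g <- moments_to_gamma(m, se)
    expect_equal(g$shape * g$scale, m, tolerance = 1e-9)
    expect_equal(sqrt(g$shape) * g$scale, se, tolerance = 1e-9)
    mb <- runif(1, 0.05, 0.95)
    seb <- 0.5 * sqrt(mb * (1 - mb)) * runif(1, 0.1, 0.9)
    b <- moments_to_beta(mb, seb)
    expect_equal(b$alpha / (b$alpha + b$beta), mb, tolerance = 1e-9)
    v <- b$alpha * b$beta / ((b$alpha + b$beta)^2 * (b$alpha + b$beta + 1))
    expect_equal(sqrt(v), seb, tolerance = 1e-9)
  }
  expect_error(moments_to_beta(0.5, 0.6), "infeasible beta variance")
  expect_error(moments_to_gamma(-1, 2), "positive mean")
})

test_that("large samples reproduce the declared moments", {
  n <- 1e6
  set.seed(99)
  g <- moments_to_gamma(100, 10)
  x <- rgamma(n, shape = g$shape, scale = g$scale)
  expect_lt(abs(mean(x) - 100), 3 * 10 / sqrt(n))
  b <- moments_to_beta(0.5, 0.1)
  y <- rbeta(n, b$alpha, b$beta)
  expect_lt(abs(mean(y) - 0.5), 3 * 0.1 / sqrt(n))
})

test_that("a zero-width DSA sweep sits on the base case", {
  cfg <- random_scenario(71)
  base <- evaluate_config(cfg)$cea$icer
  dsa <- one_way_dsa(cfg, "cost_blind", relative_range = 0, grid_size = 5)
  expect_true(all(dsa$icer == base))
  expect_error(one_way_dsa(cfg, "no_such_param"), "unknown parameter")
})

test_that("a parameter used by neither strategy leaves the ICERs untouched", {
  cfg <- random_scenario(72)
  cfg <- set_param(cfg, "specificity", 1)   # no false positives
  base <- evaluate_config(cfg)$cea
  dsa <- one_way_dsa(cfg, "cost_confirmatory", 0.5, grid_size = 5)
  expect_true(all(dsa$icer == base$icer))
  expect_true(all(dsa$cer_teleglaucoma == base$strategies$cer[1]))
  expect_true(all(dsa$cer_in_person == base$strategies$cer[2]))
})

test_that("tornado widths match an independent recomputation and sort stably", {
  cfg <- random_scenario(73)
  pars <- c("cost_blind", "prevalence", "sensitivity",
            "tp_untreated_severe_blind")
  tor <- tornado(cfg, parameters = pars, relative_range = 0.2)
  expect_identical(sort(tor$parameter), sort(pars))
  expect_true(all(diff(tor$width) <= 0))
  wtp <- cfg$settings$wtp
  for (r in seq_len(nrow(tor))) {
    row <- tor[r, ]
    inc <- function(v) {
      ev <- evaluate_config(set_param(cfg, row$parameter, v))
      st <- ev$cea$strategies
      nmb(st$cost[1], st$effect[1], wtp) - nmb(st$cost[2], st$effect[2], wtp)
    }
    expect_equal(row$width, abs(inc(row$value_high) - inc(row$value_low)),
                 tolerance = 1e-9)
  }
  # order of the input parameter list does not change the result
  tor2 <- tornado(cfg, parameters = rev(pars), relative_range = 0.2)
  expect_equal(tor, tor2)
})

test_that("fixed-kind parameters get zero tornado width and rank last", {
  cfg <- random_scenario(74)
  cfg$parameters$cost_blind$dist <- "fixed"
  tor <- tornado(cfg, parameters = c("cost_blind", "prevalence"))
  expect_identical(tor$parameter[2], "cost_blind")
  expect_identical(tor$width[2], 0)
  expect_error(tornado(cfg, parameters = character(0)), "at least one")
})

test_that("degenerate distributions make the PSA collapse to the base case", {
  cfg <- random_scenario(81)
  for (nm in names(cfg$parameters)) cfg$parameters[[nm]]$dist <- "fixed"
  base <- evaluate_config(cfg)$cea$strategies
  psa <- run_psa(cfg, n_samples = 20, seed = 1)
  tele <- psa$samples[psa$samples$strategy == "teleglaucoma", ]
  inp <- psa$samples[psa$samples$strategy == "in_person", ]
  expect_true(all(tele$cost == base$cost[1]))
  expect_true(all(tele$effect == base$effect[1]))
  expect_true(all(inp$cost == base$cost[2]))
  expect_equal(psa$summary$mean_cost, base$cost)
  expect_equal(psa$summary$sd_cost, c(0, 0))
  # tele is cheaper and more effective here or not; either way CEAC is 0/1
  expect_true(all(psa$ceac$p_teleglaucoma %in% c(0, 1)))
})

test_that("PSA runs are bit-reproducible and extend without reshuffling", {
  cfg <- random_scenario(82)
  a <- run_psa(cfg, n_samples = 30, seed = 7)
  b <- run_psa(cfg, n_samples = 30, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ceac, b$ceac)
  # first draws unchanged when n grows (per-draw substreams)
  c <- run_psa(cfg, n_samples = 60, seed = 7)
  expect_identical(a$samples[a$samples$draw <= 30 &
                               a$samples$strategy == "teleglaucoma", ],
                   c$samples[c$samples$draw <= 30 &
                               c$samples$strategy == "teleglaucoma", ])
  d <- run_psa(cfg, n_samples = 30, seed = 8)
  expect_false(identical(a$samples, d$samples))
})

test_that("the CEAC is a complementary probability pair on the WTP grid", {
  cfg <- random_scenario(83)
  psa <- run_psa(cfg, n_samples = 50, seed = 3,
                 wtp_grid = seq(0, 1e5, length.out = 101))
  expect_true(all(psa$ceac$p_teleglaucoma >= 0 &
                    psa$ceac$p_teleglaucoma <= 1))
  expect_equal(psa$ceac$p_teleglaucoma + psa$ceac$p_in_person,
               rep(1, 101))
  expect_equal(nrow(psa$samples), 2 * 50)
  # summary statistics are the statistics of the stored samples
  tele <- psa$samples[psa$samples$strategy == "teleglaucoma", ]
  expect_equal(psa$summary$mean_cost[1], mean(tele$cost))
  expect_equal(psa$summary$sd_cost[1], sd(tele$cost))
})

test_that("infeasible beta moments are rejected before any sampling", {
  cfg <- random_scenario(84)
  expect_error({
    cfg$parameters$prevalence$se <- 0.9
    run_psa(cfg, n_samples = 5, seed = 1)
  }, "infeasible beta variance")
})

test_that("PSA exports write the documented CSV headers", {
  cfg <- random_scenario(85)
  psa <- run_psa(cfg, n_samples = 10, seed = 2,
                 wtp_grid = seq(0, 1e5, length.out = 11))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_psa_csv(psa, p1)
  write_ceac_csv(psa, p2)
  write_tornado_csv(tornado(cfg, parameters = c("cost_blind", "prevalence")),
                    p3)
  expect_identical(readLines(p1, n = 1), "draw,strategy,cost,effect")
  expect_identical(readLines(p2, n = 1), "wtp,p_teleglaucoma,p_in_person")
  expect_identical(readLines(p3, n = 1), "parameter,nmb_low,nmb_high,width")
})
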