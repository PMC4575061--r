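#' Generate a random but valid model configuration
#'
#' Draws a complete, validation-passing configuration for property-based
#' testing: a progressive disease with non-increasing utilities,
#' non-negative severity-increasing costs, a treated arm that progresses
#' no faster than the untreated arm, and gamma/beta uncertainty
#' distributions with feasible moments. The same seed always yields the
#' same configuration. (Calls `set.seed`, so the session RNG state is
#' advanced.)
#'
#' @param seed Integer seed.
#' @return A validated [model_config].
#' @export
#' @examples
#' cfg <- random_scenario(7)
#' evaluate_config(cfg)$cea$icer
random_scenario <- function(seed) {
  set.seed(as.integer(seed))
  r <- function(lo, hi) stats::runif(1, lo, hi)

  u_dis <- sort(stats::runif(4, 0.3, 0.95), decreasing = TRUE)
  c_ar <- r(2, 50)
  c_dis <- c_ar + cumsum(stats::runif(4, 20, 250))
  q_tr <- stats::runif(4, 0.02, 0.3)
  q_un <- pmin(q_tr + stats::runif(4, 0, 0.4), 0.95)

  beta_p <- function(value, source = "generated") {
    se <- min(0.1 * value, 0.4 * sqrt(value * (1 - value)))
    if (se <= 0 || value <= 0 || value >= 1) {
      param(value, dist = "fixed", source = source)
    } else {
      param(value, dist = "beta", se = se, source = source)
    }
  }
  gamma_p <- function(value, source = "generated") {
    param(value, dist = "gamma", se = 0.2 * value, source = source)
  }

  model_config(
    meta = list(currency = "CAD", note = sprintf("random scenario seed %d",
                                                 as.integer(seed))),
    settings = list(horizon = 30L, discount_rate = r(0, 0.06),
                    wtp = r(10000, 80000), timing = "start",
                    entry_state = "at_risk",
                    psa = list(n_samples = 100L, seed = as.integer(seed))),
    parameters = list(
      prevalence = beta_p(r(0.05, 0.6)),
      sensitivity = beta_p(r(0.6, 0.95)),
      specificity = beta_p(r(0.6, 0.95)),
      utility_at_risk = param(1.0, source = "generated"),
      utility_mild = beta_p(u_dis[1]),
      utility_moderate = beta_p(u_dis[2]),
      utility_severe = beta_p(u_dis[3]),
      utility_blind = beta_p(u_dis[4]),
      cost_at_risk = gamma_p(c_ar),
      cost_mild = gamma_p(c_dis[1]),
      cost_moderate = gamma_p(c_dis[2]),
      cost_severe = gamma_p(c_dis[3]),
      cost_blind = gamma_p(c_dis[4]),
      cost_screen_tele = gamma_p(r(20, 300)),
      cost_service_inperson = gamma_p(r(500, 4000)),
      cost_confirmatory = gamma_p(r(50, 300)),
      tp_treated_at_risk_mild = beta_p(q_tr[1]),
      tp_treated_mild_moderate = beta_p(q_tr[2]),
      tp_treated_moderate_severe = beta_p(q_tr[3]),
      tp_treated_severe_blind = beta_p(q_tr[4]),
      tp_untreated_at_risk_mild = beta_p(q_un[1]),
      tp_untreated_mild_moderate = beta_p(q_un[2]),
      tp_untreated_moderate_severe = beta_p(q_un[3]),
      tp_untreated_severe_blind = beta_p(q_un[4])
    )
  )
}
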