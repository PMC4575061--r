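#' Method-of-moments gamma parameters
#'
#' Recovers the shape/scale of a gamma distribution from its mean and
#' standard error: `shape = mean^2/var`, `scale = var/mean`. Used to give
#' cost parameters second-order (parameter-uncertainty) distributions.
#'
#' @param mean Distribution mean (> 0).
#' @param standard_error Distribution standard deviation (> 0).
#' @return List with `shape` and `scale`.
#' @export
#' @examples
#' moments_to_gamma(100, 10)  # shape 100, scale 1
moments_to_gamma <- function(mean, standard_error) {
  if (!is.numeric(mean) || mean <= 0) {
    stop("gamma requires a positive mean", call. = FALSE)
  }
  if (!is.numeric(standard_error) || standard_error <= 0) {
    stop("gamma requires a positive standard error", call. = FALSE)
  }
  v <- standard_error^2
  list(shape = mean^2 / v, scale = v / mean)
}

#' Method-of-moments beta parameters
#'
#' Recovers the alpha/beta of a beta distribution from its mean and
#' standard error. The variance must satisfy
#' `var < mean * (1 - mean)`; otherwise no beta distribution has those
#' moments and a configuration error is raised.
#'
#' @param mean Distribution mean in (0, 1).
#' @param standard_error Distribution standard deviation (> 0).
#' @return List with `alpha` and `beta`.
#' @export
#' @examples
#' moments_to_beta(0.5, 0.1)  # alpha = beta = 12
moments_to_beta <- function(mean, standard_error) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop("beta requires a mean strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(standard_error) || standard_error <= 0) {
    stop("beta requires a positive standard error", call. = FALSE)
  }
  v <- standard_error^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf(
      paste0("infeasible beta variance: se^2 = %.6g must be below ",
             "mean*(1-mean) = %.6g for mean %.6g"),
      v, mean * (1 - mean), mean), call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

# clamp a swung parameter into its feasible range: probabilities into
# [0, 1], costs to >= 0, and state utilities additionally truncated at the
# neighbouring states' utilities so the severity ordering survives a
# one-at-a-time swing
clamp_param <- function(name, value, config = NULL) {
  if (!prob_like(name)) {
    return(pmax(value, 0))
  }
  value <- pmin(pmax(value, 0), 1)
  order <- c("utility_at_risk", "utility_mild", "utility_moderate",
             "utility_severe", "utility_blind")
  i <- match(name, order)
  if (!is.na(i) && !is.null(config)) {
    if (i > 1L) value <- pmin(value, param_value(config, order[i - 1L]))
    if (i < 5L) value <- pmax(value, param_value(config, order[i + 1L]))
  }
  value
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates both strategies over a grid of values of a single
#' parameter (all other parameters held at base case), recording
#' per-strategy cost, effect and CER, and the incremental ICER
#' (teleglaucoma as reference).
#'
#' @param config A [model_config].
#' @param parameter Parameter name (see [config_parameter_table]).
#' @param relative_range Half-width of the swing as a proportion of the
#'   base value; default 0.20 (the published blindness-cost swing).
#' @param grid_size Number of grid points.
#' @return A data.frame of class `dsa_result`: `parameter`, `value`, and
#'   per-strategy `cost_*`, `effect_*`, `cer_*` columns plus `icer`.
#' @export
#' @examples
#' dsa <- one_way_dsa(reference_config(), "cost_blind")
#' plot(dsa$value, dsa$icer, type = "l")
one_way_dsa <- function(config, parameter, relative_range = 0.2,
                        grid_size = 11L) {
  if (!parameter %in% PARAM_NAMES) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  if (relative_range < 0) {
    stop("relative_range must be non-negative", call. = FALSE)
  }
  base <- param_value(config, parameter)
  grid <- clamp_param(parameter,
                      base * seq(1 - relative_range, 1 + relative_range,
                                 length.out = grid_size), config)
  rows <- lapply(grid, function(v) {
    ev <- evaluate_config(set_param(config, parameter, v))
    st <- ev$cea$strategies
    data.frame(parameter = parameter, value = v,
               cost_teleglaucoma = st$cost[1],
               effect_teleglaucoma = st$effect[1],
               cer_teleglaucoma = st$cer[1],
               cost_in_person = st$cost[2],
               effect_in_person = st$effect[2],
               cer_in_person = st$cer[2],
               icer = ev$cea$icer)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dsa_result", class(out))
  out
}

#' Tornado analysis of incremental net monetary benefit
#'
#' Swings each parameter to its low and high bound (default +/-20% of
#' the base value, probabilities clamped to \[0, 1\]) and records the
#' incremental net monetary benefit of teleglaucoma versus the
#' comparator at the given willingness to pay. Parameters whose
#' distribution kind is `fixed` are not swung and get width 0. Entries
#' are sorted by descending width.
#'
#' @param config A [model_config].
#' @param parameters Parameter names to include; default the full set.
#' @param relative_range Swing half-width as a proportion; default 0.2.
#' @param wtp Willingness to pay; default the configured value.
#' @return A data.frame of class `tornado_result`: `parameter`,
#'   `value_low`, `value_high`, `nmb_low`, `nmb_high`, `width`.
#' @export
tornado <- function(config, parameters = NULL, relative_range = 0.2,
                    wtp = NULL) {
  parameters <- parameters %||% PARAM_NAMES
  if (length(parameters) == 0) {
    stop("tornado needs at least one parameter", call. = FALSE)
  }
  bad <- setdiff(parameters, PARAM_NAMES)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  wtp <- wtp %||% config$settings$wtp

  inc_nmb <- function(cfg) {
    ev <- evaluate_config(cfg)
    st <- ev$cea$strategies
    nmb(st$cost[1], st$effect[1], wtp) - nmb(st$cost[2], st$effect[2], wtp)
  }

  rows <- lapply(parameters, function(nm) {
    e <- config$parameters[[nm]]
    if (e$dist == "fixed") {
      lo <- hi <- e$value
    } else {
      lo <- clamp_param(nm, e$value * (1 - relative_range), config)
      hi <- clamp_param(nm, e$value * (1 + relative_range), config)
    }
    n_lo <- inc_nmb(set_param(config, nm, lo))
    n_hi <- if (hi == lo) n_lo else inc_nmb(set_param(config, nm, hi))
    data.frame(parameter = nm, value_low = lo, value_high = hi,
               nmb_low = n_lo, nmb_high = n_hi,
               width = abs(n_hi - n_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", class(out))
  out
}

# deterministic per-draw substream seed: draws 1..i are unchanged when
# n_samples grows
draw_seed <- function(seed, draw) {
  as.integer((as.numeric(seed) * 7919 + draw * 104729) %% 2147483647)
}

sample_parameters <- function(config, seed, draw) {
  set.seed(draw_seed(seed, draw))
  vals <- vapply(PARAM_NAMES, function(nm) {
    e <- config$parameters[[nm]]
    if (e$dist == "fixed" || e$se == 0) {
      e$value
    } else if (e$dist == "gamma") {
      g <- moments_to_gamma(e$value, e$se)
      stats::rgamma(1L, shape = g$shape, scale = g$scale)
    } else {
      b <- moments_to_beta(e$value, e$se)
      stats::rbeta(1L, b$alpha, b$beta)
    }
  }, 0)
  # independent utility draws can invert the severity ordering; restore it
  # by sorting the five utilities decreasingly (documented convention)
  uidx <- match(c("utility_at_risk", "utility_mild", "utility_moderate",
                  "utility_severe", "utility_blind"), PARAM_NAMES)
  vals[uidx] <- sort(vals[uidx], decreasing = TRUE)
  vals
}

#' Second-order probabilistic sensitivity analysis
#'
#' Monte Carlo simulation over parameter uncertainty: for each draw, all
#' uncertain parameters are jointly redrawn from their gamma/beta
#' distributions (method-of-moments parameterisation of the configured
#' mean and standard error; parameters are sampled independently), both
#' strategies are evaluated on the same draw, and the
#' cost-effectiveness acceptability curve (CEAC) is computed over a
#' willingness-to-pay grid as the fraction of draws in which each
#' strategy has the higher net monetary benefit.
#'
#' A fixed seed reproduces the samples bit-identically; per-draw
#' substreams are derived deterministically from the seed and draw
#' index, so increasing `n_samples` does not reshuffle earlier draws.
#'
#' @param config A [model_config].
#' @param n_samples Number of Monte Carlo draws; default from the
#'   config's psa block (1000).
#' @param seed Integer seed; default from the config.
#' @param wtp_grid Willingness-to-pay grid for the CEAC; default 0 to
#'   100,000 CAD/QALY in 2,000 steps.
#' @return An object of class `psa_result`: `samples` (data.frame
#'   `draw,strategy,cost,effect`), `summary` (per-strategy mean/sd of
#'   cost and effect), `ceac` (data.frame
#'   `wtp,p_teleglaucoma,p_in_person`), `seed`, `n_samples`.
#' @export
#' @examples
#' psa <- run_psa(reference_config(), n_samples = 100)
#' psa$summary
run_psa <- function(config, n_samples = NULL, seed = NULL,
                    wtp_grid = seq(0, 1e5, length.out = 2001L)) {
  n_samples <- as.integer(n_samples %||% config$settings$psa$n_samples)
  seed <- as.integer(seed %||% config$settings$psa$seed)
  if (is.na(n_samples) || n_samples < 1L) {
    stop("n_samples must be >= 1", call. = FALSE)
  }
  validate_config(config)  # catches infeasible distributions up front

  cost <- matrix(0, n_samples, 2L,
                 dimnames = list(NULL, c("teleglaucoma", "in_person")))
  effect <- cost
  for (i in seq_len(n_samples)) {
    vals <- sample_parameters(config, seed, i)
    cfg_i <- config
    for (nm in PARAM_NAMES) {
      cfg_i$parameters[[nm]]$value <- vals[[nm]]
    }
    ev <- evaluate_config(cfg_i)
    st <- ev$cea$strategies
    cost[i, ] <- st$cost
    effect[i, ] <- st$effect
  }

  samples <- data.frame(
    draw = rep(seq_len(n_samples), 2L),
    strategy = rep(colnames(cost), each = n_samples),
    cost = c(cost[, 1], cost[, 2]),
    effect = c(effect[, 1], effect[, 2])
  )
  summary <- data.frame(
    strategy = colnames(cost),
    mean_cost = colMeans(cost),
    sd_cost = apply(cost, 2, stats::sd),
    mean_effect = colMeans(effect),
    sd_effect = apply(effect, 2, stats::sd),
    row.names = NULL
  )
  p_tele <- vapply(wtp_grid, function(l) {
    mean(l * effect[, 1] - cost[, 1] > l * effect[, 2] - cost[, 2])
  }, 0)
  ceac <- data.frame(wtp = wtp_grid, p_teleglaucoma = p_tele,
                     p_in_person = 1 - p_tele)

  structure(list(samples = samples, summary = summary, ceac = ceac,
                 seed = seed, n_samples = n_samples),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, seed %d\n", x$n_samples, x$seed))
  print(transform(x$summary,
                  mean_cost = round(mean_cost, 2),
                  sd_cost = round(sd_cost, 2),
                  mean_effect = round(mean_effect, 4),
                  sd_effect = round(sd_effect, 4)), row.names = FALSE)
  invisible(x)
}

#' Export PSA samples, CEAC and tornado tables as CSV
#'
#' @param x A [run_psa] or [tornado] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(x, path) {
  stopifnot(inherits(x, "psa_result"))
  utils::write.csv(x$samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_psa_csv
#' @export
write_ceac_csv <- function(x, path) {
  stopifnot(inherits(x, "psa_result"))
  utils::write.csv(x$ceac, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_psa_csv
#' @export
write_tornado_csv <- function(x, path) {
  stopifnot(inherits(x, "tornado_result"))
  utils::write.csv(x[, c("parameter", "nmb_low", "nmb_high", "width")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
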