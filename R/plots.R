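#' Plot a cohort trace
#'
#' State-occupancy probabilities over the model horizon, one line per
#' health state.
#'
#' @param trace A [run_cohort] result.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  df <- as.data.frame(trace)
  long <- do.call(rbind, lapply(health_states(), function(s) {
    data.frame(cycle = df$cycle, state = s, probability = df[[s]])
  }))
  long$state <- factor(long$state, levels = health_states())
  ggplot2::ggplot(long, ggplot2::aes(cycle, probability, colour = state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle (years)", y = "state occupancy",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param psa A [run_psa] result.
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  df <- rbind(
    data.frame(wtp = psa$ceac$wtp, strategy = "teleglaucoma",
               probability = psa$ceac$p_teleglaucoma),
    data.frame(wtp = psa$ceac$wtp, strategy = "in_person",
               probability = psa$ceac$p_in_person)
  )
  ggplot2::ggplot(df, ggplot2::aes(wtp, probability, colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "willingness to pay (CAD/QALY)",
                  y = "probability cost-effective") +
    ggplot2::theme_minimal()
}

#' Plot the PSA cost-effectiveness scatter
#'
#' @param psa A [run_psa] result.
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  ggplot2::ggplot(psa$samples,
                  ggplot2::aes(effect, cost, colour = strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "effect (QALY)", y = "cost (CAD)") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the incremental net-monetary-benefit range of
#' each swung parameter, widest on top.
#'
#' @param tor A [tornado] result.
#' @param top Show only the `top` widest parameters; default all.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tor, top = NULL) {
  stopifnot(inherits(tor, "tornado_result"))
  df <- as.data.frame(tor)
  if (!is.null(top)) df <- df[seq_len(min(top, nrow(df))), ]
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  df$lo <- pmin(df$nmb_low, df$nmb_high)
  df$hi <- pmax(df$nmb_low, df$nmb_high)
  ggplot2::ggplot(df, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi, yend = parameter),
                          linewidth = 3, colour = "steelblue") +
    ggplot2::labs(x = "incremental NMB (CAD), teleglaucoma vs in-person",
                  y = NULL) +
    ggplot2::theme_minimal()
}
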