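#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes incremental cost and effect of the comparator relative to the
#' reference strategy, the incremental cost-effectiveness ratio (ICER),
#' per-strategy average cost-effectiveness ratios (CER = cost/effect), and
#' a dominance classification. The ICER is reported from the reference
#' strategy's perspective: a negative ICER with positive incremental
#' effect for the reference means the reference saves money per QALY
#' gained, and the comparator is dominated.
#'
#' Note the field naming: `incremental_cost` and `incremental_effect` are
#' comparator minus reference (the orientation of the comparator row of a
#' summary table); `icer = incremental_cost / incremental_effect` is
#' identical to the reference-perspective ratio
#' `(ref_cost - comp_cost) / (ref_effect - comp_effect)`.
#'
#' @param ref_cost,ref_effect Cost (CAD) and effect (QALY) of the
#'   reference strategy.
#' @param comp_cost,comp_effect Cost and effect of the comparator.
#' @param ref_name,comp_name Strategy labels.
#' @return An object of class `cea_result` with fields `strategies`
#'   (data.frame: name, cost, effect, cer), `incremental_cost`,
#'   `incremental_effect`, `icer` (`NA` when the incremental effect is
#'   zero), `icer_defined`, and `dominance` -- `"dominated"` when the
#'   comparator is dominated (reference cheaper and more effective),
#'   `"dominant"` when the comparator dominates, otherwise `"none"`.
#' @export
#' @examples
#' icer(871.54, 18.32, 4441.42, 18.19)
icer <- function(ref_cost, ref_effect, comp_cost, comp_effect,
                 ref_name = "reference", comp_name = "comparator") {
  vals <- c(ref_cost, ref_effect, comp_cost, comp_effect)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("costs and effects must be finite numbers", call. = FALSE)
  }
  d_cost <- comp_cost - ref_cost
  d_eff <- comp_effect - ref_effect
  defined <- d_eff != 0
  ratio <- if (defined) d_cost / d_eff else NA_real_
  dominance <- if (d_cost > 0 && d_eff < 0) {
    "dominated"
  } else if (d_cost < 0 && d_eff > 0) {
    "dominant"
  } else {
    "none"
  }
  structure(list(
    strategies = data.frame(
      name = c(ref_name, comp_name),
      cost = c(ref_cost, comp_cost),
      effect = c(ref_effect, comp_effect),
      cer = c(ref_cost, comp_cost) / c(ref_effect, comp_effect)
    ),
    incremental_cost = d_cost,
    incremental_effect = d_eff,
    icer = ratio,
    icer_defined = defined,
    dominance = dominance
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  print(transform(x$strategies, cer = round(cer, 2)))
  cat(sprintf("incremental cost %.2f, incremental effect %.4f (comparator - reference)\n",
              x$incremental_cost, x$incremental_effect))
  if (x$icer_defined) {
    cat(sprintf("ICER %.2f CAD/QALY", x$icer))
  } else {
    cat("ICER undefined (zero incremental effect)")
  }
  if (x$dominance != "none") {
    cat(sprintf("  [comparator %s]", x$dominance))
  }
  cat("\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = WTP x effect - cost`. At a given willingness to pay, the
#' strategy with the larger NMB is the one the ICER threshold rule
#' selects.
#'
#' @param cost Cost (CAD); vectorised.
#' @param effect Effect (QALY); vectorised.
#' @param wtp Willingness to pay (CAD per QALY, >= 0).
#' @return Net monetary benefit in CAD.
#' @export
#' @examples
#' nmb(871.54, 18.32, 40000)
nmb <- function(cost, effect, wtp) {
  if (!is.numeric(wtp) || any(!is.finite(wtp)) || any(wtp < 0)) {
    stop("willingness to pay must be non-negative", call. = FALSE)
  }
  wtp * effect - cost
}

#' Export a CEA result as a JSON report
#'
#' @param result A [icer] result.
#' @param path Output file path.
#' @param wtp Willingness to pay at which per-strategy NMB is reported.
#' @return `path`, invisibly.
#' @export
write_cea_json <- function(result, path, wtp = 40000) {
  stopifnot(inherits(result, "cea_result"))
  out <- list(
    strategies = transform(result$strategies,
                           nmb = nmb(cost, effect, wtp)),
    incremental = list(cost = result$incremental_cost,
                       effect = result$incremental_effect,
                       icer = result$icer,
                       icer_defined = result$icer_defined,
                       dominance = result$dominance),
    wtp = wtp
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
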