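#' Classify the cost-effectiveness quadrant
#'
#' Labels the position of the intervention relative to the comparator on
#' the cost-effectiveness plane:
#' * `intervention_dominant` — cheaper and at least as effective (or equally
#'   cheap and strictly more effective): no willingness-to-pay deliberation
#'   needed.
#' * `comparator_dominant` — the mirror case.
#' * `tradeoff_ne` — costlier and more effective (north-east quadrant):
#'   adoption depends on willingness to pay.
#' * `tradeoff_sw` — cheaper and less effective (south-west quadrant).
#' * `equivalent` — both deltas zero.
#'
#' Ties (one delta exactly zero) resolve toward dominance when the other
#' delta is favourable.
#'
#' @param delta_cost Incremental cost (intervention minus comparator), Euro.
#' @param delta_effect Incremental effectiveness.
#' @return One of the five labels above.
#' @examples
#' classify_dominance(-133.25, 0.0106)  # "intervention_dominant"
#' classify_dominance(100, 0.05)        # "tradeoff_ne"
#' @export
classify_dominance <- function(delta_cost, delta_effect) {
  stopifnot(is.numeric(delta_cost), is.numeric(delta_effect),
            length(delta_cost) == 1, length(delta_effect) == 1)
  if (delta_cost == 0 && delta_effect == 0) return("equivalent")
  if (delta_cost <= 0 && delta_effect >= 0) return("intervention_dominant")
  if (delta_cost >= 0 && delta_effect <= 0) return("comparator_dominant")
  if (delta_cost > 0) "tradeoff_ne" else "tradeoff_sw"
}

#' Incremental cost-effectiveness analysis of two strategy valuations
#'
#' Computes incremental cost, incremental effectiveness, the incremental
#' cost-effectiveness ratio (ICER) and the dominance label. The ICER is
#' `delta_cost / delta_effect`, computed from unrounded inputs — the
#' published ratio is only reproduced this way — and is `NA` when
#' `delta_effect` is zero (no exception: the dominance label carries the
#' decision). A negative ICER is reported numerically but is not directly
#' interpretable; decisions rest on the quadrant.
#'
#' @param intervention,comparator Valuations: anything with `$cost` and
#'   `$effect` (a one-row data.frame row from [rollback()], or a list).
#' @return An object of class `wcea_incremental`: a list with
#'   `delta_cost`, `delta_effect`, `icer`, `dominance`.
#' @examples
#' bc <- rollback(paper_scenario())
#' incremental_analysis(bc[1, ], bc[2, ])
#' @export
incremental_analysis <- function(intervention, comparator) {
  dc <- intervention$cost - comparator$cost
  de <- intervention$effect - comparator$effect
  structure(
    list(delta_cost = dc, delta_effect = de,
         icer = if (de != 0) dc / de else NA_real_,
         dominance = classify_dominance(dc, de)),
    class = "wcea_incremental")
}

#' @export
print.wcea_incremental <- function(x, ...) {
  cat("<wcea_incremental>\n")
  cat(sprintf("  delta cost:    %.2f\n", x$delta_cost))
  cat(sprintf("  delta effect:  %.4f\n", x$delta_effect))
  cat(sprintf("  ICER:          %s\n",
              if (is.na(x$icer)) "undefined (delta effect = 0)"
              else sprintf("%.2f", x$icer)))
  cat(sprintf("  dominance:     %s\n", x$dominance))
  invisible(x)
}

#' Net monetary benefit of a valuation
#'
#' `NMB = wtp * effect - cost` at willingness-to-pay `wtp` per unit of
#' effectiveness. The strategy with the higher NMB at a given `wtp` is the
#' cost-effective one; this is the decision rule behind the acceptability
#' curve. Vectorised over `wtp`.
#'
#' @param valuation Anything with `$cost` and `$effect`.
#' @param wtp Willingness to pay, Euro per unit effectiveness (>= 0).
#' @return NMB in Euro, same length as `wtp`.
#' @examples
#' net_monetary_benefit(list(cost = 749.80, effect = 0.6068), 10000)
#' @export
net_monetary_benefit <- function(valuation, wtp) {
  if (any(wtp < 0)) stop("willingness to pay must be >= 0", call. = FALSE)
  wtp * valuation$effect - valuation$cost
}

#' Base-case analysis of a scenario
#'
#' Rolls back the decision tree at baselines and runs the incremental
#' analysis, producing the headline results table: per-strategy cost and
#' healing rate, incremental cost and effectiveness, ICER and dominance.
#'
#' @param scn A [scenario()].
#' @return An object of class `wcea_base_case`: list with `arms` (the
#'   [rollback()] data.frame), `incremental` (a `wcea_incremental`) and
#'   `currency`.
#' @examples
#' base_case(paper_scenario())
#' @export
base_case <- function(scn) {
  arms <- rollback(scn)
  structure(
    list(arms = arms,
         incremental = incremental_analysis(arms[1, ], arms[2, ]),
         currency = scn$currency),
    class = "wcea_base_case")
}

#' @export
print.wcea_base_case <- function(x, ...) {
  cat(sprintf("Base-case results (costs in %s)\n", x$currency))
  a <- x$arms
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-10s cost %8.2f   healing rate %.4f\n",
                a$strategy[i], a$cost[i], a$effect[i]))
  }
  inc <- x$incremental
  cat(sprintf("  incremental cost %.2f, incremental healing %.4f\n",
              inc$delta_cost, inc$delta_effect))
  cat(sprintf("  ICER %s   [%s]\n",
              if (is.na(inc$icer)) "undefined" else sprintf("%.2f", inc$icer),
              inc$dominance))
  invisible(x)
}
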