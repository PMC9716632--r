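#' One-way deterministic sensitivity analysis
#'
#' Re-runs the model once per parameter with that parameter set to its low
#' and then its high OWSA bound, all others held at baseline. The outcome
#' per evaluation is the incremental net monetary benefit of the
#' intervention at `reference_wtp`:
#' `wtp * delta_effect - delta_cost`, which at the default `reference_wtp
#' = 0` equals minus the incremental cost. The incremental NMB is used
#' rather than the ICER because wide healing-rate ranges can flip the sign
#' of `delta_effect` and make the ratio explode; NMB stays bounded and
#' monotone in each cost parameter.
#'
#' Note that at `reference_wtp = 0` the healing-rate rows have zero width
#' by construction (effects do not enter costs), and a shared change tariff
#' cancels out of the incremental cost whenever both arms use the same
#' baseline number of units per week.
#'
#' @param scn A [scenario()].
#' @param reference_wtp Willingness to pay at which incremental NMB is
#'   evaluated, Euro per unit effectiveness (default 0).
#' @return A data.frame of class `wcea_owsa`, one row per parameter, with
#'   columns `parameter`, `low`, `high`, `outcome_low`, `outcome_high`,
#'   `width` (`= |outcome_high - outcome_low|`).
#' @examples
#' run_owsa(paper_scenario())
#' @seealso [tornado_table()]
#' @export
run_owsa <- function(scn, reference_wtp = 0) {
  stopifnot(inherits(scn, "wcea_scenario"))
  if (reference_wtp < 0)
    stop("reference_wtp must be >= 0", call. = FALSE)
  params <- scenario_parameters(scn)
  inmb_at <- function(name, value) {
    ov <- stats::setNames(list(value), name)
    arms <- rollback(scn, ov)
    inc <- incremental_analysis(arms[1, ], arms[2, ])
    reference_wtp * inc$delta_effect - inc$delta_cost
  }
  rows <- lapply(params, function(p) {
    lo_out <- inmb_at(p$name, p$owsa_low)
    hi_out <- inmb_at(p$name, p$owsa_high)
    data.frame(parameter = p$name, low = p$owsa_low, high = p$owsa_high,
               outcome_low = lo_out, outcome_high = hi_out,
               width = abs(hi_out - lo_out))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "reference_wtp") <- reference_wtp
  class(out) <- c("wcea_owsa", "data.frame")
  out
}

#' Tornado-ranked sensitivity table
#'
#' Sorts OWSA rows by outcome range (widest first), the ordering of the
#' bars in a tornado diagram. The sort is stable with ties broken by
#' parameter name, lexicographically.
#'
#' @param rows A data.frame from [run_owsa()] (or any data.frame with
#'   `parameter` and `width` columns).
#' @return The rows reordered by decreasing `width`.
#' @examples
#' tornado_table(run_owsa(paper_scenario()))
#' @export
tornado_table <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("tornado_table requires a non-empty OWSA table", call. = FALSE)
  out <- rows[order(-rows$width, rows$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}
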