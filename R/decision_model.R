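# The decision tree has one decision node (choice of dressing strategy) and,
# per strategy, one chance node splitting into healed / not healed at the end
# of the horizon. Cost is identical across the two branches of each chance
# node — dressings and dressing changes accrue for the full horizon whether
# or not the wound heals — so rollback reduces to: expected cost = the
# deterministic costing formula, expected effect = the healing probability.

#' Weekly cost of a dressing strategy
#'
#' Each dressing unit applied in a week is one billed application: the unit
#' price of the dressing plus the home-care tariff for the dressing change.
#' Weekly cost is therefore `units_per_week * (unit_price + change_tariff)`.
#'
#' Vectorised over all three arguments.
#'
#' @param units_per_week Dressings applied per week (>= 0).
#' @param unit_price Price per dressing unit, Euro (>= 0).
#' @param change_tariff Tariff per dressing change, Euro (>= 0).
#' @return Weekly cost in Euro.
#' @examples
#' weekly_cost(2, 19.075, 12.1667)  # 62.4834
#' @export
weekly_cost <- function(units_per_week, unit_price, change_tariff) {
  if (any(units_per_week < 0) || any(unit_price < 0) || any(change_tariff < 0))
    stop("units, prices and tariffs must be >= 0", call. = FALSE)
  units_per_week * (unit_price + change_tariff)
}

#' Expected cost of a strategy arm over the horizon
#'
#' Weekly cost multiplied by the number of weeks in the horizon. No
#' discounting is applied: the horizon is under one year. Full floating
#' precision is retained; rounding happens only at reporting.
#'
#' @param arm A [strategy_arm()], evaluated at its baselines.
#' @param change_tariff Tariff per dressing change, Euro.
#' @param horizon_weeks Horizon length in weeks (>= 1).
#' @return Total expected cost in Euro.
#' @examples
#' scn <- paper_scenario()
#' strategy_cost(scn$intervention, 12.1667, 12)  # 749.8008
#' @export
strategy_cost <- function(arm, change_tariff, horizon_weeks) {
  stopifnot(inherits(arm, "wcea_arm"), horizon_weeks >= 1)
  horizon_weeks * weekly_cost(arm$units_per_week$baseline,
                              arm$unit_price$baseline, change_tariff)
}

#' Complete-healing rate from pooled counts
#'
#' The effectiveness endpoint is the proportion of patients with complete
#' healing at the end of the horizon, pooled across trials:
#' `healed / total`. The built-in scenario's intervention rate derives from
#' 125 healed of 206 treated (0.6068); the comparator counts 148 of 254
#' give 0.5827, though the published analysis carries 0.5962 for that arm.
#'
#' @param healed Number of patients completely healed (>= 0, integer).
#' @param total Total number of patients treated (> 0, integer).
#' @return Healing probability in `[0, 1]`.
#' @examples
#' healing_rate_from_counts(125, 206)  # 0.6068 to 4 dp
#' healing_rate_from_counts(148, 254)  # 0.5827 to 4 dp
#' @export
healing_rate_from_counts <- function(healed, total) {
  if (!is.numeric(healed) || !is.numeric(total) ||
      healed != round(healed) || total != round(total))
    stop("counts must be integers", call. = FALSE)
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (healed < 0 || healed > total)
    stop("healed must lie in [0, total]", call. = FALSE)
  healed / total
}

#' Roll back the decision tree to per-strategy expected values
#'
#' Evaluates both strategies at their baseline parameter values, optionally
#' overriding named parameters (the mechanism used by OWSA and PSA). Cost is
#' outcome-independent (see module note above), so each arm's valuation is
#' its horizon cost paired with its healing probability.
#'
#' @param scn A [scenario()].
#' @param overrides Optional named list/vector mapping parameter names (see
#'   [scenario_parameters()]) to replacement values. Unknown names are an
#'   error.
#' @return A data.frame with columns `strategy`, `cost`, `effect` and one
#'   row per strategy (intervention first).
#' @examples
#' rollback(paper_scenario())
#' rollback(paper_scenario(), list(units_per_week_Silver = 5))
#' @export
rollback <- function(scn, overrides = NULL) {
  stopifnot(inherits(scn, "wcea_scenario"))
  vals <- scenario_baselines(scn)
  if (length(overrides)) {
    ov <- unlist(overrides)
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("overrides must be named", call. = FALSE)
    unknown <- setdiff(names(ov), names(vals))
    if (length(unknown))
      stop(sprintf("unknown parameter(s) in overrides: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    vals[names(ov)] <- ov
  }
  arm_valuation <- function(arm) {
    cost <- scn$horizon_weeks * weekly_cost(
      vals[[arm$units_per_week$name]],
      vals[[arm$unit_price$name]],
      vals[[scn$change_tariff$name]])
    effect <- vals[[arm$healing_rate$name]]
    if (effect < 0 || effect > 1)
      stop(sprintf("healing rate override for arm '%s' outside [0, 1]",
                   arm$name), call. = FALSE)
    c(cost = cost, effect = effect)
  }
  vi <- arm_valuation(scn$intervention)
  vc <- arm_valuation(scn$comparator)
  data.frame(strategy = c(scn$intervention$name, scn$comparator$name),
             cost = c(vi[["cost"]], vc[["cost"]]),
             effect = c(vi[["effect"]], vc[["effect"]]))
}
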