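# Synthetic two-strategy scenarios with analytically known ground truth.
# Unlike the built-in published scenario — whose PSA distributions are kept
# exactly as printed and are NOT centred on the baselines — generated
# scenarios moment-match every PSA distribution to its baseline, so
# closed-form expectations are exact and parameter-recovery tests are clean.

#' Generate a random scenario with known analytic truth
#'
#' Draws baseline prices, units per week, healing rates and a shared tariff
#' uniformly from the stated ranges, builds OWSA bounds bracketing each
#' baseline, attaches moment-matched PSA distributions (gamma for prices
#' and tariff, binomial over 8 trials for units, beta with concentration 5
#' for rates), and returns the scenario together with closed-form expected
#' costs/effects and the baseline dominance label.
#'
#' @param seed Optional integer seed for reproducibility.
#' @param price_range Unit-price range in Euro (both > 0).
#' @param units_range Integer range of units per week (within 1..8, so a
#'   binomial over 8 trials can be centred on the baseline).
#' @param rate_range Healing-rate range, strictly inside (0, 1).
#' @param tariff_range Change-tariff range in Euro (both > 0).
#' @param horizon_weeks Positive integer horizon.
#' @return An object of class `wcea_truth`: list with `scenario`,
#'   `expected_cost` and `expected_effect` (named numeric, intervention and
#'   comparator), and `dominance_at_baseline`.
#' @examples
#' truth <- generate_scenario(seed = 7)
#' truth$expected_cost
#' @export
generate_scenario <- function(seed = NULL,
                              price_range = c(5, 50),
                              units_range = c(1, 4),
                              rate_range = c(0.05, 0.95),
                              tariff_range = c(5, 20),
                              horizon_weeks = 12L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  ok_range <- function(r) is.numeric(r) && length(r) == 2 && !anyNA(r) &&
    r[1] <= r[2]
  if (!ok_range(price_range) || price_range[1] <= 0)
    stop("price_range must be positive and increasing", call. = FALSE)
  if (!ok_range(tariff_range) || tariff_range[1] <= 0)
    stop("tariff_range must be positive and increasing", call. = FALSE)
  if (!ok_range(rate_range) || rate_range[1] <= 0 || rate_range[2] >= 1)
    stop("rate_range must lie strictly inside (0, 1)", call. = FALSE)
  if (!ok_range(units_range) || units_range[1] < 1 || units_range[2] > 8 ||
      any(units_range != round(units_range)))
    stop("units_range must be integers within 1..8", call. = FALSE)

  make_arm <- function(arm_name) {
    price <- stats::runif(1, price_range[1], price_range[2])
    units <- sample(units_range[1]:units_range[2], 1)
    rate <- stats::runif(1, rate_range[1], rate_range[2])
    strategy_arm(
      arm_name,
      unit_price = parameter_spec(
        paste0("unit_price_", arm_name), "unit_price", price,
        price * 0.95, price * 1.05, moment_match_gamma(price, price / 400)),
      units_per_week = parameter_spec(
        paste0("units_per_week_", arm_name), "units_per_week", units,
        units, units + 1, dist_spec("binomial", c(8, units / 8))),
      healing_rate = parameter_spec(
        paste0("healing_rate_", arm_name), "healing_rate", rate,
        max(0, rate - 0.1), min(1, rate + 0.1),
        dist_spec("beta", c(rate * 5, (1 - rate) * 5))))
  }
  arm_i <- make_arm("A")
  arm_c <- make_arm("B")
  tariff_val <- stats::runif(1, tariff_range[1], tariff_range[2])
  tariff <- parameter_spec(
    "change_tariff", "change_tariff", tariff_val,
    tariff_val * 0.95, tariff_val * 1.05,
    moment_match_gamma(tariff_val, tariff_val / 50))
  scn <- scenario(arm_i, arm_c, tariff, horizon_weeks = horizon_weeks,
                  currency = "synthetic Euro")

  ec <- c(intervention = analytic_expected_cost(arm_i, tariff, horizon_weeks),
          comparator = analytic_expected_cost(arm_c, tariff, horizon_weeks))
  ee <- c(intervention = dist_mean(arm_i$healing_rate$dist),
          comparator = dist_mean(arm_c$healing_rate$dist))
  structure(
    list(scenario = scn, expected_cost = ec, expected_effect = ee,
         dominance_at_baseline = classify_dominance(
           ec[["intervention"]] - ec[["comparator"]],
           ee[["intervention"]] - ee[["comparator"]])),
    class = "wcea_truth")
}

#' Closed-form expected cost of an arm under its PSA distributions
#'
#' By independence of units, price and tariff draws, the expected horizon
#' cost factorises:
#' `E[cost] = horizon * E[units] * (E[price] + E[tariff])`,
#' with each expectation taken analytically via [dist_mean()]. This is the
#' oracle the Monte-Carlo mean is tested against.
#'
#' @param arm A [strategy_arm()].
#' @param change_tariff The shared tariff: a [parameter_spec()] or a bare
#'   [dist_spec()].
#' @param horizon_weeks Positive integer horizon.
#' @return Expected cost in Euro.
#' @examples
#' scn <- paper_scenario()
#' analytic_expected_cost(scn$intervention, scn$change_tariff, 12)
#' @export
analytic_expected_cost <- function(arm, change_tariff, horizon_weeks) {
  stopifnot(inherits(arm, "wcea_arm"), horizon_weeks >= 1)
  tariff_dist <- if (inherits(change_tariff, "wcea_param"))
    change_tariff$dist else change_tariff
  stopifnot(inherits(tariff_dist, "wcea_dist"))
  horizon_weeks * dist_mean(arm$units_per_week$dist) *
    (dist_mean(arm$unit_price$dist) + dist_mean(tariff_dist))
}

#' Point-mass scenario hitting exact target valuations
#'
#' Builds a scenario whose every distribution is a point mass, chosen so
#' the two arms take exactly the given (cost, effect) pairs: units fixed at
#' 1 per week, tariff fixed at 0, unit price set to
#' `cost / horizon_weeks`. The PSA of such a scenario degenerates to the
#' base case, which makes it the brute-force oracle for acceptability
#' curves (probability 1 / 0 / 0.5 under strict dominance / the mirror /
#' exact equivalence).
#'
#' @param cost_i,cost_c Target 12-week costs, Euro (>= 0).
#' @param effect_i,effect_c Target healing probabilities in `[0, 1]`.
#' @param horizon_weeks Positive integer horizon (default 12).
#' @return A [scenario()] with arms named `"A"` (intervention) and `"B"`.
#' @examples
#' scn <- degenerate_scenario(700, 0.6, 900, 0.5)
#' rollback(scn)
#' @export
degenerate_scenario <- function(cost_i, effect_i, cost_c, effect_c,
                                horizon_weeks = 12L) {
  vals <- c(cost_i = cost_i, effect_i = effect_i,
            cost_c = cost_c, effect_c = effect_c)
  if (!is.numeric(vals) || anyNA(vals))
    stop("all targets must be numbers", call. = FALSE)
  if (cost_i < 0 || cost_c < 0)
    stop("target costs must be >= 0", call. = FALSE)
  if (effect_i < 0 || effect_i > 1 || effect_c < 0 || effect_c > 1)
    stop("target effects must lie in [0, 1]", call. = FALSE)
  fixed_param <- function(name, role, value) {
    parameter_spec(name, role, value, value, value,
                   dist_spec("fixed", value))
  }
  make_arm <- function(arm_name, cost, effect) {
    strategy_arm(
      arm_name,
      unit_price = fixed_param(paste0("unit_price_", arm_name), "unit_price",
                               cost / horizon_weeks),
      units_per_week = fixed_param(paste0("units_per_week_", arm_name),
                                   "units_per_week", 1),
      healing_rate = fixed_param(paste0("healing_rate_", arm_name),
                                 "healing_rate", effect))
  }
  scenario(make_arm("A", cost_i, effect_i), make_arm("B", cost_c, effect_c),
           fixed_param("change_tariff", "change_tariff", 0),
           horizon_weeks = horizon_weeks, currency = "synthetic Euro")
}
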