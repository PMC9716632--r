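#' Model parameter with baseline, sensitivity range and PSA distribution
#'
#' One model input: its point estimate (baseline), the low/high bounds swept
#' by one-way sensitivity analysis (OWSA), and the distribution sampled in
#' probabilistic sensitivity analysis (PSA).
#'
#' @param name Identifier, unique within a scenario.
#' @param role One of `"unit_price"`, `"units_per_week"`, `"healing_rate"`,
#'   `"change_tariff"`.
#' @param baseline Point estimate (Euro for prices and the tariff, a count
#'   for units per week, a probability for healing rates).
#' @param owsa_low,owsa_high OWSA bounds; must bracket the baseline.
#' @param dist A [dist_spec()] giving the PSA distribution.
#' @return An object of class `wcea_param`.
#' @export
parameter_spec <- function(name, role, baseline, owsa_low, owsa_high, dist) {
  role <- match.arg(role,
    c("unit_price", "units_per_week", "healing_rate", "change_tariff"))
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("parameter name must be a non-empty string", call. = FALSE)
  for (v in c(baseline = baseline, owsa_low = owsa_low, owsa_high = owsa_high)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop(sprintf("parameter '%s': baseline and OWSA bounds must be numbers",
                   name), call. = FALSE)
  }
  if (owsa_low > baseline || baseline > owsa_high)
    stop(sprintf(
      "parameter '%s': OWSA bounds must bracket the baseline (low %g <= baseline %g <= high %g)",
      name, owsa_low, baseline, owsa_high), call. = FALSE)
  if (role == "healing_rate") {
    if (owsa_low < 0 || owsa_high > 1 || baseline < 0 || baseline > 1)
      stop(sprintf(
        "parameter '%s': healing rates and their OWSA bounds must lie in [0, 1]",
        name), call. = FALSE)
  } else if (owsa_low < 0) {
    stop(sprintf("parameter '%s': prices and units must be >= 0", name),
         call. = FALSE)
  }
  if (!inherits(dist, "wcea_dist"))
    stop(sprintf("parameter '%s': dist must be a dist_spec()", name),
         call. = FALSE)
  structure(
    list(name = name, role = role, baseline = baseline,
         owsa_low = owsa_low, owsa_high = owsa_high, dist = dist),
    class = "wcea_param")
}

#' Treatment strategy arm
#'
#' Bundles the three arm-specific parameters of one dressing strategy:
#' unit price, units applied per week, and 12-week complete-healing
#' probability.
#'
#' @param name Strategy label (e.g. `"HA"`).
#' @param unit_price,units_per_week,healing_rate [parameter_spec()] objects
#'   with the matching roles.
#' @return An object of class `wcea_arm`.
#' @export
strategy_arm <- function(name, unit_price, units_per_week, healing_rate) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("strategy name must be a non-empty string", call. = FALSE)
  roles <- list(unit_price = unit_price, units_per_week = units_per_week,
                healing_rate = healing_rate)
  for (r in names(roles)) {
    p <- roles[[r]]
    if (!inherits(p, "wcea_param"))
      stop(sprintf("arm '%s': %s must be a parameter_spec()", name, r),
           call. = FALSE)
    if (p$role != r)
      stop(sprintf("arm '%s': parameter '%s' has role '%s', expected '%s'",
                   name, p$name, p$role, r), call. = FALSE)
  }
  structure(c(list(name = name), roles), class = "wcea_arm")
}

#' Two-strategy cost-effectiveness scenario
#'
#' The unit of analysis: an intervention arm, a comparator arm, one shared
#' dressing-change tariff applied to both arms, and the time horizon in
#' weeks. The tariff is shared because it is a single payer-negotiated price
#' per change, independent of the dressing chosen.
#'
#' @param intervention,comparator [strategy_arm()] objects with distinct
#'   names.
#' @param change_tariff A [parameter_spec()] with role `"change_tariff"`.
#' @param horizon_weeks Positive integer time horizon (default 12).
#' @param currency Currency label carried into reports.
#' @return An object of class `wcea_scenario`.
#' @seealso [paper_scenario()] for the built-in published scenario,
#'   [load_scenario()] / [write_scenario()] for JSON I/O.
#' @export
scenario <- function(intervention, comparator, change_tariff,
                     horizon_weeks = 12L, currency = "2021 Euro") {
  if (!inherits(intervention, "wcea_arm") || !inherits(comparator, "wcea_arm"))
    stop("intervention and comparator must be strategy_arm() objects",
         call. = FALSE)
  if (identical(intervention$name, comparator$name))
    stop("the two strategies must have distinct names", call. = FALSE)
  if (!inherits(change_tariff, "wcea_param") ||
      change_tariff$role != "change_tariff")
    stop("change_tariff must be a parameter_spec() with role 'change_tariff'",
         call. = FALSE)
  if (!is.numeric(horizon_weeks) || length(horizon_weeks) != 1 ||
      is.na(horizon_weeks) || horizon_weeks < 1 ||
      horizon_weeks != round(horizon_weeks))
    stop("horizon_weeks must be a positive integer", call. = FALSE)
  scn <- structure(
    list(intervention = intervention, comparator = comparator,
         change_tariff = change_tariff,
         horizon_weeks = as.integer(horizon_weeks), currency = currency),
    class = "wcea_scenario")
  nm <- names(scenario_parameters(scn))
  if (anyDuplicated(nm))
    stop(sprintf("duplicate parameter name(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  scn
}

#' All parameters of a scenario as a named list
#'
#' Returns the seven [parameter_spec()]s (three per arm plus the shared
#' tariff) keyed by parameter name, in a fixed documented order:
#' intervention price, units, healing; comparator price, units, healing;
#' change tariff.
#'
#' @param scn A [scenario()].
#' @return Named list of `wcea_param` objects.
#' @export
scenario_parameters <- function(scn) {
  stopifnot(inherits(scn, "wcea_scenario"))
  ps <- list(
    scn$intervention$unit_price, scn$intervention$units_per_week,
    scn$intervention$healing_rate,
    scn$comparator$unit_price, scn$comparator$units_per_week,
    scn$comparator$healing_rate,
    scn$change_tariff)
  names(ps) <- vapply(ps, `[[`, "", "name")
  ps
}

#' Baseline values of all scenario parameters
#'
#' @param scn A [scenario()].
#' @return Named numeric vector of baselines, in [scenario_parameters()]
#'   order.
#' @export
scenario_baselines <- function(scn) {
  vapply(scenario_parameters(scn), `[[`, numeric(1), "baseline")
}

#' @export
print.wcea_scenario <- function(x, ...) {
  cat(sprintf("<wcea_scenario> %s vs %s, %d-week horizon (%s)\n",
              x$intervention$name, x$comparator$name, x$horizon_weeks,
              x$currency))
  b <- scenario_baselines(x)
  for (nm in names(b)) cat(sprintf("  %-28s %g\n", nm, b[[nm]]))
  invisible(x)
}

#' Built-in published scenario: hyaluronic-acid vs silver dressings
#'
#' The analysed scenario exactly as printed in its source: hyaluronic-acid
#' (HA) dressings as intervention versus silver-containing dressings as
#' comparator, German statutory-health-insurance prices in 2021 Euro, a
#' 12-week horizon.
#'
#' Parameter registry (baseline, OWSA range, PSA distribution):
#' * HA unit price 19.0750 Euro, +/- 5%, gamma(scale 0.0477, shape 400)
#' * Silver unit price 24.6270 Euro, +/- 5%, gamma(scale 0.0616, shape 400)
#' * HA units/week 2, range 2-3, binomial(8, 0.18)
#' * Silver units/week 2, range 2-5, binomial(8, 0.23)
#' * HA 12-week healing rate 0.6068, range 0.24-0.96, beta(2.03, 1.2960)
#' * Silver 12-week healing rate 0.5962, range 0.07-0.64, beta(1.82, 1.4323)
#' * Dressing-change tariff 12.1667 Euro, range 9.14-14.44, gamma (below)
#'
#' The published tariff gamma "(0.5264; 213.55)" has mean 112.4 Euro under
#' the (scale, shape) convention that reproduces both price baselines
#' (0.0477 x 400 = 19.08; 0.0616 x 400 = 24.64) — inconsistent with the
#' tariff's own baseline of 12.1667 Euro, an apparent misprint. The default
#' `tariff_gamma = "moment_matched"` keeps the printed scale 0.5264 and
#' solves the shape so the mean equals the baseline (shape ~ 23.113);
#' `"as_printed"` uses the literal parameters instead.
#'
#' Percentage OWSA ranges on prices are materialised to absolute bounds
#' (baseline x 0.95 / 1.05) so downstream code treats all ranges uniformly.
#'
#' @param tariff_gamma `"moment_matched"` (default) or `"as_printed"`.
#' @return A [scenario()].
#' @examples
#' scn <- paper_scenario()
#' scenario_baselines(scn)
#' @export
paper_scenario <- function(tariff_gamma = c("moment_matched", "as_printed")) {
  tariff_gamma <- match.arg(tariff_gamma)
  tariff_dist <- switch(tariff_gamma,
    moment_matched = moment_match_gamma(12.1667, 0.5264),
    as_printed     = dist_spec("gamma", c(0.5264, 213.55)))
  ha <- strategy_arm(
    "HA",
    unit_price = parameter_spec(
      "unit_price_HA", "unit_price", 19.0750,
      19.0750 * 0.95, 19.0750 * 1.05, dist_spec("gamma", c(0.0477, 400))),
    units_per_week = parameter_spec(
      "units_per_week_HA", "units_per_week", 2, 2, 3,
      dist_spec("binomial", c(8, 0.18))),
    healing_rate = parameter_spec(
      "healing_rate_HA", "healing_rate", 0.6068, 0.24, 0.96,
      dist_spec("beta", c(2.03, 1.2960))))
  silver <- strategy_arm(
    "Silver",
    unit_price = parameter_spec(
      "unit_price_Silver", "unit_price", 24.6270,
      24.6270 * 0.95, 24.6270 * 1.05, dist_spec("gamma", c(0.0616, 400))),
    units_per_week = parameter_spec(
      "units_per_week_Silver", "units_per_week", 2, 2, 5,
      dist_spec("binomial", c(8, 0.23))),
    healing_rate = parameter_spec(
      "healing_rate_Silver", "healing_rate", 0.5962, 0.07, 0.64,
      dist_spec("beta", c(1.82, 1.4323))))
  tariff <- parameter_spec(
    "change_tariff", "change_tariff", 12.1667, 9.14, 14.44, tariff_dist)
  scenario(ha, silver, tariff, horizon_weeks = 12L, currency = "2021 Euro")
}
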