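#' Probabilistic sensitivity analysis by Monte-Carlo simulation
#'
#' Propagates parameter uncertainty through the decision tree: each
#' iteration draws every parameter independently from its PSA distribution
#' and revalues both arms. Per iteration the draws are: intervention unit
#' price, units per week and healing rate; comparator unit price, units per
#' week and healing rate; and ONE shared change-tariff draw applied to both
#' arms (the tariff is a single model parameter, not arm-specific). No
#' correlation structure is imposed.
#'
#' Identical `(scenario, n, seed)` yields identical output.
#'
#' @param scn A [scenario()].
#' @param n Number of Monte-Carlo iterations (default 10000).
#' @param seed Integer RNG seed; required, so no run is silently
#'   non-deterministic.
#' @return An object of class `wcea_psa`: list with `draws` (n-row
#'   data.frame of sampled parameter values, columns named as in
#'   [scenario_parameters()]), `intervention` and `comparator` (n-row
#'   data.frames with `cost`, `effect`), `n`, `seed`, and the scenario's
#'   strategy names.
#' @examples
#' psa <- run_psa(paper_scenario(), n = 500, seed = 1)
#' colMeans(psa$intervention)
#' @seealso [ce_plane()], [ceac()]
#' @export
run_psa <- function(scn, n = 10000, seed) {
  stopifnot(inherits(scn, "wcea_scenario"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("an integer seed is required for run_psa()", call. = FALSE)
  if (n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  params <- scenario_parameters(scn)
  draws <- as.data.frame(lapply(params, function(p) dist_sample(p$dist, n)))
  names(draws) <- names(params)
  h <- scn$horizon_weeks
  tariff <- draws[[scn$change_tariff$name]]
  valuation <- function(arm) {
    data.frame(
      cost = h * weekly_cost(draws[[arm$units_per_week$name]],
                             draws[[arm$unit_price$name]], tariff),
      effect = draws[[arm$healing_rate$name]])
  }
  structure(
    list(draws = draws,
         intervention = valuation(scn$intervention),
         comparator = valuation(scn$comparator),
         strategies = c(scn$intervention$name, scn$comparator$name),
         n = n, seed = as.integer(seed)),
    class = "wcea_psa")
}

#' @export
print.wcea_psa <- function(x, ...) {
  cat(sprintf("<wcea_psa> %d iterations (seed %d), %s vs %s\n",
              x$n, x$seed, x$strategies[1], x$strategies[2]))
  cat(sprintf("  mean cost:   %.2f vs %.2f\n",
              mean(x$intervention$cost), mean(x$comparator$cost)))
  cat(sprintf("  mean effect: %.4f vs %.4f\n",
              mean(x$intervention$effect), mean(x$comparator$effect)))
  invisible(x)
}

#' Cost-effectiveness plane points
#'
#' Per-iteration incremental pairs `(delta_effect, delta_cost)` of the
#' intervention over the comparator. Points in the south-east quadrant
#' (more effective, cheaper) are unambiguously cost-effective; the
#' north-east and south-west quadrants are willingness-to-pay trade-offs.
#'
#' @param psa A [run_psa()] result.
#' @return A data.frame with columns `delta_effect`, `delta_cost`, one row
#'   per iteration.
#' @export
ce_plane <- function(psa) {
  stopifnot(inherits(psa, "wcea_psa"))
  if (psa$n < 1) stop("empty PSA", call. = FALSE)
  data.frame(delta_effect = psa$intervention$effect - psa$comparator$effect,
             delta_cost = psa$intervention$cost - psa$comparator$cost)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda`, the probability (share of
#' PSA iterations) that each strategy is cost-effective, i.e. has the
#' higher net monetary benefit `lambda * effect - cost`. Exact NMB ties —
#' which occur with positive probability at `lambda = 0` when both arms
#' draw zero units — are split half/half, keeping the two curves exactly
#' complementary.
#'
#' The default grid spans 0 to 10,000 Euro in steps of 100 (101 points).
#'
#' @param psa A [run_psa()] result.
#' @param wtp Numeric vector of willingness-to-pay values (>= 0).
#' @return A data.frame of class `wcea_ceac` with columns `wtp`,
#'   `p_intervention`, `p_comparator` (summing to 1 per row).
#' @examples
#' psa <- run_psa(paper_scenario(), n = 500, seed = 1)
#' head(ceac(psa))
#' @export
ceac <- function(psa, wtp = seq(0, 10000, by = 100)) {
  stopifnot(inherits(psa, "wcea_psa"))
  if (psa$n < 1) stop("empty PSA", call. = FALSE)
  if (length(wtp) == 0 || any(wtp < 0))
    stop("wtp grid must be non-empty and >= 0", call. = FALSE)
  de <- psa$intervention$effect - psa$comparator$effect
  dc <- psa$intervention$cost - psa$comparator$cost
  p_i <- vapply(wtp, function(lambda) {
    inmb <- lambda * de - dc
    (sum(inmb > 0) + 0.5 * sum(inmb == 0)) / psa$n
  }, numeric(1))
  out <- data.frame(wtp = wtp, p_intervention = p_i, p_comparator = 1 - p_i)
  class(out) <- c("wcea_ceac", "data.frame")
  out
}
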