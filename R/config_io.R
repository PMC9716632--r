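# JSON scenario schema (documented in README):
#   {
#     "strategies": [ { "name", "unit_price", "units_per_week",
#                       "healing_rate" }, x2 ],
#     "change_tariff": { ... },
#     "horizon_weeks": 12,
#     "currency": "2021 Euro"
#   }
# Each parameter object: { "name"?, "baseline",
#   "owsa": {"low", "high"} | {"pct": 5}, "dist": {"family", "params"} }.
# Percentage OWSA ranges are materialised to absolute bounds at load time.

parse_param <- function(obj, role, default_name, where) {
  for (k in c("baseline", "owsa", "dist")) {
    if (is.null(obj[[k]]))
      stop(sprintf("%s: missing required field '%s'", where, k),
           call. = FALSE)
  }
  baseline <- obj$baseline
  if (!is.numeric(baseline))
    stop(sprintf("%s: 'baseline' must be a number", where), call. = FALSE)
  owsa <- obj$owsa
  if (!is.null(owsa$pct)) {
    if (!is.numeric(owsa$pct) || owsa$pct < 0)
      stop(sprintf("%s: 'owsa.pct' must be a non-negative number", where),
           call. = FALSE)
    lo <- baseline * (1 - owsa$pct / 100)
    hi <- baseline * (1 + owsa$pct / 100)
  } else if (!is.null(owsa$low) && !is.null(owsa$high)) {
    lo <- owsa$low
    hi <- owsa$high
  } else {
    stop(sprintf("%s: 'owsa' must supply either {low, high} or {pct}", where),
         call. = FALSE)
  }
  d <- obj$dist
  if (is.null(d$family) || is.null(d$params))
    stop(sprintf("%s: 'dist' must supply 'family' and 'params'", where),
         call. = FALSE)
  dist <- tryCatch(dist_spec(d$family, unlist(d$params)),
                   error = function(e)
                     stop(sprintf("%s: %s", where, conditionMessage(e)),
                          call. = FALSE))
  name <- if (!is.null(obj$name)) obj$name else default_name
  parameter_spec(name, role, baseline, lo, hi, dist)
}

parse_arm <- function(obj, idx) {
  where <- sprintf("strategies[%d]", idx)
  if (is.null(obj$name))
    stop(sprintf("%s: missing required field 'name'", where), call. = FALSE)
  mk <- function(role) {
    if (is.null(obj[[role]]))
      stop(sprintf("%s: missing required field '%s'", where, role),
           call. = FALSE)
    parse_param(obj[[role]], role, paste0(role, "_", obj$name),
                sprintf("%s.%s", where, role))
  }
  strategy_arm(obj$name,
               unit_price = mk("unit_price"),
               units_per_week = mk("units_per_week"),
               healing_rate = mk("healing_rate"))
}

#' Load a scenario from a JSON document
#'
#' Reads a scenario configuration, validates it against the schema, and
#' checks every parameter invariant (OWSA bounds bracket the baseline,
#' healing rates lie in `[0, 1]`, distribution parameters are admissible).
#' Percentage OWSA ranges (`"owsa": {"pct": 5}`) are converted to absolute
#' bounds at load time.
#'
#' @param config Path to a JSON file, or a JSON string.
#' @return A validated [scenario()].
#' @examples
#' txt <- write_scenario(paper_scenario())
#' scn <- load_scenario(txt)
#' scn$intervention$unit_price$baseline  # 19.075
#' @seealso [write_scenario()]
#' @export
load_scenario <- function(config) {
  if (length(config) == 1 && !grepl("[{\n]", config) && file.exists(config)) {
    config <- paste(readLines(config, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(config, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("not valid JSON: %s", conditionMessage(e)),
                         call. = FALSE))
  if (is.null(doc$strategies) || length(doc$strategies) != 2)
    stop("'strategies' must be an array of exactly 2 strategy objects",
         call. = FALSE)
  if (is.null(doc$change_tariff))
    stop("missing required field 'change_tariff'", call. = FALSE)
  arms <- lapply(1:2, function(i) parse_arm(doc$strategies[[i]], i))
  tariff <- parse_param(doc$change_tariff, "change_tariff", "change_tariff",
                        "change_tariff")
  horizon <- if (!is.null(doc$horizon_weeks)) doc$horizon_weeks else 12L
  currency <- if (!is.null(doc$currency)) doc$currency else "Euro"
  scenario(arms[[1]], arms[[2]], tariff, horizon_weeks = horizon,
           currency = currency)
}

param_to_list <- function(p) {
  list(name = p$name, baseline = p$baseline,
       owsa = list(low = p$owsa_low, high = p$owsa_high),
       dist = list(family = p$dist$family, params = p$dist$params))
}

#' Serialise a scenario to a JSON document
#'
#' The written document reloads to an equal scenario ([load_scenario()] of
#' the output is the identity, exact for integers and labels and to full
#' double precision for reals).
#'
#' @param scn A [scenario()].
#' @param path Optional file path; when given the document is written there
#'   and the path returned invisibly.
#' @return The JSON document as a string (class `json`), or `path`
#'   invisibly when a path is supplied.
#' @export
write_scenario <- function(scn, path = NULL) {
  stopifnot(inherits(scn, "wcea_scenario"))
  arm_to_list <- function(a) {
    list(name = a$name,
         unit_price = param_to_list(a$unit_price),
         units_per_week = param_to_list(a$units_per_week),
         healing_rate = param_to_list(a$healing_rate))
  }
  doc <- list(
    strategies = list(arm_to_list(scn$intervention),
                      arm_to_list(scn$comparator)),
    change_tariff = param_to_list(scn$change_tariff),
    horizon_weeks = scn$horizon_weeks,
    currency = scn$currency)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(path))
  }
  json
}
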