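# Shared fixtures and comparison helpers for the test suite.

# Field-by-field scenario equality: exact for names/labels/integers, to
# 1e-12 relative tolerance for reals (the round-trip contract).
expect_scenario_equal <- function(a, b) {
  cmp_param <- function(p, q) {
    expect_identical(p$name, q$name)
    expect_identical(p$role, q$role)
    expect_equal(p$baseline, q$baseline, tolerance = 1e-12)
    expect_equal(p$owsa_low, q$owsa_low, tolerance = 1e-12)
    expect_equal(p$owsa_high, q$owsa_high, tolerance = 1e-12)
    expect_identical(p$dist$family, q$dist$family)
    expect_equal(p$dist$params, q$dist$params, tolerance = 1e-12)
  }
  for (arm in c("intervention", "comparator")) {
    expect_identical(a[[arm]]$name, b[[arm]]$name)
    for (role in c("unit_price", "units_per_week", "healing_rate")) {
      cmp_param(a[[arm]][[role]], b[[arm]][[role]])
    }
  }
  cmp_param(a$change_tariff, b$change_tariff)
  expect_identical(a$horizon_weeks, b$horizon_weeks)
  expect_identical(a$currency, b$currency)
}

# A small scenario with non-degenerate PSA but point-mass healing rates,
# effect_i > effect_c: every iteration has delta_effect >= 0 (used for the
# CEAC monotonicity property).
fixed_effect_scenario <- function() {
  arm <- function(name, price, effect) {
    strategy_arm(
      name,
      unit_price = parameter_spec(
        paste0("unit_price_", name), "unit_price", price,
        price * 0.9, price * 1.1, moment_match_gamma(price, price / 100)),
      units_per_week = parameter_spec(
        paste0("units_per_week_", name), "units_per_week", 2, 2, 3,
        dist_spec("binomial", c(8, 0.25))),
      healing_rate = parameter_spec(
        paste0("healing_rate_", name), "healing_rate", effect,
        effect, effect, dist_spec("fixed", effect)))
  }
  scenario(arm("A", 20, 0.7), arm("B", 22, 0.5),
           parameter_spec("change_tariff", "change_tariff", 10, 9, 11,
                          moment_match_gamma(10, 0.5)))
}
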