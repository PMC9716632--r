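test_that("incremental analysis reproduces the published increments", {
  inc <- incremental_analysis(list(cost = 749.8008, effect = 0.6068),
                              list(cost = 883.0488, effect = 0.5962))
  expect_equal(round(inc$delta_cost, 2), -133.25)
  expect_equal(inc$delta_effect, 0.0106)
  # the published ratio only reproduces from unrounded inputs
  expect_equal(round(inc$icer, 2), -12570.57)
  expect_false(round(-133.25 / 0.0106, 2) == -12570.57)
  expect_identical(inc$dominance, "intervention_dominant")
})

test_that("ICER is undefined (not an error) when effects are equal", {
  inc <- incremental_analysis(list(cost = 500, effect = 0.5),
                              list(cost = 500, effect = 0.5))
  expect_true(is.na(inc$icer))
  expect_identical(inc$dominance, "equivalent")
  inc2 <- incremental_analysis(list(cost = 400, effect = 0.5),
                               list(cost = 500, effect = 0.5))
  expect_true(is.na(inc2$icer))
  expect_identical(inc2$dominance, "intervention_dominant")
})

test_that("trade-off quadrants compute positive ICERs by hand", {
  inc <- incremental_analysis(list(cost = 1100, effect = 0.65),
                              list(cost = 1000, effect = 0.60))
  expect_equal(inc$icer, 2000)
  expect_identical(inc$dominance, "tradeoff_ne")
})

test_that("dominance classification covers all quadrants and ties", {
  expect_identical(classify_dominance(-133.25, 0.0106),
                   "intervention_dominant")
  expect_identical(classify_dominance(10, -0.01), "comparator_dominant")
  expect_identical(classify_dominance(0, 0), "equivalent")
  expect_identical(classify_dominance(100, 0.05), "tradeoff_ne")
  expect_identical(classify_dominance(-100, -0.05), "tradeoff_sw")
  # one delta zero resolves toward dominance when the other is favourable
  expect_identical(classify_dominance(0, 0.01), "intervention_dominant")
  expect_identical(classify_dominance(-10, 0), "intervention_dominant")
  expect_identical(classify_dominance(0, -0.01), "comparator_dominant")
  expect_identical(classify_dominance(10, 0), "comparator_dominant")
})

test_that("arm swap negates deltas, mirrors dominance, preserves the ICER", {
  set.seed(11)
  for (i in 1:50) {
    vi <- list(cost = runif(1, 0, 2000), effect = runif(1))
    vc <- list(cost = runif(1, 0, 2000), effect = runif(1))
    ab <- incremental_analysis(vi, vc)
    ba <- incremental_analysis(vc, vi)
    expect_equal(ba$delta_cost, -ab$delta_cost)
    expect_equal(ba$delta_effect, -ab$delta_effect)
    expect_equal(ba$icer, ab$icer)
    mirror <- c(intervention_dominant = "comparator_dominant",
                comparator_dominant = "intervention_dominant",
                tradeoff_ne = "tradeoff_sw", tradeoff_sw = "tradeoff_ne",
                equivalent = "equivalent")
    expect_identical(ba$dominance, unname(mirror[ab$dominance]))
  }
})

test_that("net monetary benefit: identity and hand-computed values", {
  expect_equal(net_monetary_benefit(list(cost = 749.80, effect = 0.6068), 0),
               -749.80)
  expect_equal(net_monetary_benefit(list(cost = 749.80, effect = 0.6068),
                                    10000), 5318.20)
  expect_equal(net_monetary_benefit(list(cost = 0, effect = 0.37), 0), 0)
  expect_error(net_monetary_benefit(list(cost = 1, effect = 0.5), -100),
               ">= 0")
})

test_that("NMB ordering agrees with the wtp-threshold rule (brute force)", {
  # for delta_effect > 0: intervention preferred at wtp <=> wtp * dE > dC
  # <=> wtp > ICER; checked over a grid of (dC, dE, wtp) triples
  for (dc in c(-500, -133.248, 0, 250, 1000)) {
    for (de in c(0.0106, 0.05, 0.5)) {
      for (wtp in c(0, 100, 5000, 12570, 50000)) {
        vi <- list(cost = 1000 + dc, effect = 0.4 + de)
        vc <- list(cost = 1000, effect = 0.4)
        nmb_rule <- net_monetary_benefit(vi, wtp) >
          net_monetary_benefit(vc, wtp)
        expect_identical(nmb_rule, wtp * de > dc)
        expect_identical(nmb_rule, wtp > dc / de)
      }
    }
  }
})
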