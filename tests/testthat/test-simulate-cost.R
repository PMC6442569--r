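test_that("trajectories conserve units and report every integer year", {
  an <- default_analysis()
  for (tr in list(an$traj_disclosure, an$traj_base)) {
    tot <- tr$Sr + tr$Ir + tr$Sv + tr$Iv + tr$Svp
    expect_lt(max(abs(tot - 1000)), 1e-8 * 1000)
    expect_true(all(0:20 %in% tr$t))
  }
  fine <- simulate_market(an$params, "disclosure", horizon = 5.5,
                          report_step = 0.4)
  expect_true(all(0:5 %in% fine$t))
})

test_that("accumulators start at zero and never decrease", {
  an <- default_analysis()
  for (col in c("acc_treatments", "acc_turnovers", "acc_vacancy")) {
    expect_equal(an$traj_disclosure[[col]][1], 0)
    expect_true(all(diff(an$traj_disclosure[[col]]) >= 0))
  }
})

test_that("the stationary comparator has the analytic event rates", {
  sys <- default_system()
  tr <- simulate_market(sys$params, "base", init = sys$equilibrium,
                        horizon = 5)
  eq <- sys$equilibrium
  yearly <- function(col) diff(tr[[col]][tr$t %in% 0:5])
  # treatments/unit/year = gamma * p; turnovers = n * vacant share
  expect_equal(yearly("acc_treatments"), rep(2 * 0.05, 5), tolerance = 1e-6)
  expect_equal(yearly("acc_turnovers"),
               rep(6 * (eq[["Sv"]] + eq[["Iv"]]) / 1000, 5),
               tolerance = 1e-6)
  expect_equal(yearly("acc_vacancy"),
               rep((eq[["Sv"]] + eq[["Iv"]]) / 1000, 5), tolerance = 1e-6)
})

test_that("annual costs decompose exactly and vanish when s = 0", {
  an <- default_analysis()
  expect_equal(an$costs$total,
               an$costs$treatment + an$costs$turnover + an$costs$vacancy)
  expect_equal(an$costs$cumulative_total, cumsum(an$costs$total))

  pars0 <- market_params(s = 0)
  an0 <- disclosure_analysis(pars0, horizon = 10)
  expect_lt(max(abs(an0$costs$total)), 1e-4)
})

test_that("cost components reproduce the qualitative policy picture", {
  an <- default_analysis()
  cs <- an$costs
  # vacancy cost: positive and declining after its early peak
  expect_true(all(cs$vacancy[1:10] > 0))
  expect_true(all(diff(cs$vacancy[2:10]) < 0))
  # treatment starts slightly negative (savings) and keeps growing
  expect_true(all(cs$treatment <= 0))
  expect_true(all(diff(cs$treatment) < 0))
  # net effect: early cost, later savings that keep increasing
  expect_gt(cs$total[2], 0)
  expect_lt(cs$total[20], 0)
  expect_true(all(diff(cs$total[2:20]) < 0))
})

test_that("break-even detection handles annual, cumulative and degenerate series", {
  an <- default_analysis()
  expect_equal(break_even_year(an$costs, "annual"), 5L)
  be_cum <- break_even_year(an$costs, "cumulative")
  expect_gt(be_cum, break_even_year(an$costs, "annual"))
  an0 <- disclosure_analysis(market_params(s = 0), horizon = 5)
  # all-zero costs never break even
  expect_true(is.na(break_even_year(an0$costs, "annual")))
  expect_error(break_even_year(an$costs[0, ], "annual"), "empty")
})

test_that("discounting rescales each year and preserves signs", {
  an <- default_analysis()
  cs <- an$costs
  expect_equal(discount_costs(cs, 0), cs)
  d5 <- discount_costs(cs, 0.05)
  expect_equal(d5$total, cs$total / 1.05^cs$year)
  expect_lt(abs(d5$total[20]), abs(cs$total[20]))
  expect_equal(sign(d5$total), sign(cs$total))
  expect_equal(d5$cumulative_total, cumsum(d5$total))
})

test_that("mismatched trajectory horizons are rejected", {
  an <- default_analysis()
  short <- simulate_market(an$params, "base", horizon = 2)
  expect_error(annual_cost_components(an$traj_disclosure, short,
                                      cost_rates(), 5), "cover")
})
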