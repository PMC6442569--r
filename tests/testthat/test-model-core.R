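pars_beta <- function(beta = 2.2572, ...) {
  p <- market_params(...)
  p$beta <- beta
  p
}

test_that("relocation fraction behaves at its edge cases", {
  pars <- market_params()
  expect_equal(relocation_fraction(market_state(800, 0, 150, 50), pars), 0)
  pars1 <- market_params(b = 1)
  expect_equal(relocation_fraction(market_state(100, 100, 700, 100), pars1),
               0.5)
  # degenerate empty market: no occupied units, no movers
  expect_equal(relocation_fraction(market_state(0, 0, 900, 100), pars), 0)
})

test_that("relocation fraction at the endemic equilibrium matches the closed form", {
  pars <- market_params()
  eq <- endemic_equilibrium(0.05, pars)
  # b*Ir/(Sr + b*Ir) at (Sr, Ir) = (875.77, 46.24), b = 1.3
  expect_equal(relocation_fraction(eq, pars), 0.064234, tolerance = 1e-4)
  # increasing in Ir at fixed Sr
  f1 <- relocation_fraction(market_state(800, 20, 150, 30), pars)
  f2 <- relocation_fraction(market_state(800, 40, 130, 30), pars)
  expect_gt(f2, f1)
})

test_that("base-model derivatives match a hand evaluation", {
  pars <- pars_beta(2.2572)
  d <- rhs_base(market_state(900, 50, 45, 5), pars)
  # term-by-term evaluation with f = 65/965 = 0.067358
  expect_equal(unname(d), c(-187.0296, 4.5300, 190.0, -7.5), tolerance = 1e-4)
})

test_that("the disease-free market balance is a fixed point of both models", {
  pars <- pars_beta()
  expect_equal(max(abs(rhs_base(disease_free_state(pars), pars))), 0)
  expect_equal(max(abs(rhs_disclosure(disease_free_state(pars, TRUE), pars))),
               0)
})

test_that("derivatives conserve the total number of units", {
  set.seed(42)
  pars <- pars_beta()
  mig <- migration_params(0.3, 0.15)
  for (rep in 1:25) {
    st4 <- random_state(1000)
    st5 <- random_state(1000, disclosed = TRUE)
    expect_lt(abs(sum(rhs_base(st4, pars))), 1e-12 * 1000)
    expect_lt(abs(sum(rhs_disclosure(st5, pars))), 1e-12 * 1000)
    expect_lt(abs(sum(rhs_migration(st5, pars, mig))), 1e-12 * 1000)
  }
})

test_that("with no selectivity the disclosure model reduces to the base model", {
  set.seed(7)
  pars <- pars_beta(); pars$s <- 0
  for (rep in 1:20) {
    st5 <- random_state(1000, disclosed = TRUE)
    st4 <- market_state(st5[["Sr"]], st5[["Ir"]],
                        st5[["Sv"]] + st5[["Svp"]], st5[["Iv"]])
    d5 <- rhs_disclosure(st5, pars)
    d4 <- rhs_base(st4, pars)
    agg <- c(d5[["Sr"]], d5[["Ir"]], d5[["Sv"]] + d5[["Svp"]], d5[["Iv"]])
    expect_equal(agg, unname(d4), tolerance = 1e-12)
  }
})

test_that("s = 0 trajectories of the two models coincide over 20 years", {
  sys <- default_system()
  pars <- sys$params; pars$s <- 0
  tr_b <- simulate_market(pars, "base", init = sys$equilibrium, horizon = 20)
  init5 <- c(sys$equilibrium, Svp = 0)
  tr_d <- simulate_market(pars, "disclosure", init = init5, horizon = 20)
  expect_equal(tr_d$Sr, tr_b$Sr, tolerance = 1e-7)
  expect_equal(tr_d$Ir, tr_b$Ir, tolerance = 1e-7)
  expect_equal(tr_d$Sv + tr_d$Svp, tr_b$Sv, tolerance = 1e-7)
  expect_equal(tr_d$Iv, tr_b$Iv, tolerance = 1e-7)
})

test_that("per-unit trajectories are invariant to market size", {
  runs <- lapply(c(1000, 1e6), function(N) {
    pars <- market_params(N = N)
    pars$beta <- calibrate_beta(0.05, pars)
    disclosure_analysis(pars, horizon = 10)
  })
  expect_equal(runs[[1]]$traj_disclosure$prevalence,
               runs[[2]]$traj_disclosure$prevalence, tolerance = 1e-7)
  expect_equal(runs[[1]]$costs$total, runs[[2]]$costs$total,
               tolerance = 1e-6)
})

test_that("integration preserves positivity from nonnegative starts", {
  set.seed(11)
  pars <- pars_beta()
  for (rep in 1:3) {
    st <- random_state(1000, disclosed = TRUE)
    tr <- simulate_market(pars, "disclosure", init = st, horizon = 20,
                          report_step = 0.25)
    expect_gte(min(tr$Sr, tr$Ir, tr$Sv, tr$Iv, tr$Svp), -1e-9 * 1000)
  }
})

test_that("external mover fraction has the expected limits", {
  expect_equal(external_mover_fraction(0, 1.3), 0)
  expect_equal(external_mover_fraction(0.2, 1), 0.2)
  expect_gt(external_mover_fraction(0.2, 1.3), 0.2)
})
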