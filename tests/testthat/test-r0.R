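calibrated <- function(...) {
  pars <- market_params(...)
  pars$beta <- calibrate_beta(pars$p, pars)
  pars
}

test_that("R0 at calibrated defaults reproduces the threshold analysis", {
  pars <- calibrated(s = 0)
  bd <- r0_closed_form(pars)
  expect_equal(round(bd$r0, 2), 1.05)
  # relocation route contributes ~8-9% of the new-infestation rate
  expect_equal(100 * bd$relocation_share, 8.56, tolerance = 1e-2)
  expect_equal(bd$infectious_share + bd$relocation_share, 1)
  expect_lte(bd$mean_infectious_time, 1 / pars$gamma)
  # full quarantine: the implemented formula gives ~0.86
  s1 <- pars; s1$s <- 1
  expect_equal(r0_closed_form(s1)$r0, 0.86, tolerance = 0.005)
})

test_that("R0 vanishes without transmission routes", {
  pars <- market_params(k = 0); pars$beta <- 0
  expect_equal(r0_closed_form(pars)$r0, 0)
})

test_that("closed form and numeric next-generation matrix agree on a Latin grid", {
  set.seed(20240901)
  n_pts <- 200
  grid <- if (requireNamespace("lhs", quietly = TRUE))
    lhs::randomLHS(n_pts, 5) else matrix(stats::runif(n_pts * 5), n_pts)
  checked <- 0
  for (i in seq_len(n_pts)) {
    u <- grid[i, ]
    pp <- market_params(k = u[1], b = 1 + 4 * u[2], s = 0.01 + 0.99 * u[3],
                        duration_months = 2 + 10 * u[4],
                        p = 0.001 + 0.099 * u[5])
    beta <- tryCatch(calibrate_beta(pp$p, pp), error = function(e) NA)
    if (is.na(beta)) next
    pp$beta <- beta
    expect_equal(r0_ngm(pp), r0_closed_form(pp)$r0, tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gt(checked, 150)
})

test_that("R0 does not depend on the disclosure period", {
  vals <- vapply(c(0.25, 1, 4), function(D) {
    pars <- calibrated(D = D)
    r0_ngm(pars)
  }, numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
})

test_that("R0 is strictly decreasing in renter selectivity", {
  r0s <- vapply(seq(0, 1, by = 0.25), function(s) {
    pars <- calibrated(s = s)
    r0_closed_form(pars)$r0
  }, numeric(1))
  expect_true(all(diff(r0s) < 0))
})

test_that("without relocation transmission R0 reduces to the classic SIS form", {
  pars <- calibrated(k = 0, s = 0)
  bd <- r0_closed_form(pars)
  expect_equal(bd$relocation_share, 0)
  expect_equal(bd$r0,
               pars$beta * pars$n / (pars$n + pars$m) *
                 (pars$gamma + pars$n) /
                 (pars$gamma * (pars$gamma + pars$b * pars$m + pars$n)),
               tolerance = 1e-12)
})

test_that("threshold classification matches R0 and the simulated growth sign", {
  p_persist <- calibrated(s = 0)
  expect_equal(threshold_classification(p_persist), "persists")
  p_decline <- calibrated(s = 1)
  expect_equal(threshold_classification(p_decline), "declines")
  p_zero <- market_params(k = 0.3); p_zero$beta <- 0
  expect_equal(threshold_classification(p_zero), "declines")
  # boundary flag: rescale beta so R0 = 1 exactly
  pb <- p_persist
  tau <- r0_closed_form(pb)$mean_infectious_time
  pb$beta <- (1 / tau - pb$k * pb$b * pb$m) * (pb$n + pb$m) / pb$n
  expect_equal(threshold_classification(pb), "boundary")

  # sign of the initial growth of a tiny seed matches sign(R0 - 1)
  for (pars in list(p_persist, p_decline)) {
    N <- pars$N
    seed <- market_state(N * pars$n / (pars$n + pars$m) - 1e-4 * N,
                         1e-4 * N, N * pars$m / (pars$n + pars$m), 0,
                         Svp = 0)
    tr <- simulate_market(pars, "disclosure", init = seed, horizon = 3,
                          report_step = 0.5)
    growth <- tr$Ir[nrow(tr)] + tr$Iv[nrow(tr)] - (tr$Ir[1] + tr$Iv[1])
    expect_equal(sign(growth), sign(r0_closed_form(pars)$r0 - 1))
  }
})
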