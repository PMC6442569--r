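#' Annual landlord cost of disclosure, by component
#'
#' Cost of disclosure for a given policy year: the difference (disclosure
#' minus no-disclosure) in the per-unit quantity of treatments, turnover
#' events, and vacant unit-time over the year, each multiplied by its dollar
#' rate. Vacancy is costed per unit-month (`12 * c_vac` per unit-year).
#' Year `y` is the interval `[y-1, y]` after policy start.
#'
#' @param traj_disc Trajectory of the disclosure (or migration) run.
#' @param traj_base Trajectory of the no-disclosure comparator, started from
#'   its own endemic equilibrium with the same parameters and integrator
#'   settings.
#' @param rates A [cost_rates()] object.
#' @param year Integer policy year (>= 1).
#' @return A one-row data.frame: `year`, `treatment`, `turnover`, `vacancy`,
#'   `total` (dollars per unit; `total` is the exact sum of the components).
#' @export
annual_cost_components <- function(traj_disc, traj_base, rates, year) {
  stopifnot(inherits(rates, "cost_rates"), year >= 1, year == round(year))
  d1 <- acc_increment(traj_disc, year)
  d0 <- acc_increment(traj_base, year)
  treatment <- rates$c_trt * (d1["acc_treatments"] - d0["acc_treatments"])
  turnover <- rates$c_tov * (d1["acc_turnovers"] - d0["acc_turnovers"])
  vacancy <- 12 * rates$c_vac * (d1["acc_vacancy"] - d0["acc_vacancy"])
  data.frame(year = year, treatment = unname(treatment),
             turnover = unname(turnover), vacancy = unname(vacancy),
             total = unname(treatment + turnover + vacancy))
}

# Accumulator increments over [year-1, year]; errors if the grid lacks them.
acc_increment <- function(traj, year) {
  cols <- c("acc_treatments", "acc_turnovers", "acc_vacancy")
  i0 <- which(abs(traj$t - (year - 1)) < 1e-9)
  i1 <- which(abs(traj$t - year) < 1e-9)
  if (length(i0) == 0 || length(i1) == 0)
    stop("trajectory does not cover the interval [", year - 1, ", ", year,
         "]", call. = FALSE)
  unlist(traj[i1[1], cols]) - unlist(traj[i0[1], cols])
}

#' Cost table over a range of policy years
#'
#' Applies [annual_cost_components()] to each year and appends the running
#' sum `cumulative_total`.
#'
#' @inheritParams annual_cost_components
#' @param years Integer years to report (default all complete years of the
#'   shorter trajectory).
#' @return A `cost_report` data.frame with columns `year`, `treatment`,
#'   `turnover`, `vacancy`, `total`, `cumulative_total` (all dollars per
#'   unit).
#' @export
cost_table <- function(traj_disc, traj_base, rates = cost_rates(),
                       years = NULL) {
  if (is.null(years))
    years <- seq_len(floor(min(max(traj_disc$t), max(traj_base$t))))
  out <- do.call(rbind, lapply(years, function(y)
    annual_cost_components(traj_disc, traj_base, rates, y)))
  out$cumulative_total <- cumsum(out$total)
  structure(out, class = c("cost_report", "data.frame"))
}

#' First year in which disclosure yields net savings
#'
#' @param costs A `cost_report` (from [cost_table()]).
#' @param mode `"annual"`: first year whose annual total is negative;
#'   `"cumulative"`: first year whose running total is negative.
#' @param tol Negligibility threshold (dollars per unit): totals within
#'   `tol` of zero do not count as savings, so an identically-zero policy
#'   (s = 0) never "breaks even" on integrator noise.
#' @return The break-even year (integer), or `NA` if costs never turn
#'   negative within the series.
#' @export
break_even_year <- function(costs, mode = c("annual", "cumulative"),
                            tol = 1e-6) {
  mode <- match.arg(mode)
  if (nrow(costs) == 0) stop("empty cost series", call. = FALSE)
  x <- if (mode == "annual") costs$total else costs$cumulative_total
  hit <- which(x < -tol)
  if (length(hit) == 0) NA_integer_ else as.integer(costs$year[hit[1]])
}

#' Discount a cost series
#'
#' Standard exponential discounting: year-`y` entries are multiplied by
#' `(1 + rate)^(-y)`; the cumulative total is recomputed from the
#' discounted annual totals. `rate = 0` is the identity.
#'
#' @param costs A `cost_report`.
#' @param rate Annual discount rate (>= 0).
#' @return The discounted `cost_report`.
#' @export
discount_costs <- function(costs, rate) {
  stopifnot(rate >= 0)
  fac <- (1 + rate)^(-costs$year)
  for (col in c("treatment", "turnover", "vacancy", "total"))
    costs[[col]] <- costs[[col]] * fac
  costs$cumulative_total <- cumsum(costs$total)
  costs
}

#' One-call disclosure cost analysis
#'
#' Calibrates `beta` to the baseline prevalence, runs the no-disclosure
#' comparator from its own equilibrium and the disclosure (or migration)
#' model from the same equilibrium with the disclosed-vacant class empty,
#' and returns the annual cost table plus both trajectories. Both runs use
#' identical integrator settings so discretization bias cancels in the
#' cost differences.
#'
#' @param pars A [market_params()] object; `beta` is (re)calibrated to
#'   `pars$p` unless `recalibrate = FALSE`.
#' @param rates A [cost_rates()] object.
#' @param horizon Years to simulate.
#' @param migration Optional [migration_params()]; when supplied, the policy
#'   run uses the open-population migration model.
#' @param recalibrate Recalibrate `beta` to `pars$p` (default `TRUE`).
#' @return A list of class `disclosure_analysis`: `params`, `costs`
#'   (a `cost_report`), `traj_disclosure`, `traj_base`, `r0`.
#' @examples
#' an <- disclosure_analysis(market_params(), horizon = 5)
#' an$costs
#' @export
disclosure_analysis <- function(pars = market_params(), rates = cost_rates(),
                                horizon = 20, migration = NULL,
                                recalibrate = TRUE) {
  if (recalibrate || is.na(pars$beta))
    pars$beta <- calibrate_beta(pars$p, pars, migration = migration)
  eq <- endemic_equilibrium(pars$p, pars)
  model <- if (is.null(migration)) "disclosure" else "migration"
  traj_d <- simulate_market(pars, model, init = as_disclosure_state(eq),
                            horizon = horizon, migration = migration)
  # the no-disclosure comparator lives in the same (open or closed) market
  traj_b <- if (is.null(migration)) {
    simulate_market(pars, "base", init = eq, horizon = horizon)
  } else {
    pars0 <- pars; pars0$s <- 0
    simulate_market(pars0, "migration", init = as_disclosure_state(eq),
                    horizon = horizon, migration = migration)
  }
  costs <- cost_table(traj_d, traj_b, rates)
  if (rates$discount_rate > 0)
    costs <- discount_costs(costs, rates$discount_rate)
  pars0 <- pars; pars0$s <- 0  # R0 reported without and with disclosure
  structure(list(params = pars,
                 costs = costs,
                 traj_disclosure = traj_d,
                 traj_base = traj_b,
                 r0 = r0_closed_form(pars),
                 r0_no_disclosure = r0_closed_form(pars0)),
            class = "disclosure_analysis")
}

#' @export
print.disclosure_analysis <- function(x, ...) {
  cat(sprintf("Disclosure policy analysis (p = %g, s = %g, beta = %.4f)\n",
              x$params$p, x$params$s, x$params$beta))
  cat(sprintf("R0: %.3f without disclosure, %.3f with (s = %g)\n",
              x$r0_no_disclosure$r0, x$r0$r0, x$params$s))
  be_a <- break_even_year(x$costs, "annual")
  be_c <- break_even_year(x$costs, "cumulative")
  cat(sprintf("Break-even year: %s (annual), %s (cumulative)\n",
              ifelse(is.na(be_a), "none", be_a),
              ifelse(is.na(be_c), "none", be_c)))
  cat("Annual per-unit cost of disclosure ($; negative = savings):\n")
  print(format(x$costs, digits = 3), row.names = FALSE)
  invisible(x)
}
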