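#' Policy surface over baseline prevalence and renter selectivity
#'
#' For every grid cell `(p, s)`: recalibrate `beta` to that baseline
#' prevalence, run the disclosure model against its no-disclosure
#' comparator, and record the annual total cost per unit and the year-end
#' prevalence for every policy year. This is the machinery behind
#' cost/prevalence policy surfaces.
#'
#' @param p_values Baseline prevalences (each must admit a feasible
#'   calibration).
#' @param s_values Renter selectivities in `[0, 1]`.
#' @param horizon Years per run.
#' @param rates A [cost_rates()] object.
#' @param pars Template [market_params()]; `p`, `s`, `beta` are overridden
#'   cell by cell.
#' @return A `sweep_result` data.frame in long format: columns `p`, `s`,
#'   `year`, `cost_total` ($/unit, annual), `prevalence` (year-end), and
#'   `feasible` (FALSE rows flag cells where calibration failed; their
#'   metrics are `NA`, never silently dropped).
#' @export
sweep_grid <- function(p_values, s_values, horizon = 20,
                       rates = cost_rates(), pars = market_params()) {
  cells <- expand.grid(p = p_values, s = s_values, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    pp <- pars; pp$p <- cells$p[i]; pp$s <- cells$s[i]
    an <- tryCatch(disclosure_analysis(pp, rates, horizon),
                   error = function(e) NULL)
    if (is.null(an))
      return(data.frame(p = pp$p, s = pp$s, year = seq_len(horizon),
                        cost_total = NA_real_, prevalence = NA_real_,
                        feasible = FALSE))
    yr_prev <- vapply(seq_len(horizon), function(y)
      prevalence_at(an$traj_disclosure, y), numeric(1))
    data.frame(p = pp$p, s = pp$s, year = an$costs$year,
               cost_total = an$costs$total, prevalence = yr_prev,
               feasible = TRUE)
  })
  structure(do.call(rbind, res),
            class = c("sweep_result", "data.frame"))
}

#' One-at-a-time sensitivity analysis with recalibration
#'
#' Varies a single hard-to-estimate parameter — the relocation-transmission
#' probability `k`, the mean infestation duration `1/gamma` (months), or the
#' vacancy multiplier `b` — while holding everything else at its default,
#' RE-calibrating `beta` to the same baseline prevalence for every value
#' (the observable prevalence is fixed; the infectivity absorbs the change).
#' Reports year-`horizon` prevalence and annual savings, plus their ratios
#' to the default-parameter run.
#'
#' @param param_name `"k"`, `"duration"` (mean infestation duration, months)
#'   or `"b"`.
#' @param values Parameter values to evaluate (`k` in `[0,1]`, duration in
#'   months, `b >= 1`).
#' @param horizon Years per run; metrics are taken at the final year.
#' @param rates A [cost_rates()] object.
#' @param pars Template [market_params()].
#' @return A data.frame: `value`, `beta` (recalibrated), `prevalence`
#'   (year-`horizon`), `savings` (negative of the year-`horizon` annual
#'   total, $/unit), `cum_savings` (cumulative analogue), `prevalence_ratio`
#'   and `savings_ratio` (vs. the default-parameter run), `feasible`.
#' @export
sensitivity_oat <- function(param_name = c("k", "duration", "b"), values,
                            horizon = 20, rates = cost_rates(),
                            pars = market_params()) {
  param_name <- match.arg(param_name)
  run_one <- function(v) {
    pp <- pars
    switch(param_name,
           k = { pp$k <- v },
           duration = { pp$gamma <- 12 / v },
           b = { pp$b <- v })
    an <- tryCatch(disclosure_analysis(pp, rates, horizon),
                   error = function(e) NULL)
    if (is.null(an))
      return(data.frame(value = v, beta = NA_real_, prevalence = NA_real_,
                        savings = NA_real_, cum_savings = NA_real_,
                        feasible = FALSE))
    last <- an$costs[an$costs$year == horizon, ]
    data.frame(value = v, beta = an$params$beta,
               prevalence = prevalence_at(an$traj_disclosure, horizon),
               savings = -last$total,
               cum_savings = -last$cumulative_total,
               feasible = TRUE)
  }
  default_value <- switch(param_name, k = pars$k,
                          duration = 12 / pars$gamma, b = pars$b)
  ref <- run_one(default_value)
  out <- do.call(rbind, lapply(values, run_one))
  out$prevalence_ratio <- out$prevalence / ref$prevalence
  out$savings_ratio <- out$savings / ref$savings
  attr(out, "reference") <- ref
  attr(out, "param_name") <- param_name
  out
}

#' Structured-population scenarios
#'
#' Runs several disconnected subpopulations, each with its own parameter
#' set, as independent disclosure analyses — e.g. a small high-prevalence
#' subpopulation (lower treatment rate, higher move-out, higher aversion)
#' next to a larger low-prevalence one. With no mixing the subpopulations
#' are exactly independent single-population runs.
#'
#' @param scenarios Named list of [market_params()] objects, one per
#'   subpopulation.
#' @param rates A [cost_rates()] object.
#' @param horizon Years per run.
#' @return Named list of `disclosure_analysis` objects.
#' @export
structured_population <- function(scenarios, rates = cost_rates(),
                                  horizon = 20) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1)
  lapply(scenarios, disclosure_analysis, rates = rates, horizon = horizon)
}
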