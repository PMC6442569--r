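#' Model parameters for the rental-market bed bug model
#'
#' Constructs and validates the full parameter set of the coupled
#' rental-market/infestation model. All rates are per year; the unit of
#' infection is a rental unit.
#'
#' @param beta Infectivity (per year): rate constant of infectious
#'   transmission into occupied units. Usually left `NA` and filled in by
#'   [calibrate_beta()] so that the no-disclosure model is stationary at the
#'   baseline prevalence `p`.
#' @param gamma Treatment rate (per year); `1/gamma` is the mean time for an
#'   infested unit to initiate and complete successful treatment. The default
#'   corresponds to a 6-month mean infestation duration.
#' @param k Probability that a tenant moving out of an infested unit seeds an
#'   infestation in their next unit (relocation transmission), in `[0, 1]`.
#' @param b Vacancy multiplier: factor (>= 1) by which infestation raises the
#'   move-out rate of an occupied unit.
#' @param m Baseline move-out rate (per year); `1/m` is the mean tenancy.
#' @param n Move-in rate (per year); `1/n` is the mean vacancy spell for an
#'   undisclosed susceptible unit.
#' @param s Renter selectivity in `[0, 1]`: fractional reduction of the
#'   move-in rate to disclosed (currently or recently infested) units.
#'   `s = 1` is a full quarantine; `s = 0` means disclosure changes nothing.
#' @param D Disclosure period (years): mean time a treated unit remains
#'   flagged before returning to the undisclosed pool.
#' @param N Total number of rental units (closed market).
#' @param p Baseline (pre-policy) infestation prevalence `(Ir+Iv)/N`,
#'   in `[0, 1)`.
#' @param duration_months Optional convenience: mean infestation duration in
#'   months; overrides `gamma` with `12/duration_months`.
#'
#' @return An object of class `market_params`: a validated named list with
#'   the fields above.
#'
#' @details Defaults are the point estimates used throughout the package's
#'   reference analyses: `p = 5\%`, `s = 0.5`, `1/gamma` = 6 months,
#'   `k = 0.3`, `b = 1.3`, `m = 0.5`, `n = 6`, `D = 1` year, `N = 1000`.
#'   `m` and `n` reproduce a low-prevalence vacancy share of
#'   `m/(n+m)` (about 7.7%), close to the US national rental vacancy rate.
#'
#' @examples
#' pars <- market_params()
#' pars$beta <- calibrate_beta(pars$p, pars)
#' @export
market_params <- function(beta = NA_real_, gamma = 2, k = 0.3, b = 1.3,
                          m = 0.5, n = 6, s = 0.5, D = 1, N = 1000,
                          p = 0.05, duration_months = NULL) {
  if (!is.null(duration_months)) {
    stopifnot(is.numeric(duration_months), duration_months > 0)
    gamma <- 12 / duration_months
  }
  pars <- list(beta = as.numeric(beta), gamma = as.numeric(gamma),
               k = as.numeric(k), b = as.numeric(b), m = as.numeric(m),
               n = as.numeric(n), s = as.numeric(s), D = as.numeric(D),
               N = as.numeric(N), p = as.numeric(p))
  class(pars) <- "market_params"
  validate_params(pars)
  pars
}

#' Validate a `market_params` object
#'
#' Checks every parameter invariant and stops with a message naming the
#' offending field. `beta` may be `NA` (not yet calibrated).
#'
#' @param pars A `market_params` object or a named list with the same fields.
#' @param require_beta If `TRUE`, `beta` must be set (finite, >= 0).
#' @return `pars`, invisibly, if valid.
#' @export
validate_params <- function(pars, require_beta = FALSE) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid parameter `", field, "`: ", what,
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L
  for (f in c("beta", "gamma", "k", "b", "m", "n", "s", "D", "N", "p"))
    chk(num1(pars[[f]]), f, "must be a single numeric value")
  if (require_beta || !is.na(pars$beta))
    chk(is.finite(pars$beta) && pars$beta >= 0, "beta", "must be >= 0")
  chk(pars$gamma > 0, "gamma", "must be > 0 (finite mean infestation duration)")
  chk(pars$k >= 0 && pars$k <= 1, "k", "must lie in [0, 1]")
  chk(pars$b >= 1, "b", "must be >= 1 (infestation cannot lower move-out)")
  chk(pars$m > 0, "m", "must be > 0")
  chk(pars$n > 0, "n", "must be > 0")
  chk(pars$s >= 0 && pars$s <= 1, "s", "must lie in [0, 1]")
  chk(pars$D > 0, "D", "must be > 0")
  chk(pars$N > 0, "N", "must be > 0")
  chk(pars$p >= 0 && pars$p < 1, "p", "must lie in [0, 1)")
  invisible(pars)
}

#' @export
print.market_params <- function(x, ...) {
  cat("Rental-market bed bug model parameters (rates per year):\n")
  cat(sprintf("  beta  = %s (infectivity%s)\n",
              ifelse(is.na(x$beta), "<uncalibrated>", format(x$beta)),
              ifelse(is.na(x$beta), "; see calibrate_beta()", "")))
  cat(sprintf("  gamma = %g  (mean infestation duration %.3g mo)\n",
              x$gamma, 12 / x$gamma))
  cat(sprintf("  k = %g, b = %g, m = %g, n = %g, s = %g, D = %g y\n",
              x$k, x$b, x$m, x$n, x$s, x$D))
  cat(sprintf("  N = %g units, baseline prevalence p = %g\n", x$N, x$p))
  invisible(x)
}

#' Landlord cost rates
#'
#' Dollar cost constants entering the disclosure cost accounting.
#'
#' @param c_trt Cost of one successful extermination (dollars per treatment
#'   event). Default $1,225.
#' @param c_tov Cost of turning a unit over to new tenants (dollars per
#'   move-in event). Default $1,000.
#' @param c_vac Opportunity cost of one vacant unit-MONTH (the monthly rent).
#'   Default $1,000; enters annual costs through the explicit factor 12.
#' @param discount_rate Annual discount rate applied by [discount_costs()];
#'   the default 0 means no discounting.
#' @return An object of class `cost_rates`.
#' @export
cost_rates <- function(c_trt = 1225, c_tov = 1000, c_vac = 1000,
                       discount_rate = 0) {
  stopifnot(c_trt >= 0, c_tov >= 0, c_vac >= 0, discount_rate >= 0)
  structure(list(c_trt = as.numeric(c_trt), c_tov = as.numeric(c_tov),
                 c_vac = as.numeric(c_vac),
                 discount_rate = as.numeric(discount_rate)),
            class = "cost_rates")
}

#' Intermarket migration parameters
#'
#' Open-population extension: a fraction `i` of tenants moving into vacant
#' units originate in external markets with a stable net infestation
#' prevalence `e`. `i = 0` recovers the closed model exactly.
#'
#' @param i Fraction of new tenants from external markets, in `[0, 1]`.
#' @param e Net infestation prevalence of the external markets, in `[0, 1)`.
#' @return An object of class `migration_params`.
#' @export
migration_params <- function(i = 0, e = 0) {
  stopifnot(is.numeric(i), length(i) == 1L, i >= 0, i <= 1,
            is.numeric(e), length(e) == 1L, e >= 0, e < 1)
  structure(list(i = as.numeric(i), e = as.numeric(e)),
            class = "migration_params")
}

#' Market states
#'
#' Compartment occupancies. The closed no-disclosure model has four
#' classes: susceptible-occupied `Sr`, infested-occupied `Ir`,
#' susceptible-vacant `Sv`, infested-vacant `Iv`. Under disclosure a fifth
#' class `Svp` (susceptible-vacant-disclosed: treated but still flagged)
#' is added. States are continuous occupancies (mean-field semantics).
#'
#' @param Sr,Ir,Sv,Iv,Svp Nonnegative compartment occupancies.
#' @return A named numeric vector.
#' @export
market_state <- function(Sr, Ir, Sv, Iv, Svp = NULL) {
  x <- c(Sr = Sr, Ir = Ir, Sv = Sv, Iv = Iv)
  if (!is.null(Svp)) x <- c(x, Svp = Svp)
  if (any(x < 0)) stop("compartment occupancies must be nonnegative",
                       call. = FALSE)
  x
}

# Internal: coerce a 4-state to a 5-state (Svp = 0) and check conservation.
as_disclosure_state <- function(state) {
  if (!("Svp" %in% names(state))) state <- c(state, Svp = 0)
  state[c("Sr", "Ir", "Sv", "Iv", "Svp")]
}
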