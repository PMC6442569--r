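#' Endemic equilibrium of the no-disclosure model
#'
#' Closed-form stationary state of the four-compartment model at a given
#' overall infestation prevalence `p = (Ir + Iv)/N`. Derived from the
#' stationarity conditions: `dIv = 0` fixes the occupied/vacant split of the
#' infested units (`Ir/Iv = (gamma + n)/(b m)`), `dSv = 0` fixes the split of
#' the susceptible units, and conservation closes the system. Note the
#' equilibrium does not involve `beta`; it is the anchor from which
#' [calibrate_beta()] solves for the infectivity.
#'
#' @param p Target prevalence in `[0, 1)`.
#' @param pars A [market_params()] object (`beta` not required).
#' @return A named state vector `(Sr, Ir, Sv, Iv)` summing to `N` with
#'   `(Ir + Iv)/N = p`.
#' @examples
#' endemic_equilibrium(0.05, market_params())
#' @export
endemic_equilibrium <- function(p, pars) {
  validate_params(pars)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p < 1)
  A <- pars$b * pars$m + pars$gamma + pars$n
  Ir <- pars$N * p * (pars$gamma + pars$n) / A
  Iv <- pars$N * p * pars$b * pars$m / A
  Sr <- pars$N / (pars$m + pars$n) *
    (pars$n * (1 - p) - p * pars$m * pars$b * pars$gamma / A)
  Sv <- pars$N * (1 - p) - Sr
  if (Sr < 0 || Sv < 0)
    stop("no valid endemic equilibrium: prevalence p = ", p,
         " yields a negative compartment (Sr = ", signif(Sr, 6),
         ", Sv = ", signif(Sv, 6), ")", call. = FALSE)
  market_state(Sr, Ir, Sv, Iv)
}

#' Calibrate the infectivity to a baseline prevalence
#'
#' Solves for the infectivity `beta` that makes the no-disclosure model
#' stationary at the endemic equilibrium with overall prevalence `p`:
#' setting `dIr = 0` at the [endemic_equilibrium()] state gives
#' \deqn{\beta = \frac{N}{S_r^* I_r^*}\left[(\gamma + b m) I_r^* -
#'   k\frac{b I_r^*}{S_r^* + b I_r^*} n S_v^* - n I_v^*\right].}
#' The infectivity is not observable directly; the observable baseline
#' prevalence (assumed to represent a market at or near equilibrium) is the
#' calibration anchor.
#'
#' @param p Target baseline prevalence, `0 < p < 1`.
#' @param pars A [market_params()] object (`beta` ignored).
#' @param method `"closed_form"` (default) evaluates the expression above;
#'   `"numeric"` is an independent cross-check that solves the full
#'   stationarity system (three rhs components, conservation, and the
#'   prevalence constraint) for the state and `beta` jointly by a damped
#'   Newton iteration with numerical derivatives.
#' @param tol Convergence tolerance for the numeric method.
#' @param migration Optional [migration_params()]. When supplied, `beta` is
#'   calibrated so the OPEN no-disclosure market (tenant immigration active
#'   before any policy) is stationary at prevalence `p`: the relocation
#'   seeding probability in the stationarity condition becomes
#'   `k*((1-i)*f + i*f_ext)` with `f_ext` from
#'   [external_mover_fraction()]. External seeding pressure then absorbs part of
#'   the infectivity, so `beta` decreases with `i*e`. With `i = 0` this is
#'   identical to the closed-market calibration.
#' @return The calibrated `beta` (per year).
#' @examples
#' calibrate_beta(0.05, market_params())  # ~2.257 at defaults
#' @export
calibrate_beta <- function(p, pars, method = c("closed_form", "numeric"),
                           tol = 1e-12, migration = NULL) {
  method <- match.arg(method)
  validate_params(pars)
  stopifnot(p > 0, p < 1)
  eq <- endemic_equilibrium(p, pars)
  if (method == "numeric")
    return(calibrate_beta_newton(p, pars, tol, migration))
  Sr <- eq[["Sr"]]; Ir <- eq[["Ir"]]; Sv <- eq[["Sv"]]; Iv <- eq[["Iv"]]
  f <- pars$b * Ir / (Sr + pars$b * Ir)
  q <- if (is.null(migration)) pars$k * f
  else pars$k * ((1 - migration$i) * f +
                   migration$i * external_mover_fraction(migration$e, pars$b))
  num <- (pars$gamma + pars$b * pars$m) * Ir - q * pars$n * Sv -
    pars$n * Iv
  if (num <= 0)
    stop("calibration infeasible: relocation transmission alone more than ",
         "sustains prevalence p = ", p, " (bracketed rate = ",
         signif(num, 6), " <= 0); beta would be non-positive", call. = FALSE)
  pars$N / (Sr * Ir) * num
}

#' Calibrated system: parameters plus their endemic anchor state
#'
#' Convenience wrapper bundling [calibrate_beta()] and
#' [endemic_equilibrium()]; the returned parameters have `beta` filled in
#' and the equilibrium is the standard initial condition for policy runs.
#'
#' @inheritParams calibrate_beta
#' @return A list of class `calibrated_system` with elements `params` (a
#'   [market_params()] object with `beta` set) and `equilibrium` (the
#'   stationary `(Sr, Ir, Sv, Iv)` state).
#' @export
calibrate_system <- function(p, pars = market_params()) {
  pars$p <- p
  pars$beta <- calibrate_beta(p, pars)
  structure(list(params = pars, equilibrium = endemic_equilibrium(p, pars)),
            class = "calibrated_system")
}

# Independent numeric calibration: damped Newton on
#   F(Sr, Ir, Sv, beta) = (rhs_Sr, rhs_Ir, rhs_Sv, (Ir + Iv)/N - p)
# with Iv = N - Sr - Ir - Sv (conservation eliminates one unknown).
calibrate_beta_newton <- function(p, pars, tol = 1e-12, migration = NULL,
                                  max_iter = 200L) {
  N <- pars$N
  Ffun <- function(x) {
    st <- market_state(Sr = max(x[1], 0), Ir = max(x[2], 0),
                       Sv = max(x[3], 0), Iv = max(N - x[1] - x[2] - x[3], 0))
    pp <- pars; pp$beta <- x[4]
    d <- if (is.null(migration)) rhs_base(st, pp)
    else rhs_base_seeded(st, pp, pp$k *
                           ((1 - migration$i) * relocation_fraction(st, pp) +
                              migration$i *
                                external_mover_fraction(migration$e, pp$b)))
    c(d[["Sr"]], d[["Ir"]], d[["Sv"]], (st[["Ir"]] + st[["Iv"]]) / N - p)
  }
  # start from a deliberately crude guess (uniform split of the prevalence)
  x <- c(N * (1 - p) * 0.9, N * p * 0.9, N * (1 - p) * 0.1, 1)
  for (it in seq_len(max_iter)) {
    Fx <- Ffun(x)
    if (max(abs(Fx / c(N, N, N, 1))) < tol) break
    J <- matrix(0, 4, 4)
    h <- pmax(abs(x), 1) * 1e-7
    for (j in 1:4) {
      xp <- x; xp[j] <- xp[j] + h[j]
      xm <- x; xm[j] <- xm[j] - h[j]
      J[, j] <- (Ffun(xp) - Ffun(xm)) / (2 * h[j])
    }
    step <- tryCatch(solve(J, Fx), error = function(e)
      stop("numeric calibration failed: singular Jacobian", call. = FALSE))
    lam <- 1
    repeat {  # backtrack to keep the residual decreasing
      xn <- x - lam * step
      if (sum(Ffun(xn)^2) <= sum(Fx^2) || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- x - lam * step
  }
  if (max(abs(Ffun(x) / c(N, N, N, 1))) >= tol)
    stop("numeric calibration did not converge", call. = FALSE)
  if (x[4] <= 0)
    stop("calibration infeasible: numeric solution gives beta = ",
         signif(x[4], 6), " <= 0", call. = FALSE)
  x[4]
}

#' @export
print.calibrated_system <- function(x, ...) {
  cat(sprintf("Calibrated system: beta = %.6f at baseline prevalence p = %g\n",
              x$params$beta, x$params$p))
  cat("Endemic equilibrium (units):\n")
  print(round(x$equilibrium, 3))
  invisible(x)
}
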