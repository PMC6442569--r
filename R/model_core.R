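#' Fraction of movers originating in infested units
#'
#' The relocation-transmission pressure \eqn{f(t) = b I_r / (S_r + b I_r)}:
#' the fraction of tenants currently moving out of occupied units who come
#' from infested units, given that infestation raises the move-out rate by
#' the factor `b`. An incoming tenant seeds a new infestation in an S-class
#' unit with probability `k * f(t)`.
#'
#' @param state Named state vector with at least `Sr` and `Ir`.
#' @param pars A [market_params()] object.
#' @return A fraction in `[0, 1]`; defined as 0 in the degenerate empty
#'   market (`Sr = Ir = 0`, no occupied units and hence no movers).
#' @export
relocation_fraction <- function(state, pars) {
  Sr <- state[["Sr"]]; Ir <- state[["Ir"]]
  den <- Sr + pars$b * Ir
  if (den <= 0) return(0)
  pars$b * Ir / den
}

#' Time derivatives of the no-disclosure model
#'
#' Right-hand side of the closed four-compartment
#' susceptible-infested-susceptible market model. Units become infested by
#' infectious transmission (rate `beta * Sr * Ir / N`) or by relocation
#' transmission (an incoming tenant seeds a vacant unit with probability
#' `k * f`); infested units are treated at rate `gamma`; tenants move out at
#' rate `m` (times `b` if infested) and move in at rate `n`.
#'
#' @param state Named vector `(Sr, Ir, Sv, Iv)`.
#' @param pars A [market_params()] object with `beta` set.
#' @return Named vector of per-year rates of change; components sum to 0
#'   (the market is closed in units).
#' @export
rhs_base <- function(state, pars) {
  rhs_base_seeded(state, pars,
                  seed_prob = pars$k * relocation_fraction(state, pars))
}

# Base-model RHS with an arbitrary per-move-in seeding probability; the
# open-market (migration, s = 0) aggregate reduces to this form.
rhs_base_seeded <- function(state, pars, seed_prob) {
  Sr <- state[["Sr"]]; Ir <- state[["Ir"]]
  Sv <- state[["Sv"]]; Iv <- state[["Iv"]]
  q <- seed_prob
  inf <- pars$beta * Sr * Ir / pars$N
  c(Sr = -inf + pars$gamma * Ir + pars$n * (1 - q) * Sv - pars$m * Sr,
    Ir = inf + q * pars$n * Sv + pars$n * Iv -
      (pars$gamma + pars$b * pars$m) * Ir,
    Sv = pars$m * Sr + pars$gamma * Iv - pars$n * Sv,
    Iv = pars$b * pars$m * Ir - (pars$gamma + pars$n) * Iv)
}

#' Time derivatives of the disclosure model
#'
#' Right-hand side of the five-compartment model under a disclosure policy.
#' Infested-vacant units (`Iv`) are immediately disclosed; on treatment they
#' move to the susceptible-vacant-disclosed class (`Svp`), which returns to
#' the undisclosed pool `Sv` at rate `1/D`. Renter selectivity `s` reduces
#' the move-in rate to disclosed classes (`Iv`, `Svp`) by the factor
#' `(1 - s)` — a leaky quarantine. Relocation transmission seeds move-ins
#' into both `Sv` and `Svp` with probability `k * f`.
#'
#' @param state Named vector `(Sr, Ir, Sv, Iv, Svp)`.
#' @param pars A [market_params()] object with `beta` set.
#' @return Named vector of per-year rates of change; components sum to 0.
#'   With `s = 0` the induced dynamics of `(Sr, Ir, Sv + Svp, Iv)` coincide
#'   with [rhs_base()].
#' @export
rhs_disclosure <- function(state, pars) {
  rhs_disclosure_seeded(state, pars, seed_prob = pars$k *
                          relocation_fraction(state, pars))
}

# Shared disclosure-model RHS with an arbitrary per-move-in seeding
# probability; the migration variant only changes seed_prob.
rhs_disclosure_seeded <- function(state, pars, seed_prob) {
  Sr <- state[["Sr"]]; Ir <- state[["Ir"]]; Sv <- state[["Sv"]]
  Iv <- state[["Iv"]]; Svp <- state[["Svp"]]
  q <- seed_prob
  s <- pars$s
  inf <- pars$beta * Sr * Ir / pars$N
  c(Sr = -inf + pars$gamma * Ir + pars$n * (1 - q) * Sv +
      (1 - s) * pars$n * (1 - q) * Svp - pars$m * Sr,
    Ir = inf + pars$n * q * Sv + (1 - s) * pars$n * q * Svp +
      (1 - s) * pars$n * Iv - (pars$gamma + pars$b * pars$m) * Ir,
    Sv = pars$m * Sr + Svp / pars$D - pars$n * Sv,
    Iv = pars$b * pars$m * Ir - (pars$gamma + (1 - s) * pars$n) * Iv,
    Svp = pars$gamma * Iv - ((1 - s) * pars$n + 1 / pars$D) * Svp)
}

#' Time derivatives of the intermarket-migration model
#'
#' Open-population variant of [rhs_disclosure()]: a fraction `i` of tenants
#' moving into vacant units come from external markets with net infestation
#' prevalence `e`. External movers are weighted like internal ones — because
#' infestation raises the move-out rate by `b`, the fraction of external
#' movers who left an infested dwelling is
#' \eqn{f_{ext} = b e / (1 - e + b e)} (the same form as the internal
#' relocation fraction, evaluated at the external prevalence). The
#' probability that a move-in seeds an infestation becomes
#' `k * ((1 - i) * f + i * f_ext)`. Units do not migrate (the market stays
#' closed in units); only the origin mix of incoming tenants changes.
#'
#' @param state Named vector `(Sr, Ir, Sv, Iv, Svp)`.
#' @param pars A [market_params()] object with `beta` set.
#' @param mig A [migration_params()] object.
#' @return Named vector of per-year rates of change; components sum to 0.
#'   With `i = 0` this equals [rhs_disclosure()] exactly.
#' @export
rhs_migration <- function(state, pars, mig) {
  f <- relocation_fraction(state, pars)
  rhs_disclosure_seeded(state, pars,
                        seed_prob = pars$k * ((1 - mig$i) * f +
                                                mig$i * external_mover_fraction(mig$e, pars$b)))
}

#' Fraction of external movers originating in infested dwellings
#'
#' Applies the move-out weighting to an external market of net prevalence
#' `e`: infested dwellings shed tenants `b` times faster, so movers from
#' such a market come from infested dwellings with probability
#' `b*e / (1 - e + b*e)` (0 when `e = 0`; `e` itself when `b = 1`).
#'
#' @param e External net prevalence in `[0, 1)`.
#' @param b Vacancy multiplier (>= 1).
#' @return A fraction in `[0, 1]`.
#' @export
external_mover_fraction <- function(e, b) {
  b * e / (1 - e + b * e)
}

#' Disease-free market balance state
#'
#' The stationary occupancy split with no infestation: a fraction
#' `n/(n+m)` of units rented and `m/(n+m)` vacant.
#'
#' @param pars A [market_params()] object.
#' @param disclosure If `TRUE`, return a five-compartment state
#'   (with `Iv = Svp = 0`).
#' @return A named state vector.
#' @export
disease_free_state <- function(pars, disclosure = FALSE) {
  Sr <- pars$N * pars$n / (pars$n + pars$m)
  Sv <- pars$N * pars$m / (pars$n + pars$m)
  if (disclosure) market_state(Sr, 0, Sv, 0, Svp = 0)
  else market_state(Sr, 0, Sv, 0)
}
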