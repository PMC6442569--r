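#' Basic reproductive ratio with route decomposition
#'
#' Closed-form basic reproductive ratio of the disclosure model, obtained by
#' the next-generation-matrix method at the disease-free market balance:
#' \deqn{R_0 = \left(\beta\frac{n}{n+m} + k b m\right)
#'   \frac{\gamma + (1-s)n}{\gamma\,(\gamma + b m + (1-s)n)}.}
#' The parenthetical is the rate of new infestations per infested-occupied
#' unit, split over the two routes: infectious transmission of already
#' rented units (`beta * n/(n+m)`, the rented share at market balance) and
#' relocation transmission seeding previously vacant units (`k*b*m`). The
#' second factor is the mean time an infested unit remains infested before
#' treatment, counting time spent vacant; selectivity `s` shortens it by
#' keeping infested-vacant units out of circulation. `R_0` does not depend
#' on the disclosure period `D`.
#'
#' @param pars A [market_params()] object with `beta` set (typically via
#'   [calibrate_beta()]).
#' @return An object of class `r0_breakdown`: list with `r0`,
#'   `infectious_share`, `relocation_share` (fractions of the
#'   new-infestation rate at the disease-free equilibrium; they sum to 1),
#'   and `mean_infectious_time` (years, in `(0, 1/gamma]`).
#' @examples
#' sys <- calibrate_system(0.05, market_params(s = 0))
#' r0_closed_form(sys$params)  # ~1.05
#' @export
r0_closed_form <- function(pars) {
  validate_params(pars, require_beta = TRUE)
  infectious <- pars$beta * pars$n / (pars$n + pars$m)
  relocation <- pars$k * pars$b * pars$m
  rate <- infectious + relocation
  tau <- (pars$gamma + (1 - pars$s) * pars$n) /
    (pars$gamma * (pars$gamma + pars$b * pars$m + (1 - pars$s) * pars$n))
  structure(list(r0 = rate * tau,
                 infectious_share = if (rate > 0) infectious / rate else 1,
                 relocation_share = if (rate > 0) relocation / rate else 0,
                 mean_infectious_time = tau),
            class = "r0_breakdown")
}

#' @export
print.r0_breakdown <- function(x, ...) {
  cat(sprintf("R0 = %.4f (%s)\n", x$r0,
              if (x$r0 > 1) "infestation persists" else "infestation declines"))
  cat(sprintf("  infectious route: %.1f%%, relocation route: %.1f%%\n",
              100 * x$infectious_share, 100 * x$relocation_share))
  cat(sprintf("  mean infested time: %.4f y\n", x$mean_infectious_time))
  invisible(x)
}

#' Numeric next-generation-matrix R0
#'
#' Independent cross-check of [r0_closed_form()]. The infested subsystem
#' `(Ir, Iv)` of the disclosure model is linearized numerically at the
#' disease-free market balance; the new-infection matrix `F` is built by
#' numerically differentiating the new-infestation inflow (infectious plus
#' relocation seeding), the transition matrix is `V = F - J` with `J` the
#' numerical Jacobian of the infested subsystem, and `R0` is the spectral
#' radius of `F V^{-1}`.
#'
#' @param pars A [market_params()] object with `beta` set.
#' @return The dimensionless `R0` (a bare number).
#' @export
r0_ngm <- function(pars) {
  validate_params(pars, require_beta = TRUE)
  if (pars$gamma <= 0) stop("gamma must be positive (V singular)",
                            call. = FALSE)
  dfe <- disease_free_state(pars, disclosure = TRUE)
  # rate of NEW infestations (into Ir) as a function of the infested seed;
  # susceptible occupancies held at their disease-free values
  new_inf <- function(Ir, Iv) {
    st <- dfe; st[["Ir"]] <- Ir; st[["Iv"]] <- Iv
    f <- relocation_fraction(st, pars)
    c(pars$beta * st[["Sr"]] * Ir / pars$N +
        pars$n * pars$k * f * st[["Sv"]] +
        (1 - pars$s) * pars$n * pars$k * f * st[["Svp"]],
      0)  # nothing enters Iv as a new infestation (bm*Ir is a transfer)
  }
  infected_rhs <- function(Ir, Iv) {
    st <- dfe; st[["Ir"]] <- Ir; st[["Iv"]] <- Iv
    d <- rhs_disclosure(st, pars)
    c(d[["Ir"]], d[["Iv"]])
  }
  # central differences: the seeding term is nonlinear in Ir, and the
  # one-sided O(h) error would swamp the 1e-8 agreement with the closed form
  h <- 1e-6 * pars$N
  jac <- function(fun) {
    cbind((fun(h, 0) - fun(-h, 0)) / (2 * h),
          (fun(0, h) - fun(0, -h)) / (2 * h))
  }
  Fm <- jac(new_inf)
  J <- jac(infected_rhs)
  V <- Fm - J
  K <- Fm %*% solve(V)
  max(abs(eigen(K, only.values = TRUE)$values))
}

#' Threshold classification of the infestation dynamics
#'
#' Infestation persists at an endemic equilibrium when `R0 > 1` and declines
#' to zero when `R0 < 1`.
#'
#' @param pars A [market_params()] object with `beta` set.
#' @param boundary_tol Half-width of the indeterminate band around
#'   `R0 = 1`.
#' @return `"persists"`, `"declines"`, or `"boundary"` when `R0` is within
#'   `boundary_tol` of 1.
#' @export
threshold_classification <- function(pars, boundary_tol = 1e-6) {
  r0 <- r0_closed_form(pars)$r0
  if (abs(r0 - 1) <= boundary_tol) return("boundary")
  if (r0 > 1) "persists" else "declines"
}
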