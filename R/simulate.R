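#' Integrate the market model over time
#'
#' Deterministic time integration of the chosen model variant with three
#' event accumulators carried as extra ODE components (a single solve, no
#' post-hoc quadrature): cumulative treatments per unit
#' (\eqn{\int \gamma (I_r + I_v)\,dt / N}), cumulative move-in (turnover)
#' events per unit, and cumulative vacant unit-years per unit. The
#' accumulators feed the landlord cost accounting in
#' [annual_cost_components()].
#'
#' @param pars A [market_params()] object with `beta` set.
#' @param model One of `"base"` (closed, no disclosure), `"disclosure"`, or
#'   `"migration"` (disclosure with open tenant population).
#' @param init Initial state; defaults to the calibrated endemic equilibrium
#'   ([endemic_equilibrium()] at `pars$p`), with the disclosed-vacant class
#'   `Svp` empty for the disclosure/migration models (infested-vacant units
#'   are immediately disclosed, so the pre-policy `Iv` stock starts in `Iv`).
#' @param horizon Length of the run in years.
#' @param report_step Reporting interval in years. The reported grid always
#'   contains every integer year (annual costs are read off these points).
#' @param migration A [migration_params()] object (required when
#'   `model = "migration"`).
#' @param rtol,atol Integrator tolerances (`atol` is scaled by `N`).
#' @return A `market_trajectory`: a data.frame with columns `t`, `Sr`, `Ir`,
#'   `Sv`, `Iv`, `Svp` (0 for the base model), `prevalence`
#'   (`(Ir + Iv)/N`), `f` (relocation fraction), and the per-unit
#'   accumulators `acc_treatments`, `acc_turnovers`, `acc_vacancy`.
#'   Attributes `params`, `model`, and `migration` record the run.
#' @examples
#' sys <- calibrate_system(0.05)
#' traj <- simulate_market(sys$params, "disclosure", horizon = 10)
#' traj[traj$t == 10, "prevalence"]  # ~0.027 at defaults
#' @export
simulate_market <- function(pars, model = c("base", "disclosure", "migration"),
                            init = NULL, horizon = 20, report_step = 1,
                            migration = NULL, rtol = 1e-8, atol = NULL) {
  model <- match.arg(model)
  validate_params(pars, require_beta = TRUE)
  if (model == "migration") {
    if (is.null(migration)) stop("model = \"migration\" requires `migration`",
                                 call. = FALSE)
    stopifnot(inherits(migration, "migration_params"))
  }
  if (is.null(atol)) atol <- 1e-10 * pars$N
  stopifnot(horizon >= report_step, report_step > 0)
  if (is.null(init)) {
    init <- endemic_equilibrium(pars$p, pars)
    if (model != "base") init <- as_disclosure_state(init)
  }
  disclosed <- model != "base"
  if (disclosed) init <- as_disclosure_state(init)
  if (abs(sum(init) - pars$N) > 1e-6 * pars$N)
    stop("initial state does not sum to N", call. = FALSE)

  times <- sort(unique(c(seq(0, horizon, by = report_step),
                         0:floor(horizon), horizon)))
  y0 <- c(init, acc_treatments = 0, acc_turnovers = 0, acc_vacancy = 0)

  deriv <- function(t, y, parms) {
    st <- y[seq_along(init)]
    d <- switch(model,
                base = rhs_base(st, pars),
                disclosure = rhs_disclosure(st, pars),
                migration = rhs_migration(st, pars, migration))
    Svp <- if (disclosed) st[["Svp"]] else 0
    s_eff <- if (disclosed) pars$s else 0
    acc <- c(pars$gamma * (st[["Ir"]] + st[["Iv"]]) / pars$N,
             pars$n * (st[["Sv"]] + (1 - s_eff) * Svp +
                         (1 - s_eff) * st[["Iv"]]) / pars$N,
             (st[["Sv"]] + Svp + st[["Iv"]]) / pars$N)
    list(c(d, acc))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  out <- as.data.frame(sol)
  names(out)[1] <- "t"
  if (!disclosed) out$Svp <- 0
  state_cols <- c("Sr", "Ir", "Sv", "Iv", "Svp")
  if (any(as.matrix(out[state_cols]) < -1e-9 * pars$N))
    stop("integration produced a negative compartment beyond tolerance",
         call. = FALSE)
  out$prevalence <- (out$Ir + out$Iv) / pars$N
  out$f <- ifelse(out$Sr + pars$b * out$Ir > 0,
                  pars$b * out$Ir / (out$Sr + pars$b * out$Ir), 0)
  out <- out[c("t", state_cols, "prevalence", "f",
               "acc_treatments", "acc_turnovers", "acc_vacancy")]
  structure(out, params = pars, model = model, migration = migration,
            class = c("market_trajectory", "data.frame"))
}

#' Prevalence at a reported time
#'
#' @param traj A `market_trajectory`.
#' @param t Time (years) present on the reported grid.
#' @return Prevalence `(Ir + Iv)/N` at time `t`.
#' @export
prevalence_at <- function(traj, t) {
  i <- which(abs(traj$t - t) < 1e-9)
  if (length(i) == 0) stop("time ", t, " not on the reported grid",
                           call. = FALSE)
  traj$prevalence[i[1]]
}
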