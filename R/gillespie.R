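#' Exact stochastic simulation of the disclosure model
#'
#' Event-driven continuous-time Markov chain whose propensities are exactly
#' the flow terms of the disclosure model: infection (`beta*Sr*Ir/N`),
#' move-outs (`m*Sr`, `b*m*Ir`), move-ins (`n*Sv`, `(1-s)*n*Svp`,
#' `(1-s)*n*Iv`, with S-class move-ins resolved as seeded with probability
#' `k*f` at the current state), treatments (`gamma*Ir`, `gamma*Iv`), and
#' disclosure expiry (`Svp/D`). The direct (exact) method is used; states
#' are integer occupancies conserving `N` at every event. Serves as the
#' demographic-noise oracle against the mean-field ODE: replicate means
#' converge to [simulate_market()] output as `N` grows.
#'
#' @param pars A [market_params()] object with `beta` set.
#' @param init Integer five-compartment state summing to `N`; default is
#'   the endemic equilibrium rounded to integers (`Svp = 0`).
#' @param horizon Years to simulate.
#' @param seed Integer RNG seed; identical seeds replay identical event
#'   sequences. The caller's RNG state is restored on exit.
#' @param report_step Interval (years) of the summarized state table.
#' @param keep_events Keep the full event log (times, types, state after
#'   each event). Memory scales with the event count (~`2.5*N` events per
#'   year at default rates), so leave `FALSE` for large `N`.
#' @return A list of class `event_trajectory`: `yearly` (data.frame `t`,
#'   `Sr`, `Ir`, `Sv`, `Iv`, `Svp`, `prevalence` at the report grid),
#'   `counts` (named event counts: infection, move_out, move_in_clean,
#'   move_in_seeded, treatment, disclosure_expiry), `final`, `final_time`,
#'   `rng_seed`, and (if kept) `events`.
#' @examples
#' sys <- calibrate_system(0.05)
#' run <- gillespie_run(sys$params, horizon = 2, seed = 1)
#' run$yearly
#' @export
gillespie_run <- function(pars, init = NULL, horizon = 20, seed = 1,
                          report_step = 1, keep_events = FALSE) {
  validate_params(pars, require_beta = TRUE)
  if (is.null(init)) {
    eq <- as_disclosure_state(endemic_equilibrium(pars$p, pars))
    init <- round_state_to_N(eq, pars$N)
  }
  init <- as_disclosure_state(init)
  if (any(init != round(init)) || abs(sum(init) - pars$N) > 1e-9)
    stop("init must be an integer state summing to N", call. = FALSE)
  report_times <- sort(unique(c(seq(0, horizon, by = report_step), horizon)))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  raw <- gillespie_core(as.numeric(init), pars$beta, pars$gamma, pars$k,
                        pars$b, pars$m, pars$n, pars$s, pars$D, pars$N,
                        report_times, keep_events)
  yearly <- as.data.frame(raw$report)
  names(yearly) <- c("t", "Sr", "Ir", "Sv", "Iv", "Svp")
  yearly$prevalence <- (yearly$Ir + yearly$Iv) / pars$N
  counts <- as.integer(raw$counts)
  names(counts) <- c("infection", "move_out", "move_in_clean",
                     "move_in_seeded", "treatment", "disclosure_expiry")
  out <- list(yearly = yearly, counts = counts,
              final = stats::setNames(raw$final,
                                      c("Sr", "Ir", "Sv", "Iv", "Svp")),
              final_time = raw$final_time, rng_seed = seed, params = pars)
  if (keep_events)
    out$events <- data.frame(
      t = raw$event_times,
      type = names(counts)[raw$event_types + 1L],
      Sr = raw$event_states[, 1], Ir = raw$event_states[, 2],
      Sv = raw$event_states[, 3], Iv = raw$event_states[, 4],
      Svp = raw$event_states[, 5])
  structure(out, class = "event_trajectory")
}

#' Replicate stochastic runs, summarized yearly
#'
#' @param pars A [market_params()] object with `beta` set.
#' @param replicates Number of independent runs.
#' @param horizon Years per run.
#' @param seed Base seed; replicate `j` uses `seed + j - 1`.
#' @param init Optional integer initial state (see [gillespie_run()]).
#' @return A data.frame with columns `replicate`, `t`, `Sr`, `Ir`, `Sv`,
#'   `Iv`, `Svp`, `prevalence`.
#' @export
gillespie_replicates <- function(pars, replicates = 10, horizon = 20,
                                 seed = 1, init = NULL) {
  do.call(rbind, lapply(seq_len(replicates), function(j) {
    run <- gillespie_run(pars, init = init, horizon = horizon,
                         seed = seed + j - 1)
    cbind(replicate = j, run$yearly)
  }))
}

# Round a continuous state to integers preserving the total N
# (largest-remainder assignment).
round_state_to_N <- function(state, N) {
  fl <- floor(state)
  rem <- state - fl
  short <- as.integer(round(N - sum(fl)))
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    fl[ord[seq_len(short)]] <- fl[ord[seq_len(short)]] + 1
  }
  fl
}

#' @export
print.event_trajectory <- function(x, ...) {
  cat(sprintf("Stochastic run (seed %d): %s events over %.3g y, N = %g\n",
              x$rng_seed, format(sum(x$counts), big.mark = ","),
              x$final_time, x$params$N))
  print(x$counts)
  invisible(x)
}
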