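# Shared fixtures; heavier runs are cached so multiple test files can reuse
# the default 20-year policy analysis without recomputing it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_system <- function() cached("sys", calibrate_system(0.05, market_params()))

default_analysis <- function() cached("analysis",
  disclosure_analysis(market_params(), cost_rates(), horizon = 20))

# random valid market states (uniform on the simplex, scaled to N)
random_state <- function(N = 1000, disclosed = FALSE, rng = NULL) {
  k <- if (disclosed) 5L else 4L
  w <- stats::rexp(k)
  x <- N * w / sum(w)
  if (disclosed) market_state(x[1], x[2], x[3], x[4], Svp = x[5])
  else market_state(x[1], x[2], x[3], x[4])
}

# parameter draws over the sensitivity ranges (prevalence-calibratable)
random_params <- function() {
  market_params(k = stats::runif(1, 0, 1),
                b = stats::runif(1, 1, 5),
                s = stats::runif(1, 0.01, 1),
                duration_months = stats::runif(1, 2, 12),
                p = stats::runif(1, 0.001, 0.1))
}
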