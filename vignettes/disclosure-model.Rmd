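---
title: "A market-coupled SIS model of bed bug infestation under disclosure policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A market-coupled SIS model of bed bug infestation under disclosure policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedbugsis)
```

## The model and its assumptions

The unit of infection is a *rental unit*. Units are susceptible (bed bug
free) or infested, and occupied or vacant; under a disclosure policy a
fifth class holds treated-but-still-flagged vacant units. The closed
system is

\[
\begin{aligned}
\dot S_r &= -\beta S_r I_r/N + \gamma I_r + n(1-kf)S_v - mS_r\\
\dot I_r &= \beta S_r I_r/N + k f n S_v + n I_v - (\gamma + bm) I_r\\
\dot S_v &= m S_r + \gamma I_v - n S_v\\
\dot I_v &= b m I_r - (\gamma + n) I_v,
\end{aligned}
\qquad f = \frac{b I_r}{S_r + b I_r},
\]

with move-out rate $m$, move-in rate $n$, treatment rate $\gamma$, and a
vacancy multiplier $b \ge 1$ expressing that tenants flee infested units
faster. New infestations arise two ways. *Infectious transmission* brings
bugs into occupied units at rate $\beta S_r I_r / N$ — homogeneous mixing,
as in classic compartmental models, here meaning any two units are equally
likely to exchange people or objects. *Relocation transmission* seeds a
unit at move-in with probability $k f$: $f$ is the fraction of current
movers who left infested units (the $b$-weighting makes infested units
over-represented among movers), and $k$ the chance such a mover establishes
a new infestation.

Under disclosure, infested-vacant units are flagged immediately, treated
ones move to the disclosed class $S_v'$ and revert to $S_v$ at rate $1/D$,
and the move-in rate to flagged classes is reduced by the renter
selectivity $s$ — a *leaky quarantine*, total at $s=1$, absent at $s=0$.
With $s=0$ the five-class system reduces exactly to the base model under
the aggregation $S_v + S_v'$; this reduction is enforced by tests at both
the derivative and the trajectory level.

Key structural assumptions: units are homogeneous in market and
transmission parameters; the market is closed in units (N constant);
treatment is the only exit from infestation, with exponentially distributed
treatment times; disclosure lapses as a continuous rate rather than a fixed
term; rents are inelastic (landlords let flagged units sit vacant rather
than discount them).

## Parameters

All rates are per year; durations in years except where months are the
natural unit.

| parameter | meaning | default | rationale |
|---|---|---|---|
| `p` | baseline prevalence | 0.05 | city-level survey estimates (~5%) |
| `beta` | infectivity | calibrated | not observable; see below |
| `s` | renter selectivity | 0.5 | theoretical mid-range; swept 0.01–1 |
| `1/gamma` | mean infestation duration | 6 mo | detection and treatment delays; swept 2–12 mo |
| `k` | relocation-transmission probability | 0.3 | intermediate value; swept 0–1 |
| `b` | vacancy multiplier | 1.3 | conservative 30% excess move-out; swept 1–5 |
| `m` | move-out rate | 0.5 | mean tenancy of 2 y |
| `n` | move-in rate | 6 | gives a low-prevalence vacancy share $m/(n+m) \approx 7.7\%$, near the US rental vacancy average |
| `D` | disclosure period | 1 y | typical mandated length |
| `N` | market size | 1000 | per-unit results are N-invariant (tested) |
| `c_trt`, `c_tov`, `c_vac` | treatment, turnover, vacancy-month costs | \$1225, \$1000, \$1000 | national medians; `c_vac` is the monthly rent |

## Calibration

$\beta$ cannot be measured, but the baseline prevalence can, and field
prevalences are assumed to represent a market at or near equilibrium. The
endemic equilibrium of the base model at prevalence $p$ follows from
stationarity: $\dot I_v = 0$ fixes $I_r^*/I_v^* = (\gamma+n)/(bm)$,
$\dot S_v = 0$ fixes the susceptible split, and conservation closes the
system. Setting $\dot I_r = 0$ there yields

\[
\beta = \frac{N}{S_r^* I_r^*}\Big[(\gamma+bm)I_r^* -
  k\tfrac{bI_r^*}{S_r^*+bI_r^*}\,n S_v^* - n I_v^*\Big].
\]

At the defaults this gives $\beta = 2.2573$ (2.4692 with $k=0$, since
removing relocation transmission forces infectious transmission to carry
the whole load). If the bracket is non-positive — relocation transmission
alone more than sustains $p$, which happens at high $k$, high $b$ and slow
treatment — calibration is infeasible and signalled as an error rather
than returning a negative infectivity.

An independent numeric calibration (damped Newton on the full stationarity
system with the prevalence constraint, numerical Jacobian) is exposed via
`calibrate_beta(method = "numeric")` and agrees with the closed form to
below $10^{-10}$; it exists purely as a cross-check of the algebra.

## Threshold behaviour

The next-generation-matrix construction on the infested subsystem
$(I_r, I_v)$ at the disease-free market balance gives

\[
R_0 = \Big(\beta\tfrac{n}{n+m} + kbm\Big)\,
\frac{\gamma + (1-s)n}{\gamma\,(\gamma + bm + (1-s)n)} .
\]

The parenthetical is the new-infestation rate per infested-occupied unit,
split between the infectious route ($\beta$ times the rented share) and
the relocation route ($kbm$: movers leave at $bm$ and seed with
probability $k$ — the $S_v$ occupancy and the $1/S_r$ in $f$'s
linearisation cancel exactly, so no $n/(n+m)$ factor multiplies this
term; the numeric NGM of the full model confirms this parse). The second
factor is the mean time a unit remains infested, counting time spent
vacant; selectivity shortens it by keeping flagged units out of
circulation, which is the entire mechanism by which disclosure lowers
$R_0$. $D$ does not appear: the disclosure period affects costs, never
persistence.

At calibrated defaults $R_0 = 1.054$ without disclosure — the endemic
market sits just above threshold — and falls to 0.86 at $s=1$. (A value of
0.88 has circulated for the full-quarantine case; the formula above and
the numeric NGM both give 0.86 with $\beta$ calibrated to 5%, and the
package reports what it computes.) `r0_ngm()` rebuilds $R_0$ by numerical
linearisation (central differences; one-sided differencing is not accurate
enough for the $10^{-8}$ agreement the tests demand, because the seeding
term is nonlinear in $I_r$) and matches the closed form across a 200-point
Latin-hypercube sample of the sensitivity ranges.

## Cost accounting

Landlord cost of disclosure in policy year $y$ (the interval $[y-1, y]$;
the policy starts at $t=0$ from the pre-policy equilibrium with the
disclosed class empty) is the difference, disclosure minus no-disclosure,
of three integrated event streams priced at constant rates: treatments
$\int \gamma(I_r+I_v)\,dt/N$, turnovers (move-ins)
$\int n(S_v + (1-s)S_v' + (1-s)I_v)\,dt/N$, and vacant unit-years
$\int (S_v + S_v' + I_v)\,dt/N$, the last priced at $12\,c_{vac}$ since
rent is monthly. The accumulators are integrated as extra ODE components in
the same solve as the state (relative tolerance $10^{-8}$, absolute
$10^{-10}N$), not by post-hoc quadrature of yearly samples — the vacancy
transient after policy start has a time scale of $1/n$ (two months), which
yearly-grid quadrature visibly distorts. The comparator run uses identical
integrator settings so discretisation bias cancels in the differences.

At the defaults the annual cost peaks at \$26.6/unit in year 2, turns into
savings in year 5 (year 9 cumulatively), and prevalence falls from 5% to
2.7% by year 10. Discounting (`discount_costs()`) applies the standard
$(1+r)^{-y}$ factor per year and recomputes the cumulative series;
break-even detection ignores totals within $10^{-6}$ of zero so that the
identically-zero $s=0$ policy never "breaks even" on integrator noise.

## Sensitivity analyses

`sensitivity_oat()` varies one of the hard-to-estimate parameters ($k$,
$1/\gamma$, $b$) while **recalibrating $\beta$ to the same baseline
prevalence** — the observable is held fixed and the infectivity absorbs
the change. "Savings" is the negative of the *annual* year-20 total (the
cost surfaces are reported per year); the cumulative analogue is also
returned for transparency. Computed behaviour at the defaults: doubling
$k$ changes year-20 prevalence and savings by ~1% (the recalibration
almost exactly compensates); doubling $b$ cuts year-20 prevalence by a
factor of 2.52 and multiplies savings by 2.53; doubling $1/\gamma$ leaves
year-20 prevalence nearly unchanged but *reduces* annual savings by 62%.

That last direction deserves a note, since slower treatment is sometimes
expected to make disclosure look better. Under this cost definition it
cannot: the dominant savings channel is averted treatments, whose dollar
flow is $c_{trt}\gamma\,\Delta\!\int(I_r{+}I_v)$ and therefore scales with
$\gamma$. With $\gamma$ halved, even complete eradication bounds the
treatment savings near \$67/unit/yr, turnover adds at most a few dollars,
and the vacancy difference cannot fall below the baseline's small
infested-vacancy excess (disclosure can only add vacancy relative to the
disease-free floor) — so year-20 savings larger than the default run's
\$67/unit/yr are unreachable at $1/\gamma = 12$ mo. Conversely *shortening*
the duration to 2–3 months raises annual savings by roughly 50–60%. The
package reports the computed direction.

## Intermarket migration

The open-population variant lets a fraction $i$ of incoming tenants
originate in external markets with net prevalence $e$; units do not
migrate. Two design choices were genuinely open, and both are resolved the
same way the internal market is treated:

1. **External movers are $b$-weighted.** Among movers out of a market with
   unit-prevalence $e$, the fraction who left infested dwellings is
   $f_{ext} = be/(1-e+be)$ — the same form as the internal $f$. The
   per-move-in seeding probability becomes
   $k\,[(1-i)f + i\,f_{ext}]$. (The unweighted alternative, using $e$
   directly, was implemented and compared; it weakens external pressure
   and was not retained.)
2. **Calibration includes migration.** If tenants migrate after the policy
   starts, they migrated before it too, so the observed 5% baseline is
   taken as the equilibrium of the *open* no-disclosure market and $\beta$
   is calibrated against it ($\beta$ falls to 2.138 at $i=e=0.2$, external
   seeding absorbing the difference). The no-disclosure comparator for
   costs is the same open market, which is stationary by construction.

With $i=0$ both choices reduce exactly to the closed model (tested). At
$i = e = 0.2$ prevalence falls only to 3.67% after 10 years versus 2.7%
closed; with external prevalence comparable to baseline ($e = 5\%$) even
$i = 40\%$ migration changes the 10-year prevalence by ~0.6 percentage
points, and annual savings appear by year 10 in all migration scenarios
examined.

## Stochastic counterpart

`gillespie_run()` simulates the exact continuous-time Markov chain whose
propensities are the disclosure model's flow terms, with integer states
conserving $N$ at every event (the event loop is compiled; ~2.5N events
per simulated year at the defaults). Move-ins from susceptible classes are
resolved seeded-vs-clean by a single uniform draw against $k f$ at the
current state, matching the ODE's instantaneous-probability reading. Runs
replay exactly under a fixed seed, and the caller's RNG stream is
restored afterwards.

The chain serves as an oracle for the mean-field ODE: replicate-mean
prevalence converges to the deterministic trajectory as $N$ grows (tested
at $N = 10^3, 10^4, 10^5$), while at small $N$ demographic noise produces
eliminations even where $R_0 > 1$ predicts persistence — a real feature of
near-threshold systems that the ODE cannot show. Tau-leaping was not
implemented; the direct method is comfortably fast at the market sizes of
interest.

## What the deterministic runs do and do not show

Everything here is generated by the model itself — there is no external
data path. Passing tests therefore demonstrate internal consistency
(conservation, reductions, closed forms vs. numerics, CTMC vs. ODE), and
reproduction of the reference scenario's published headline figures, *not*
fit to observed infestation data. Features of real markets deliberately
absent: rent elasticity (landlords discounting flagged units — omitting it
overstates vacancy costs), heterogeneity across units and neighbourhoods
(a disconnected high-prevalence subpopulation can be explored with
`structured_population()`, but there is no partial mixing), seasonality,
network/spatial contact structure, landlord non-compliance, and feedback
of disclosure pressure on treatment rates.

## Numerical choices, edge cases and problem sizes

* `lsoda` with rtol $10^{-8}$, atol $10^{-10}N$; reported grids always
  include every integer year. Negative excursions beyond $10^{-9}N$ abort
  with an error rather than being clipped.
* The relocation fraction is defined as 0 in an empty market
  ($S_r = I_r = 0$), keeping the vector field total.
* Equilibria with a negative compartment (pathological $p$ near 1) and
  non-positive calibrated $\beta$ raise informative errors.
* `threshold_classification()` returns a `"boundary"` flag within
  $10^{-6}$ of $R_0 = 1$ instead of forcing a class.
* Default sweep resolution is 25×25 (configurable); the test suite uses
  3×3–2×3 grids, 5–20-year horizons, and stochastic replicate counts of
  8–60, sized so the whole suite runs in well under a minute on one CPU
  while still exercising every code path.
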