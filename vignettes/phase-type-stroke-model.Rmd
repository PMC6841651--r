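---
title: "Methods: a labelled phase-type model of stroke recovery and discharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a labelled phase-type model of stroke recovery and discharge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`phrex` treats a stroke in-patient stay as the time to absorption of a
continuous-time Markov chain on four transient recovery phases and three
absorbing discharge modes (death, private nursing home, usual residence).
The phases are *labelled*: phase 1 is the acute haemorrhagic state, phase 2
the infarction entry state, phase 3 the common late recovery state, and
phase 4 a short-stay state visited only by mild TIA events. This labelling
is the central modelling commitment. It buys two things: the entry phase is
observed (it is the diagnosis), so the likelihood of an observed
(stay, destination) pair is a short closed-form expression rather than a
latent-path sum; and every phase and rate has a clinical reading, so the
fitted object supports interpretable key performance indicators.

The assumptions that matter:

* **Markov sojourns.** Each phase is left at a constant total rate; stay
  distributions are therefore phase-type (mixtures/convolutions of
  exponentials). This fits right-skewed hospital stay data well but cannot
  express non-monotone hazards within a phase.
* **Age acts on progression and on TIA severity, not on exits.** The
  progression intensities are log-linear in age,
  $\lambda_i(x) = \exp(\gamma_i + \beta_i x)$, $i = 1, 2$, and the mild-TIA
  probability is complementary log-log,
  $p(x) = \exp\{-\exp(\theta_0 + \theta_1 x)\}$. The exit rates
  $\mu_i, \nu_i, \rho_i$ are age-free: age changes how quickly patients move
  to milder phases, which induces the observed age gradients in mortality
  and destination without separate age terms per exit.
* **Structural zeros.** Phase 4 can only discharge home
  ($\mu_4 = \nu_4 = 0$, always). The *revised* model additionally fixes
  $\nu_1 = \nu_2 = \rho_1 = 0$ — no nursing-home transfer from the acute
  phases and no home discharge from phase 1 — which is both what the data
  support (see pruning below) and clinically sensible.
* **No censoring.** Every record ends in one of the three discharges; the
  likelihood has no censored contributions.

## Parameters, units, defaults

The sixteen estimable parameters are the six link coefficients
($\gamma_1, \beta_1, \gamma_2, \beta_2$ on the log scale per year;
$\theta_0, \theta_1$ dimensionless, age in years) and ten exit rates per
year. The package stores them in a `stroke_params` object together with the
`zero_mask` (default `{nu1, nu2, rho1}`) and the day-count constant.

* **`days_per_year` (default 365.25).** Rates are per year; stays are read
  and reported in days. Both 365 and 365.25 reproduce the shipped
  estimate set's destination and mean-stay tables to one decimal; 365.25 is
  the default and the constant is exposed in the parameter object and the
  YAML config.
* **Ages are continuous** (years, fractional allowed); integer ages from
  administrative files are used as-is, never binned.
* **Mode order** is fixed everywhere as (death, nursing home,
  usual residence), matching the ($\mu, \nu, \rho$) columns of the
  absorption-rate matrix, and phases are 1-based in all output.
* **Unknown diagnosis codes are rejected** at parse time. Administrative
  data also contain "unspecified" stroke admissions; the model has no
  pathway for them, and silently merging them into a type would bias the
  severity mix, so the reader refuses them with a row-level error.

## Numerical evaluation

Because the transient generator $T$ is upper bidiagonal, $\alpha' e^{Ty}$
is evaluated in closed form via divided differences of
$\varphi(r) = e^{-ry}$ over the total exit rates $\Lambda_1, \Lambda_2,
\Lambda_3$: the first divided difference is computed through `expm1` to
avoid cancellation, and the second through a sorted recursion. When two
rates agree to better than a relative gap of `1e-7` the exact limit forms
($y e^{-ry}$, $y^2 e^{-ry}/2$) are substituted; the switch is continuous to
about `1e-6`, which matters because the optimizer is free to wander through
ties. The same divided differences *are* the likelihood contributions, so
the density and the likelihood cannot drift apart. An independent
uniformization (scaled Taylor series) matrix exponential is kept in the
package as `oracle_density()` and used by the test-suite to verify the
closed form to `1e-8` relative on a thousand random parameter/record pairs.

Conditional means use back-substitution on the triangular system
$(-T)x = v$ rather than a general inverse. Reported tables round half away
from zero at one decimal; raw values are always available
(`digits = NULL`).

## Estimation

The staged backward fit mirrors the pathway structure:

1. TIA records alone estimate $\theta_0, \theta_1, \mu_3, \nu_3, \rho_3,
   \rho_4$;
2. with those fixed, infarction records estimate $\gamma_2, \beta_2, \mu_2,
   \nu_2, \rho_2$;
3. TIA + infarction records jointly re-estimate all eleven (the joint
   update is a genuine simultaneous refit, not a sweep);
4. with those fixed, haemorrhagic records estimate $\gamma_1, \beta_1,
   \mu_1, \nu_1, \rho_1$;
5. all records free every unmasked parameter, started from the staged
   estimates plus two jittered restarts (jitter sd 0.05 on the transformed
   scale, seeded), best log-likelihood wins.

Optimization runs on a transformed scale — log for rates (positivity),
identity for the link coefficients — with `optim`'s L-BFGS-B
(`factr = 1e7`, gradient step `ndeps = 1e-6`, log-rates bounded in
$[\log 10^{-8}, \log 10^4]$). Line searches can stall on the flat
$(\theta_0, \theta_1)$ ridge, so an uncertified stop triggers a
Nelder–Mead polish alternated with a fresh quasi-Newton pass, and a stop is
accepted as converged when the projected finite-difference gradient falls
below 0.5 on the transformed scale. Where no prior stage supplies starting
values, method-of-moments values are used: exit rates as
(mode fraction)/(mean sojourn), the mild-TIA mixing fraction from the share
of sub-7-day home discharges, flat age slopes.

Standard errors come from the observed information — the negative Hessian
of the log-likelihood by central differences on the transformed scale
(relative step `1e-4`) — inverted and mapped to the natural scale by the
delta method, matching the convention of reporting natural-scale rates with
normal-theory errors. The Hessian is always recomputed this way for
determinism rather than recycled from the optimizer. When a direction
carries no information (typically a rate pinned at zero in an
over-parameterised fit) the information matrix is singular; its near-null
eigenvalues are mapped to *large* variances, not discarded, so that the
corresponding Z statistics correctly collapse toward zero. The fit records
a `pseudo_inverse` flag when this happens.

**Pruning.** `prune_rates()` masks every rate with two-sided $p$ above the
threshold (default 0.90) *and* magnitude below a floor (default 0.05/yr),
then refits. It refuses to disconnect phase 3 from absorption or remove the
only phase-4 exit. On cohorts simulated under the revised model, the full
sixteen-parameter fit followed by pruning removes only rates within
$\{\nu_1, \nu_2, \rho_1\}$ — the module's null behaviour, exercised in the
test-suite.

## The cohort simulator

`simulate_cohort()` draws phase paths by competing exponentials, so the
simulator and the likelihood describe exactly the same process; the
test-suite checks the empirical stay distribution against the closed-form
CDF (Kolmogorov–Smirnov at $n = 10^4$) and the empirical destination
fractions against $\alpha' P$.

The default profile emulates the motivating hospital cohort: $n = 1{,}234$,
stroke-type mix proportional to 139 haemorrhagic : 707 infarction :
410 TIA, and — because the true admission-age distribution is not
published — ages from a normal distribution (mean 75, sd 10) truncated to
[40, 100], chosen so the three standard reporting ages (65, 75, 85) are
well covered. Stays are emitted in fractional days by default, with an
integer-rounding option to mimic administrative granularity.

What passing simulator-based tests does *not* show: the synthetic cohort is
generated by the model itself, so recovery and calibration results
demonstrate internal consistency of estimator and simulator, not fit to any
real hospital's data. Real discharge data have day-granular stays,
administrative artefacts (weekend discharge peaks, transfers), and
unmodelled heterogeneity; none of these are emulated.

## Goodness of fit

For each stroke type, discharge mode and age band (defaults [60,70),
[70,80), [80,90)), `gof_report()` overlays the Nelson–Aalen estimate of the
cause-specific cumulative intensity — competing discharges treated as
right-censoring, the standard construction — with the model curve
$\int_0^t \alpha' e^{Ts} t_A e_m / (\alpha' e^{Ts} 1_4)\, ds$ evaluated by
trapezoidal quadrature (100 subdivisions per reporting interval; halving
changes results by under `1e-6`). Confidence limits are log-transformed
95% intervals with the $\sum d_i/n_i^2$ variance; the log variant is chosen
because it respects positivity — the plain variant is the main alternative
and differs negligibly at these event counts. The summary statistic per
cell is the *coverage fraction*: the share of event-time grid points at
which the model curve lies inside the nonparametric band. On cohorts of
$10^4$ per band simulated from the model itself the median cell coverage
sits near 0.99 — the module's null calibration. Cells with fewer than 10
events of a mode are skipped and listed rather than compared.

## Problem sizes used in the checks

The shipped verification uses cohorts of 5,000 patients and 20 replicates
for parameter recovery, 5,000 for pruning, and $3 \times 10^4$ for the
diagnostics calibration; these sizes give per-parameter standardised-error
medians stable to a few hundredths while keeping the whole suite
comfortably fast on a single core.

## Known limitations

* The $(\theta_0, \theta_1)$ pair is weakly identified: the two
  coefficients are correlated at about $-0.99$, and the profile
  log-likelihood along the ridge is extremely flat. In recovery experiments
  their standardised errors are overdispersed (sd of $z$ near 1.5 versus
  the nominal 1, with a mild positive bias), so occasional replicates place
  the pair beyond three marginal standard errors of the truth even at the
  exact maximum-likelihood point. Joint (profile or Wald-ellipse) intervals
  for the pair are more faithful than marginal ones. The same holds more
  mildly for $(\gamma_i, \beta_i)$; centring age would decorrelate all
  three pairs at the cost of non-standard reporting, and was deliberately
  not done.
* The conditional death probability given an incurred stay is *not*
  globally monotone: it falls steeply over the acute weeks, dips below the
  phase-3 share $\mu_3/(\mu_3+\nu_3+\rho_3)$, then climbs back toward it.
  Summaries should not assume monotone improvement.
* Exit rates are age-free by design; cohorts with strong within-phase age
  effects on discharge would need the link structure extended.
* No censored stays, no arrival process or occupancy modelling, and no
  intervention (thrombolysis/delayed-discharge) states are included.
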