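---
title: "Methods: nested Monte Carlo estimation of the probability of pharmacological success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested Monte Carlo estimation of the probability of pharmacological success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pops)
```

## The estimand and the estimator

Early-development dose decisions hinge on a joint question: can most
patients reach adequate pharmacology while few are exposed to safety risk,
given what is *not* yet known — the true potency, the translation from
animals or in vitro systems to patients, and even the level of response
that will count as adequate? The probability of pharmacological success
(PoPS) formalises this as the probability, over all of those uncertainties,
that a virtual patient population meets every pre-specified benefit and
risk criterion at a given dose.

Two sources of randomness are deliberately kept distinct:

* **uncertainty** (what we do not know about the drug-disease system):
  priors on fixed effects and translation factors, on the magnitude of
  between-subject variability, and on the criteria themselves (threshold
  `K`, required proportion `n`). One joint realisation defines one
  *virtual trial*.
* **between-subject variability** (real heterogeneity among patients):
  subject-level random effects `eta ~ N(0, Omega)` applied inside each
  virtual trial.

The estimator nests them: `M` outer replicates, each simulating `N`
subjects, each checked against its own realised criteria; PoPS is the
fraction of replicates passing all criteria jointly. The joint check
matters — two criteria can each pass marginally in 80% of trials while
jointly passing in far fewer, which is precisely the benefit-risk tension
the tool exists to expose.

## Distributions and their conventions

* Between-subject variability is log-normal by default on positive
  parameters — a subject's parameter is `theta * exp(eta)`, which keeps the
  median at the typical value; `sd(eta) = sqrt(log(1 + (CV/100)^2))`
  converts the conventional percent CV. A normal scale (`theta + eta`) is
  available for baselines that may be negative. A CV may itself carry a
  prior, realised once per trial.
* Correlated priors (e.g. an estimation correlation between `Emax` and
  `EC50`) use a Gaussian dependence structure on the (log-)scale: a
  multivariate standard normal is pushed through each marginal's location
  and scale. Only normal and log-normal marginals can be coupled; richer
  copulas are out of scope.
* The pharmacology-need prior of the second case study ("usually about
  2-fold, occasionally much more") is a beta distribution rescaled to
  `[lower, upper]` and parameterised by its density mode and a
  concentration `c = shape1 + shape2 > 2`, with shapes recovered
  analytically (`shape1 = m(c-2)+1` on the unit scale). The default
  concentration 4 gives the gently decaying right tail that motivates the
  family; with the mode at the lower bound the density is monotone
  decreasing, the natural limiting shape.
* Species-weighted safety limits are a weighted categorical draw over
  candidate exposure limits (weights normalised internally).
* Point masses never consume random numbers, so replacing any prior by a
  point estimate leaves all other draws in a replicate unchanged — scenario
  comparisons stay paired.

## Reproducibility and common random numbers

All randomness derives from one master seed through deterministic
substreams: replicate `i` draws its fixed effects (declared order,
correlated block first), BSV magnitudes and criteria realisations (`K`
before `n`, set order) from substream `(i, 0)`, and its subject random
effects from `(i, 1)`. Under common random numbers — the default — those
draws are reused across the dose grid, so one realisation of the uncertain
quantities is assigned to each virtual trial and the PoPS-versus-dose curve
is smooth; an independent-draws mode (`common_rng = FALSE`, substreams
`(i, 2d)` and `(i, 2d+1)` for dose `d`) is available when independence
across doses is preferred. The substream mixing is a double Lehmer step
modulo `2^31 - 1`, keeping every derived seed valid for R's RNG. The
engine's draw discipline is part of its documented contract: the test suite
reproduces it with a naive double loop over base-R samplers and requires
bit-exact agreement.

The case 1 fixture runs both compounds on the *same* master seed: ranking
two candidates is then a paired comparison, which stabilises the
maximal-PoPS difference far beyond what independent seeds would give at the
same `M`.

## Structural models and the analytic-steady-state choice

The model library assembles closed-form and ODE building blocks:
one-compartment absorption profiles (with the `ka = ke` limiting form),
steady-state average concentration `dose/(CL tau)`, free/partition
translation (`fu`, unbound brain-to-plasma `kp_uu`, tissue `Kp`),
saturable Emax/Imax response with an exact inverse, turnover
(indirect-response) models in all four modulation modes with an optional
transit chain, and target-mediated drug disposition in full microscopic
(`kon`/`koff`) and quasi-steady-state (`KSS`) forms.

Endpoints that are steady-state summaries are computed analytically rather
than by long ODE simulation: the turnover steady states
(`R0(1±E)`, `R0/(1±E)`), the linear `Css,avg`, and the steady-state average
concentration under linear-plus-saturable elimination, which solves the
elimination balance quadratic in closed form (the quasi-steady-state
reduction of target-mediated disposition at the trial time scale). This is
exact where it applies and orders of magnitude faster than per-subject ODE
solving, which is what makes `M x N x doses` simulation practical in pure
R; the ODE solvers remain for time-dependent endpoints and serve as the
cross-check in the tests (turnover ODE converges to the analytic steady
state within 0.5% after ten `kout` half-lives; the full TMDD model with
zero target matches the independent two-compartment closed form to 0.1%
and conserves drug mass to integration tolerance). ODE tolerances default
to `rtol 1e-8 / atol 1e-10` with `lsoda`, which is stiff-capable as TMDD
requires.

Concentration units are declared in the configuration (`mg/L`, `ug/L`,
`ng/mL`) and checked at model assembly; there is no silent conversion, and
the nonlinear-elimination model refuses unit rescaling outright because its
`Km` is a concentration.

## Criteria semantics

Benefit criteria pass when the achieved proportion reaches `n`
*inclusively* (`>= n`); risk criteria pass when the violating proportion
stays *strictly* below `n` — mirroring the ">= 80%" / "< 5%" phrasing such
criteria are written in. Both boundaries are configurable per criterion
(the second case study uses an inclusive "<= 5%" risk bound; the third
phrases both its conditions as strict "> 50%" benefits). Ties between an
endpoint value and `K` are resolved exactly by the configured comparator —
no epsilon fuzzing — and compound conditions (case 1's "balanced": central
activity normalised *and* >= 10% peripheral activity preserved) are
computed per subject as derived 0/1 endpoints before proportion counting.
Uncertainty on `n` is supported but defaults to a point mass, since none of
the case studies exercises it.

## Tunable parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `M` (outer trials) | 500 | — | convention for uncertainty replicates; fixtures use 200 for speed |
| `N` (subjects/trial) | 1000 | — | convention for within-trial proportions; fixtures use 500 |
| `common_rng` | `TRUE` | — | paired dose/scenario comparisons |
| BSV CV on oral CL | 30 | % | moderate BSV typical of low-solubility/high-permeability oral drugs |
| scaled-beta concentration | 4 | — | mild mode with slow right-tail decay |
| percentile rule | type 7 | — | pinned for golden tests |
| band level | 90 | % | 5th-95th predictive interval |
| ODE tolerances | 1e-8/1e-10 | — | stiff TMDD system |
| overlap bins | 64 | — | pinned log-spaced histogram estimator |

## The synthetic case fixtures

The four bundled configurations emulate published case studies whose
compounds were anonymised, so *no real parameter set exists to recover*.
Each fixture therefore distinguishes, value by value (in `meta$notes`),
what is **anchored** — distribution families, ranges, CVs, criteria,
weights and plan sizes that the underlying studies state (uniform
`kp_uu` 0.45-0.75 / 0.35-0.50, fold elevation 1.5-3.0, 30% CL CV, the
scaled-beta mode at 2-fold, the 60:30:10 species weights, uniform 70-95%
required reduction, 500 x 500 trials, N = 3000 pairing) — from what is an
**invented placeholder** (every typical PK/PD value, exposure limit and
dose grid), chosen once so the fixtures reproduce the qualitative outcomes:
compound A outranks B; rise-then-fall PoPS curves whose decline is caused
by the safety criterion (verifiable in the per-criterion pass rates); high
interior optimum with a sharp top-dose collapse; negligible candidate-
benchmark overlap. Passing tests on these fixtures therefore demonstrates
that the estimator and its machinery behave correctly, *not* that any
real compound has these properties; the published headline PoPS numbers
are not reproducible from public information and are not targets.

What the generator deliberately does not emulate: real dropout or dosing
nonadherence, covariate structure (supported as an extension point but
unused), model misspecification, assay noise on the endpoint, and
enterohepatic or absorption complexities — results on fixtures say nothing
about those features of real data.

The translation-coefficient prior in case 3 needed a family choice the
source material does not state; a log-normal (median 0.1, 30% CV) was
chosen as the standard positive-ratio family, configurable like every
other prior. Case 1's steady-state driver (average free concentration
rather than full profiles) follows the simplest reading of its source;
full-profile simulation remains available through the profile functions.

## Numerical and degenerate-input choices

Empty criteria sets, non-monotone dose grids, negative CVs, unknown
structural models, correlation over unsupported marginals, non-PSD
covariance matrices and missing endpoints are all rejected with errors
naming the offending configuration path. A structural-model failure for
any subject aborts the whole run loudly — silently dropping subjects would
bias PoPS. An all-zero `Omega` yields exactly zero random effects;
semidefinite matrices use an eigenvalue square root so zero-variance
components stay exactly zero. `optimal_dose()` breaks ties towards the
lowest dose. The overlap coefficient uses a shared 64-bin log-spaced
histogram (linear if any index is non-positive), making the estimator
symmetric and reproducible; MIC fitting is least squares on the cumulative
frequencies (the standard presentation of MIC data), with doubling-dilution
quantisation available but off by default.

## Problem sizes used in the checks

The test suite runs the fixtures at their default sizes (M = 200-500,
N = 500; the scenario grid at M = 200 over 9 cells), calibration checks at
`n = 1e5` draws, the oracle-equivalence check at M <= 10, N <= 10, and the
stability check at M = 1000 versus 4000 on a single dose — sizes chosen so
Monte-Carlo tolerances (3 SE bands, 2-3% relative) are meaningful while
the whole suite completes in well under a minute of simulation time.

## Known limitations

Uncertainty enters only through sampling of declared priors: there is no
posterior updating from data, no MCMC, and no value-of-information layer.
Criteria combine conjunctively only. Dependence between priors is
Gaussian. The PTA path uses steady-state AUC summaries rather than full
profiles for the bundled index, and the benchmark's required index value
enters as a configured quantile since the benchmark meta-analysis itself
is out of scope. Execution is single-threaded; the analytic steady-state
endpoints are what keep full runs in the seconds-to-minutes range.
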