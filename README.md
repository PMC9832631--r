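# pops — probability of pharmacological success by nested Monte Carlo

`pops` is an R package for translational pharmacologists and
pharmacometricians who must decide, early in development and under heavy
uncertainty, whether a drug candidate is likely to deliver adequate
pharmacology to most patients without exposing too many of them to safety
risk — and at which dose.

## The quantity it computes

For a dosing regimen, a per-subject PK or PD endpoint is modelled as

```
k_j = f(theta, z_j, eta_j),    eta ~ N(0, Omega),   j = 1..N
```

where `theta` are fixed effects (typical PK/PD parameters and translation
factors), `z_j` optional covariates, and `eta_j` between-subject random
effects. Success criteria take the thresholded-proportion form

```
k_j  >  (or >=, <, <=)  K     for n% of subjects
```

with benefit criteria requiring the proportion to reach `n` and risk
criteria requiring the violating proportion to stay below `n`. Every
uncertain ingredient carries a prior: `theta ~ d1`, `Omega ~ d2`,
`K ~ d3`, `n ~ d4`.

The estimator is a nested Monte Carlo:

1. draw `M` replicates of `(theta_i, Omega_i, K_i, n_i)` from their priors
   (one joint realisation per virtual trial);
2. for each replicate simulate a virtual population of `N` subjects and
   compute the endpoints;
3. check each population against its realised criteria; with `M'` the
   number of populations meeting all criteria jointly,

```
PoPS = M' / M
```

reported per dose, with per-criterion pass rates and 90% predictive bands
of the subject proportions. Common random numbers across doses (the
default) make the dose-response of PoPS smooth and make scenario
comparisons paired.

The package also implements the anti-infective variant: probability of
target attainment (PTA) against an in-class benchmark, built from a fitted
MIC distribution (logistic CDF on log2(MIC) or log-normal), random pairing
of simulated AUCs with MIC draws into AUC:MIC indices, and an
overlap/attainment comparison of candidate versus benchmark index
distributions.

## Worked example

The bundled case-study fixtures are fully synthetic: the analyses they
emulate were published with anonymised compounds, so every PK/PD value here
is an invented placeholder chosen to reproduce the qualitative decision
pattern (documented per value in `meta$notes`). Numeric PoPS values are
therefore properties of the fixtures, not of any real molecule.

Case 1 ranks two candidate compounds for a CNS indication where benefit
requires normalising an elevated brain target without over-inhibiting the
same target peripherally (>= 80% of patients balanced, < 5% over-inhibited):

```r
library(pops)
cfg <- make_case1_config(seed = 42)   # 200 trials x 500 subjects per compound
res <- run_case(cfg)
res$summary
#>   compound max_pops optimal_dose
#> 1        A    0.750           20
#> 2        B    0.425           24

res$curves$A[4:8, c("dose", "pops", "pass_rate_balance",
                    "pass_rate_over_inhibition", "prop_median_balance")]
#>  dose  pops pass_rate_balance pass_rate_over_inhibition prop_median_balance
#>    12 0.345             0.345                     1.000               0.639
#>    16 0.570             0.570                     1.000               0.846
#>    20 0.750             0.760                     0.985               0.915
#>    24 0.000             0.850                     0.000               0.898
#>    32 0.000             0.015                     0.000               0.758
```

Reading the curve: at 20 mg, 76% of virtual trials meet the benefit
criterion and 98.5% stay within the risk criterion, so PoPS peaks at 0.75;
at 24 mg the median trial still has 89.8% of subjects balanced, but the
over-inhibition criterion now fails in essentially every trial, collapsing
PoPS to zero — the benefit-risk window closes from the safety side.
Compound A's higher maximal PoPS (driven by its more favourable unbound
brain-to-plasma partition range) is what separates the two otherwise
similar candidates.

The other fixtures: `make_case2_config()` (turnover-driven biomarker
fold-increase with a scaled-beta pharmacology-need prior and a 60:30:10
species-weighted safety limit, plus a 3 x 3 scenario grid),
`make_case3_config()` (target-mediated disposition, tissue-translated Imax
protein reduction, Q4W dosing), `make_case4_config()` (AUC:MIC target
attainment versus a benchmark). A thin CLI covering the same operations is
installed at `inst/cli/pops` (`pops run|scenarios|pta|fixtures`).

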