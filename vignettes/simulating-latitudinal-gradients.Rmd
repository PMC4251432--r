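---
title: "Simulating latitudinal diversity gradients: model, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating latitudinal diversity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ldgsim` simulates the diversification of a single clade along a
one-dimensional thermal gradient of ten adjacent regions, running from the
warm tropics (region 1, 40 °C) to the cool temperate zone (region 10,
0 °C).  A run starts from one ancestral species in either end region, with
a thermal optimum equal to its home environment.  Every species carries
exactly one heritable trait — that thermal optimum — and experiences four
processes each discrete time step:

1. **Population allocation.**  A species' performance in region $k$ is the
   Gaussian environmental-filter weight
   $w_{ik} = \exp\!\big(-(z_i - E_k)^2 / 2\omega^2\big)$,
   where $z_i$ is its optimum, $E_k$ the regional temperature and
   $\omega$ the filter width.  Under the zero-sum energetic constraint,
   region $k$ supports at most $K_k$ individuals summed over species, and
   each resident attains $N_{ik} = \mathrm{round}(K_k\, w_{ik} / \sum_j w_{jk})$:
   every additional species shrinks everyone else's population.  With the
   constraint switched off (the pure niche conservatism scenario) each
   species independently attains $N_{ik} = \mathrm{round}(K_k\, w_{ik})$,
   so individuals and species can accumulate without bound.
2. **Disturbance** (only in the disturbance scenario).  At regular
   intervals a pulse kills a fraction $m_k$ of every population,
   increasing linearly from the tropics to the temperate zone.
3. **Speciation.**  Each individual has a fixed per-step probability of
   founding a daughter species, so a population of size $N$ spawns
   $\mathrm{Binomial}(N, p_k)$ daughters.  A daughter inherits the
   parent's optimum plus a $\mathrm{Normal}(0, \sigma_E)$ deviation —
   niche conservatism — and starts in the parent's region.
4. **Dispersal.**  Each individual has a fixed per-step probability of
   emigrating to an adjacent region, so a species colonizes a neighboring
   region it does not yet occupy with probability $1-(1-p_d)^{N}$.
5. **Extinction.**  Each population goes locally extinct with probability
   $e^{-\alpha N}$ — a negative exponential of population size — and a
   species with no populations left is globally extinct, permanently.

Populations are re-equilibrated from the weights every step (allocation is
instantaneous; there are no lagged growth dynamics), which is why
disturbance acts between allocation and the extinction draw of the same
step: its dynamical signature is the elevated extinction risk of the
diminished populations.

## Scenarios

Four preset scenarios differ in which single parameter varies along the
gradient:

| parameter | pure NC | energy | speciation | disturbance | units |
|---|---|---|---|---|---|
| environmental gradient | 0–40 | 0–40 | 0–40 | 0–40 | °C |
| niche conservatism $\sigma_E$ | 1 | 1 | 1 | 1 | °C |
| carrying capacity $K$ | 40,000 | 4,000–40,000 | 22,000 | 22,000 | individuals |
| speciation probability | $10^{-6}$ | $10^{-6}$ | $3.2\times10^{-7}$–$3.2\times10^{-6}$ | $10^{-6}$ | per individual·step |
| disturbance magnitude | 0 | 0 | 0 | 75–99 | % killed per event |
| zero-sum constraint | no | yes | yes | yes | |

All three zero-sum scenarios support the same global number of individuals
($\sum_k K_k = 220{,}000$).  Zero-sum runs default to 100,000 steps; the
pure niche conservatism run stops once extant richness exceeds 10,000
species, which happens within a few hundred steps of the exponential
explosion.

## Calibrated defaults

Four knobs are not fixed by the scenario definitions and are package
defaults, chosen once by calibration and exposed as configuration fields:

* **Filter width $\omega$ = 3 °C.**  About two-thirds of a region-to-region
  temperature step (4.4 °C), so a species is viable in a handful of
  adjacent regions but cannot span the gradient; regional assemblages
  remain thermally distinct while adaptation across the gradient stays
  possible.
* **Dispersal probability $p_d = 10^{-6}$ per individual per step.**
  Calibrated jointly with $\omega$ so that (a) a zero-sum clade colonizes
  all ten regions early in a run (observed: within the first ~1,000 steps,
  against a 100,000-step horizon — colonization is fast because the first
  colonist of an empty region inherits its whole capacity), and (b) in the
  unconstrained scenario the spread of the clade remains limited by trait
  evolution rather than saturating several regions instantly, producing the
  steep, nearly linear richness decline away from the origin that
  characterizes that scenario.  At $10^{-4}$ every abundant species occupies
  all thermally accessible regions within a couple of steps and the
  richness profile flattens near the origin.
* **Extinction decay $\alpha$ = 0.01 per individual.**  Populations below
  ~100 individuals face appreciable risk ($e^{-1} \approx 0.37$ at
  $N = 100$), populations above ~1,000 are effectively safe; with
  $K = 22{,}000$ this yields equilibrium regional richness of a few tens
  of species, large enough for tree statistics and small enough to keep
  100,000-step runs cheap.
* **Disturbance frequency = 100 steps**, several times shorter than the
  time scale on which regional richness equilibrates, so the disturbance
  scenario reaches a speciation–extinction steady state with high
  turnover rather than oscillating between recoveries.

## Diagnostic metrics

At every snapshot interval the simulator records the multi-pattern
fingerprint used to tell the scenarios apart:

* **Latitude–richness correlation** — Pearson $r$ of (region index,
  richness) over occupied regions; $-1$ is the classical gradient.
* **Occupancy-time–richness correlation** — the time-for-speciation
  effect, with each region's occupancy time measured from its extant
  residents' earliest colonization.
* **Scaled MRD–richness slope** — each tip's root distance is the number
  of internal nodes between it and the root of the extant tree; the
  regional mean, scaled by the tree's maximum, is regressed (OLS) on
  regional richness.
* **β imbalance** — the maximum-likelihood estimate of the beta-splitting
  parameter over $[-2, 10]$ from the sizes of all informative splits.
  β = 0 is Yule; imbalanced trees are negative.  The likelihood is
  topology-only, so the estimate is invariant to branch-length rescaling.
  Boundary optima are returned as the boundary value and flagged.  On
  moderate-size Yule trees the estimator's sampling distribution is
  right-skewed (bounded below at −2, stretching to +10), so its median,
  not its mean, should be compared to zero — the test suite does exactly
  that at 64 tips and checks the mean only at 256 tips where the skew has
  died out.
* **Tip speciation rates**, two estimators averaged over residents per
  region: the *equal-splits* (DR) statistic
  $1/\mathrm{ES}_i$ with $\mathrm{ES}_i = \sum_j l_j 2^{-(j-1)}$ summed
  from the pendant branch rootward, a phylogeny-only proxy weighted
  toward recent branching; and the *realized* rate — speciation events on
  the root-to-tip lineage path from the event log, divided by clade age.

One structural caveat discovered while validating the estimators: the
realized path rate of a tip is its root-to-tip branching count divided by
clade age, so its regional pattern is the MRD pattern by construction.
Under any zero-sum scenario temperate assemblages carry elevated MRD,
hence elevated realized rates, regardless of mechanism — the replicate
runs show strong positive realized-rate–latitude rank correlations under
all three zero-sum scenarios, including the energy gradient whose true
per-capita rates are uniform and the speciation gradient whose true rates
are ten-fold *higher* in the tropics.  The realized estimator is
therefore a whole-history summary, not a rate diagnostic.  All three
rate-versus-latitude fingerprints are instead evaluated on the
equal-splits statistic, which is dominated by recent branching and does
not inherit the deep-history confound: it falls steeply with latitude
under the speciation gradient, rises (weakly but consistently in sign)
under the disturbance gradient, and shows no significant trend under the
energy gradient.

## Numerical choices

* Populations are rounded half-to-even.  Under the zero-sum constraint
  rounding can overshoot $K_k$ by a few individuals, so a deterministic
  repair decrements the largest populations (ties broken by species id)
  until $\sum_i N_{ik} \le K_k$ holds exactly; the shortfall is bounded by
  half the resident count.
* A population that rounds to zero is an immediate local extinction,
  logged as such.
* All stochastic draws use one seeded generator per run, and within each
  phase cells are processed in (species id, region) order, so a
  configuration plus seed reproduces every output bit-for-bit.
* Simultaneous daughters of one parent are resolved into bifurcations in
  species-id order with zero-length internal branches; polytomies never
  arise.
* The stem below the first surviving split is excluded from all tree
  statistics; undefined statistics (fewer than three occupied regions,
  zero variance, fewer than three tips) are reported as `NA`, never as 0.
* β optimization uses Brent search to $10^{-6}$ on $[-2+10^{-5}, 10]$ with
  explicit boundary checks; the unit suite verifies the maximized
  log-likelihood against a brute-force grid (step 0.01) on every tree
  shape of up to 8 tips.

## What the generator does and does not emulate

The simulator captures niche conservatism, environmental filtering, an
individual-based energetic ceiling, dispersal limitation and
population-size-dependent extinction — enough to reproduce the qualitative
fingerprints that separate the four hypotheses.  It does not model
within-region individuals (populations are deterministic shares),
additional niche axes, temporally varying climate, non-linear gradients or
two-dimensional geography.  Consequently, passing fingerprint tests shows
that the *mechanisms* produce the diagnostic patterns under these
idealized conditions; it does not show that any empirical clade evolved
under them.

## Problem sizes in the test and acceptance suites

The packaged checks run each zero-sum scenario for 20,000 steps — several
times past the point where regional richness equilibrates (by roughly step
4,000) and past the window in which temperate-origin runs flip to the
classical gradient — with three replicate seeds per condition, and
summarize "equilibrium" behavior as the median of each metric over the
snapshots in the second half of a run, since single-snapshot values of β
fluctuate.  Pure-niche-conservatism runs go to their 10,000-species stop
rule.  The acceptance script (`scripts/acceptance.R`) reruns only the
pure-niche-conservatism condition, three derived seeds per origin, and
reports the latitude–richness correlations rounded to one decimal.

## Known limitations

* The realized tip-rate estimator is confounded with root distance (see
  above); treat it as a whole-history summary, not an instantaneous rate.
* β estimates on trees below ~30 tips are noisy and skewed; the boundary
  flag should be consulted before interpreting extreme values.
* With very narrow filters ($\omega \lesssim 1$) a zero-sum clade can fail
  to cross the gradient within a run; the validator does not guard against
  scientifically unproductive parameter combinations.
* Occupancy times are measured from extant residents only, so recently
  re-colonized regions look young even if they held the clade before.
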