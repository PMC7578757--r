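---
title: "Modelling WZ/ZZ sex determination with intersex males"
author: "WZdynamics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling WZ/ZZ sex determination with intersex males}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WZdynamics)
```

## The biological setting

In a female-heterogametic system, females carry a W and a Z sex
chromosome and males are ZZ.  Some crustaceans — the Australian
redclaw crayfish is the motivating case — additionally produce
*intersex* animals: individuals with the female WZ genotype that bear
a mix of male and female gonopores but function, permanently, as
males.  When such a WZ male mates with an ordinary WZ female, standard
Mendelian segregation gives offspring genotypes in a 1 ZZ : 2 WZ :
1 WW ratio, so a quarter of the brood are viable homogametic WW
females and the phenotypic female:male ratio is skewed to 3:1.

`WZdynamics` packages this genetics together with a population model
that asks what such crosses do to the sexual composition of a
population over time, plus the statistical tooling used around it:
segregation-ratio goodness-of-fit tests, cohort tallies, and a
presence/absence screen for W-linked RAD-tag markers.

## The four-class projection model

Individuals fall into four functional classes: ZZ males, intersex WZ
males (IS), WZ females and WW females.  A fraction $\alpha$ of WZ
progeny emerge as intersex; this is treated as a constant of the
population, not an environmental response.  One discrete time step is
one generation, taken to be about six months.

Each step, every functional female (WZ or WW) mates with a sire whose
class is drawn proportional to the male-class abundances — intersex
males are assumed fully fertile, and polygyny is implicit in that male
abundance only sets sire-class frequencies.  Writing $u$ for the share
of intersex animals among functional males and $v$ for the share of WW
among functional females, the newborn genotype probabilities follow
from gamete segregation:

$$P(\mathrm{ZZ}) = \frac{(1-v)(2-u)}{4},\qquad
  P(\mathrm{WW}) = \frac{u(1+v)}{4},\qquad
  P(\mathrm{WZ}) = 1 - P(\mathrm{ZZ}) - P(\mathrm{WW}),$$

with the WZ newborns split $\alpha$ : $(1-\alpha)$ between the IS and
WZ-female classes.  The density-independent recurrence for each class
$k$ is

$$N'_k = \sigma_a N_k + \sigma_0\,\phi\,F\,p_k,$$

where $\sigma_a$ is adult survival per step, $\sigma_0$ newborn
survival, $\phi$ per-capita female fecundity, $F$ the number of
functional females and $p$ the newborn class distribution above.
Recruits mature in one step — the model has no juvenile age class, so
$\sigma_0$ simply scales $\phi$ and only their product matters.  A
constant-size variant (`constantPopulationStep`) replaces exactly the
$(1-\sigma_a)N$ adults that die with recruits and reaches the same
structural fixed point.

### Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha` | fraction of WZ progeny emerging intersex | 0.04 | the value used for the published stable-distribution figures |
| `sigmaA` | adult survival per step | 0.6 | plausible semiannual survival; shapes transients only |
| `sigma0 * phi` | recruits per female per step | 1.2 | gives an asymptotic growth rate $\lambda_\infty = \sigma_a + 0.5\,\sigma_0\phi = 1.2$ |
| `stepMonths` | months per generation | 6 | stated generation length; years = steps / 2 |

The exact survival/fecundity values behind the published trajectory
figures are not printed anywhere recoverable, so these defaults are a
declared configuration, not a calibration.  The long-term stable
distribution (LTSD) is provably independent of them.

### The stable distribution and the half-alpha rule

Because survivors and recruits scale the same way, the fixed point of
the class *fractions* satisfies $x = p(x)$: at equilibrium the
standing class distribution equals the newborn distribution.
`stableDistribution()` finds it two ways — by iterating the projection
from ZZ = WZ = 50% (method `"iterate"`), and by eliminating $v$ from
the fixed-point equations and solving a single scalar root in $u$ with
`uniroot` (method `"solve"`), which serves as an independent check.

```{r}
stableDistribution(alpha = 0.04)
```

At $\alpha = 4\%$ the fractions are 47.96% ZZ, 2.04% IS, 48.96% WZ
females and 1.04% WW females.  Functional males (ZZ + IS) and females
(WZ + WW) balance exactly at 1:1 — the Fisherian outcome — and the
intersex fraction is *about* half of $\alpha$.  The exact coefficient
is the stable WZ-genotype fraction $q(\alpha) = \mathrm{IS}_\infty +
\mathrm{WZ}_\infty$:

```{r}
sapply(c(0.01, 0.04, 0.1), function(a)
  classFractions(stableDistribution(a))[["IS"]] / a)
```

$q$ grows from 0.50 at $\alpha \to 0$ to 0.5025, 0.5100 and 0.5248 at
$\alpha$ = 0.01, 0.04 and 0.1.  Two consequences are worth knowing.
First, a "half-alpha" band of [0.50, 0.52] holds for $\alpha \le
0.04$ but is exceeded (0.5248) at $\alpha = 0.1$; the corresponding
acceptance test is deliberately left failing rather than widened,
because it encodes the stated band.  Second, since
$\mathrm{IS}_\infty = \alpha\,q(\alpha)$, the moment estimator
$\hat\alpha = 2 \times$ (intersex fraction) has expectation
$2 q(\alpha)\,\alpha$ at the LTSD: at $\alpha = 0.04$ that is
$2 \times 0.0204 = 0.0408$, a structural +2% bias relative to the
true $\alpha$.  Averaged over
hundreds of large cohorts this bias is resolvable (it sits just
outside a 3-standard-error band of a 200-replicate mean), while for
any single field cohort it is far inside sampling noise; the test
suite records both facts.

### Convergence and transients

From a 50% ZZ / 50% WZ founder population with the default
parameters, all class fractions come within 0.1 percentage point of
the LTSD in 10 generations — comfortably inside the reported "about
30 generations".  Founder composition matters in the short term:
replacing the ZZ males of a 200-animal founder group with intersex
animals makes the early broods female-rich, and the population crosses
1,000 individuals several generations sooner:

```{r}
p <- DemographicParams()
c(IS_founded = timeToThreshold(populationState(IS = 100, WZ = 100), p, 1000),
  ZZ_founded = timeToThreshold(populationState(ZZ = 100, WZ = 100), p, 1000))
```

Only this ordering is asserted anywhere: the published "15 vs 26
years" depends on the unavailable demographic parameter values.

### Stochastic mode

`simulateTrajectory(mode = "stochastic")` draws survivors binomially
($\sigma_a$), brood totals Poisson ($\sigma_0\phi$ per female) and
recruit classes multinomially from the newborn distribution, all from
one seeded generator; runs that hit zero are truncated and flagged
extinct.  With large founder counts the ensemble mean tracks the
deterministic trajectory.

## Statistical tooling

`chiSquareGof()` is the uncorrected Pearson statistic with
`categories - 1` degrees of freedom and an upper-tail `pchisq`
p-value.  No Yates correction is applied: the uncorrected test is
what reproduces the published progeny-table p-values (0.34, 0.16,
0.27 for observed WZ/ZZ : WW counts of 66:17, 56:12, 42:19 against
3:1).  By default WZ and ZZ offspring are pooled into one category —
the W-marker assay distinguishes WW from not-WW among females — with a
three-category 1:2:1 test available.  Ratio labels in tallies use
nearest-integer "k:1" display alongside exact quotients, and females
with undetermined genotype are excluded from genotype tallies (with a
count) but kept in phenotype tallies.

`screenSexMarkers()` implements the W-association filter: a tag is a
candidate W-linked marker when present in strictly more than 60% of
female samples and absent from every male sample.  Missing calls
default to "absent", which is conservative for the zero-male
criterion; `naAction = "exclude"` drops them from denominators
instead.  A symmetric Z-linked mode exists but requires genotype
labels and is off by default, since Z markers were historically
derived by sequencing rather than by this filter.

## What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline consumes:
multinomial cross progenies with marker bands (optionally flipped at a
per-band error rate, creating the undetermined double-negative calls);
pond experiments stocked with chosen class compositions, with dams
mating against the stocked male mix and offspring sampled without
replacement from the pooled broods; native cohorts drawn from the
LTSD (a burn-in mode exists for transient studies); and RAD-tag
matrices with planted W-linked tags subject to dropout and
false-presence noise over a default 12-male / 8 WZ + 4 WW female
design.

Declared-but-uncalibrated choices: brood size defaults to 300
offspring per female (redclaw broods run into the hundreds; nothing
citable fixes the value, and only the pool size depends on it), equal
across females unless a negative-binomial `dispersion` is requested;
genotyping error defaults to 0 because no marker error rate is
reported.  The generators do not simulate sequence reads, geographic
structure, size- or age-structured demography, or density dependence
beyond the constant-N variant — so a green test establishes the
statistical machinery and the model's internal claims, not fidelity
to any particular wild population.

## Numerical choices

* LTSD iteration stops when the largest class-fraction change drops
  below `tol` (default 1e-10), capped at 10,000 steps; the direct
  solver brackets the scalar root on the subinterval where the
  eliminated variable stays in [0, 1] (needed for large $\alpha$).
* "Generations to convergence" uses a 0.1-percentage-point tolerance
  by default, an upper-bound reading of the published "about 30
  generations" claim, whose original criterion is unstated.
* Populations with no functional males or no females have zero
  recruitment and decay geometrically; class fractions are undefined
  (NA) once the total is zero.
* Sire weighting is proportional to male abundance; whether the
  original model weighted sires this way or formed pairs is unstated,
  but at the 1:1 equilibrium the two coincide.
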