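---
title: "An individual-based eco-evolutionary model of alewife morphology in a size-structured prey community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based eco-evolutionary model of alewife morphology in a size-structured prey community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alewifesim)
```

## The problem

Alewife (*Alosa pseudoharengus*) populations trapped in freshwater lakes
over the last ~300 years have shifted from an anadromous to a landlocked
morphology: smaller bodies, narrower gapes, smaller inter-gill-raker
spacings, earlier maturation, lower fecundity. The shift is driven by a
feedback between the fish and the zooplankton community: alewives crop
large-bodied prey, the prey community becomes dominated by small-bodied
forms, and small-bodied, densely-rakered fish then forage more profitably
than large-bodied ones.

`alewifesim` simulates this feedback with an annual-time-step hybrid model:

* **Fish** are individuals with diploid biallelic quantitative trait loci
  (QTLs) for two traits — growth capacity and gill-raker count — plus age,
  sex, length and maturity state. A trait equals the fraction of
  trait-increasing alleles over the `2 L` alleles at its loci
  (`L = 8` by default).
* **Prey** form two or three trophic clusters, each a vector of 21
  body-size classes (the genotype classes of 10 diploid prey loci), updated
  by discrete Lotka–Volterra difference equations whose coefficients come
  from allometric power laws.

## Fish traits and the foraging trade-off

Body mass follows the alewife length–mass law
$w = 10^{-5.289}\, bO^{3.063}$ (mm to g). Two derived traits bracket a
fish's usable prey-size window:

* **Gape** $u = 0.01\,w$: the prey mass at which large-prey capture
  efficiency has fallen to one half.
* **Gill-raker spacing**
  $l = l_{Mn} + (l_{Mx} - l_{Mn})\bigl(1 - \tfrac{nml}{2\,nll}\bigr)
  x^{eb}$, with $x = (w - w_{Mn})/(w_{Mx} - w_{Mn})$ the scaled body mass,
  $nml$ the raker-allele count, $l_{Mx} = 0.02$ g and $l_{Mn} = 0.001$ g
  (twice and a tenth of a large zooplankter's mass). More raker alleles or
  a smaller body mean narrower spacing, i.e. better retention of small
  prey.

Foraging efficiency over prey mass $k$ is a normalised double-logistic
tent in $\log_{10} k$,

$$fe(k) = pf(k, l, lp)\; cF(u, l, fs)\;
  \frac{1}{1 + e^{-fs\,\log_{10}(k/u)}}\;
  \frac{1}{1 + e^{+fs\,\log_{10}(k/l)}},$$

zero when $u \le l$. The normaliser $cF = (1 + e^{fs\,d})^2$ with
$d = \tfrac12\log_{10}(u/l)$ makes the maximum exactly 1 at the geometric
mean $\sqrt{u\,l}$ when the clogging penalty is off, and $fe = 1/2$ at
$k = u$ and $k = l$. The clogging penalty $pf = (l/k)^{lp}$ for $k > l$
encodes the cost of narrow rakers when handling large prey; `lp = 0.5` by
default. `fs = 10` sets how fast efficiency decays outside the window.

Scarce prey impose search/handling costs: foraging on a cluster with
abundance $N$ is scaled by $M = 1/(1 + (c_H\, ra/N)^{bf})$, a type-II-style
saturation that equals one half when $N$ is 10% of the power-law abundance
$ra$ at the default $c_H = 0.1$, and disappears as $c_H \to 0$. Only the
50%-at-10% anchor is stated for this term; the ratio form here is the
simplest function satisfying it, increasing in $N$ and recovering $M = 1$
without handling costs.

## The prey community

Cluster $r$ with representative mass $rMu_r$ (0.01, 0.224, 5 g by default)
has power-law abundance $ra_r = c_A\, rMu_r^{-e_A}$ ($c_A = 5 \times 10^6$,
$e_A = 0.75$). Its 21 class masses are log-spaced over $[rMu/2,\, 2\,rMu]$
with the centre class at $rMu$; class $j$ represents $j$ copies of the
size-increasing allele. Each year every class is multiplied by the growth
ratio

$$rt = \frac{1 + rI + pI}{1 + sI + nI + fI},$$

where $rI$ is 1 for the basal cluster and 0 otherwise; $sI$ = total
cluster abundance over $ra$ (within-cluster competition); $nI$ = predation
by larger clusters; $pI$ = feeding benefit from smaller clusters; and
$fI = cn\, fc_r\, nc$ is fish foraging pressure, with
$fc_r = cn\, c_i (rMu_r / w_f)^{e_I}$ and $nc$ the fractional number of
fish foraging on the class. Between-cluster coefficients scale with the
predator–prey mass ratio, $in = c_i (m_{prey}/m_{pred})^{e_I}$
($c_i = 2.5\times10^{-6}$, $e_I = 0.25$). After growth, expected mutation
flow moves fraction $(2\,nll - j)\,\mu$ of class $j$ up and $j\,\mu$ down
one class ($\mu = 10^{-5}$), conserving totals exactly. A cluster whose
total drops below one individual is zeroed and flagged extinct.

An isolated basal cluster has $ra$ as an attracting fixed point of this
map, which the burn-in tests verify to $10^{-9}$ relative.

## Demography

* **Growth**: von Bertalanffy, $\Delta = (L_\infty - bO)(1 - e^{-K})$,
  multiplied by lognormal noise with mean 1 and coefficient of variation
  `bcv` (0.01). $L_\infty = bLo + (bMx - bLo)\,\min(1, p/(4\,b_A))$ maps
  the growth-allele fraction $p$ onto asymptotic length; at the default
  $b_A = 0.25$ the map is the identity in $p$. $K = 0.5955$ and
  $bLo = 134.3$ mm are solved from two printed anchors: the largest
  genotype averages 260 mm at age 5 (anadromous adults) and the smallest
  genotype reaches ~95 mm at age 2, slightly under the 97 mm landlocked
  mean.
* **Survival**: Beverton–Holt in the ratio of annual prey-mass intake $A$
  to metabolic demand, $s = s_{Mx}\,\rho/(1+\rho)$,
  $\rho = A/(c_m w^{0.75})$, using the Kleiber exponent. Intake is the
  fish's share of the prey abundance actually removed through the $fI$
  term, partitioned within each size class proportionally to (allocation
  weight × efficiency), so prey losses and fish intake balance exactly —
  a property asserted to $10^{-9}$ in the tests.
* **Maturation** is delayed by growth alleles:
  $age = 2 + \mathrm{round}(3p)$ (round-half-up), from 2 years
  (landlocked) to 5 (anadromous).
* **Reproduction**: each mature female picks one mature male uniformly
  with replacement and bears Poisson offspring with mean
  $10\,w/w_{Mx}$; offspring get one mutated gamete per trait from each
  parent (unlinked loci, free recombination), are female with probability
  one half, and enter at 5 mm, age 0. Fish older than 10 are removed.

## The annual loop

Years 1–1000 are prey-only burn-in. At the end of year 1000 the founding
population (500 females + 500 males, allele frequencies
$P(A)_0 = 0.99$, $P(B)_0 = 0.01$, ages uniform 3–6, lengths from
deterministic growth) is created and recorded as `years_post = 0`; fish
live their first year in year 1001. Each later year runs: growth →
trait/allocation computation → prey update (with the removal ledger) →
intake partition → survival, aging, age cap → maturity update →
reproduction → recording. Growth leads the year: newborns are 5 mm at
birth, and a fish must grow before its gape exceeds the minimum raker
spacing; without growth-first ordering no newborn could ever feed.

Replicate $i$ runs on seed `base_seed + i - 1`, so replicates are
independent and a fixed seed reproduces a run bit-for-bit (tested).

## Design choices made where the design was open

**Body-size exponent mode (`eb_mode`).** The printed spacing law applies
the exponent `eb` directly to scaled body mass, but the study's prose
labels read as if small `eb` meant a strong small-body advantage, which
suggests a reciprocal exponent `1/eb` instead. Both modes are implemented.
The package defaults to the **direct** (as-printed) form because only it
reproduces the documented sensitivity structure: with `eb <= 0.25`,
$x^{eb}$ is near 1 for all realistic masses, so body size alone cannot
deliver narrow spacing, raker alleles are the only route to small-prey
retention, and the raker count responds to selection; with `eb = 0.5`
small-bodied fish get narrow spacing for free and the raker response
disappears. In reciprocal mode, by contrast, anadromous-size adults
acquire intermediate spacing that maximises their efficiency on 0.01 g
prey under the default clogging penalty; selection then favours *large*
bodies, the raker trait is inert for all but near-maximal masses, and the
population collapses under every demographic calibration we probed — the
opposite of the documented dynamics.

**Allocation sharpness (`q`).** A fish's foraging time is allocated over
prey classes with weights proportional to
$(fe \cdot M \cdot k \cdot N)^q$. With fully graded sharing (`q = 1`) the
allocation feedback equalises harvestable mass across classes at
equilibrium and thereby *neutralises* selection on the raker trait: the
measured per-allele survival gradients sit at drift level and the raker
frequency never moves. The behavioural rule being modelled — an individual
concentrates on *the* prey type with the highest total mass — is a
near-argmax rule, so the default is `q = 10`, a smooth approximation of
it. Under `q = 10` fish deplete their individually-best classes, the prey
size spectrum reshapes, and the raker allele frequency reproduces the
documented threshold rise (more than +0.1 within 300 years in the
strong-small-body-benefit setting).

**Metabolic scale (`cm`).** Survival's only free scale is calibrated, not
printed. `calibrate_demography()` walks a descending grid and keeps the
largest `cm` for which all probe replicates of both the 2- and 3-cluster
default communities hold at least 1000 fish over a 300-year probe; the
shipped default `cm = 0.2` is its output under the shipped structural
defaults (populations settle at order $10^4$). The routine should be
re-run whenever a structural switch (`eb_mode`, `q`, handling form)
changes.

**Other reconstructions.** Class masses span a two-fold range around
`rMu` (log-spaced); the initial class distribution is a discretised normal
with a 2-class standard deviation; the handling multiplier inside
between-cluster predation uses the predator abundance against the prey's
predicted abundance; the founding adults' ages are uniform on 3–6 with
deterministic-growth lengths; prey extinction is declared below one
individual. Each is configurable.

## What the tests do and do not establish

The synthetic fixtures (`make_fixture("tiny")`) preserve every structural
feature — two trophic clusters, 5 prey classes, 50 + 50 founders, 50-year
burn-in — so unit and property tests exercise the full machinery in
seconds. They do not emulate: real lakes' seasonality, alewife predators,
environmental growth effects, or the marine phase of anadromy, all of
which are outside the model's scope. A green suite establishes that the
implementation matches the stated equations and conventions and that the
desk-scale quantitative anchors hold; the long-horizon trajectories remain
stochastic model outputs, summarised over replicates.

One stated neutrality check is deliberately narrowed: with the foraging
surface flattened (`flat_fe` hook), the raker trait is truly neutral and
its frequency drifts trend-free (tested), but the growth trait still
touches fitness through maturation delay and mass-dependent fecundity, so
strict neutrality is not expected of it and is not asserted.

## Numerical choices

Efficiencies are computed with the algebraic form
$cF = (1+e^{fs\,d})^2$, overflow-safe for all realistic trait values; the
printed quotient form is kept in the tests as an independent oracle
(agreement to $10^{-12}$ relative). The clog penalty in the vectorised
path caps $\log_{10}(l/k)$ at 0 rather than branching. Mutation flow is
applied as expected value (deterministic), which conserves cluster totals
exactly. All stochasticity flows through R's RNG; every public entry point
takes or derives an explicit seed. Degenerate cases are pinned by tests:
`u <= l` gives zero efficiency; an empty population yields `NA` allele
frequencies (not 0); `0^0` in the spacing law is defined as 0 so `eb = 0`
keeps its cliff semantics in both modes; round-half-up is used for
maturation ages.

## Known limitations

* Several supplementary-material equations of the source model are not
  printed; the reconstructions above follow the stated constraints but
  cannot be verified term-by-term.
* The demographic calibration targets persistence, not absolute abundance
  data; fish population sizes are meaningful only on a relative scale.
* Prey demography is deterministic (expected-value updates); prey drift
  and within-cluster selection beyond fish-imposed mortality are absent.
* No alewife predators, no environmental effects on growth or maturation,
  no migration: the model is a closed lake from the moment of landlocking.
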