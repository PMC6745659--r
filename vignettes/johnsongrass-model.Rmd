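---
title: "An individual-based model of herbicide-resistance evolution in a seed- and rhizome-propagated perennial weed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based model of herbicide-resistance evolution in a seed- and rhizome-propagated perennial weed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jgrass)
```

## The system being modelled

Johnsongrass (*Sorghum halepense*) is a perennial grass weed of soybean
systems that reproduces along two routes at once: sexually, through a soil
seedbank, and asexually, through a three-tier rhizome system. Because most
herbicides act on aboveground tissue while the rhizomes persist
belowground, and because clonal propagation transmits a genotype unchanged,
the evolutionary dynamics of herbicide resistance in this species differ
qualitatively from the annual weeds that most resistance models describe.

`jgrass` implements a stochastic individual-based model of this life cycle
on an annual time step. Two resistance architectures are modelled:

* **Single dominant gene** (ACCase-inhibiting herbicides such as haloxyfop
  and clethodim): each individual carries a genotype SS, RS or RR at one
  nuclear locus; RR and RS survive the herbicide (complete dominance),
  SS individuals are killed at the stated efficacy.
* **Quantitative tolerance** (glyphosate): each individual carries a
  phenotype Pz, the highest dose (g a.e./ha) it can survive. Founding Pz is
  log-normal, Ln(Pz) ~ Normal(ln LD50, sigma_log), and an individual
  survives a dose d whenever Pz >= d.

A replicate simulates a 10,000 m^2 field for 30 years. Control **fails**
in the first year the standing plant density at the post-application
census strictly exceeds 5 plants/m^2 (the replicate then stops); a
replicate **chronicles evolved resistance** to a herbicide when the
resistant fraction of standing plants (by that herbicide's classification)
exceeds a threshold (0.20 by default) in any season. Ensembles of
replicates estimate the probability of each outcome.

## The annual cycle

Each season executes, in order:

1. Overwintered **primary rhizomes** branch into Poisson(2) **secondary
   rhizomes**; every node crown of a secondary (Poisson(3) nodes) sprouts
   one apical **tiller**, so a primary fields about 2 x 3 = 6 tillers.
   One dormant reserve meristem per crown remains for regrowth.
2. 26 % of the **seedbank** germinates into seedlings; the remainder is
   lost to predation and loss of viability (no multi-year carryover).
   Emergence dates of seedlings and tillers are Weibull-distributed
   (days after start of season, DASS), with regional parameters.
3. **Clean field at sowing**: plants emerged before the sowing date are
   removed. Killed tillers trigger regrowth from their rhizome's reserve
   meristems, emerging 21 days after removal.
4. **Early postemergence application** (sowing + 30 d) hits all plants
   emerged by the application date: resistant plants survive each
   herbicide of the tank mix with certainty, sensitive plants escape each
   component independently with probability 1 - efficacy (0.95 early).
   Each application also kills sensitive rhizomes with probability 0.25
   (no-till) or 0.50 (tillage). Killed tillers regrow three weeks later.
5. **Late postemergence application** (sowing + 60 d) covers every plant
   of the season at 0.90 efficacy; its reduced efficacy folds in the
   plants that emerge after it, so no further regrowth wave follows.
6. **Census**: standing live plants are counted; density above the
   threshold terminates the replicate.
7. **Reproduction**: every surviving adult mothers
   `min(a * exp(b * x), max)` seeds for emergence date x (the exponential
   decline proxies competition with the crop canopy), selfing with
   probability 0.95, otherwise outcrossing to a father drawn uniformly
   from the adults. Adults also clone themselves into Poisson(0.8)
   **tertiary rhizomes** (see *Calibrated knobs*).
8. **Overwintering**: aboveground biomass dies; primary and secondary
   rhizomes die after reproduction; each tertiary rhizome survives winter
   with probability 1 - mortality and becomes next season's primary.

All probabilistic events are independent Bernoulli/Poisson draws at the
individual level, vectorized over cohorts.

## Inheritance

Seeds draw one allele from each parent at the resistance locus (both from
the mother under selfing, so a selfed RS plant segregates 1:2:1).
Clonal offspring — tillers, regrown tillers, and all rhizome tiers — copy
the parental genotype and Pz exactly.

For the quantitative trait, each season's seed crop draws Ln(Pz)
independently from a normal whose mean and SD are the realized mean and SD
of Ln(Pz) among the adults, multiplied by inheritance ratios mu_ratio = 1
and sigma_ratio = 1.18. These ratios are not free parameters: they are the
output of an a-priori individual-based cross simulation
(`infinitesimal_cross_sim()`) in which Ln(Pz) is the sum of 20 unlinked
additive diploid loci and mating follows the weed's 95 % selfing rate.
Partial selfing converts within-plant heterozygosity into between-seed
variance, which is why the SD inflates: the closed-form expectation is
sqrt((0.95 x 3 + 0.05 x 2) / 2) = 1.21 at selfing 0.95 (sqrt(1.5) = 1.22
under complete selfing), and the package's simulation reproduces the
adopted 1.18 within a few percent. Because the seed crop's Pz is drawn
from the *population-level* adult distribution, selection response in the
sexual channel operates through shifts of the adult mean and the
variance-inflation ratchet; a single rare high-Pz adult influences seeds
only through its (small) effect on the pooled moments. The clonal channel,
by contrast, preserves individual Pz exactly and so responds to selection
lineage by lineage. This is the main place where an implementation choice
(population-level versus per-family seed Pz) materially affects behaviour:
it damps the evolution of quantitative resistance from very rare founders
relative to a per-family scheme, and the glyphosate-solo scenario is the
one place we expect under-prediction for that reason. The per-family
scheme is not implementable from the published information (it would need
a within-family variance that is never stated).

A fitness cost can burden carriers of the resistance allele: survival of
every newly created seedling, tiller or regrown tiller is multiplied by
1 - 0.42 and seed production by 1 - 0.36 (the "literature" preset; "max"
is 0.90/0.90 and "none" disables the cost). The cost applies equally to RR
and RS, mirroring the complete dominance of the resistance phenotype —
with a recessive cost, the extreme 90 % preset would no longer prevent
establishment of heterozygous lineages, contradicting the intended
behaviour of the maximal-cost scenario.

## Parameters

Regional values (South = Colón, Rolling Pampas; North = Tartagal, Salta):

| quantity | South | North |
|---|---|---|
| sowing date (DASS) | 138 | 142 |
| seedling emergence Weibull (k, lambda) | 10.5, 169 | 4.1, 165 |
| tiller emergence Weibull (k, lambda) | 6.5, 160 | 5.2, 165 |
| fecundity a (seeds), b (/day) | 298,660, -0.066 | 1,554,053, -0.066 |
| seed cap (seeds/plant) | 356 | 1,852 |
| winter mortality no-till / tillage | 0.25 / 0.50 | 0.10 / 0.40 |

Shared defaults: field 10,000 m^2; failure threshold 5 plants/m^2;
horizon 30 years; initial seedbank 10 seeds/m^2 and rhizome bank
1 primary/m^2 (genotypes Hardy-Weinberg at allele frequency q, Pz
log-normal around the founding LD50); germination 0.26; selfing 0.95;
foliar efficacies 0.95/0.90 (early/late); rhizome efficacies 0.25/0.50
(no-till/till); glyphosate dose 1,120 g a.e./ha; sigma_log 0.5087.
`sigma_log` is treated as the *standard deviation* of Ln(Pz): only that
reading reproduces all three founding tail equivalences (LD50 1,719 ->
80 % above 1,120; 139 -> 0.002 %; 85 -> 0.00002 %), which
`resistant_fraction_analytic()` verifies in closed form.

The scenario presets `T1`-`T9` (see `build_scenario()`) vary one axis at a
time around the baseline `T5` (South, no-till, dual tank-mixed program,
q = 1e-5, LD50 1,719, literature cost).

## Design choices where the design was genuinely open

* **Tillers per rhizome.** Every node crown of a secondary rhizome
  sprouts one apical tiller. The alternative — one tiller per secondary
  rhizome with nodes held only as reserves — makes tiller output
  insensitive to the node count, which contradicts the observed strong
  sensitivity of population density to node number; the per-crown reading
  also matches the 2 x 3 = 6 expected tillers per primary that the
  branching means imply.
* **Regrowth bookkeeping.** One reserve meristem per node crown; at most
  one regrowth per killed tiller, never exceeding the remaining reserves,
  and only while the rhizome is alive. Regrowth follows the pre-plant
  removal and the early application; plants emerging after the late
  application are folded into its reduced efficacy instead of spawning a
  third wave.
* **Pre-plant removal.** The clean-field rule removes tillers as well as
  seedlings (killed tillers may regrow at sowing + 21). The
  seedlings-only variant (flag `preplant_removes_tillers = FALSE`) leaves
  early-emerged tillers carrying near-cap fecundity in the field and
  makes resistant lineages grow unrealistically fast.
* **Fathers for outcrossing** are drawn uniformly from all adults alive
  at seed set; **seed counts** use stochastic rounding (expectation
  preserving — plain truncation would bias low-fecundity plants to zero);
  boundary conventions are strict `<` for pre-plant removal, `>=` for
  Pz against dose, and strict `>` for the failure threshold.
* **Seedbank carryover.** Seeds that fail the 26 % germination draw are
  removed — the complement is attributed to predation and loss of
  viability, not dormancy.

## Calibrated knobs

Two quantities are not field observations and are deliberately exposed as
knobs, with their values recorded in every run manifest:

* `tertiary_rate` (Poisson mean tertiary rhizomes per adult) = **0.8**.
  Calibrated once against the baseline scenario's joint behaviour
  (resistance probability, mean failure year, and the regional
  seedbank:rhizome ratios), favouring the failure-year and
  fitness-cost-contrast cluster where the model is structurally tightest.
* `classify_threshold` (resistant fraction of standing plants that marks
  evolved resistance) = **0.20**. Because established resistant lineages
  sweep the census within a couple of seasons while the susceptible
  background collapses under the dual program, classification is
  insensitive to this value over a wide range; it is a reporting
  convention, not a dynamical parameter.

## What the synthetic-data generators emulate

`generate_emergence_data()` simulates a quadrat survey: n plants with
Weibull emergence dates tallied at five evaluation visits, so counts carry
exactly the binomial interval noise a field survey would. It does not
emulate quadrat-to-quadrat spatial heterogeneity, observer error, or
weather-driven deviations from the Weibull form — so recovery of the true
parameters by `fit_weibull_emergence()` demonstrates estimator
correctness, not robustness of the Weibull assumption on real fields.
`generate_fecundity_data()` produces exponential-decline counts with
log-normal noise for `fit_exponential_fecundity()`, with the same caveat.
The published panicle-regression adjustment chain is implemented in
`adjust_fecundity()`; note that applying it to the published panicle and
seed counts does not reproduce the tabulated regional `a` values, so the
tabulated values are used verbatim in simulation and the adjustment is
provided as a parameterization tool.

## Numerical and problem-size choices

Cohorts are plain vectors and every demographic operation is vectorized;
a 1,000-replicate baseline ensemble runs in minutes on one core. The test
suite runs scaled-down ensembles (120-600 replicates depending on the
statistic; ratio statistics pool over every replicate-season record and
converge fastest) and widens stochastic tolerances by three Monte-Carlo
standard errors at the scaled size — a fixed mechanical rule, so smaller
ensembles never silently tighten a check. The sensitivity driver shares
one root seed across all perturbed ensembles (common random numbers) and
rescales the repeat-run natural-variation band by sqrt(1000 / n).

## Known limitations

* No intraspecific competition: the model is meant for the low-density
  management regime below the 5 plants/m^2 ceiling.
* No spatial structure, seed/pollen immigration, or mutation: resistance
  can only arise from the founding variation.
* Population-level seed-Pz inheritance damps rare-lineage quantitative
  selection (see *Inheritance*).
* No within-season growth stages or herbicide decay; dates matter only
  through event ordering and the fecundity-vs-emergence relation.

## A short example

```{r example, eval = FALSE}
cfg <- build_scenario("T5")
ens <- run_ensemble(cfg, n_replicates = 200, seed = 1)
print(ens)
plot(ens)

# sensitivity of the baseline to the ecological parameters
run_sensitivity(cfg, n_replicates = 200, seed = 1)
```
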