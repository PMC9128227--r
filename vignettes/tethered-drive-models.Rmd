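---
title: "Models and inference for tethered toxin-antidote gene drives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and inference for tethered toxin-antidote gene drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherdrive)
```

## The system being modelled

A *tethered* gene-drive system pairs two CRISPR elements that only work
together. The first is a Toxin-Antidote Recessive Embryo (TARE) drive: a
cassette inserted into an essential but haplosufficient gene (in the flies
these models describe, *hairy* on chromosome 3L), carrying Cas9, gRNAs
against the wild-type copy of that gene, and a recoded, uncleavable rescue
copy. Cas9 in the germline of drive carriers disrupts wild-type alleles;
Cas9 and gRNAs deposited in the egg by drive-carrying mothers disrupt
wild-type alleles in the zygote regardless of which parent contributed
them. Disrupted alleles are recessive lethal, so they are purged when two
meet, and each purge removes wild-type alleles while sparing drive alleles.
This gives the TARE element two properties that matter for deployment: it
biases inheritance without super-Mendelian copying, and it is *confined* —
below an introduction-threshold frequency the fitness cost of the cassette
outweighs the toxin effect and the drive declines.

The second element is a *split homing drive*: gRNAs plus a rescue or cargo
at a second locus, with no Cas9 of its own. In individuals that also carry
the TARE element, the homing locus is cut and converted by
homology-directed repair; in wild-type individuals it is inert. Two homing
architectures are supported:

* a **modification drive** inserted in a haplolethal gene (*RpL35A*):
  germline cuts that resolve by end joining produce nonfunctional
  resistance alleles whose carriers die, so resistance self-eliminates and
  the drive can reach fixation;
* a **suppression drive** inserted in a haplosufficient female-fertility
  gene (*yellow-g*): both drive and resistance alleles disrupt the gene,
  and females with no functional copy are sterile, which loads the
  population as the drive rises.

## Genotype space and cross mechanics

The unit of all computation is a phased two-locus genotype: an unordered
pair of haplotypes, each haplotype an allele at the TARE locus
(`W`/`D`/`R` — wild, drive, disrupted) and an allele at the homing locus
(`W`/`D`/`R`, or `A` when no homing locus is configured). Functional
resistance at either locus is excluded by design: multiplexed gRNAs make
its formation rare enough to neglect on cage time scales.

Gamete formation enumerates, in order: sex-specific recombination between
the loci (`recomb_male = 0` by default — Drosophila males lack meiotic
crossing over, which matters because both elements sit on chromosome 3),
independent per-allele germline disruption at the TARE locus (probability
`c_germ_tare` per wild-type allele, in carriers of either sex),
independent per-allele cutting at the homing locus when Cas9 and the
homing gRNAs are both present (`homing_germ_cut`, resolved to a drive copy
with `homing_conversion_frac`), and a uniform draw of one haplotype.
Embryo cleavage then applies to *every* remaining wild-type allele in the
zygote — maternal and paternal copies alike — when the mother carries the
TARE drive (`c_embryo_tare`; `c_embryo_homing` likewise when she carries
both elements, always yielding resistance). The choice to cut maternal as
well as paternal copies is deliberate: with germline cleavage 0.888 and
embryo cleavage 0.632 it reproduces a 71.7% (printed 72%) drive-carrier
fraction among viable progeny of drive-heterozygous mothers, whereas a
paternal-only variant gives 69.5%. The two gRNAs of the TARE cassette are
collapsed into one effective per-allele cut probability, since only
aggregate cleavage rates are identifiable from phenotype counts.

Every offspring distribution in the package is checked exactly (to 1e-12)
against a brute-force oracle that enumerates the full outcome tree.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `c_germ_tare` | germline disruption per wild-type TARE-locus allele | 0 | probability |
| `c_embryo_tare` | embryo disruption per wild-type TARE-locus allele, drive mothers | 0 | probability |
| `homing_germ_cut` | germline cut per wild-type homing allele (needs both drives) | 0 | probability |
| `homing_conversion_frac` | cut resolved as drive copy | 0 | fraction |
| `c_embryo_homing` | embryo cut per wild-type homing allele (to resistance) | 0 | probability |
| `recomb_female` / `recomb_male` | inter-locus recombination per meiosis | 0.5 / 0 | probability |
| `f_hom` | drive homozygote fitness (wild type = 1) | 1 | relative fitness |
| `ne_fraction` | effective population size / census | 0.036 | fraction |

The measured cleavage rates used throughout the examples are
`c_germ_tare = 0.888` and `c_embryo_tare = 0.632`; they are exactly
recoverable from the two diagnostic crosses by
`estimate_cleavage_rates()`, which inverts the closed-form carrier
fractions of the drive-female × wild cross and the heterozygote ×
heterozygote cross (a one-dimensional root find after eliminating the
germline rate). Mendelian inputs are flagged as unidentifiable rather than
inverted.

Fitness uses the codominant multiplicative convention: heterozygotes take
the square root of the homozygote value, and genotypes with one wild-type
and one disrupted copy (no drive allele) keep fitness 1 because the target
is haplosufficient. The `component` argument places the cost on female
fecundity, male mating success, offspring viability, or on both parents
multiplicatively. With shared genotype frequencies in the two sexes, the
female-fecundity and male-mating components induce identical *frequency*
dynamics whenever nothing else distinguishes the sexes; maternal
deposition breaks that symmetry slightly (down-weighting drive mothers
also reduces embryo cutting), so with embryo cleavage active the
components differ, but only weakly. A one-sex cost `f^2` still closely
matches a two-sex cost `f`, so cage data mostly constrain the
per-mating-pair product rather than the component.

## Deterministic dynamics and the introduction threshold

`next_generation()` iterates the infinite-population expectation: discrete
non-overlapping generations, random mating at a 1:1 sex ratio, mothers
weighted by the female-side fitness component (sterile females excluded),
fathers weighted competitively by the male-side component, offspring
pooled through the exact cross distributions and viability rules, then
renormalised. Genetic load is reported as one minus the population's
viable reproductive output relative to an all-wild-type population (female
side absolute, male side competitive).

`find_introduction_threshold()` bisects on the release proportion of TARE
homozygotes mixed into a wild-type population. A release *spreads* if the
carrier frequency reaches 0.99 within the horizon (default 1,000
generations) or ends at least 0.05 above its start and still rising;
otherwise it declines. The default tolerance is 1e-4 on the release
proportion; the boundary this locates is the unstable interior equilibrium
of the bistable system. Degenerate cases are flagged: a cost-free drive
spreads from any frequency (threshold 0, `always_spreads`).

Two structural points deserve emphasis. First, the threshold *falls* as
the embryo cleavage rate rises: embryo cutting is the toxin, and more of
it removes wild-type alleles faster relative to the drive's cost. Second,
the threshold is sensitive to the standing pool of disrupted alleles
hidden in phenotypically wild-type individuals (`W/R` heterozygotes).
These alleles are a delayed toxin — they kill only when they meet a second
disrupted allele generations later — and bookkeeping that drops them
(as a purely phenotype-level model must) yields substantially higher
thresholds than the full genotype recursion computed here. Threshold
values are therefore statements about a specific, fully specified model,
and this package always reports the full-recursion value.

```{r threshold, eval = FALSE}
params <- drive_params(c_germ_tare = 0.888, c_embryo_tare = 0.632)
find_introduction_threshold(params, fitness_model(0.867))
```

`find_equilibrium()` covers the tethered phase: a homing release into a
TARE-fixed background, reporting the long-run homing-carrier frequency
with a convergence flag. The haplolethal modification drive fixes from a
6% release; a suppression drive with low conversion and a fitness cost
balances at an interior equilibrium, because sterile drive-homozygous
females remove drive alleles at a rate that grows with drive frequency.

## The cage simulator and its drift contract

`simulate_cage()` emulates a discrete-generation cage experiment. Each
transition: (1) the deterministic expected offspring distribution; (2) a
single multinomial draw of `round(ne_fraction × mean(census_t,
census_t+1))` *individuals* (genotype-level drift, referenced to the
average census of the transition); (3) releases mixed into the realised
frequencies — before the census draw, so released cohorts are phenotyped
in their generation, as in the experiments; (4) a multinomial census
observation, phenotyped by the fluorescent markers (EGFP ⇔ ≥1 TARE drive
allele, DsRed ⇔ ≥1 homing drive allele). Defaults follow the study
conditions: census 3,491, `ne_fraction` 0.036 — cage populations show far
more drift than their census suggests, and the effective size is estimated
rather than assumed.

The likelihood in `fit_fitness()` uses the *same* drift contract, which is
what makes simulate-then-fit internally consistent: because multinomials
aggregate, collapsing the two stages to phenotype classes is exact, and
the transition likelihood is a compound of a `Multinomial(Ne, p)` drift
draw and a `Multinomial(N, X/Ne)` census draw. With two live phenotype
classes and `Ne ≤ 5000` the compound is evaluated by exact summation over
the latent drift count; otherwise a moment-matched normal approximation is
used, with the exact covariance of the two-stage draw (overdispersion
factor `1 + (N−1)/Ne`). The two branches agree to well within 0.1
log-units at cage scale.

## Fitness estimation: design and measured limitations

Phenotype counts do not identify genotypes — an EGFP-positive fly may be
`D/D`, `D/W` or `D/R` — so the likelihood tracks the within-phenotype
genotype composition by the model's own running prediction, initialised
from the known release genotype (drive homozygotes), and rescales it to
each generation's observed phenotype frequencies. Transitions are then
treated as conditionally independent given this filtered state. The first
two transitions of each cage are discounted by default (`discard_first =
2`): freshly released cohorts show transient parental effects that the
steady-state model should not absorb. Profile-likelihood 95% intervals use
the 1.92 log-unit chi-squared cutoff; the optimiser is a coarse
multi-start fitness grid followed by local refinement, with the effective
size profiled out at each fitness value (the propagation depends only on
fitness, so it is cached across the Ne profile).

The plug-in filter is an approximation with measurable consequences,
which the package's own recovery tests quantify rather than hide. For
isolated transitions the likelihood is exactly specified and the
likelihood-ratio statistic is chi-squared calibrated. In full sequential
cage data the hidden composition (how many carriers are homozygous; how
many disrupted alleles hide in wild-looking flies) drifts with effective
sizes of order a hundred individuals and is persistent across generations,
while the filter collapses it to its predicted mean each step. At the
default study conditions this leaves fitness point estimates mildly high
(a few hundredths) and brings profile-CI coverage somewhat below nominal
in the 50-study recovery experiment of the test suite. Users fitting real
cage data should read the intervals as approximate; a full state-space
treatment (particle filtering over genotype composition) is the natural
upgrade and is out of scope here.

`compare_components()` refits each fitness component and tabulates
log-likelihood differences; `threshold_ci()` maps a fitted fitness and its
interval through the threshold bisection (a monotone decreasing map, so
the lower fitness bound gives the upper threshold bound).

## Synthetic data: what it does and does not emulate

`gen_cage_dataset()` generates multi-cage studies at the study conditions
(four cages, census 3,491, `ne_fraction` 0.036, twelve transitions,
TARE-homozygote releases at carrier frequencies 0.1, 0.2, 0.61 and 0.71 —
two near the introduction threshold, two well above it).
`gen_cross_dataset()` generates per-vial phenotype counts with
Dirichlet-multinomial batch overdispersion (`icc`, default 0.02) around
the exact cross prediction; the pooled-rate-with-SEM estimator
(`rate_with_sem()`) weights vials by size and its two-SEM band covers the
truth at close to the nominal rate in simulation (slightly below 95%, the
usual finite-batch shortfall of a normal-theory band with twenty vials).

What the generators deliberately do not emulate: egg/larva/adult stage
structure and density regulation inside bottles, spatially patchy egg
laying, parental effects in released cohorts (handled only through
`discard_first`), functional resistance alleles, and time-varying census
schedules beyond a user-supplied vector. Passing tests on synthetic data
therefore demonstrates internal consistency of model, simulator and
inference — not that real cages obey the model; indeed real cage
trajectories are known to deviate from this model family at intermediate
frequencies.

## Numerical choices

* All distributions are exact enumerations; nothing is sampled inside the
  deterministic engine, and engines are memoised per parameter set.
* Threshold bisection: tolerance 1e-4, horizon 1,000 generations, spread
  margin +0.05 with a rising check at the horizon.
* Equilibrium location: convergence when the carrier frequency changes by
  less than 1e-6 across the last five generations of the horizon.
* Likelihood: exact compound summation whenever only two phenotype classes
  are live and `Ne ≤ 5000`; otherwise the moment-matched normal. Counts
  impossible under the model (e.g. DsRed carriers before any homing
  release) return `-Inf` with a diagnostic rather than an error.
* The cleavage-rate inversion reduces to a single `uniroot` on the embryo
  rate over its admissible interval `[A, sqrt(A)]` (where
  `A = 2 − 1/inh_f`), after solving the female-cross equation for the
  germline rate; round-trip accuracy is at solver tolerance (1e-12).
* Test problem sizes: the recovery experiment uses 50 four-cage studies at
  full census scale; oracle comparisons sweep every viable genotype pair.

## Known limitations

* Infinite-population expectations plus one drift stage; no stage
  structure, spatial structure or migration.
* The fitness filter's composition approximation, as measured above.
* Sex-specific germline cut rates are not separated (the cross design
  cannot identify them; equal rates are assumed and flagged).
* Introduction thresholds are model-bound quantities; comparisons across
  bookkeeping conventions (full recursion vs phenotype-level) can differ
  by nearly a factor of two at realistic parameter values.
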