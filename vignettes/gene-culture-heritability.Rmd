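---
title: "Gene-culture transmission and what twin studies actually estimate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-culture transmission and what twin studies actually estimate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultherit)
```

## The model

`cultherit` studies a dichotomous phenotype (states 1 and 2) shaped by
three forces at once: a diallelic locus, vertical cultural transmission
from the parents' phenotypes, and partial phenotypic assortative mating.
The joint state of an individual — genotype in {AA, Aa, aa} and phenotype
in {1, 2} — is its *phenogenotype*; the population state is the vector of
six phenogenotype frequencies.

One generation is composed of three exact operations:

1. **Mating.** With probability `m` a mate is drawn at random from the
   partner's own phenotype class, otherwise at random from the whole
   population: `M = m A + (1 - m) R`. Margins equal the adult distribution
   exactly, and the spousal phenotype correlation is exactly `m`, so `m`
   is directly interpretable as an observed spouse correlation.
2. **Segregation.** Offspring genotypes follow Mendelian segregation from
   the parental genotype pair.
3. **Phenotype acquisition.** Given its own genotype and its parents'
   phenotypes, the offspring acquires phenotype 1 with the transmission
   table probability. The bilinear scheme writes the twelve probabilities
   as `baseline + genetic increment + cultural increment`:
   genetic `2*alpha` (AA), `sigma*alpha` (Aa), `0` (aa); cultural
   `2*eta` (both parents phenotype 1), `tau*eta` (one), `0` (neither);
   plus `beta` everywhere.

There is no selection: allele frequency `p` is conserved exactly (the test
suite verifies drift below 1e-10 over ten thousand generations). Total
mass is conserved analytically too, but the one-generation map is
*quadratic* in the state, so in floating point a mass error would double
every generation; the stepper therefore renormalizes by the computed total
each step. Fixed-point iteration (L-infinity tolerance `1e-12`, cap `1e6`
iterations; convergence reported honestly, never assumed) reaches the
equilibrium in tens of iterations for all parameter sets explored here.

## Parameters

| parameter | meaning | range | default used in examples |
|---|---|---|---|
| `alpha` | genetic increment per A allele | entries must stay in [0,1] | 0.2 |
| `beta`  | baseline acquisition probability | [0,1] | 0.1 |
| `eta`   | cultural increment per phenotype-1 parent | entries in [0,1] | 0.2 |
| `sigma` | genetic dominance (1 additive, 2 complete) | [0,2] | 1 |
| `tau`   | marital dominance (2: one parent as good as two) | [0,2] | 1 |
| `m`     | assortment rate = spousal correlation | [0,1] | 0.5 |
| `p`     | allele frequency (conserved) | [0,1] | 0.5 |

The footnote constraint `0 <= 2*eta + 2*alpha + beta <= 1` (and its
analogues cell by cell) is enforced eagerly at table construction; the
offending cell is named in the error.

`m = 0.5` is the default in the examples because it matches spouse
correlations reported for attitude traits in large spousal samples;
`beta = 0.1` and `p = 0.5` are this package's documented stand-ins where a
baseline and allele frequency are needed but not otherwise determined.

## Kin statistics and the two heritabilities

At equilibrium the package enumerates exact 2x2 joint phenotype
distributions (no sampling): spouses (aggregating the mating distribution
over genotypes), parent-offspring (either parental role; the bilinear
scheme is parentally symmetric), and twins. Twin phenotypes are
**conditionally independent given own genotype and parental phenotypes**;
MZ twins share a single genotype draw, DZ twins (identified with full
sibs) draw genotypes independently. This deliberate choice makes
`r_MZ - r_DZ` purely genetic in origin, which is exactly the premise of
the twin design the model interrogates. Whether real MZ twins also share
phenotype-realization events beyond this is a separate empirical question
the model does not take a position on; adding such sharing would raise
`r_MZ` and inflate `h2_F` further.

Correlations are phi (Pearson) correlations of the phenotype-1 indicators,
undefined — and signalled, not silently zeroed — when a margin is
degenerate. The indicator coding is immaterial: correlations are invariant
to relabeling.

Two heritabilities are then compared:

* **Actual narrow-sense `h2_A`**: the additive genetic variance `V_A` over
  `V_P = k(1-k)`. `V_A` comes from least-squares regression of the
  phenotype indicator on allele dosage (0/1/2) over the *realized* joint
  distribution. Under random mating this coincides with the textbook
  average-effect formula `2pq (a + d(q-p))^2` (verified in the tests); the
  regression form remains well defined when assortment distorts genotype
  frequencies away from Hardy-Weinberg.
* **Twin-based `h2_F = 2(r_MZ - r_DZ)` and `c2_F = 2 r_DZ - r_MZ`**,
  reported unclipped so the identity `h2_F + c2_F = r_MZ` stays exact;
  clipping negatives is left to consumers.

Limiting regimes anchor both computations analytically: with `eta = 0`,
`m = 0`, `sigma = 1` the model is purely additive and `h2_F = h2_A =
2pq alpha^2 / (k(1-k))` with `c2_F = 0`; with `alpha = 0`, `tau = 1`,
`m = 0` it is purely cultural and `k* = beta/(1-2 eta)`, `r_po = eta`,
`r_MZ = r_DZ = 2 eta^2`, so `h2_F = 0` while the *shared-environment*
estimate absorbs everything. With both forces active the two heritabilities
generically disagree:

```{r}
summary(gc_model(alpha = 0.2, beta = 0.1, eta = 0.2, m = 0.5, p = 0.5))
```

## The finite-population simulator

`simulate_population()` is an agent-based realization of the identical
rules — it samples matings from the *same* `mating_distribution()` object
the deterministic engine integrates over, so the mating law has one code
path. Each generation `N/2` ordered matings produce two offspring each
(independent Mendelian draws, Bernoulli phenotypes). It emulates exactly
the model's assumptions: non-overlapping generations, no sexes, no
mutation, selection or migration, binomial sampling noise only. Agreement
of its `k`, spouse, DZ and MZ correlations with the exact enumeration
(within three Monte-Carlo standard errors at `N = 20000`) therefore
validates the implementation, not the model's fit to any real data; real
twin registries violate these assumptions in ways the simulator does not
emulate (ascertainment, shared uterine environment, measurement error,
polygenicity).

Default problem sizes — `N = 20000`, 15-20 generations, 20000-50000 twin
pairs — keep every Monte-Carlo standard error below about 0.007 so that
3-SE checks are meaningful yet the full validation runs in seconds.

## Design choices where the design was open

* **Six-dimensional state as source of truth.** The dynamics are often
  summarized by `(k, p1)` (phenotype-1 frequency, allele frequency among
  phenotype-1 individuals). Whether the recursion is exactly closed in
  those two coordinates is not obvious under assortment, so the package
  iterates the full six-dimensional system and exposes
  `reduced_coordinates()` descriptively.
* **Ordered parental pairs.** The mother x father pair is ordered; the
  bilinear scheme makes the two single-parent rows equal, but
  `general_table()` accepts asymmetric parental roles and the
  parent-offspring enumeration supports both roles.
* **Eager validation.** Tables and distributions are checked at
  construction; the recursion itself runs unchecked for speed (the hot
  path is three stacked 6x18 quadratic forms per generation, about 20
  microseconds, making 10^6-generation property tests cheap).
* **Degenerate classes.** If a phenotype class is empty, its assortative
  component carries zero mass; reports on degenerate equilibria flag the
  undefined statistics instead of fabricating zeros.
* **Default initial state.** Hardy-Weinberg at `p` with phenotype drawn
  independently at the table's baseline rate; all interior starting points
  explored converge to the same equilibrium, and a `multiple`-start probe
  is available by passing explicit `init` distributions.

## Known limitations

* One locus, two phenotype states, vertical transmission only: no
  polygenic traits, no oblique or horizontal cultural transmission, no
  selection or drift in the deterministic engine.
* Dominance variance is computable from the genotypic means but is not
  reported as a separate component; the comparison of interest is
  `h2_A` versus `h2_F`.
* The twin estimators are evaluated at the model's exact equilibrium
  correlations; sampling error in real twin studies adds a further layer
  this package treats only through the synthetic twin generator.
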