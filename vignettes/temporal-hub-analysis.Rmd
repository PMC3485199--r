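---
title: "Temporal interaction networks and competitive regulation of cell-cycle hubs"
author: "cyclehubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal interaction networks and competitive regulation of cell-cycle hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclehubs)
```

## The scientific problem

Date-hub proteins in the yeast interactome have many interaction partners
but, when "singlish", only one or two structurally distinct interaction
interfaces, so their partners must bind one or two at a time, mutually
exclusively. Whether the cell leaves those partners to compete freely for
the interface, or schedules their expression so that competition is
lessened, is a question about the *temporal* structure of the interaction
network. `cyclehubs` addresses it by overlaying synchronized-culture
expression time courses on hub-seeded interaction networks: a protein and
its interactions are treated as present only while its expression sits at
or above a display threshold, which turns a static graph into a stack of
per-timepoint network frames.

Two regulatory regimes emerge. A **dynamic (periodic) hub** with
constitutively expressed partners is *competitive*: whenever the hub
appears, many partners are co-present and must compete for its
interface(s). A **static (constitutively expressed) hub** with periodic
partners is *non-competitive*: the partners' regulated, often staggered,
expression determines who meets the interface when.

## The pipeline and its model

The stages, each an exported function, are:

1. **Read** (`readExpression`, `readNetwork`): gene x timepoint log2-ratio
   matrices with a minutes axis and an explicit missing-value mask;
   undirected simple interaction graphs from SIF / TSV / GraphML.
   Identifiers are normalized to uppercase at parse time, and all joins use
   the normalized symbols.
2. **Smooth** (`smoothSeries`, `smoothMatrix`): degree-1 local regression
   with tricube weights, neighbourhood `q = ceiling(span * n)` non-missing
   points (span 0.5 by default), distance ties broken toward the earlier
   time, no robustness iterations, evaluated at the observed timepoints
   only. Missing points are excluded from local fits, never interpolated.
   Series with fewer than 4 usable points (or `span * n < 2`) are flagged
   unsmoothable and propagate to an unclassifiable verdict.
3. **Periodicity** (`estimatePeriod`, `scoreGene`, `callGene`,
   `combineCalls`): a cosinor model
   `x(t) = m + A cos(2 pi (t - phi) / T)` fitted by least squares at a
   period shared by the whole experiment (synchronized cultures have one
   oscillator), a permutation test on the cosinor r-squared
   (`p = (1 + #{r2_perm >= r2_obs}) / (1 + nPerm)`, timepoint labels
   shuffled under a recorded seed), and a two-gate call: periodic iff
   `p <= alpha` **and** fitted amplitude `A >= 0.2` log2 units. Calls from
   the synchronization experiments are combined by strict majority among
   usable experiments; ties or fewer than two usable experiments are
   unclassifiable.
4. **Classify** (`classifyHub`, `regulatoryClass`, `tabulateHubs`): a
   periodic hub is Dynamic; an aperiodic hub with at least one periodic
   direct partner is Static; an aperiodic hub with none is reported as
   `unassigned` (the published rule is conditional and silent about this
   case; such hubs are excluded from the competitive/non-competitive
   tallies); an unclassifiable hub is `not_classified`. Dynamic hubs with
   at least one aperiodic partner are competitive; Static hubs are
   non-competitive; a dynamic hub whose whole neighbourhood oscillates in
   phase is co-ordinately regulated, not competitive.
5. **Frames and competition** (`activityMask`, `frameAt`, `exportFrames`,
   `competitionProfile`, `partnerOverlap`): threshold-gated visibility at
   -0.2 log2 units (inclusive boundary: the convention hides what falls
   *below* threshold), per-gene overrides for low-amplitude exceptions, and
   per-timepoint counts of active partners against the number of
   interfaces.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `span` | 0.5 | fraction of points | the smoothing the field applies to these time courses for continuous viewing |
| `threshold` | -0.2 | log2 ratio | set below the expression floor of constitutive hubs to suppress stochastic flicker; one published exception uses -0.1 |
| `alpha` | 0.05 | — | permutation-test level; no multiple-testing correction, matching field practice for these per-gene calls |
| `minAmplitude` | 0.2 | log2 ratio | fitted cosine amplitude floor; sub-floor oscillations cannot be rendered at the default threshold and are not trusted as periodicity |
| `nPerm` | 1000 | — | p-value resolution 1/1001, ample for alpha 0.05 |
| `grid` | 40–120 by 1 | minutes | brackets the cell-cycle lengths of the usual synchronization protocols |
| staggered `cutoff` | 0.5 | Jaccard | no published number exists; exposed in configuration |

The amplitude floor is read as the *fitted* cosine amplitude (half the
peak-to-trough swing). The published phrase "peak amplitude less than 0.2"
is ambiguous between fitted amplitude and peak height; the fitted reading
is the one a cosinor model can evaluate.

## Where periodicity is scored: raw, not smoothed

Smoothing and scoring serve different masters, and the package keeps them
apart deliberately. The span-0.5 local smoother is a low-pass filter whose
window is a *fraction of points*, so its bandwidth in minutes depends on
the sampling grid: on an 18-point/119-min course it attenuates a 66-min
cosine by roughly 40%, on a 17-point/160-min course by ~75%, and on a
24-point/290-min course by ~96% (the window there spans more than two full
cycles). Scoring smoothed values against a fixed 0.2 amplitude floor would
therefore erase true periodicity on the longer grids — the floor is a
statement about the measurement scale. So the cosinor fit, the permutation
test and the period estimate run on the **raw** series, while the smoothed
series drive what smoothing exists for: continuous viewing, i.e. the
activity masks and frame stacks. (`scoreExperiment` accepts either object;
the pipeline wires it to the raw matrices.)

## The synthetic study design

The generator (`simulationConfig`, `simulateBundle`) emulates the
statistical structure the analysis assumes, with ground-truth labels:

* three experiments on the classical sampling grids (18 points/119 min,
  24 points/290 min, 17 points/160 min), sharing one period (66 min) and
  per-gene amplitude/phase/baseline, with independent Gaussian noise
  (sd 0.15 log2 units) per experiment;
* periodic genes `m + A cos(...) + e` with `A ~ U(0.4, 1.0)`; static genes
  `m + e`; stochastic genes a random walk (step sd 0.08) realized
  independently per experiment, the mechanism behind expression that is
  inconsistent between synchronization conditions;
* ten hubs covering the four regimes (dynamic hub + static partners,
  static hub + staggered periodic partners, co-ordinate hub + co-phased
  partners, stochastic hub + stochastic partners), each with dedicated
  partners; a 44-gene background periphery (30% periodic) attaches to the
  partner shell — never directly to a hub — and sparse cross-links
  (probability 0.02) run between background pairs only, so each hub's
  1-step neighbourhood remains its dedicated partners and the intended
  classes stay well defined. Intended classes are nevertheless recomputed
  from the realized topology and labels, so truth is self-consistent under
  any wiring.

Baselines are drawn near zero (U(-0.05, 0.05)) so the -0.2 threshold
retains its meaning. The staggered-partner generator uses amplitude 1 with
baseline -0.3: each partner is then active slightly less than half the
cycle under the -0.2 threshold, which makes evenly phase-shifted troughs
pairwise low-overlap by construction.

What the generator does **not** emulate: array-specific noise structure,
loss of synchrony over successive cycles, cross-hybridization, or the
coupling between expression and protein abundance. Passing recovery tests
therefore show the inference is correct *under its own model*, not that
the published visual classifications would be reproduced on the original
microarray data — those depended on judgement the package replaces with an
explicit statistic.

## Numerical choices and degenerate inputs

* Local fits solve the 2-parameter weighted normal equations directly; a
  rank-deficient window (all weight on one point) falls back to the
  weighted mean.
* A constant series has cosinor r-squared defined as 0 and amplitude 0, so
  it is called aperiodic through the amplitude gate, with `p = 1` from the
  permutation test (all shuffles tie).
* Period ties on the candidate grid break toward the shorter period;
  the grid is sorted before scanning.
* Usability for scoring requires at least 6 non-missing points spanning at
  least one full period; failures are marked unusable, never errors.
* Frames exist only at sampled timepoints (no interpolation); a value
  exactly at threshold is visible; missing values are invisible.
* Equal-threshold boundary cases, permutation ties and RNG are all exact:
  every stochastic step derives from an integer seed recorded in the
  output, and the suite asserts byte-identical reruns.

## Design choices that were genuinely open

* **Periodicity statistic.** The published classification was visual,
  validated against periodicity databases. The package substitutes a
  cosinor + permutation test (the natural fixed-period test for short,
  unevenly powered series) with an amplitude floor taken from the
  published rendering exception. Defaults are configuration-exposed.
* **Cross-experiment rule.** Whether the original analysis required
  periodicity in all three experiments or any is unstated; strict majority
  among usable experiments, with ties unclassifiable, mirrors the
  published treatment of "inconsistent between conditions" without being
  derivable from it.
* **Partners for classification** are the 1-step neighbours; 2-step ego
  networks are rendering context only ("interaction partner" means a
  direct interactor).
* **Smoothing per experiment**, never across concatenated experiments:
  the grids differ and the cultures are independent synchronizations.
* **Merging of source interactomes** (union with provenance vs
  intersection) is unresolved in the literature the formats come from; the
  readers support multi-file union but no merge policy is baked in.

## Known limitations

* Interface-to-partner assignments are structurally unresolved, so all
  partners are treated as competing for all interfaces; cooperative or
  priming interactions (kinase first, then substrate at the same
  interface) are indistinguishable from competition here and are flagged
  as an interpretive caveat, not modelled.
* mRNA is a proxy for protein presence; half-life, abundance and
  localization are outside the model.
* The published hub annotation table carries small internal
  inconsistencies in its printed totals (20 vs 21 classified hubs, 35 vs
  36 singlish hubs, depending on the section); the packaged fixture
  transcribes the table as printed and the tallies the package reports are
  the table's own.

## Problem sizes used by the test suite

The recovery suite runs the default design: 100 genes (10 hubs, 46
partners, 44 background), three experiments, 1000 permutations per gene
per experiment — a few seconds end to end. The oracle suites use 50
20-point series for the smoother and 20 series at 200 permutations for the
permutation test. These sizes were chosen so the whole suite exercises
every stage at full fidelity while staying quick enough to run on every
change.

## A worked run

```{r, eval = FALSE}
cfg <- simulationConfig(seed = 7)
bundle <- simulateBundle(cfg)
res <- runPipeline(bundle$network, bundle$experiments,
  hubs = data.frame(hub = sprintf("HUB%02d", 1:10),
                    n_interfaces = cfg$hubSpecs$nInterfaces),
  outDir = "run1", seed = 7)
res$tallies
```
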