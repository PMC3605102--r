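---
title: "Inferring metabolic states from expression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring metabolic states from expression: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(examo)
```

## The problem and the modelling assumptions

A constraint-based metabolic model admits every steady-state flux vector
satisfying `S v = 0` and the bounds `lb <= v <= ub`. When the nutrients
available to the cells are unknown, all exchange reactions must be opened
in both directions, and the feasible set is far too large to pinpoint the
actual metabolic state. The package's working hypotheses are:

* transcript abundance, discretized coarsely into high / neither / low,
  carries enough signal to distinguish pathways that are "on" from
  pathways that are "off", even though transcript levels correlate poorly
  with flux magnitudes;
* the cell's state maximizes the *agreement* between these calls and flux
  activity (the iMAT objective), and among the typically many optima, only
  what is common to all of them should be trusted;
* the reactions active in every optimum (HFR) are really active, those in
  none (ZFR) really inactive, and a minimal flux-consistent network around
  the HFR approximates the condition-specific metabolism;
* absolute flux levels are set by enzyme economy: among states with all
  HFR active, the cell realizes (approximately) the one of minimal total
  flux.

Each stage is usable on its own; `examo()` chains them.

## Stages and their tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `bound_magnitude` | 1000 | flux (mmol/gDW/h in real models, dimensionless in tests) | "effectively unbounded" exchange bound; also the big-M constant, so it must stay finite |
| `hi_frac`, `lo_frac` | 0.15 | fraction | percentile cutoffs for +1 / −1 gene calls |
| `eps` | 1.0 | flux | activation threshold: an rH reaction agrees when `|v| >= eps`; forced activations in the flux state use the same scale |
| `biomass_min` | `eps` | flux | quantifies the "non-zero biomass" constraint; tied to `eps` so one scale governs all activation constraints |
| `trim_tol` | 1e-9 | flux | LP-optimum magnitude below which a reaction counts as blocked (solver noise floor) |
| `activity_tol` | 1e-6 | flux | "carries flux" threshold when counting activity across optima: well above LP noise, well below `eps` |
| `growth_tol` | 1e-6 | flux | FBA optimum below which a gene deletion counts as lethal; with open exchanges, viable growth is bound-limited and far above this |
| `seed` | 0 | — | pruning order of the context-model sweep |

With approximately log-normal expression values the 15% cutoffs sit about
one standard deviation above and below the mean on the log scale (the test
suite checks this on simulated data), which is the rationale for the
default; the fraction is a parameter, not a fitted quantity.

## Discretization and GPR logic

Gene calls are mapped onto reactions by evaluating each GPR with AND as
minimum and OR as maximum over the order −1 < 0 < +1, unmeasured genes
counting 0. On flat rules this reproduces the four prose conventions — a
complex is highly expressed only if *all* subunits are and lowly expressed
if *any* subunit is; an isoenzyme set is highly expressed if *any* isoform
is and lowly expressed only if *all* are — and it is the unique monotone
recursive extension of those rules to nested expressions, which is why it
was adopted for arbitrary rule trees. Ties at the percentile boundary are
broken by value and then by gene id, and set sizes use the ceiling rule,
so calls are reproducible across platforms.

## The agreement-score program and its exploration

The iMAT MILP (see the README for the formulation) is solved to proven
optimality — the indicator linearizations use each reaction's own finite
bounds as big-M, the integrality tolerance is the solver default and the
relative MIP gap is fixed at 0. "Inactive" for an rL reaction is enforced
as exactly `v = 0` by the indicator constraint, not as a small interval.

The space of alternative optima is explored by reaction modulation: each
reaction is in turn forced off (`v = 0`), forward (`v >= eps`) and, when
reversible, backward (`v <= -eps`), and each modified program is re-solved.
Runs that become infeasible or lose the optimal score are recorded and
discarded — both outcomes are expected and are reported in the ensemble's
provenance table. Frequencies are counted over the retained raw solutions
at `activity_tol`; deduplicated distribution counts are reported
separately, because HFR/ZFR membership is all-or-none and unaffected by
duplicates.

Because forcing a reaction off and asking for the same score decides
exactly the question "is there an optimum without this reaction?", the
modulation scheme determines the HFR set faithfully. For the ZFR the
forced activation uses the `eps` scale, so an optimum carrying a flux
between `activity_tol` and `eps` through some reaction could in principle
be missed; the test suite therefore checks, on small instances against an
exhaustive no-good-cut oracle, that the heuristic sets always *contain*
the exhaustive ones (they can only be equal or larger/smaller in the safe
direction).

"Flux distribution" in the discrete counts of the toy example is
operationalized as a *support-minimal* biomass-producing route (an
elementary-mode-like object): raw flux vectors form a continuum, and only
route-level counting makes integers such as "8 possible distributions, 3
of them optimal" well defined. The enumeration finds minimum-cardinality
activity patterns under no-good cuts until infeasibility and verifies each
returned route by re-solving with every single active reaction forced off.

## Context-model extraction

Zero-frequency reactions are deleted first; if that blocks any
high-frequency reaction the conflict is reported as an error rather than
silently repaired, since it signals contradictory frequency sets. The
remaining non-core reactions are visited in a seeded random order and
removed when every core reaction still passes a flux-variability check at
`activity_tol`. One sweep suffices to reach the fixed point: deleting
reactions only shrinks the flux space, so a candidate whose removal once
blocked the core can never become removable later. The result is locally
minimal — removing any remaining non-core reaction blocks some core
reaction — which the tests verify exhaustively on fixtures. The original
batch formulation with a "moderate-probability" reaction class is not
used because this pipeline defines no moderate set. The sweep order is the
only stochastic element of the whole pipeline; genome-scale users should
compare results across a few seeds, while all shipped analyses fix seed 0.

## Flux states and essentiality

Total-flux minimization splits each reversible reaction into non-negative
forward and reverse half-fluxes and minimizes their sum; each forced
reaction gets either a fixed `v+ >= eps` (irreversible) or a binary
direction selector (reversible) so that exactly one direction is active.
Simultaneous forward-and-reverse activity in unforced reactions cannot
survive at an optimum (it would add to the objective at no benefit) and is
asserted rather than constrained. Reported flux tables suppress entries
below 1e-10, matching the convention of published flux-state tables.
Essentiality evaluates GPRs two-valued (deleted gene FALSE, everything
else TRUE, independent of expression calls), closes the reactions whose
rule fails, and calls a gene essential when the FBA biomass optimum drops
below `growth_tol`. With fully open exchanges FBA growth is bound-limited,
so the threshold's exact value is immaterial over many orders of
magnitude; scoring versus observed essentials removes an optional excluded
set from both sides first, the convention needed when mutants essential on
a reference medium were never assayed on the test medium.

## The solver layer

No exact MILP solver is available as an R library in this package's
dependency footprint, so all programs are assembled in R as dense
matrices and solved by HiGHS through `scipy.optimize.milp` in a small
bundled Python helper (`inst/python/milp_batch.py`). Problems are batched
— flux-variability runs, exploration modulations, deletion screens and
oracle enumerations each travel as one JSON batch per solver process — so
interpreter start-up does not dominate. HiGHS is deterministic
single-threaded, which makes every pipeline stage reproducible bit-for-bit
given the same inputs and seeds.

## The toy network

The shipped ten-reaction toy synthesizes a five-carbon biomass precursor
from a two-carbon substrate (r1) or a three-carbon substrate (r2), with a
one-carbon byproduct pool closed by salvage (r4), an alternative
condensation (r8) and an export (r10). Carbon is conserved in every
internal reaction. Reaction r3 carries a two-gene OR rule (isoenzymes, one
gene high) and r7 a two-gene AND rule (a complex, both genes high). The
published figure from which such toys are drawn is not machine-readable,
so the topology was reconstructed to satisfy the typed constraints and the
printed counts simultaneously — 8 support-minimal routes, 2 after closing
the two-carbon uptake, optimal agreement score 4, and exactly 3 optimal
routes — and those four counts gate the fixture in the acceptance tests.
The three optimal routes share the backbone r1, r3, r5, r6, r9 and differ
only in the disposal of the one-carbon byproduct (r4 / r8 / r10); the
single disagreement is the highly expressed complex r7, inactive in every
optimum.

## The synthetic generator, and what passing tests do not show

`generate_synthetic()` emulates the method's target situation: a planted
flux-consistent backbone (uptake, chain, biomass) whose genes are called
high, decoy branches whose genes are (mostly) called low, gene-free
bypasses that create genuine alternative optima, a configurable fraction
of reversible backbone steps, and sign-flip call noise. Decoy steps point
away from the backbone so decoy exchanges cannot act as hidden substrate
sources, which keeps "the planted subnetwork is the active one" true by
construction at zero noise.

What it does *not* emulate: realistic network topology (loops,
cofactor coupling, compartments), correlated noise between genes of one
operon/complex, dosage effects, or any magnitude information — calls are
ternary by design. Passing the recovery tests therefore shows that the
optimization and pruning machinery is correct and stable under call noise,
not that 15% thresholds or the agreement objective are biologically
optimal for a given organism.

Test problem sizes are deliberately small so that the exhaustive oracles
stay exact: random networks for the oracle-equivalence checks have at most
12 reactions (50 seeded instances), recovery runs use 5-step backbones
over 20 seeds (plus 10 noisy seeds), and the full-pipeline smoke instance
has about 30 reactions. These sizes are the package's choices for exact
cross-checking; the algorithms themselves scale to genome-scale models,
where the dominant cost is the roughly `2m + 1` MILP solves of the
exploration stage.

## Known limitations

* HFR/ZFR are defined relative to the optima the modulation scheme visits;
  the scheme provably settles membership questions at the `eps` activation
  scale, but optima with sub-`eps` activity can escape the ZFR check (see
  above).
* The greedy pruning gives a locally, not globally, minimal context model,
  and its content is seed-dependent; only HFR membership is
  seed-invariant.
* With fully open exchanges, FBA essentiality misses genes whose loss is
  lethal only under specific nutrient limitations; this is inherent to
  modelling unknown environments.
* The reaction-list CSV reader maps headers permissively but expects one
  pre-aggregated expression value (or call) per gene; probe-level data
  must be summarized upstream.
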