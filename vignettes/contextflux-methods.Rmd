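---
title: "Methods: expression-constrained flux prediction, biomarker calling and knockout ranking"
author: "contextflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-constrained flux prediction, biomarker calling and knockout ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextflux)
```

## Overview

`contextflux` predicts context-specific metabolic flux states by
integrating a gene × sample expression table with a constraint-based
metabolic model, then uses those states for three downstream analyses:
calling reactions and exchange-metabolite biomarkers whose permissible
flux changes between two conditions, testing pathways for enrichment in
the altered set, and ranking single-reaction knockouts by their
predicted ability to move a "source" (disease-like) flux state back
toward a "target" (healthy-like) state.

The pipeline is:

1. **Discretization.** Within each sample, a gene is called highly
   expressed (+1) above the across-gene mean + 0.3 SD, lowly expressed
   (−1) below mean − 0.3 SD, moderate (0) otherwise. A gene's final
   state is the level it reaches in at least 2/3 of the condition's
   samples. Gene states map to reaction states through the
   gene–protein–reaction (GPR) rules with `and` = min, `or` = max.
2. **Consistency-maximizing flux fit.** A mixed-integer linear program
   finds a steady-state flux vector (S·v = 0, bounds −1000..1000 by
   default) maximizing the number of highly-cued reactions carrying
   activating flux (|v| ≥ ε) plus lowly-cued reactions carrying zero
   flux. Discrepancies at the optimum are reported as
   post-transcriptional regulation calls (low-but-active = up,
   high-but-inactive = down).
3. **Optimality-locked flux variability.** With the consistency
   objective constrained to its optimum, each reaction's minimum and
   maximum flux are computed; control and disease intervals are compared
   by the ordering rule `A < B` iff
   `(minA < minB & maxA ≤ maxB) | (minA ≤ minB & maxA < maxB)`, with a
   change counted as significant only when the smaller interval is at
   least 90% lower than the larger. Significant changes on exchange
   reactions become metabolite biomarker calls (positive flux =
   secretion, negative = uptake; disjoint intervals = high confidence).
4. **Enrichment.** Upper-tail hypergeometric tests per pathway with
   Benjamini–Hochberg control at FDR 0.05.
5. **Knockout ranking.** See the transformation-scoring section below;
   the top 10% of ranked knockouts feed a target-pathway enrichment.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `k` | 0.3 | SD multiplier for the discretization thresholds |
| `consensus_fraction` | 2/3 | share of samples a level must reach |
| model bounds | ±1000 | flux units; applied where a file omits bounds |
| `epsilon` | 1 | activation threshold: active means \|v\| ≥ ε |
| `delta` | 0.9 | interval-significance fraction ("90% lower") |
| `alpha` | 0.05 | FDR level for every enrichment |
| `top_fraction` | 0.1 | share of ranked knockouts taken as targets |

The discretization axis (across genes within a sample, the default,
versus across samples within a gene) is exposed in
`discretize_matrix(axis =)`; the per-sample axis is the default because
the thresholds are defined per sample. The consensus is single-valued
for any fraction above one half. Values lying exactly on a threshold
stay moderate, so results do not depend on how equality is represented.

## The consistency MILP

Activation of a highly-cued reversible reaction counts in either
direction, via separate forward/backward binaries of which at most one
may be set; big-M constants come from each reaction's own bounds, which
keeps the relaxation tight. A lowly-cued reaction's binary forces
`lb(1−y) ≤ v ≤ ub(1−y)`, i.e. exactly zero flux. The objective is the
binary sum and is therefore integral, so the variability stage can lock
it exactly — no slack tolerance is needed (an integer slack is available
for sensitivity analysis). ε = 1 in bound units of 1000 is a
configurable default: small enough that activation is rarely the binding
constraint, large enough to be distinguishable from solver noise.

The programs are solved by a dense bounded-variable two-phase primal
simplex with branch and bound, bundled in the package (`solve_lp()`,
`solve_milp()`); Bland's rule guards against cycling, branching is
most-fractional with the nearest integer explored first, and integral
objectives enable rounding-based pruning. The solver is dimensioned for
toy networks (tens of reactions); the suite cross-checks it against a
vertex-enumeration oracle and exhaustive binary enumeration.

## Interval comparison and biomarker direction

The published ordering rule fixes when one interval is "lower", but
"at least 90% lower" names no reference quantity. The package reads it
on the flux magnitudes of the side of zero where the change lives: for
positive (secretion-side) intervals the maxima are compared, for
negative (uptake-side) intervals the absolute minima, and intervals
straddling zero are judged on the larger-magnitude side. A reaction
altered on both sides yields two biomarker calls. These comparisons
carry a 1e−9 relative tolerance so that decimal fractions such as
0.1·10 compare as intended in binary floating point. `delta` is
configurable, and `threshold_sweep()` reruns the comparison stage across
a set of values, reporting the per-value enrichments and the robust
intersection of altered reactions.

## Transformation scoring

Candidate knockouts are scored by how far the post-knockout state moves
toward the target. The changed/steady gene sets come from per-gene
rank-sum tests between the two conditions (BH at `alpha`; with fewer
than two samples per arm a fold-change rule is used), pushed through the
GPRs to label reactions as required-to-increase (R_F),
required-to-decrease (R_B), or steady (R_S).

Scoring is a two-stage prediction of metabolic adjustment. Stage 1
finds the feasible steady-state flux closest to the source state —
minimum total |v − v_source| with the knocked-out reaction fixed at
zero; a linear program. Stage 2 asks, among the minimum-adjustment
states, for the largest number of desired changes realized: an R_F
reaction counts when its absolute flux rises by at least ε over the
source magnitude, an R_B reaction when it falls to
max(|source| − ε, 0). The score is
`achieved / (1 + mean steady deviation)`.

The minimal-adjustment stage is what makes the score discriminating. A
pure "can the desired changes be achieved" objective is uninformative
here: in a linear feasible region every voluntary change is available to
every knockout (and to the wildtype), so all candidates tie. Anchoring
the post-knockout state to the source means an unrelated knockout simply
stays near the source and achieves nothing, while the knockout whose
*forced* rerouting matches the desired direction scores highly — the
wildtype baseline achieves exactly zero. Knockouts that share identical
flux consequences (e.g. consecutive reactions in an unbranched segment)
tie by construction and are ordered by steady deviation, then id; this
is a real degeneracy of the prediction, not an artifact.

Knockouts are enumerated at reaction granularity by default; a
gene-level mode silences all reactions whose GPR evaluates false without
the gene.

## The synthetic benchmark generator

`generate_toy_model()` builds linear pathways — uptake exchange,
labeled interior chain, secretion exchange — plus one cross-link between
each adjacent pathway pair. Cross-links leave a pathway late
(penultimate metabolite) and enter the next one early; this fixed
geometry gives every knockout implant a rerouting escape while keeping
the set of flux-equivalent knockouts (the tie group) small. All
generated models are verified flux-consistent by unlocked variability
analysis. Expression is simulated on a log2-like scale, baseline 8,
noise SD 1 — arbitrary but recorded; only relative shifts matter to the
discretization.

Two-condition datasets default to 50 samples per arm, a desk-scale
stand-in for cohort-sized expression studies. Implanted condition pairs
are *balanced* — one pathway switched on in control and off in disease,
a second switched the other way, ±3 SD — because the discretization
thresholds are computed within each sample across genes: a one-sided
implant would shift every sample's mean and SD and turn unshifted decoy
pathways into spurious calls. The balanced design keeps the mixture
comparable between conditions; the implanted pathways are non-adjacent
so no cross-link couples them.

Knockout benchmark pairs (`implant_knockout_pair()`, 10 samples per
arm) encode reaction activity as on/off expression at baseline ± 8.
The offset is large because the active/inactive mixture is heavily
imbalanced (most reactions carry flux): the across-gene mean tracks the
active genes, and the margin by which an active gene clears the
mean + 0.3·SD threshold grows only as a small fraction of the offset.
±8 gives the 2/3 consensus a comfortable per-gene success rate, and a
pathway's chain is locked by a single cued member.

What the generator does **not** emulate: probe-level noise, batch
effects, correlated genes, realistic pathway topology or
compartmentalization. Passing the implant-recovery benchmarks shows the
inference machinery is sound end to end, not that effect sizes on real
microarray data are detectable.

## Numerical choices and degenerate inputs

- Solver tolerances: pivot 1e−9, feasibility 1e−7, integrality 1e−6;
  mass balance is checked to 1e−6 in the tests.
- Fluxes below 1e−9 are reported as exact zeros; FVA endpoints likewise.
- A constant expression vector (SD = 0) discretizes to all-moderate
  with a warning. Genes absent from the model are dropped before
  discretization; genes missing from a state vector evaluate as
  moderate in GPRs.
- Alternate MILP optima are acknowledged: downstream stages depend only
  on the objective value and the locked flux intervals, which are
  well-defined over the whole optimal set, never on one particular
  optimum.
- Deterministic ordering everywhere (declaration order for reactions,
  index order in the solver, lexicographic tie-breaks in rankings);
  rerunning any stage with the same inputs and seed is byte-identical.

## Problem sizes

The shipped checks run on models of roughly 15–45 reactions: oracle
comparisons use 2-pathway models (≈13 reactions) where exhaustive
enumeration is cheap; biomarker recovery uses 4-pathway models (≈27
reactions, 20 seeds); knockout recovery uses 6-pathway models (≈41
reactions, 20 seeds, within the 30–60 range the benchmark targets).
These sizes exercise every code path while keeping the full suite in
tens of seconds.

## Known limitations

- The bundled simplex is dense and unsuited to genome-scale models;
  the file formats (canonical JSON, an SBML Level 3 subset) are
  format-compatible with larger reconstructions, but solving them needs
  an industrial solver backend.
- The transformation score ranks; its magnitude has no calibrated
  biological unit.
- Thermodynamically infeasible loops are not excluded; none arise in
  the generated topologies.
- The SBML reader covers ids, stoichiometry, bounds (fbc attributes or
  reversibility), notes-field GPR/pathway only.
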