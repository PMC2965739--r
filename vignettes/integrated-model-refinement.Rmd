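---
title: "Reconciling integrated metabolic and regulatory models with growth phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling integrated metabolic and regulatory models with growth phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneforce)
```

## The problem

Constraint-based metabolic models predict growth phenotypes of knockout
mutants across media by flux balance analysis (FBA). Layering a Boolean
transcriptional-regulatory network on top (SR-FBA) usually improves those
predictions, but the regulatory layer is reconstructed from incomplete
evidence: some rules wrongly silence genes that the cell in fact expresses.
The symptom is a characteristic disagreement pattern — the experiment and
the unregulated metabolic model both say a mutant grows in a condition,
while the integrated model says it cannot (a `+/+/-` case).

This package finds the **minimal set of regulatory-rule violations** that
lets the integrated model grow again. Each violation forces one unexpressed
gene into the expressed state; minimality keeps the reconstruction as
intact as possible, so the violated rules are strong, testable candidates
for correction. The same machinery, run on `-/+/-` cases (no experimental
growth, metabolic capability present, regulation correctly blocking it),
proposes genes whose over-expression would create a new growth phenotype.

## Models and constraints

An `integrated_model` couples:

* a **metabolic network**: stoichiometric matrix $S$, flux bounds
  $l \le v \le u$ (mmol/gDW/hr), a biomass reaction whose flux $\mu$ is the
  growth readout, and a Boolean gene-protein-reaction (GPR) association per
  enzymatic reaction (OR = isozymes, AND = complex subunits);
* a **regulatory network**: one Boolean rule per gene and per transcription
  factor, over TF activities, environmental predicates (`met(e)>0`: the
  metabolite is available in the medium), and flux predicates (`RXN>0`,
  `Growth>0`: a reaction carries flux in the same steady state).

**FBA** maximizes $\mu$ subject to $Sv = 0$ and the bounds, with reactions
closed when their GPR evaluates false under the knockout set. **SR-FBA**
solves one mixed-integer program in which, additionally, every reaction can
carry flux only if its GPR is true under the gene-expression indicators
$y_g \in \{0,1\}$, and every rule holds as a fixed-point constraint
(the indicator of each target equals its rule's value).

### Rule-violation minimization

For a `+/+/-` case the package introduces a surrogate expression indicator
$y'_g$ per regulated metabolic gene and re-gates the reactions by $y'$
instead of $y$, subject to

$$y'_g \ge y_g, \qquad y'_g = 0 \text{ for deleted genes}, \qquad
\mu \ge \mu_{\text{threshold}},$$

minimizing $\sum_g (y'_g - y_g)$ — the number of genes forced on in
violation of their rules. The growth threshold is a fraction (default
**0.1**) of the pure-FBA optimum for the same mutant and condition; an
objective of 0 means the integrated model already reaches the threshold.
`threshold_sweep()` reproduces the standard sensitivity check: on all
shipped and generated fixtures the violation set is identical for fractions
0.05–0.5, because integrated-model growth predictions tend to sit either
far above or far below the metabolic optimum. A per-gene weight hook is
exposed (`weights =`), with uniform weights as the default.

Alternative optima matter scientifically (two or three isozymes can each
rescue the same reaction). `enumerate_alternates()` re-solves with an
integer cut over the incumbent's violation difference variables
($\sum_{g \in V}(y'_g - y_g) \le |V| - 1$), collecting every set of minimum
cardinality. The cut deliberately ranges only over the incumbent's violated
genes; cutting the full $y'$ vector would wrongly exclude solutions that
differ only in free genes. The first MILP solution is solver-dependent;
deterministic reporting comes from enumeration plus lexicographic ordering
of the violation sets.

## MILP encoding choices

* **Boolean linearization.** Rules and GPRs are compiled by one auxiliary
  binary per internal node: NOT as complement ($z = 1 - x$), AND/OR as the
  standard min/max inequalities. The encoding is exact: for every 0/1 leaf
  assignment the only feasible output value equals direct evaluation, and
  the test suite verifies this by brute force over random expression trees.
* **Reaction gating.** Every gated reaction is split into non-negative
  forward/backward components, each bounded by $M z_r$ with $M = 1000$
  (dominating all default bounds of ±1000 mmol/gDW/hr). Splitting gives
  sound indicator semantics for reversible reactions and for `>0` flux
  predicates.
* **Strict inequalities.** Flux predicates implement `v > τ` as
  $v \ge τ + \varepsilon_{\text{flux}}$ with
  $\varepsilon_{\text{flux}} = 10^{-4}$ (configurable via
  `solver_settings()`), since strict inequalities are not MILP-expressible;
  `b = 0` forces $v \le τ$. `Growth>0` references the biomass flux variable
  itself — self-referential but linear.
* **Environmental predicates** are decided by medium composition (the
  metabolite is available for uptake), not by simulated exchange flux; this
  matches condition-driven rule inputs and keeps the predicate layer fixed
  per condition. Flux-dependent logic belongs in flux predicates.
* **Boolean cycles.** TFs may regulate TFs; any consistent fixed point is
  admissible and the optimizer may choose among them — a steady-state, not
  trajectory, semantics. A rule system with no fixed point (e.g. a gene
  repressing itself) yields a no-growth call rather than an error.
* **Knockouts** are fixed unexpressed in every Boolean layer, their rules
  are skipped (deletion removes the gene, not just its product), and they
  are excluded from the violation candidates — the algorithm must never
  "rescue" a knockout by expressing a deleted gene.
* **Growth calls** use $\varepsilon_{\text{growth}} = 10^{-6}$: optima above
  it are `+`. This separates simplex noise from genuine growth.

## The optimizer

All programs run through a small bounded-variable LP/MILP layer
(`milp_new()` and friends): a dense two-phase tableau simplex with Bland's
anti-cycling rule, plus depth-first branch-and-bound on the most fractional
binary with best-bound pruning. The layer is pinned by its own tests
against hand-solved programs and exhaustive binary enumeration. Problems in
this package's scope are small (tens to a few hundred variables), where a
dense simplex is entirely adequate and keeps the package free of external
solver dependencies; genome-scale work would swap in an industrial MILP
solver behind the same interface.

## The rule language

Operator precedence is NOT > AND > OR, with left association within a
level; `ON`/`OFF` are constants; quoted names (`"CRP noMAN"`) are atomic
symbols; `met(e)` with or without an explicit `>0` is an environmental
predicate (thresholds are stored, not hard-coded, though published rules
only use 0). All published rules are fully parenthesized, so the precedence
choice only affects user-authored text — the parser warns when an
unparenthesized AND appears under OR, where the choice actually decides the
reading. Symbol matching is case-sensitive; spelling variants (`metR` vs
`MetR`) are resolved by an alias table in the model files, not by the
parser.

## Conditions

`condition()` translates a medium into exchange bounds: uptake $u_m$
becomes a lower bound of $-u_m$ on the metabolite's exchange reaction, and
absent extracellular metabolites are closed to uptake. The standard screen
constants are built into the helpers: `carbon_source_condition()` adds
ammonia at 10 mmol/gDW/hr, `nitrogen_source_condition()` adds pyruvate at
11.3 mmol/gDW/hr as the carbon source, and aerobic conditions bound oxygen
uptake at 10 mmol/gDW/hr. Per-condition essential-nutrient sets beyond
these are supplied by the caller; the shipped fixtures define their own
minimal media.

## Phenotype comparison and reporting

Raw Biolog-style readings become binary calls by negative-control
subtraction and a cutoff of 0.1 OD units (the published bimodal separation
point; `call_growth_from_od()` exposes it as a parameter, and corrected
values below −0.1 are flagged as suspect wells). Plate-reader absorbances
convert to 1-cm-pathlength OD600 by the calibration line
$\mathrm{OD}_{600} = 2.566\,\mathrm{OD}_{\mathrm{Tecan}} + 0.0028$.

`run_grid()` evaluates every (mutant, condition) cell three ways —
experimental, FBA, SR-FBA — classifies the triple (`classify_case()` is a
pure function over all eight patterns), runs the violation minimization on
every rule-correction case, and aggregates violated-gene frequencies by
mutant and by condition. The report ranks candidates; no numeric frequency
threshold is imposed, because accepting a correction is a judgment that
needs literature or new experiments. Rescue-case analysis is off by default
(its violations are deliberate falsifications of correct rules) and is
enabled by a flag that labels outputs as over-expression candidates. A
condition blacklist (empty by default) supports excluding media known to
produce false-positive plate calls. Missing experimental cells are excluded
from accuracy denominators; per-cell solver failures are logged and skipped
without aborting the grid. `audit_correction()` quantifies the side effects
of an applied correction: cells fixed versus new false positives created
(`-/+/-` turning `-/+/+`).

## Rule transfer across organisms

`transfer_rules()` builds a chimeric regulatory layer through a two-column
ortholog map: rules whose target gene lacks a metabolic ortholog are
dropped; rules referencing *any* TF (or gene symbol) without an ortholog
are dropped whole, leaving the target unregulated — all-or-nothing, never
partially rewritten logic. Environmental and flux predicates transfer
unchanged but must resolve against the target network; unresolvable
predicates also drop the rule, reported in a separate category. The report
partitions the source rules (transferred + dropped per reason = total), and
the chimera re-validates as a full integrated model.

## The synthetic generator

`generate_planted_model()` emulates the failure modes the method is built
for: a linear biosynthetic pathway of essential gene-gated steps (all
stoichiometric coefficients 1, so every optimum is hand-checkable), an
alternative substrate with its own transporter rule, non-essential gated
side branches, a TF layer driven by medium-composition predicates, and
`k_planted` rules that wrongly repress essential genes under the designated
condition. By construction the unregulated model grows, the integrated
model does not, and the planted set is the unique minimum violation set
(isozyme duplication at `isozyme_rate` creates controlled alternative
optima instead). Generation is bit-reproducible per seed, with randomness
confined to structural choices.

What the generator does **not** emulate: genome-scale topology (thousands
of reactions, long GPRs, highly interconnected cofactor pools), realistic
biomass compositions, noisy or batch-structured plate data, and regulatory
cascades deeper than one TF layer. Passing the planted-recovery and
oracle-equivalence suites therefore demonstrates correctness of the
encodings and algorithms at desk scale, not predictive accuracy on real
genome-scale reconstructions, which additionally depends on the quality of
the input models.

## Validation strategy and problem sizes

The test suite pins every optimizer claim to an independent oracle:

* SR-FBA optima equal exhaustive enumeration of rule-consistent Boolean
  states with one LP per state, on 50 seeded models (4-step pathways plus
  branches and isozymes; at most 12 regulated genes).
* Violation objectives and the *complete family* of minimum violation sets
  equal exhaustive subset search on the same models.
* Planted rule sets are recovered exactly on 100 seeds with
  `k_planted` ∈ {1, 2, 3} and no isozymes.
* Boolean linearization is verified against direct evaluation over random
  expression trees and leaf assignments.

These sizes were chosen so the whole suite runs in about two minutes on a
single CPU while still exercising every encoding path (isozymes, branches,
alternative substrates, free genes, TF layers).

## Known limitations

Expression is binary — graded expression, essential-gene regulation, and
kinetic effects are out of scope, as are dynamic (time-stepped) regulatory
FBA, MOMA-style knockout re-optimization, and thermodynamic constraints.
Corrections are found one case at a time; reconciling many cases
simultaneously is a different (harder) optimization that this package does
not attempt. SBML support is read-only (Level 3 with the fbc package,
covering species, stoichiometry, bounds, gene associations, and the active
objective); the TSV dialect is the round-trip format.
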