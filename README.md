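# geneforce

Phenotype-driven refinement of integrated metabolic and Boolean
transcriptional-regulatory models.

## The problem

Flux balance analysis (FBA) predicts whether a knockout mutant can grow in
a medium from a stoichiometric model alone; steady-state regulatory FBA
(SR-FBA) adds a Boolean regulatory network and usually predicts better.
But reconstructed regulatory rules are imperfect, and a wrong rule shows up
as a tell-tale pattern: experiment and the unregulated metabolic model both
say *growth*, while the integrated model says *no growth* (`+/+/-`).
Hunting the culprit rule by hand in a network of hundreds of rules is slow.

This package automates that hunt. It is for systems biologists who maintain
constraint-based reconstructions and want to reconcile them with
growth-phenotype screens (Biolog-style plates, knockout collections).

## The algorithm

Each regulated metabolic gene carries a rule-determined expression
indicator $y_g \in \{0,1\}$ and a *surrogate* indicator $y'_g$. Reactions
are gated by $y'$ instead of $y$, with

$$y'_g \ge y_g,\qquad y'_g = 0 \ \text{for deleted genes},\qquad
\mu \ \ge\ \mu_{\text{threshold}} = f \cdot \mu_{\text{FBA}},$$

and the MILP minimizes the number of rule violations
$\sum_g (y'_g - y_g)$ subject to the full SR-FBA constraint system
($Sv = 0$, bounds, GPR gating, Boolean fixed-point consistency of every
rule). The threshold fraction $f$ defaults to 0.1, and results are
insensitive to it between 0.05 and 0.5. Alternative optimal violation sets
(isozyme ambiguity) are enumerated with integer cuts. Violated genes in
`+/+/-` cases are rule-correction candidates; in `-/+/-` cases they are
over-expression candidates that could create a new growth phenotype.

Everything runs on an in-package LP/MILP layer (two-phase dense simplex
with Bland's rule plus branch-and-bound), so no external solver is needed
at the desk scales the package targets.

## Worked example

The packaged two-gene, two-TF example network: uptake of metabolite A,
an essential path A → B → C → biomass gated by gene G1, a branch A → D
gated by G2. TF1 activates G1 but is inactivated by the presence of A;
constitutively active TF2 represses G2.

```r
library(geneforce)
m    <- toy_model()
cond <- toy_condition()          # A available at 10 mmol/gDW/hr

maximize_growth(m, cond)
#> <flux_solution: mu = 10 (+), status = optimal>

solve_srfba(m, cond)
#> <srfba_solution: mu = 0 (-), status = optimal>

gf <- minimal_violations(m, cond, threshold_fraction = 0.1)
gf
#> <geneforce_solution: 1 violation(s) {G1}; mu = 1 >= threshold 1 (optimal)>
tidy(gf)
#> # A tibble: 2 x 4
#>   gene      y y_prime violated
#>   <chr> <dbl>   <dbl> <lgl>
#> 1 G1        0       1 TRUE
#> 2 G2        0       0 FALSE
```

Reading: the metabolic model grows at $\mu = 10$, the integrated model at
$\mu = 0$ (G1 is repressed and B → C is essential), and exactly **one**
rule violation — forcing G1 on — restores growth above the 10% threshold
($\mu = 1$). G2's surrogate stays 0: overriding its (correct) repression
would be an unnecessary violation. The violation count is flat across
threshold fractions:

```r
threshold_sweep(m, cond)
#> # A tibble: 4 x 4
#>   fraction objective    mu violations
#>      <dbl>     <int> <dbl> <list>
#> 1     0.05         1   0.5 <chr [1]>
#> 2     0.1          1   1   <chr [1]>
#> 3     0.25         1   2.5 <chr [1]>
#> 4     0.5          1   5   <chr [1]>
```

Beyond single cases: `run_grid()` sweeps a mutant × condition phenotype
matrix, classifies every cell (`rule_correction`, `rescue_non_growth`,
`correct`, or the literal pattern), aggregates violated-gene frequencies
into a ranked candidate report, and `audit_correction()` counts the cells a
rule edit fixes versus the new false positives it creates.
`transfer_rules()` ports a regulatory network to a related organism through
an ortholog map; `generate_planted_model()` builds seeded synthetic models
with known-bad rules for validation. A thin command-line front-end lives in
`inst/cli/geneforce.R` (subcommands `solve`, `grid`, `transfer`,
`fixture`).

Model input is either SBML Level 3 (fbc) or a hand-authorable TSV dialect
(`reactions.tsv` / `metabolites.tsv` / `rules.tsv`); see
`inst/extdata/toy/` for a complete example, and
`vignettes/integrated-model-refinement.Rmd` for the methods account.

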