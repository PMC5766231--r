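---
title: "Inferring context-specific metabolic reaction activity from transcriptomics"
author: "fluxstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring context-specific metabolic reaction activity from transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxstate)
```

## The problem and the model

A genome-scale metabolic reconstruction describes which biochemical
reactions a cell *could* run; which of them are actually used differs
between cell states. `fluxstate` infers a context-specific activity state
(ACTIVE / INACTIVE / UNDETERMINED) for every reaction of a constraint-based
model from gene expression data, in the iMAT tradition: expression does not
fix fluxes quantitatively, it biases a steady-state flux distribution toward
using reactions whose genes are highly expressed and toward silencing those
whose genes are lowly expressed.

The flux vector $v$ lives in the steady-state polytope

$$ \{ v : S v = 0,\; v_{\min} \le v \le v_{\max} \}, $$

where $S$ is the stoichiometric matrix. The method works on the
irreversible form of the model (every reversible reaction split into a
forward and a backward copy, suffixes `_fwd` / `_bwd`), so all fluxes are
non-negative. The MILP maximizes

$$ \sum_{i \in R_H} (y^+_i + y^-_i) \; + \; \sum_{i \in R_L} y^+_i $$

where $R_H$ and $R_L$ are the highly / lowly expressed reaction sets. For
$i \in R_H$, $y^+_i = 1$ forces $v_i \ge \varepsilon$ (a significant
positive flux) and $y^-_i = 1$ would force $v_i \le -\varepsilon$; on an
irreversible model the negative branch can never fire, and the solver
carries it only so that the encoding matches the published formulation. For
$i \in R_L$, $y^+_i = 1$ forces $v_i = 0$: the objective *rewards shutting
off* lowly expressed reactions. All indicator constraints are linearized
with each reaction's own bounds as big-M constants, never a global one, and
$y^+_i + y^-_i \le 1$ tightens the relaxation. The published description
writes the second $R_H$ inequality with $v_{\min,i}+\varepsilon$, which on
an irreversible model would let $y^-$ fire freely and inflate the
objective, contradicting the accompanying prose ("cannot occur"); the
package encodes the standard indicator $y^-_i = 1 \Rightarrow v_i \le
-\varepsilon$ instead, which is what the prose describes.

## From expression to $R_H$ and $R_L$

Gene-protein-reaction (GPR) rules are and/or sentences: AND joins subunits
of a complex, OR joins isoenzymes. Expression is mapped to reactions by
substituting AND with minimum and OR with maximum — a complex is only as
expressed as its scarcest subunit, isoenzymes contribute their best member.
Replicates are averaged per gene *before* GPR evaluation (arithmetic mean;
the data this emulates are RMA-scale microarray intensities, where the mean
is the least surprising choice). A gene without measurement is ignored
inside its node, and a rule with no measured gene yields "no data", which
classifies as moderate.

Reactions are then partitioned by two percentile cutoffs of the
reaction-level expression values (type-7 linear interpolation, strict
inequalities on both sides, per the "above which"/"below which" reading):
above the upper percentile is $R_H$, below the lower is $R_L$, everything
else — including "no data" — is moderate. The default operating point is
(33, 66). `select_thresholds()` picks a symmetric pair $(q, 100-q)$ from a
candidate grid (default 25, 33, 40) by maximizing the number of reactions
highly expressed in one condition and lowly expressed in the other, with
ties broken toward 33; note that the symmetric partner of 33 is 67, while
the fixed default operating point keeps the conventional (33, 66).
Whether the discordance should be counted over reactions or genes is not
settled by the published description; the package counts reactions, since
the classification is reaction-level.

## Model reduction

Blocked reactions — those that cannot carry flux in any steady state — are
found by flux variability analysis (two LPs per reaction) and removed,
together with metabolites left orphaned. Blockedness uses a tolerance of
1e-9 on the LP optima, the solver noise floor. Exchange reactions of
experimentally measured metabolites are first forced active (both split
directions bounded to [0.001, 1000]) so measurement targets can never be
reduced away; the published bounds notation ("-1000/-0.001 for the backward
reactions") refers to the pre-splitting orientation — after splitting, each
direction carries magnitude at least 0.001. The forcing is reverted before
inference. Classified reactions that are removed as blocked are dropped
from the classification with a warning. Removing blocked reactions cannot
change the optimal objective for a classification restricted to the
surviving reactions, and the test suite checks exactly that invariance.

## Activity calls, consensus, and differential activity

A single MILP optimum is not unique, so per-reaction claims are made by
sensitivity analysis: solve once with the reaction forced active
($v \ge \varepsilon$) and once forced inactive ($v = 0$), and compare the
two optima. Strictly better when forced active means ACTIVE, strictly
better when forced inactive means INACTIVE, a tie means UNDETERMINED. The
objective is an integer count, so ties are exact — no floating tolerance is
involved. An infeasible forcing counts as $-\infty$, which makes blocked
reactions INACTIVE by convention. `classify_all()` exploits the
unconstrained optimum as a one-sided witness (a reaction already carrying
$\varepsilon$ flux there attains the forced-active optimum), which halves
the solve count without changing any call; the equivalence with the
two-solve definition is tested.

Robustness to the threshold choice is assessed by repeating the analysis at
(25, 75), (33, 66) and (40, 60) — normalized to lower < upper — and keeping
only states that agree across all pairs; disagreement yields UNDETERMINED.
Differential activity between two conditions keeps reactions ACTIVE in one
and INACTIVE in the other, aggregated per subsystem. The per-pathway
significance shading seen in published figures of this kind has no printed
procedure; `pathway_enrichment()` offers a hypergeometric enrichment as
this package's own, clearly optional, choice.

Predicted exchange activity is validated qualitatively: each measured
(metabolite, direction) pair maps to an exchange-direction reaction
(secretion consumes its metabolite, uptake produces it — one convention,
used everywhere), a 2x2 predicted-vs-measured table is built per
metabolite-direction entry, UNDETERMINED predictions are excluded and
counted, and the true positive rate TP/(TP+FN) (measured-active as positive
class) plus a two-sided Fisher exact p-value summarize agreement.

## The solver

No MILP solver is a hard dependency: the package ships a dense
bounded-variable two-phase primal simplex (C++, Bland's rule, hence finite
termination; feasibility tolerance 1e-7 on phase-1 artificials, pivot
threshold 1e-8) and a deterministic depth-first branch-and-bound on the
binary indicators (first-fractional branching, "up" branch first, floored
relaxation bounds — valid because the objective is integral). Determinism
matters: activity calls compare objective *values*, so repeated runs give
identical states by construction. The simplex is validated in the tests
against hand-solved programs and against `boot::simplex`, an independent
implementation; the MILP is validated against a brute-force oracle that
enumerates all activity assignments and checks each by LP feasibility.
Dense tableaus are the right tool at the intended scale (tens to a few
hundred reactions); genome-scale models are accepted by the data
structures, but solving them is outside the intended envelope of the
built-in solver.

## What the synthetic generator does and does not emulate

`generate_study()` builds toy networks of linear chains with optional
terminal branches, each chain fed by one uptake and drained by secretions,
so every reaction lies on a complete uptake-to-secretion path and nothing
is blocked by construction. Ground truth is planted by selecting whole
paths as ACTIVE (a flux witness carrying $\varepsilon$ on every active
reaction with all inactive at zero is verified and stored). Expression is
simulated with single-gene GPRs: ACTIVE genes draw from a high log-normal
component (location $\log 100$, sdlog 0.25), INACTIVE from a low one
(location $\log 1$), two conditions with three replicates each, emulating a
two-subpopulation design. Label noise swaps a gene's component with
probability $p$, using one uniform draw per gene so flip sets are nested
across noise levels, and replicate jitter is additive Gaussian truncated at
zero.

Two honest caveats. First, with a two-class planting, percentile cutoffs
cannot reproduce the planted labels as a three-way partition (both cutoffs
cannot fall in the same rank gap); what holds, and what is tested, is that
at zero noise nothing is *mis*classified — every $R_H$ member is planted
ACTIVE and every $R_L$ member planted INACTIVE — and that the MILP
sensitivity analysis then recovers all planted states through flux
coupling. Full recovery requires *identifiable* fixtures: linear chains,
whole-chain planting, and an active fraction near 0.5 so every active
chain keeps at least one $R_H$ member and every inactive chain at least
one $R_L$ member at all three threshold pairs. The recovery study uses 2
chains of length 5 (14 reactions), 20 seeds, noise in {0, 0.1, 0.2, 0.3},
replicate jitter 0.1 — sizes chosen to exercise every pipeline stage while
keeping the whole suite quick on one CPU. Second, the generator does not
attempt genome-scale structure, probe-level microarray artifacts, complex
GPR logic (tested separately with its own unit fixtures), or quantitative
flux measurements — passing these tests shows the inference machinery is
correct, not that any particular biological dataset will be predicted well.

## Worked example

The packaged toy network (also in `inst/extdata/fig5_toy.json`) has nine
metabolites Met_A…Met_I, seven enzyme-catalyzed reactions and four
exchanges. Its exact stoichiometry is this package's reconstruction — the
original toy network exists only as a figure — constrained to reproduce the
stated outcome:

```{r fig5}
fx <- make_fig5_fixture()
fit <- imat(fx$model, fx$expression)
fit
activity_states(fit)[c("EX_Met_G", "EX_Met_H", "EX_Met_I")]
```

The branch to Met_I runs through highly expressed enzymes and is predicted
active; the branches to Met_G and Met_H pass through lowly expressed
enzymes and are shut off, so only Met_I is secreted.

```{r study}
st <- generate_study(disjointness = 1, seed = 1)
fit_m <- imat(st$model, st$profiles$M)
fit_s <- imat(st$model, st$profiles$S)
compare_conditions(fit_m, fit_s)
```

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 1 (flux units) | minimum flux for "active" |
| `thresholds` | (33, 66) | percentile operating point |
| consensus sets | (25,75), (33,66), (40,60) | robustness grid |
| forced exchange bounds | [0.001, 1000] | per split direction, during reduction only |
| bound "infinity" | 1000 | default finite bound |
| blockedness tol | 1e-9 | on LP optima |
| MILP integrality tol | 1e-6 | binaries rounded, objective an exact integer |
| replicates | 3 per condition | the emulated study design |

## Known limitations

The built-in solver targets toy-to-small models; genome-scale MILPs need an
industrial solver behind the same problem interface. Alternate optima are
handled by sensitivity analysis, not enumerated. The validation is strictly
qualitative (consumed/produced), by design. Reversible-model activity
calls are made on the split form; a net-zero flux through a fwd/bwd pair is
reported per direction, not re-merged.
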