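---
title: "Classifying phenotypic essential metabolites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying phenotypic essential metabolites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemnet)
```

## The model

`pemnet` works on a stoichiometric metabolic network: a directed bipartite
graph of reactions and metabolites with positive stoichiometric labels on
its edges, kept internally in *canonical irreversible form*. A biologically
reversible reaction is represented as two irreversible reactions with
swapped reactant/product sets; the pairing (`reverse_of`) is not an
annotation but is *detected structurally* — a reaction belongs to the
reversible set exactly when some other reaction mirrors it with equal
coefficients. This makes the representation self-healing across SBML round
trips: the writer emits plain irreversible reactions and the reader re-links
the mirrors.

Three activation semantics are layered on this object, all relative to a
seed set `S` (nutrients; by construction all *boundary seeds*, the products
of reactant-free reactions, are included) and a targeted reaction `r_T`:

1. **Topological activation** (scope / network expansion). The scope
   `Σ(G, S)` is the least fixpoint in which a reaction fires once *all* its
   reactants are reachable. This is the strict semantics: a self-loop
   (metabolite both consumed and produced by the same reaction) does not
   bootstrap itself, and cycles must be initiated from outside.
2. **Stoichiometric activation**. A reaction is active when some flux
   vector satisfies steady-state mass balance `N v = 0` over the internal
   metabolites with `0 ≤ v ≤ ub` and gives it strictly positive flux.
   Because every flux is non-negative in the split representation,
   reversibility is expressed by which member of a pair carries flux.
3. **Optimal efficiency**. With the target flux maximised, a reaction is
   *essential* when forcing its flux (and its mirror's) to zero strictly
   lowers the optimum. Equivalently — and tested as an invariant — it has a
   strictly positive minimum in a flux variability analysis constrained to
   the optimum.

The three PEM classes follow by asking whether pruning a metabolite (removing
every reaction that consumes it, mirrors included) destroys, respectively,
topological activation of `r_T`, stoichiometric activation of `r_T`, or —
for single reactions rather than whole consuming sets — the optimal target
flux. The first two classes exclude seeds and target reactants from
candidacy; the optimal-efficiency class deliberately does not, so that no
class implies another. Reported *roles* resolve the resulting overlaps with
the fixed precedence seed > target > PEM > other.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `eps` (activation) | `1e-6` flux units | a flux above this counts as "positive"; LP solutions carry ~1e-9 arithmetic noise, so anything between 1e-9 and the smallest meaningful bound works |
| `delta`, `rho` (essentiality) | `1e-6` absolute, `1e-6` relative | a knockout must lower the optimum by more than *both* thresholds to count |
| `default_ub` | 1000 (SBML import), 10 (fixtures) | cap used when a file states no bound; 1000 is the conventional genome-scale cap |
| `seed_mode` | `"extend"` | user seed lists extend the boundary seeds; `"replace"` substitutes them entirely |

All flux quantities are in the units of the model's bounds (conventionally
mmol/gDW/h).

## Scope semantics at the boundary

Reactant-free inflow reactions get special treatment in the closure: they
are fired only through the seed set, i.e. their products enter the scope
only when declared seeds. Under the standing assumption that all boundary
seeds are seeds the two conventions coincide, so nothing changes for a full
analysis. The payoff is that scope queries on *seed subsets* are meaningful:
`compute_scope(net, "S1")` emulates growth on `S1` alone, with the other
inflows shut — exactly the graph-side analogue of setting a nutrient's
upper bound to zero on the flux side. The standalone activation test
(`topologically_activated`) keeps the literal definition, under which a
reactant-free reaction is trivially activated.

On the flux side, two boundary dialects coexist and are both honoured:
metabolites produced by reactant-free reactions keep ordinary mass-balance
rows (the inflow reaction supplies flux), whereas species flagged
`boundaryCondition="true"` in SBML are dropped from the balance rows
entirely.

## Numerical choices

* **LP solver.** The flux problems are solved by a bounded-variable primal
  simplex written for this package (`R/lp.R`): two phases with artificial
  variables and Bland's rule throughout. Flux polytopes at the zero vertex
  are extremely degenerate, and Bland's rule guarantees termination there at
  the price of a few extra pivots — irrelevant at these problem sizes. The
  basis is refactorised at every pivot; with tens of variables this is
  cheaper to trust than to optimise. Correctness is cross-checked in the
  test suite against an exhaustive basic-solution enumeration on small
  networks and against an independent SBML-consuming FBA implementation.
* **Determinism.** Variables are ordered lexicographically (C collation,
  radix sort, independent of locale); entering/leaving variables are chosen
  by smallest index. Degenerate alternative optima therefore never affect a
  PEM decision: decisions depend only on optimal values.
* **Knockouts and fixed fluxes.** A knockout sets the upper bound of both
  pair members to zero; a fixed flux adds an equality row. FVA "at the
  optimum" fixes the target at the value just computed by the same
  arithmetic, so the constrained problem is feasible by construction.
* **Coefficient comparisons** (mirror detection, Rev-pair validation) use a
  tolerance of `1e-9` on doubles. SBML serialises stoichiometries as
  doubles, so an exact-rational representation would add machinery without
  adding equality.
* **Degenerate inputs.** An unreachable target raises an error naming the
  missing reactants (enumeration functions) or degrades to a partial
  classification with warnings (`classify_pems`): sustainability flags
  become `NA` when the target is topologically dead, and the flux-based
  sets are empty when it carries no flux.

## Enumeration strategy

Sustainability-PEMs are found by per-candidate recomputation: for every
candidate (a scope member consumed by at least one reaction, neither seed
nor target reactant), the scope of the pruned network is recomputed from
scratch with a worklist keyed by unmet-reactant counters — linear in the
edge set per closure. Producibility costs one LP per candidate, optimal
efficiency one LP per reaction. This correctness-first strategy is quadratic
overall but transparent; a single-pass logic-programming formulation exists
and would be the natural optimisation, kept out of scope here because every
decision it makes is already reproduced (and oracle-checked) by the
fixpoint engine. One known discrepancy in the declarative formulation —
its candidate guard excludes only reactants of the target *reaction* rather
than all target reactants — is resolved here in favour of the set-based
definition (candidates exclude all of `rcts(r_T)`).

## What the fixtures emulate

The built-in fixtures are reconstructions of the didactic networks that
motivate each overlap region, constrained to satisfy every stated fact
about them (seed-subset scopes, activated-reaction lists, the reversible
pair, the `2C` cycle stoichiometry and its co-substrate coupling, the
forced `v7 = v8 = 0` consequence of closing one nutrient, bound-asymmetry
effects on essentiality). The `*_motif` fixtures encode the *mechanisms* of
their genome-scale exemplars — alternative pathway pairs, optimal pathway
choice with a co-product outlet, a self-balancing cycle with a
topologically required initiation pathway, a seed-disconnected internal
cycle, dual co-product exports — not the exact sub-networks of any
published model. `random_small` generates deterministic pseudo-random
networks (six metabolites, one inflow, five random reactions with small
integer coefficients and bounds, a terminal sink target) for property
testing; it restores the session RNG state.

What passing on these fixtures shows: the fixpoint, LP and classification
machinery implement the definitions exactly, at sizes where brute force can
confirm every answer. What it does not show: behaviour on genome-scale
reconstructions, which differ in ways no toy network exercises — thousands
of candidates (one LP each), compartmentalised duplicate compounds,
exchange-reaction dialect quirks, and media definitions that dominate the
outcome. Running those requires the published model files and their medium
configurations as inputs; the pipeline consuming them (classification,
Table-style summaries, the cross-network SPO skeleton) is the same code
exercised here at fixture scale. Test and acceptance runs use networks of
6–24 reactions, 20 random draws per property, sizes chosen so the whole
suite stays in the seconds-to-a-minute range.

## Known limitations

* Thermodynamically infeasible loops are *not* excluded (no loop law): a
  mass-balanced internal cycle may self-activate at steady state. This is a
  feature for the producibility/sustainability contrast — it is exactly how
  cycle-initiation pathways become visible — but flux values through such
  loops should not be read quantitatively.
* No parsimonious or loopless FBA, no shadow prices or reduced costs, no
  gene–protein–reaction logic: the unit of perturbation is the reaction,
  and the object of classification is the metabolite.
* Per-candidate LPs make genome-scale runs minutes-to-hours on one core;
  the dense simplex is sized for networks up to a few hundred reactions.
* When explicit flux bounds contradict the SBML `reversible` attribute, the
  bounds win (a reaction with `lower bound ≥ 0` is treated as irreversible
  even if flagged reversible); files stating neither get the attribute's
  default.

## A worked classification

```{r}
fx <- pem_fixture("fig2")
cl <- classify_pems(fx$network)
cl
subset(cl$metabolites, venn_region != "none")
```

The SPO compound is the single precursor of the target reactant; the PO
compound is a co-product whose export the flux balance cannot do without;
under `pem_fixture("fig2_bounds")` the higher-capacity branch point joins
the optimal-efficiency class:

```{r}
clb <- classify_pems(pem_fixture("fig2_bounds")$network)
subset(clb$metabolites, id == "B")
```
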