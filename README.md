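# pemnet — phenotypic essential metabolites in metabolic networks

Constraint-based and graph-based analyses of genome-scale metabolic models
usually treat every internal compound as equivalent: essentiality is studied
for genes and reactions, almost never for the metabolites that wire those
reactions together. `pemnet` classifies the internal compounds of a
stoichiometric metabolic network by their capacity to influence the
activation of a targeted reaction `r_T` (typically the biomass reaction),
for modellers curating reconstructions and for anyone asking *which
compounds are the crossroads of a growth phenotype*.

## The three classes

A network is the directed bipartite graph `G = (R ∪ M, E, s)` with
stoichiometric labels `s`, flux bounds `0 ≤ v_r ≤ ub_r`, seeds
`S ⊆ M` (nutrients, including all *boundary seeds* — products of
reactant-free reactions), and targeted metabolites `rcts(r_T)`. Pruning
`prune(G, m)` removes every reaction consuming `m` (both directions of a
reversible pair). A metabolite `m ∉ S ∪ rcts(r_T)` is a **phenotypic
essential metabolite (PEM)** of class:

* **sustainability** — `r_T` is topologically activated from `S` in `G`
  (all its reactants lie in the scope `Σ(G, S)`, the least fixpoint of
  `M₀ = S`, `M_{i+1} = M_i ∪ prds({r : rcts(r) ⊆ M_i})`) but not in
  `prune(G, m)`;
* **producibility** — `r_T` is stoichiometrically activated in `G`
  (some flux vector with `N v = 0`, `0 ≤ v ≤ ub` gives `v_{r_T} > 0`)
  but not in `prune(G, m)`;
* **optimal efficiency** — `m ∈ rcts(r₀)` for a reaction `r₀` whose single
  knockout lowers the maximum `max v_{r_T}` (no seed/target exclusion here:
  the class is deliberately single-reaction based, so none of the three
  classes implies another).

The three sets overlap in seven regions (S-only, P-only, O-only, SP, SO, PO,
SPO), and each region has a distinct mechanistic reading — cycle-initiation
pathways, alternative routes, co-product accumulation — illustrated by the
built-in fixtures (`pem_fixture("fig4")`, `"fig5"`, `"fig6_motif"`,
`"fig7_motif"`, `"fig8_motif"`).

## Worked example

```r
library(pemnet)
fx <- pem_fixture("fig2")          # two routes to E; co-product G exported by r9
cl <- classify_pems(fx$network)
print(cl)
#> PEM classification (target: r_T )
#>   maximal target flux: 10
#>   sustainability-PEMs: 1 | producibility-PEMs: 2 | optimal-efficiency-PEMs: 3
#>   regions:
#>
#> O-only     PO    SPO
#>      1      1      1
subset(cl$metabolites, venn_region != "none")
#>   id connectivity sustainability producibility optimal_efficiency venn_region   role
#> 2  C            2          FALSE         FALSE               TRUE      O-only target
#> 3  E            3           TRUE          TRUE               TRUE         SPO    PEM
#> 4  G            2          FALSE          TRUE               TRUE          PO    PEM
```

`E` is a PEM under all three semantics: it is the only precursor of the
target reactant `C`, so pruning it disconnects `C` from the seeds
(sustainability), abolishes target flux (producibility), and its consuming
reaction `r6` is essential at the optimum (optimal efficiency). `G` is the
co-product of `r6`: removing its export `r9` makes `G` accumulate, which
kills flux at steady state (producibility, optimal efficiency) yet leaves
the graph-based activation of `C` untouched — so `G` is not a
sustainability-PEM. `C` appears as O-only because the target reaction's own
knockout is trivially essential; its role column keeps it reported as a
target compound.

From a shell, the same analysis runs end to end on any SBML model:

```sh
Rscript inst/scripts/pemnet.R run --sbml model.xml --target BIOMASS --out results/
Rscript inst/scripts/pemnet.R fixtures-export --name fig1 --out fig1.xml
```

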