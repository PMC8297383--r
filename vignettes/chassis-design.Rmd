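---
title: "Model-guided design of growth-coupled chassis strains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided design of growth-coupled chassis strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chassiscraft)
```

## The design problem

A chassis strain is a host pre-optimised — here purely by gene deletions —
to channel carbon flux toward precursors shared by several target products,
before any product-specific engineering. The risk any production strain
faces is evolutionary reversion: if secretion costs fitness, adaptive
mutations erode it. Growth-coupled designs remove that failure mode by
construction: the knockouts reshape the metabolic network so that *every*
growth-optimal flux state secretes the product, making natural selection an
ally rather than a threat.

chassiscraft implements this design loop for constraint-based metabolic
models: phenotype prediction (FBA, pFBA, lMOMA, FVA), a filtering pipeline
that reduces the reaction list to admissible knockout targets, a
multi-objective evolutionary search (SPEA2) for deletion sets that couple
growth to secretion, a chassis-analysis stage that scores gene sets shared
across multiple target products, and an omics-constrained flux fit for
confronting designs with measured fold changes.

## Constraint-based phenotype prediction

All predictors operate on the steady-state flux cone
$\{v : S v = 0,\ l \le v \le u\}$ of a `metabolic_model`, where $S$ is the
stoichiometric matrix (all represented metabolites are balanced; exchange
pseudo-reactions provide the boundary) and bounds are in mmol/gDW/h.

* **FBA** maximises the objective (biomass) flux and returns one optimal
  vertex.
* **pFBA** is the two-stage variant: fix the objective at its optimum,
  then minimise $\sum_j |v_j|$ via a forward/reverse flux split. It is the
  workhorse for evaluating candidate knockouts, standing in for the
  biological tendency to realise a growth-optimal state with minimal
  enzyme usage.
* **lMOMA** minimises the L1 distance
  $\sum_j |v_j - v^{\mathrm{ref}}_j|$ of a perturbed network to a reference
  distribution, modelling the immediate (pre-adaptation) response to a
  knockout. The reference defaults to wild-type pFBA; reactions missing
  from the reference contribute $|v_j|$. The achieved growth is reported,
  not re-optimised — an L1-minimal mutant state can legitimately be the
  all-zero flux vector when every rerouting is more expensive than shutting
  flux down, as happens on the toy fixture.
* **FVA** reports, per reaction, the flux range attainable while the
  objective stays at (a fraction of) its optimum. A positive FVA *minimum*
  of the product exchange at full optimality is the package's sole
  criterion for calling a design growth-coupled; single pFBA vertices are
  never trusted for coupling claims because the stage-2 LP may itself be
  degenerate.

### Numerical choices

The LP layer is a dense two-phase primal simplex (in C++) over bounded
variables with Bland's pivoting rule: deterministic, cycle-free and exact
enough at toy-to-moderate scale; solver tolerances are $10^{-9}$ and all
post-hoc comparisons use $10^{-6}$ on the mmol/gDW/h scale. pFBA and FVA
hold the objective at its optimum with a relative slack of $10^{-9}$ — a
looser slack (e.g. $10^{-6}$) measurably leaks into reported fluxes and
would defeat the package's own $10^{-6}$ comparisons. Open flux bounds are
clamped to $\pm 1000$ mmol/gDW/h, the conventional flux box for
genome-scale models. Infeasible or zero-growth phenotypes report status
and score zero rather than erroring, so searches can traverse lethal
genotypes.

## Selecting knockout candidates

`select_candidates()` applies five screens in a fixed order, recording the
first matching reason per excluded reaction: (1) essential and nearly
essential reactions — closure drops growth below 1% of wild type (one
threshold covers both); (2) reactions without gene association, which
cannot be implemented as gene deletions; (3) drains and transport
reactions (transporters categorically by default; a flag restricts the
exclusion to blocked transporters, since genome annotations are
inconsistent the derived kind can be overridden per reaction); (4) blocked
reactions, i.e. zero FVA range over the whole feasible region; (5) fully
coupled groups — pairs of reactions each forced to zero by closing the
other, detected by pairwise FVA and closed transitively — collapse to
their lexicographically smallest member. The pairwise zero-forcing test
costs $O(n^2)$ LPs but is deterministic, which matters more here than
speed.

## The optimisation stage

`spea2_search()` runs SPEA2 over variable-size sets of candidate reaction
deletions with two maximisation objectives: biomass flux and product flux,
both from pFBA. The full-scale study conditions — an archive of 100
solutions, 100,000 evaluations per run, up to 20 deletions and 10
independent runs per product — are the package defaults; the
SPEA2 internals that no published description pins down are canonical
choices, all exposed in `search_config()`: population 100, binary
tournament mating on the archive, density via the $\sqrt{N}$-th nearest
neighbour, uniform set crossover at rate 0.8 and exactly one
add/remove/replace mutation per offspring. One deliberate deviation from
textbook SPEA2: a short archive is *not* topped up with dominated
individuals, so the archive invariantly holds a mutually nondominating
set (the fill-up only ever served mating diversity, which the small
benchmark problems do not need).

Post-processing mirrors the two-stage framework: `simplify_solution()`
greedily removes deletions whose removal leaves both objectives unchanged
within $10^{-6}$ *or* improves both (the weakest deterministic reading of
"not directly contributing"; it also shrinks lethal supersets);
`reactions_to_genes()` converts reaction sets to minimal gene cut sets
over each GPR rule's terms, cross-combines them, and discards gene sets
whose side effects on other reactions change either objective;
`merge_runs()` pools the runs and deduplicates by gene-deletion set.

Per solution the metrics are pFBA growth and substrate uptake, the FVA
range of product secretion at optimal growth, the carbon yield
$\mathrm{CYIELD} = (v_{prod} \times C_{prod}) / (v_{sub} \times C_{sub})$
(carbon counts from explicit metadata or formula parsing — the parser
distinguishes C from Cl/Ca/Cu and refuses polymeric placeholders rather
than reporting zero), the biomass–product coupled yield
$\mathrm{BPCY} = (v_{bio} \times v_{prod}) / v_{sub}$, and COST, the
number of genes in the implementing deletion set.

## The chassis-analysis stage

For each target product the merged solution set yields per-gene
frequencies $freq(g,t)$; genes are scored by

$$gscore(g) = \Big(\sum_{t} freq(g,t)\Big) \times \Big(\sum_t \mathbf{1}[freq(g,t) > 0]\Big),$$

promoting genes that recur across products. (The indicator follows the
defining text — frequency strictly positive — since that is the only
self-consistent reading.) The top 30% of genes by score (ties at the cut
all included, so input order is irrelevant) are combined into all subsets
of up to five genes; each candidate chassis $c$ is scored against the
solutions that contain it and reach at least 95% of the *identified*
maximum carbon yield of their target (identified, i.e. max over the merged
set, not the theoretical LP maximum):

$$cscore(c) = \sum_t \frac{\max \mathrm{CYIELDS}(S_{t,c})}{\min \mathrm{COSTS}(S_{t,c})},$$

with an empty group contributing 0 (a "skip" mode is available). The
score only orders the report — nothing is excluded by it. Frequency rows
are also clustered (Euclidean distance, complete linkage, rows sorted by
gene id first so leaf order is reproducible; rows with maximum frequency
below 20% are dropped from the clustering display only, not from
scoring — the display filter and the scores answer different questions).

## The omics-constrained flux fit

`fit_condition_fluxes()` confronts a (possibly knocked-out) network with
measured fold changes. Transcript and protein ratios (significant at
$q < 0.1$, linearised as $2^{\log_2 fc}$) are mapped onto reactions
through the GPR rules — complexes (AND) take the minimum of member fold
changes, isozymes (OR) the maximum, and the protein layer overrides the
transcript layer where both are present, protein abundance being the
nearer proxy for flux capacity; all three rules are configurable because
no published convention fixes them. Exometabolite ratios constrain the
matching exchange flux the same way. Each constrained reaction $r$
contributes a soft constraint $v_r = f_r \cdot v^{\mathrm{ref}}_r$ through
a non-negative slack pair (a reference flux of zero therefore pins the
reaction at zero, which is flagged); growth must reach `growth_frac`
times the reference optimum, a ratio the user supplies from measured
growth rates (wild type = 1). The LP minimises total slack, then total
absolute flux among minimal-slack solutions. This slack-minimising
formulation is this package's own; it is validated by a recovery
property — synthetic perturbations constructed to admit a consistent
solution are recovered with zero slack — rather than by claimed
equivalence to any external tool. `compare_flux_distributions()` provides
the Euclidean distance matrix over fitted states that ordination of
condition-specific flux phenotypes starts from; the ordination itself is
out of scope.

## What the toy generator emulates — and what it does not

`make_toy_model()` provides the study conditions at desk scale. The
deterministic fixture `T1` (and its two-product sibling `T2`) is the
minimal branched network with the structure growth-coupling exploits: a
substrate source capped at 10 mmol/gDW/h, an efficient product-free route
to the biomass precursor, and a route that co-produces a secreted
compound — so one knockout of the efficient route forces secretion at
optimal growth. The `random` variant draws, from a pinned seed, networks
with one or two-step direct routes (two-step routes create a fully
coupled pair the filter must collapse), a product route whose carbon cost
randomises the growth/production trade-off, optional product-free leaks,
blocked dead-end decoys and occasional isozyme/complex GPRs. Carbon
counts (substrate 4–8, product 2–6 atoms) are bookkeeping metadata; the
toys are intentionally not elementally balanced.

What passing on these networks shows: the LP stack is exact, the screens
and scores implement their definitions, the search finds true Pareto
fronts, and the stages compose. What it cannot show: behaviour on
genome-scale models — degeneracy at scale, cofactor and redox coupling,
compartmentalisation, GPR complexity — or any statement about real
organisms. Genome-scale work should load a curated SBML model via
`read_model()`, with the published model edits expressed as a
`patch_model()` edit list.

## Problem sizes used by the test-suite

The shipped tests pin seeds and use reduced sizes chosen to exercise every
code path while keeping the suite quick: Pareto-front equivalence against
exhaustive enumeration on 20 random networks at 2,000 evaluations with at
most 3 deletions; the end-to-end two-product pipeline at 2 runs × 500
evaluations per target; scoring oracles on 100 random fixtures; omics
recovery on 50 synthetic perturbations. The full-scale defaults (10 runs
× 100,000 evaluations, 20 deletions) are the package defaults in
`search_config()`.

## Known limitations

* The simplex is dense and single-threaded: ideal up to a few hundred
  reactions, not tuned for multi-thousand-reaction models.
* Coupling detection is pairwise-exhaustive ($O(n^2)$ LPs over the
  candidate list); flux-ratio sampling would scale better at the price of
  determinism.
* Quadratic MOMA is intentionally absent (the linear variant is the one
  used throughout); so are bilevel MILP formulations (OptKnock-style),
  thermodynamic constraints and flux sampling.
* The reaction-kind heuristic (exchange = one metabolite; transport =
  same base metabolite in two compartments) is exactly that — a
  heuristic — and is overridable per reaction.
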