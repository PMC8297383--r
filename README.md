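# chassiscraft

Constraint-based design of microbial **chassis strains**: hosts
pre-optimised by gene deletions to channel carbon flux toward precursors
shared by several target products, with production **growth-coupled** — in
every growth-optimal flux state the cell secretes the product, so adaptive
evolution improves rather than erodes the phenotype. The package is aimed
at metabolic engineers and systems biologists working with genome-scale
metabolic models (SBML Level 3 + fbc, or a simple JSON dialect).

## What it computes

All methods operate on the steady-state flux cone
`{v : S v = 0, l ≤ v ≤ u}` of a metabolic network:

* **Phenotype prediction** — FBA (maximise biomass flux), pFBA (then
  minimise Σ|v|), lMOMA (minimise Σ|v − v_ref|, the immediate response to a
  perturbation) and FVA (per-reaction flux ranges at optimal growth). A
  design counts as growth-coupled when the FVA *minimum* of the product
  exchange is positive at optimal biomass.
* **Target filtering** — reduces the reaction list to admissible knockout
  candidates: drop (nearly) essential reactions (< 1% of wild-type growth
  when closed), reactions without gene association, drains/transporters
  and blocked reactions; collapse fully coupled reaction sets to one
  representative.
* **Knockout optimisation** — SPEA2 multi-objective search over deletion
  sets maximising (growth, product flux), with archive management,
  solution simplification, GPR-based conversion to minimal gene-deletion
  sets and multi-run merging. Per solution: carbon yield
  `CYIELD = (v_product × C_product) / (v_substrate × C_substrate)`,
  biomass–product coupled yield `BPCY = (growth × v_product) / v_substrate`
  and `COST` = number of deleted genes.
* **Chassis analysis** — per-gene frequencies across the solution sets of
  several target products; `gscore(g) = (Σ_t freq(g,t)) × #{t : freq > 0}`;
  enumeration of candidate chassis from the top-scoring genes; and
  `cscore(c) = Σ_t max(CYIELDs)/min(COSTs)` over the solutions containing
  `c` that reach ≥ 95% of each target's identified maximum carbon yield.
* **Omics-constrained flux fitting** — transcript/protein/exometabolite
  fold changes (q < 0.1) become soft constraints `v_r = f_r · v_ref,r`
  through GPR rules (AND → min, OR → max, protein over transcript); an LP
  minimises total slack subject to a growth fraction, then total flux.

The LP layer is a built-in dense two-phase simplex (C++, Bland's rule,
deterministic); no external solver is required.

## Worked example

The canonical toy fixture `T1` is the minimal branched network with the
structure chassis design exploits: substrate A (uptake capped at 10
mmol/gDW/h) reaches the biomass precursor C either directly (`R2`, gene
`g2`) or through a route that co-produces the secreted compound P
(`R1`/`R3`). Deleting `g2` forces the co-producing route:

```r
library(chassiscraft)
t1  <- make_toy_model("T1")
env <- flux_environment(substrate = "UP")

pfba(t1, env)$growth                                  # wild-type growth
fva(t1, env, "EX_P", 1)                               # product range, wild type
ko <- simulate_knockout(t1, env, "g2", product = "EX_P")
fva(apply_gene_deletions(t1, "g2"), env, "EX_P", 1)   # product range, mutant

cs <- select_candidates(t1, env); cs
evaluate_solution(t1, env, "R2", "EX_P")[c("cyield", "bpcy", "cost")]

cfg <- search_config("EX_P", max_deletions = 2, budget = 200,
                     archive_size = 10, pop_size = 10, runs = 2, seed = 42)
optimize_knockouts(t1, env, cs, cfg)
```

prints

```
wild-type growth:      10
wild-type product FVA: 0 - 10
dg2 growth:            10
dg2 product FVA:       10 - 10
<candidate_set> 2 candidate(s): R1, R2
  excluded: coupled_duplicate (1), essential (2), non_gene (1)
CYIELD: 0.6667  BPCY: 10  COST: 1
<solution_set> product: EX_P  solutions: 1
  genes { g2 } growth 10 product 10 cyield 0.6667
```

Read line by line: the wild type grows at 10 and *may* secrete anywhere
between 0 and 10 units of P (FVA range 0–10: secretion is optional, so a
real cell would evolve away from it). After deleting `g2` the FVA range
collapses to 10–10 — every growth-optimal state secretes P: production is
growth-coupled at unchanged growth. The filter admits only `R1` and `R2`
as knockout targets (`R3` is fully coupled to `R1`; the uptake and biomass
drains are essential; the product drain has no gene). The `Δg2` solution
converts 4 of every 6 substrate carbons into product (CYIELD 0.667) at the
cost of a single gene deletion, and the evolutionary search recovers
exactly this solution as the sole Pareto-optimal design.

A command-line front end wrapping the same functions ships under
`inst/cli/` (`Rscript <pkg>/cli/chassiscraft.R make-toy --variant T1 -o t1.json`,
`... simulate -m t1.json --substrate UP --ko g2 --product EX_P`, etc.).

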