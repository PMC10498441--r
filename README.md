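# retroplan

Computer-aided synthesis planning for drug-like small molecules. Given a
target compound as SMILES, `retroplan` works backward through a small,
curated library of named-reaction retro-templates (amide coupling, Suzuki
coupling, reductive amination, ...), scores every candidate disconnection
with a per-template feasibility classifier, grows a network of candidate
reactions down to purchasable building blocks, and extracts the *k*
lowest-cost, diversified synthetic routes from the resulting AND-OR graph.

It is aimed at medicinal and process chemists (and their software) who want
explainable routes — every step is a named reaction — without training a
neural network to pick templates: with only a few dozen general SMIRKS
transformations, direct substructure screening selects the applicable ones.

## Method

The search runs in three phases:

1. **Retrosynthetic expansion.** Starting from the target, applicable
   retro-templates generate candidate single-step reactions with one or two
   reactants. Each candidate gets a feasibility score in [0, 1] from the
   template's classifier (a multilayer perceptron with one hidden layer of
   10 units over concatenated 2048-bit ECFP4 fingerprints of reactant 1,
   reactant 2 and product); reactions scoring below 0.2 are rejected.
   Which compound is expanded next is governed by one of four heuristics:
   breadth-first, depth-first, best-first compound or best-first reaction.
   The best-first priorities are

   *compound*: `heavy_atoms(c) · d^α`  *reaction*: `max_reactant_heavy · d^α`

   with depth `d` from the target and `α = 1.1`, so small molecules near
   the target are expanded first. Expansion stops at purchasable building
   blocks and known-synthesizable compounds, or when the budget of
   generated reactions is exhausted.

2. **Subnetwork extraction.** Everything reachable from the target —
   generated reactions merged with fixed literature/patent reactions that
   produce any encountered compound — is collected, with purchasability and
   prices annotated.

3. **Vectorized Dijkstra route search.** Compounds are OR nodes, reactions
   AND edges. Each node may hold up to *k* (cost, route) values instead of
   the classic single value. Costs follow

   `cost(product) = Σ cost(reactants) / yield`

   where a fixed reaction uses its reported yield (default 50% when
   unreported) and a generated reaction uses its feasibility score capped
   at 70%. Routes are diversified (distinct reaction sets), grouped into
   strategies by the reaction that directly produces the target, and can be
   constrained (keep/avoid) or allowed to end in unpurchasable leaves at a
   heavy penalty ("partial routes").

Molecular primitives (canonical SMILES, substructure matching, SMIRKS
application, fingerprints) are provided by RDKit through a persistent
Python worker process, so a `python` with `rdkit` must be on the PATH.

## Worked example

```r
library(retroplan)

bb <- building_block_db(c("CC(=O)O", "Nc1ccccc1"), price = c(2, 3))
res <- plan_routes("CC(=O)Nc1ccccc1", building_blocks = bb,
                   k = 3, max_generated = 20)
```

This prints:

```
generated 2 reactions (0 rejected) | subnetwork: 4 compounds, 2 reactions | 1 route(s) in 1 strategies | 0.1s
  route_id rank cost n_reactions is_partial strategy_id
1        1    1   10           1      FALSE           1
```

The target (acetanilide) is disconnected by the amide-coupling template
into acetic acid (price 2) and aniline (price 3), both purchasable. With no
trained classifier the template scores the neutral default 0.5, which is
also its yield, so the single one-step route costs (2 + 3) / 0.5 = 10.
`res$routes[[1]]` holds the route tree; `write_routes()` serializes the
result to JSON.

A command-line wrapper with `search`, `train` and `simulate` subcommands is
installed under `inst/cli/retroplan`:

```sh
Rscript inst/cli/retroplan search --target 'CC(=O)Nc1ccccc1' \
    --building-blocks bb.csv --k 3 --output routes.json
```

## Package layout

| Area | Files |
| --- | --- |
| Molecule identity & measures | `R/core.R`, `R/chem-backend.R` |
| Template library (27 named reactions) | `R/templates.R`, `inst/extdata/templates.tsv` |
| Labeling, encoding, classifiers | `R/feasibility.R` |
| Expansion (4 algorithms) | `R/expansion.R` |
| Subnetwork + k-best route search | `R/routesearch.R` |
| Database readers/writers | `R/chemdb.R` |
| Seeded fixture generators | `R/fixtures.R`, `inst/extdata/fragments.tsv` |
| CLI | `R/cli.R`, `inst/cli/retroplan` |

See `vignettes/route-planning.Rmd` for the full account of the model,
its parameters and its limitations.
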