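---
title: "Template-based retrosynthetic route planning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based retrosynthetic route planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`retroplan` plans synthetic routes for a target molecule in three phases:
template-driven retrosynthetic expansion, subnetwork extraction, and a
k-best search over the resulting AND-OR graph. This vignette is the
package's own account of the underlying models, the tunable parameters and
their defaults, the numerical choices, and what the test fixtures do and do
not demonstrate.

## The template library

A retro-template is a SMIRKS transformation stored in the retrosynthetic
direction: its left-hand side is the product pattern, its right-hand side
the one or two reactant patterns. The same string, reversed, is the forward
transformation, and the package requires this round trip to close — for
every shipped template, forward-applying it to the reactants of any of its
retro disconnections regenerates the product's canonical SMILES. The
shipped library holds 27 general named-reaction transformations of the
medicinal-chemistry workhorse type (amide coupling, esterifications,
N-/O-/S-alkylation, reductive amination, Suzuki, Buchwald–Hartwig,
Sonogashira, Heck, sulfonamide/urea/carbamate formation, redox steps,
Grignard addition, halogenation, cyanation). The TSV format
(`template_id`, `reaction_name`, `smirks`, `n_reactants`) is deliberately
diff-friendly so the library can be extended by hand.

Two deliberate pattern conventions:

* bonds broken between a heteroatom and a CH2 carry `-!@` (single,
  non-ring) so that templates never cut ring bonds and emit bogus
  single-fragment "reactant pairs";
* templates match with stereo-agnostic substructure semantics, and
  generated reactants inherit stereocenters untouched outside the reaction
  center. The library makes no attempt at stereoselective chemistry, which
  is a known limitation for targets with several chiral centers.

Template selection is a direct substructure screen of each template's
product pattern against the target — with a library this small, no learned
template selector is needed, and each disconnection remains explainable as
a named reaction.

## Feasibility classifiers

Template application is purely syntactic; whether the proposed reaction
would actually work is estimated by one binary classifier per template.

**Labeling.** From a corpus of single-step reaction records (1–2 reactants,
one product, optional fractional yield), a record is a *positive* example
for a template when it fully matches it — the product matches the
template's product pattern *and* forward application of the template to the
record's reactants regenerates the record's product — and its yield is
at least 10% or unreported. A full match with yield below 10% is a
*negative*, as is any record whose reactants match the template but whose
product is not among the template's forward outcomes (product mismatch),
whatever its yield. Everything else is excluded. "Full match" is
operationalized as the conjunction above because a product-pattern hit
alone does not tie the recorded product to the recorded reactants. Some
product-mismatch negatives are inevitably mislabeled (the reported
conditions may simply not have delivered the template's product); no
correction is attempted.

**Encoding.** A reaction is the concatenation of three folded 2048-bit
ECFP4 (Morgan radius-2) fingerprint slots — reactant 1, reactant 2,
product — giving a fixed 6144-bit vector; single-reactant reactions leave
the middle slot zero. Reactants are always ordered by descending heavy-atom
count with ties broken by canonical SMILES in the C collation order. One
rule is used at training *and* scoring time: an earlier draft ordered
template-generated reactants by the template's pattern roles, but then the
classifier would be asked about encodings it was never trained on — the
single deterministic rule removes that mismatch and makes the encoding
invariant to the order in which a corpus record happens to list its
reactants.

**Model.** A multilayer perceptron with a single hidden layer of 10
logistic units and a logistic output, fit with `nnet` under a fixed seed
and an iteration cap of 500. Columns of the training matrix that are
constant (fingerprint bits never set) are dropped before fitting and the
kept-column index travels with the model; this changes nothing about the
function learned on the observed support and shrinks the optimization
problem by an order of magnitude. Examples are split 80/10/10
(train/test/evaluation), stratified by label; the reported
`evaluation_accuracy` comes from the final 10%. A template with fewer than
20 positive examples is not trainable and keeps the neutral default score
of 0.5 — above the rejection threshold, so classifier-less templates remain
usable but never look better than an endorsed one. No class reweighting is
applied.

**What the synthetic corpus shows.** `make_training_set()` builds positives
by forward-applying a template to a pool of ~110 simple mono-functional
fragments and negatives as (a) low-yield full matches drawn from
combinations reserved exclusively for that role and (b) product mismatches
whose recorded product is an unrelated pool molecule. This set is separable
by construction: the held-out accuracy ≥ 0.9 demonstrated in the tests
shows the labeling/encoding/training pipeline is wired correctly, *not*
that real-corpus accuracy would be that high — real patent corpora contain
hard negatives (plausible but unformed products) and label noise that the
generator deliberately does not emulate, along with realistic yield
distributions.

## Retrosynthetic expansion

Expansion grows the reaction network from the target under a budget
`max_generated` counted over *kept* generated reactions (those scoring at
least `score_threshold`, default 0.2). Four selection strategies are
provided:

* `breadth_first` — FIFO over open compounds; finds shortest routes first
  but expands everything;
* `depth_first` — LIFO with a depth cutoff (`max_depth`, default 10; the
  depth at which further expansion of a branch stops);
* `best_first_compound` — pops the open compound minimizing
  `heavy_atoms · d^α`;
* `best_first_reaction` — pops the kept reaction minimizing
  `max(reactant heavy atoms) · d^α` and one-step expands all of its open
  reactants.

Depth is counted from the target: the target has depth 0 and a reaction
disconnecting a depth-`d` compound, together with its reactants, has depth
`d + 1`. First-level disconnections therefore use `d = 1` and are
unpenalized (`1^α = 1`); had the origin been placed at the first reactants,
the factor would vanish at depth 0 and the discount would misbehave. The
default `α = 1.1` gently prefers shallow chemistry; larger values push the
search toward breadth-first behavior. The reaction priority applies the
depth factor once — reading the compound score as already depth-discounted
and then discounting again would distort comparisons across depths without
changing the order at equal depth.

Other conventions: priority ties break by insertion order (determinism);
duplicate disconnections (same product, template and reactant multiset)
are inserted once; per-compound template applications are cached and
re-encountered compounds keep their minimum observed depth; a candidate
whose reactants include an ancestor of the product on its discovery path is
discarded, preventing trivial cycles; purchasable and known-synthesizable
compounds are terminals and are never expanded; reactions of rejected
candidates are not explored further. The budget is the only stopping
criterion besides frontier exhaustion.

## Route extraction

Phase 2 collects every compound and reaction reachable from the target
(optionally within `max_depth` steps), merging generated reactions with
fixed-database reactions producing any encountered compound, and annotates
purchasability and prices.

Phase 3 searches this AND-OR graph. Each compound may hold up to `k`
(cost, route) values; purchasable compounds hold exactly one, their price,
and always act as leaves. The candidate heap is seeded with reactions whose
reactants are all purchasable; when a candidate is admitted as its
product's next value, new candidates are formed by combining it with the
stored values of co-reactants of every consuming reaction. The cost
recursion is

```
cost(product) = sum(cost(reactant_i)) / effective_yield + overhead
```

with `effective_yield` = the reported yield of a fixed reaction (default
0.50 when unreported — deliberately worse than most reported yields, so
documented chemistry is preferred), or the feasibility score of a generated
reaction capped at 0.70 (so a confident classifier cannot make invented
chemistry look better than reliable literature steps). The per-reaction
overhead defaults to 0; route length still penalizes cost implicitly
because every extra step divides by a yield ≤ 1.

Correctness rests on admissibility: a candidate's cost is at least the cost
of each of its constituent entries (yields ≤ 1, positive costs), so
candidates pop in nondecreasing cost order and each node's values are
admitted best-first, Dijkstra-style, even in cyclic graphs. Termination is
guaranteed because candidates are only generated on admission and each node
admits at most `k`.

Numerical and semantic choices:

* **Diversity.** Two routes are distinct iff their reaction sets differ;
  identical sets reached by different heap paths are merged at admission.
  Strategy grouping (by the reaction producing the target) surfaces the
  coarser notion of strategic diversity; an optional per-strategy cap can
  be layered on top by filtering the returned list.
* **Tree semantics.** A compound appearing in two branches of one route is
  costed independently in each branch, matching the literal cost recursion;
  shared-intermediate discounting is out of scope. Routes are represented
  as nested trees, so each branch carries its own sub-route.
* **Repetition.** No compound repeats on any root-to-leaf path. The search
  enforces this at admission (the product must not occur inside any
  constituent branch), the exhaustive oracle by an ancestor ban-set; the
  two formulations are equivalent.
* **Partial routes.** When enabled, open dead-end compounds (no producing
  reaction, not purchasable) become leaves at `partial_leaf_penalty`
  (default 10000, configurable — it merely has to dwarf real prices so
  every complete route outranks every partial one). Routes with such leaves
  are flagged.
* **Known bound.** Per-node value lists are capped at `k`; in graphs where
  the k-th best route at the target requires a strictly deeper value at an
  intermediate node (possible only through reaction-set collisions or
  cycle-induced pruning), the vectorized search can in principle return a
  costlier k-th route than exhaustive enumeration. On the layered random
  networks used for validation this never occurs (200 networks × 3 values
  of k agree exactly with brute force); the caveat is noted for unusually
  pathological cyclic inputs.
* **Ties.** Equal-cost heap entries pop in insertion order; equal-cost
  routes keep their admission order.
* **Purchasable targets.** A route must contain at least one reaction, so
  a target that is itself a building block yields no routes rather than a
  trivial "buy it" route.
* **Keep/avoid.** Avoided compounds and reactions are pruned before the
  search; keep-filtering is applied to an enlarged route pool
  (`search_k = max(8k, 32)` by default), so with extremely deep keep
  constraints the filtered list can undershoot `k` even when more
  satisfying routes exist — raising `search_k` trades time for
  completeness.

## Synthetic fixtures and what they demonstrate

`make_synthetic_network()` draws layered random networks (default 12
compounds, 18 reactions, yields 0.3–1.0, prices 1–100, ~30%
template-generated) in which every interior compound is producible from
strictly lower layers, so at least one complete route exists and the graphs
are acyclic. They validate the search machinery exactly because the
exhaustive oracle is feasible at that size; they do not emulate the degree
distribution, reaction-type mix or price structure of real catalogs. The
worked examples (`chain`, `diamond`, `cycle`) are small enough to check by
hand: the chain costs (2/0.5)/0.5 = 8, the diamond orders its two routes
8 then 10, and the cycle network exercises termination and repetition
checks. The expansion fixture (a tertiary benzylamine with an aryl ethyl
ether handle, four building blocks) admits a 2-step and a 4-step route
through genuinely different disconnection sequences, which is what the
shortest-route-first property needs.

Problem sizes used by the test suite and the acceptance script — 200
networks for oracle agreement, 500 + 500 training examples, 5 fixture
products per template — were chosen so a full run completes in a few
minutes on one core while still exercising every rule at realistic scale.

## Dependencies and environment

All molecular primitives go through RDKit in a persistent Python worker
(JSON lines over stdin/stdout), started lazily and shared by the session;
the R side never parses SMILES itself. The MLP is fit with `nnet`; route
search, expansion, labeling and cost logic are plain R. A `python` binary
with `rdkit` importable must be on the PATH (or named via the
`RETROPLAN_PYTHON` environment variable).

## Known limitations

* No stereoselective templates; targets dominated by stereochemistry will
  receive formally correct but chemically naive disconnections.
* Feasibility classifiers trained on the synthetic corpus are sanity
  checks, not chemistry oracles; real deployments should retrain on a
  licensed reaction corpus.
* Prices are taken per catalog pack without per-gram normalization, and
  currency is unitless.
* The per-node `k` cap (see above) is a theoretical completeness bound on
  adversarial cyclic graphs.
* Reaction conditions (solvent, temperature, catalyst) are carried as
  metadata only and never predicted.
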