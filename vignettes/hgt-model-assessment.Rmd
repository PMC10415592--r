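---
title: "Methods: DTL reconciliation and HGT-based clock-model assessment"
author: "hgtclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DTL reconciliation and HGT-based clock-model assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtclock)
```

## The problem

Divergence-time estimates deep in the prokaryotic tree of life rest on few
fossil calibrations and on strong rate-model assumptions, so different
relaxed-clock models (autocorrelated or uncorrelated rates, uniform or
birth–death node-age priors) can return materially different chronograms.
Horizontal gene transfer offers an independent arbiter: a transfer requires
donor and recipient lineages to be contemporaneous, so each transfer
inferred from gene-tree/species-tree incongruence implies a relative-age
constraint ("the donor node is older than the recipient node") that any
credible chronogram should satisfy. The fraction of a model's posterior
sample satisfying the constraints measures the model's temporal coherence
with the transfer record, and the constraint-satisfying subset of the
posterior yields sharpened ("constrained") age distributions.

This package implements that chain for the kind of study where a
horizontally mobile marker family — here the multiheme c-type cytochromes
(MHCs) that carry extracellular electron transfer — is censused in
proteomes, reconciled against a dated species tree, and used to rank clock
models and date gene acquisitions.

## Motif census

A c-type heme-binding site is the five-residue signature C-X-X-C-H. The
scanner is purely positional: positions 1, 4, 5 must be C, C, H
(case-insensitive); positions 2–3 accept any residue symbol, including
ambiguity codes such as X, B, Z, because the signature constrains only the
cysteines and the histidine. Stops (`*`) and gaps (`-`) never match any
position — they are not residues. Every start index is scanned, so
overlapping occurrences (e.g. `CAACHACH`, hits at 0 and 3) all count:
occurrences are the unit in which heme-binding sites are counted, and no
de-overlap rule is part of the definition. A protein is classified as an
MHC when it carries at least `min_motifs = 2` motifs, and the motif total
of a proteome is summed over MHC-classified proteins only (the motifs
"carried by" the MHC complement). Both census numbers are monotone
consequences of the per-protein counts, which is what the tests exercise.

## Dated trees and posterior ensembles

A `chronogram` wraps an `ape` tree with node ages: age = tree height minus
root-to-node distance, in Ma. Construction validates ultrametricity (all
tips equidistant from the root within `tolerance` × height, default 1e-6)
and strict parent-older-than-child ordering; tip ages are then snapped to
exactly zero — all taxa are treated as extant.

Posterior samples arrive as Newick tree lists, one tree per line, possibly
split over multiple chain files. `load_ensemble()` drops the first
`floor(burn_in * n)` trees per file and keeps every `thin`-th of the rest;
chains are concatenated after burn-in. Because both 25% and 20% burn-in
conventions are in active use, burn-in is a parameter with default 0.25,
never a constant.

Clade ages are crown (MRCA age) or stem (age of the MRCA's parent; the
root's own stem equals the root age). When a clade definition is not
monophyletic in a particular sample — posterior samples can vary in
topology — the spanning MRCA is used and a warning is aggregated per
operation rather than raised per sample. Age summaries report the mean,
median and the 95% equal-tailed credible interval, i.e. the 2.5th and
97.5th sample percentiles with linear interpolation between order
statistics (`quantile` type 7). Equal-tailed was chosen over HPD because it
is reproducible without density estimation; HPD support would be an
extension, not a default.

## DTL parsimony reconciliation

The reconciliation model is the undated Duplication–Transfer–Loss
parsimony model: speciations are free, duplications cost δ, transfers τ,
losses λ, and the optimum minimizes the summed cost. The dynamic program
fills, over gene nodes in postorder and species nodes in postorder:

* `C[g, s]` — cheapest history with gene node `g` mapped exactly at
  species node `s`, taking the minimum over speciation (children descend
  into the two child subtrees of `s`), duplication (δ, both children stay
  at or below `s`) and transfer (τ, one child remains, the other maps to
  any node neither ancestral nor descendant to `s`);
* `IN[g, s]` — `g` maps anywhere in the subtree of `s`, charging λ per
  intervening speciation-loss;
* the transfer target is resolved with `OUT[g, s] = min` of `C[g, ·]` over
  the nodes incomparable with `s`.

The gene root may map anywhere at no extra charge. Transfers are
constrained only by non-ancestry — dates play no role during
reconciliation; chronological plausibility is assessed afterwards against
dated trees. This ordering (reconcile first, then test time-consistency)
is deliberate: it keeps the combinatorial optimum independent of any
particular chronogram.

Ties are broken deterministically — speciation is preferred to transfer,
transfer to duplication, and remaining ties resolve by species-node
postorder index — so `reconcile()` returns one witness event list whose
recomputed cost (`event_list_cost()`) must equal the optimum exactly.
Enumerating co-optimal reconciliations is out of scope, as is amalgamation
over gene-tree samples: input is a single rooted binary gene tree, and
polytomies are rejected rather than silently resolved (a silent resolution
would manufacture event signal).

The "dead lineage" option models transfers routed through extinct or
unsampled diversity as a single atemporal lineage running parallel to the
whole species tree: a transfer may enter it (τ) and exit it (τ), it
persists for free, and duplications inside it cost δ. This is the minimal
unsampled-lineage extension; richer Pareto-optimal strategy sets are not
modelled. Allowing the dead lineage can only lower the optimum, which is
asserted as an invariant.

`brute_force_cost()` is the testing oracle: it enumerates every assignment
of internal gene nodes to species nodes (plus the dead lineage when
enabled), derives the forced event and loss counts of each assignment from
local parent/child placements, and minimizes. It shares no costing logic
with the DP, and the two agree exactly on every rooted binary gene/species
pair with up to five leaves under both classical cost vectors (22,518
comparisons in the acceptance sweep).

`extract_transfers()` converts witness transfers into constraints (donor
clade = leaves under the donor node, likewise recipient); transfers
touching the dead lineage are reported but flagged untestable, since no
extant clade represents that side. `check_time_consistency()` additionally
reports the permissive edge-interval test — donor edge time span overlaps
recipient edge span — alongside the stricter crown-age comparison used for
ensemble scoring; the two answer different questions (could the transfer
have happened at all, versus does this chronogram order the two nodes
correctly).

## Compatibility scoring

`is_compatible()` compares one chronogram with one constraint: donor-side
age strictly greater than recipient-side age. The node pair used on each
side is explicit data on the constraint (`crown-crown` by default,
`stem-crown` and `stem-stem` selectable), because "donor older than
recipient" does not by itself fix which node represents each clade. Exact
age ties count as incompatible — a transfer needs the donor to strictly
predate the recipient node. Per-constraint fractions and the joint
(all-constraints) fraction are both always reported: published
compatibility percentages are sometimes per-event and sometimes joint, and
the two can differ materially, so neither is hidden. Model ranking sorts
by joint fraction, ties alphabetical.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; they are first-class, tested code.

* **Species trees** (`simulate_bd_tree`): forward birth–death simulation
  from two crown lineages, conditioned by retry (cap 10,000) on `n_taxa`
  survivors; after the n-th lineage appears the process is carried one
  further exponential waiting time so tips have positive terminal
  branches; extinct side branches are pruned. Defaults — 16 taxa, birth
  0.002/Ma, death 0.0005/Ma, root age capped at 4360 Ma (the upper edge of
  a plausible root-calibration window reaching back toward 4.36 Ga) —
  give crown ages on the billion-year scale typical of deep prokaryotic
  family phylogenies. Conditioning by retry was chosen over exact
  conditioned sampling for simplicity at desk scale.
* **Posterior-like ensembles** (`jitter_ensemble`): each internal node age
  is multiplied by independent lognormal noise with median 1 and
  coefficient of variation `jitter_cv` (default 0.05), then a postorder
  repair pass enforces `age(parent) ≥ max(child ages) + ε` with
  `ε = 1e-9 ×` root age, so every sample is a valid chronogram by
  construction. Multiplicative jitter plus repair was preferred to joint
  resampling of node ages: it is simple, seedable, and guarantees
  validity.
* **Planted transfers** (`plant_transfers`): event times uniform on
  (0, root age); donor and recipient edges drawn uniformly without
  replacement from the lineages alive at that time, so the two clades are
  always disjoint. Contemporaneity does not order the two crown ages, so
  the table records whether the crown comparison holds on the truth
  (`crown_ok`) and whether it is an exact tie (`crown_tie`, e.g. two
  terminal edges, both crown age 0). `oriented_constraints()` flips rows
  to hold on the truth and drops ties, which carry no ordering
  information.
* **DTL gene trees** (`simulate_dtl_gene_tree`): one gene lineage enters
  the species root and descends; duplication, transfer and loss occur as
  Poisson processes per gene copy (defaults 2e-4, 5e-4, 2e-4 events/Ma —
  transfer-dominated, as in families spread largely by HGT); transfer
  recipients are uniform over contemporaneous lineages; planted transfers
  can be injected at their recorded times for exact-recovery tests.
* **Proteomes** (`synth_proteome`): background residues are drawn from the
  18 amino acids other than C and H, so planted C-X-X-C-H motifs are the
  only motifs and the scanner must recover the plan exactly. The default
  plan (2475 proteins; 25 MHCs carrying 87 motifs) emulates the census
  scale of an ammonia-oxidizer proteome.

All generators consume a mandatory seed through one seeded stream per run
(`withr::with_seed`); nothing is wall-clock seeded, and byte-identical
reruns are asserted in the tests.

What the generators deliberately do not emulate: sequence evolution (no
alignments or substitution models — ensembles are emulated at the
chronogram level, not produced by MCMC), topological uncertainty in the
posterior (jittered samples share the true topology), gene-tree inference
error, and calibration-density mathematics (calibration tables are
validated data, used only to bound simulated root ages). Passing tests
therefore demonstrate the correctness of the census, reconciliation,
scoring and summarization machinery under known truth — not the
performance of Bayesian dating itself on real alignments.

## Credible-interval calibration

One validation deserves its own explanation. If an ensemble is generated
by jittering around the truth itself, the truth is the median of every
node's sample distribution, and the 95% equal-tailed interval of 1000
samples contains its own median essentially always — measured coverage is
~100%, and nothing about interval calibration is learned.
`ci_coverage_experiment()` therefore emulates how a *well-calibrated*
Bayesian analysis behaves: per replicate, the posterior is centred on an
estimate perturbed from the truth by the same lognormal error law
(one draw at `jitter_cv`), and the ensemble is jittered around that
centre. Under this model the interval covers the truth with probability
95% per node asymptotically, and the experiment (200 replicate trees,
8 taxa, 1000 samples, cv 0.05 — 1400 node checks) lands near 0.95, inside
the 90–98% acceptance band. The plain truth-centred jitter keeps its
literal semantics in `jitter_ensemble()` — it is what makes the
mean-recovery tests (posterior mean within three standard errors of the
truth) meaningful.

## Numerical and design choices

* Ages are compared with exact arithmetic; the only tolerance is the
  relative ultrametricity check (default 1e-6; the internal birth–death
  writer validates at 1e-8 with full-precision Newick output).
* The DP and oracle use integer-valued cost vectors in tests, so cost
  equality is exact; witness-vs-optimum identity is asserted without
  tolerance.
* Problem sizes used by the validation experiments — exhaustive
  reconciliation sweeps to five leaves, 500-sample recount ensembles,
  100-replicate direction-recovery runs at 300 samples, 200-replicate
  calibration runs at 1000 samples — were chosen to give the experiments
  clear statistical power at desk scale; all are parameters of the
  exported experiment functions.
* The command-line layer never calls `quit()` from library code: `main()`
  returns its exit code (0 success, 1 processing error, 2 usage error) so
  it is testable in-process, and the thin `inst/cli/hgtclock` launcher
  owns process exit.

## Known limitations

* The reconciliation is parsimony-only; probabilistic (likelihood-based)
  reconciliation and co-optimal enumeration are not provided, so
  constraint sets inherit the arbitrariness of a single witness when
  several histories tie.
* The dead lineage is atemporal; transfers routed through it cannot be
  time-checked.
* One gene copy per species per gene-tree leaf is assumed labelled by its
  species; paralog assignment is the caller's responsibility.
* Crown-age comparison of a leaf clade (crown age 0) can never satisfy a
  donor-side constraint; stem modes exist for exactly that case.
* NEXUS input and translate tables are not supported; tree lists are
  plain one-tree-per-line Newick.
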