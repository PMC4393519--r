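---
title: "Species-tree-aware gene tree error correction under the DTL model"
author: "dtlfix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-tree-aware gene tree error correction under the DTL model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(dtlfix)
```

## The problem

Single-gene alignments rarely carry enough signal to pin down the gene
tree topology: maximum-likelihood (ML) trees for microbial gene families
routinely get 5--15% of their splits wrong. For gene families affected by
horizontal gene transfer, the usual species-tree-aware error-correction
methods do not apply, because they explain gene tree/species tree
discordance with duplications and losses only. `dtlfix` implements error
correction under the duplication-transfer-loss (DTL) model: starting from
an ML gene tree, it searches for the topology with the lowest parsimony
DTL reconciliation cost against a trusted rooted species tree, restricted
to topologies that the alignment cannot statistically distinguish from
the ML tree.

The package has three layers:

* **Reconciliation** (`reconcile_rooted()`, `reconcile_unrooted()`,
  `dtl_cost()`): undated parsimony DTL reconciliation by dynamic
  programming, with event backtracking.
* **Correction** (`correct_gene_tree()`, `correct_gene_tree_tl()`):
  hill-climbing over NNI/SPR rearrangements, gated by a native
  Shimodaira-Hasegawa (SH) test with RELL resampling.
* **Simulation & evaluation** (`simulate_species_tree()`,
  `simulate_gene_tree()`, `simulate_alignment()`, `match_events()`,
  `run_benchmark()`): a full synthetic-data framework with recorded true
  event histories, so the method can be validated end to end without
  external data.

## The reconciliation model

A reconciliation maps every gene tree node to a species tree node and
labels each internal gene node as a speciation, a duplication, or a
transfer; losses are implied by the mapping. The species tree is undated:
a transfer may connect any two incomparable species branches, and no
time-consistency check is performed (inferred scenarios may be mutually
undatable — this is the price of polynomial-time inference).

Costs default to 2 per duplication, 3 per transfer and 1 per loss, the
standard choice for prokaryotic families; published robustness analyses
show results change little for other sensible costs. `event_costs(tl_only
= TRUE)` sets the duplication cost to infinity ("TL mode") for
single-copy families, where incongruence is attributed to additive
transfer and compensating loss; infeasible instances (e.g. two gene
copies in one species) are reported with infinite cost rather than an
error.

The dynamic programme computes, for every gene node $g$ and species node
$s$, the cheapest embedding $c(g,s)$ of the subtree of $g$ with $g$
mapped at $s$, using auxiliary quantities $in(g,s)$ (cheapest embedding
at or below $s$, charging one loss per passed speciation) and $out(g,s)$
(cheapest embedding at a species node incomparable to $s$; transfers do
not charge losses below the landing point). Unrooted gene trees are
handled by running the rooted DP once per candidate rooting (one per
edge, $2m-3$ in total) and taking the minimum; this is quadratic-in-$m$
rather than the known $O(mn)$ single-pass algorithm, but the DP kernel is
compiled and a 200-leaf unrooted reconciliation takes a few tens of
milliseconds, which is far from limiting.

Correctness is defined by exhaustive search, not by the recurrence: the
test suite checks the DP against `brute_force_reconcile()` — an
independent enumerator of all mappings with per-node event scoring — on
hundreds of random instances, including infinite duplication costs.

**Tie-breaking.** Minimum-cost reconciliations are usually not unique.
All choices are deterministic: candidate species nodes are scanned in
postorder (deepest first), the event preference at equal cost is
speciation > duplication > transfer, a lineage maps as high as its loss
chain allows, and equal-cost rootings resolve to the smallest edge index.
Determinism matters because event-level accuracy scoring depends on which
optimum is reported.

## Statistical equivalence: the SH test

Topology proposals are compared with the input ML tree by a two-tree SH
test on per-site log-likelihoods (JTT exchangeabilities, discrete-gamma
rate heterogeneity with shape 1 and 4 categories by default; the model is
held fixed across the whole run so likelihoods stay comparable). The
statistic is $\delta = \max(0, \ell_{\mathrm{ML}} - \ell_{\mathrm{alt}})$;
its null distribution is built by RELL bootstrap — resampling site
log-likelihoods without re-optimization — with per-tree centring, and the
one-sided p-value is the fraction of resamples whose centred difference
reaches $\delta$. A proposal is "statistically equivalent" when $p \ge
\alpha$ (default $\alpha = 0.05$). Site likelihoods and branch-length
optimization are delegated to phangorn's pruning-algorithm
implementation; the SH/RELL machinery itself is native, so no external
phylogenetics binary is required.

The suite verifies calibration empirically: on star-like quartet data
with site log-likelihoods computed at fixed branch lengths, the null
rejection rate at $\alpha = 0.05$ sits in the 3--7% band, and the test
has essentially full power against a wrong quartet at 1000 columns. When
branch lengths are instead re-optimized under each candidate topology —
as the search does — the construction becomes markedly conservative
(each hypothesis adapts to the data before resampling), a well-known
property of the SH family that makes the equivalence gate err on the
side of keeping candidates.

## The search

Each iteration proposes one random rearrangement (NNI or SPR with equal
probability) of the current search position. Proposals are screened by
reconciliation cost first — the DP is thousands of times cheaper than a
likelihood evaluation — and only cost-competitive proposals (or rare
escape draws, default probability 0.05) are branch-length-optimized and
SH-tested. A passing proposal replaces the search position when it
improves the (cost, $-\log L$) key; among all visited SH-passing trees
the lexicographically best one is returned, so ties in cost resolve by
likelihood. Visited topologies are memoized under a canonical split-set
hash and never re-scored.

Uniform random proposals explore less efficiently than a guided proposal
schedule, so by default the stochastic phase is followed by a
deterministic polish: steepest-descent sweeps over the complete NNI
neighbourhood of the best tree, again screened by cost and gated by the
SH test, until no statistically equivalent neighbour improves the cost.
In the package's recovery experiments this finishing step is what
reliably drains the last one or two misplaced splits. The default
iteration count is 1000.

Degenerate cases behave sensibly: an input already congruent with the
species tree (cost 0) is returned unchanged, and a TL-mode run that never
encounters a finite-cost topology returns the input with `feasible =
FALSE`.

## The simulator and its conventions

`simulate_species_tree()` draws pure-birth (Yule) trees, rescaled to unit
height. `simulate_gene_tree()` evolves a single gene lineage down the
species tree: duplication, transfer and loss compete as exponential
events with fixed rates per unit time; at a transfer the recipient branch
is chosen uniformly among contemporaneous branches (no distance bias); at
speciations the lineage enters both descendants. Extinct lineages are
pruned and unary nodes suppressed; families with fewer than three
surviving leaves are redrawn (capped at 100 retries). `simulate_alignment()`
assigns each column one of four discrete-gamma rate categories and
evolves amino acids along the (rescaled) gene tree under JTT via
phangorn. Mutation-rate scaling interprets "x substitutions per site" as
the mean root-to-leaf depth of the gene tree, the common simulator
convention; the alternative reading (total tree length) is a one-line
change but is not used.

**Observable-event conventions.** The recorded true history lists events
at the granularity at which surviving data can witness them, because
event-level accuracy is only meaningful when truth and inference speak
the same language:

* a duplication or transfer is recorded when both child lineages have
  surviving descendants (it then corresponds to a binary node of the
  pruned true tree); a transfer whose donor-side continuation died out is
  also recorded, since the jump of the surviving clade into an
  incomparable species region remains visible, with the donor placed at
  the last observable position of the lineage;
* a transfer's donor is recorded on the branch where the event happened
  and its recipient at the first observable position of the moved
  lineage (the landing branch itself, unless the lineage's top nodes
  lost one side);
* a loss is recorded per maximal extinct subtree, on the species branch
  where the gene died, but only when an anchored surviving lineage is
  forced through the speciation concerned — extinctions above the pruned
  root or directly below a transfer landing leave no trace that any
  reconciliation could recover.

Event matching (`match_events()`) is strict and one-to-one: a
duplication must agree on the gene clade and species branch, a transfer
on the moved clade and the (donor, recipient) branch pair, a loss on the
species branch and the surviving sibling clade. Losses are the loosest
category — they have no gene tree node of their own — and their matching
convention (sibling clade) is a documented package choice.

**Rate presets.** The named presets (low, medium, high, veryhigh) were
fitted with `calibrate_rates()` so that mean observable event and leaf
counts over 50-taxon unit-height Yule trees reproduce the published
simulation design (for example the medium preset yields on average about
70 leaves, 2.8 duplications, 5.5 transfers and 2.3 losses per family).
They are fixed package constants; `calibrate_rates()` is exported for
recalibration against other regimes. Achieved means are within a few
percent of the targets for events and within ten percent for leaf counts
(leaf count is an emergent quantity, not directly fitted).

What the simulator does **not** model: insertions/deletions,
lineage-specific rate variation, alignment error, incomplete lineage
sorting, replacing (non-additive) transfers, or transfer-distance bias.
Passing the packaged benchmarks therefore demonstrates correctness of
the implementation under the stated generative model, not performance on
the idiosyncrasies of real sequence data.

## Experiment drivers

`run_benchmark()` wires the pieces together: simulate a family, degrade
the true tree by a configurable number of random NNI moves, re-optimize
its branch lengths on the simulated alignment (this degraded tree stands
in for an externally inferred ML tree, keeping the benchmark
self-contained), apply a correction method, and score both trees by
normalized Robinson-Foulds distance (NRFD) plus event-level
precision/sensitivity against the recorded history.
`corrupt_species_tree()` supports the species-tree-robustness experiment
(reconciliation against a species tree degraded by rooted NNIs), and
`collapse_low_support()` the bootstrap-collapse analysis, where the
symmetric NRFD definition makes a fully collapsed tree score 0.5 against
any binary reference.

Problem sizes in the packaged tests and in `scripts/acceptance.R` are
chosen to keep a full run in the tens of minutes on one core: 100
replicates per preset for calibration checks, several hundred families
per rate preset for event recovery, 25 (tests) or 20 (script)
replicates for the search recovery
experiment at the low-rate/333-column/unit-mutation-rate cell (run at
500 stochastic iterations plus the deterministic polish, which reaches
the same recovery plateau as longer runs on these inputs), and 400--500
replicates for SH calibration. The published full grid (24
datasets of 100 families, each corrected from externally inferred ML
trees) is reproducible with the same functions given more compute and an
external ML program for the inputs.

## Known limitations

* The unrooted DP is per-rooting rather than the single-pass linear
  algorithm; fine up to a few hundred leaves.
* Only one optimal reconciliation is reported; event accuracy inherits
  the documented tie-breaks, and alternative optima can shift
  event-level precision/sensitivity by a few points.
* The SH gate inherits the known conservativeness of the SH family of
  tests; with very short alignments nearly everything is "equivalent"
  and correction is driven almost entirely by parsimony.
* Search proposals are uniform; a support-guided proposal schedule would
  likely need fewer iterations.
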