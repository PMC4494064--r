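---
title: "Models and methods behind paleozyme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleozyme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleozyme)
```

paleozyme reimplements, as tested components over synthetic data with
recorded truth, the inference chain used to study the evolution of
pectin-degrading enzyme families in fungi: ortholog filtering and
supermatrix assembly, per-gene phylogenetic-signal diagnostics,
duplication–loss reconciliation with ancestral copy numbers, and
penalized-likelihood dating of the species tree. This vignette describes
each model, its assumptions, the tunable parameters, and the numerical
and design choices that were genuinely open.

## Trees and alignments

Trees are ape `phylo` objects. Two package-maintained extras ride along:
`$support` (one value per internal node, on a 0–100 scale; values read
from Newick internal labels on a 0–1 scale are assumed to be posterior
probabilities and multiplied by 100) and `$age` (node ages in Ma, tips at
zero for ultrametric trees). Supports sit on the child node of the edge
they annotate. `write_newick()` orders children by their smallest
descendant leaf label, so isomorphic trees serialize identically; labels
containing Newick metacharacters (gene copies are named
`genome:family:copy`) are single-quoted. Polytomies are storable;
operations that need binary trees say so.

Alignments are named character vectors of equal-length strings; `-` is an
alignment gap and `?` a missing character (an absent gene in a
supermatrix). Partition intervals are 0-based and half-open, which makes
concatenation arithmetic exact. `clade_set()` returns the non-trivial
unrooted splits of a tree (n − 3 for a binary tree); this is the currency
in which RADICAL node recovery is tracked.

## Synthetic data: what it emulates, what it does not

`sim_species_tree()` draws a pure-birth tree and rescales it to a chosen
root age (default study condition here: 10–12 genomes, roots at
750–900 Ma, matching the deep-fungal setting the methods target).
`sim_gene_family()` runs a continuous-time birth–death process along each
species branch, one ancestral copy entering at the root, with per-lineage
duplication and loss rates per Ma. The defaults used across the analysis
(λ_dup = λ_loss = 0.002/Ma) give root-to-tip expectations of a few events
per lineage over an 800 Ma tree — copy numbers per genome in the 0–15
range, the order observed for pectinase families in real genomes. The
simulator records, per species branch, entering/exiting copy counts and
event counts; the conservation law `exiting = entering + dups − losses`
holds by construction and is asserted, not assumed. Families that go
globally extinct are resampled (capped at 10,000 attempts, then an
error), and the resample count is reported.

`sim_relaxed_phylogram()` draws i.i.d. lognormal branch rates with
expectation `mean_rate` (so the sample mean of rates is unbiased for it)
and standard deviation `sigma` on the log scale — an uncorrelated
lognormal clock. Branch lengths are exactly rate × duration: no Poisson
sampling noise is added, so dating error in the tests reflects rate
relaxation only. `sim_alignment()` evolves sites root-to-tips under a
reversible model with equiprobable discrete-gamma categories and records
each site's category.

What the generators do *not* emulate: alignment error and masking,
compositional heterogeneity, indels, domain-level homology, horizontal
transfer, and gene-tree estimation error beyond what the bootstrap-NJ
stages introduce. Passing tests therefore demonstrate correctness of the
inference machinery under its own model class, not robustness to real
data pathologies.

All generators are pure functions of (parameters, seed) and restore the
caller's RNG state.

## Ortholog filtering and the supermatrix

`filter_single_copy()` keeps clusters with at most one protein per genome
and genome occupancy at least `min_occupancy` (default 0.5, inclusive:
"minimum representation of 50%" is read as an attainable bound, so 20 of
40 genomes passes and 19 fails). Redundant clusters — identical protein
membership — collapse to the first by cluster id. `rbh_filter()` then
requires every member's best-scoring hit in every co-member genome to be
the cluster's member there, in both directions; a tie with an
out-of-cluster protein fails conservatively, and clusters with missing
scores are reported unevaluable rather than silently kept. The
single-copy filter runs before the RBH filter, matching the stated
pipeline order. On planted cluster tables the chain's keep/reject
decisions reproduce the truth labels exactly.

`dayhoff_recode()` collapses the 20 amino acids into the six classical
Dayhoff exchange groups `{AGPST} {DENQ} {HKR} {ILMV} {FWY} {C}`, mapped
to symbols 0–5; the source names the recoding option but not the groups,
so the standard six-group table is fixed here. Ambiguity codes map to
missing; unknown symbols are errors naming the character.

## The likelihood engine, FcLM and RADICAL

`tree_loglik()` is plain Felsenstein pruning over pattern-compressed
alignments with per-node rescaling, under a reversible model
(`subst_model()`: Poisson/equal exchangeabilities by default, LG-style
PAML matrices loadable via `read_paml_matrix()`) and `k` equiprobable
discrete-gamma categories (default 4, shape 1). It matches an explicit
sum over all internal-state assignments to 1e−8 on small instances.

`optimize_quartet()` maximizes a quartet's likelihood by cyclic Brent
line searches over the five branch lengths (deterministic start 0.1,
log-likelihood tolerance 1e−6 per cycle, at most 100 cycles,
non-convergence flagged). Each one-dimensional search holds the other
four branches' partials fixed, which makes the per-evaluation cost one
transition matrix and one matrix product. `fclm()` samples quartets (one
taxon per cluster, without replacement; the whole combination space when
it is small), converts the three topology likelihoods to simplex weights
`p_i ∝ exp(ℓ_i − max ℓ)`, and bins them into seven regions. The region
geometry is a documented convention (the source does not define one):
vertex `p_i > 1/2`; edge `p_i, p_j ≤ 1/2` with the opposite `p_k < 1/4`;
center otherwise, i.e. boundary ties fall toward the less-resolved
region. With all three weights summing to one these regions partition the
simplex.

`radical()` shuffles gene order per replicate, concatenates growing
prefixes, estimates a tree at each size (default estimator:
neighbor-joining on closed-form ML distances under the engine's model;
any `alignment → tree` function can be plugged in), and records each
tree's split set. `fixation_points()` reports, per clade, the smallest
concatenation size from which the clade appears in every tree at every
larger size in every replicate, as a fraction of the gene count; clades
missing from any final tree are "unfixed". A perfect estimator can only
lower a clade's fixation point relative to a noisy one, and this is
tested.

## Reconciliation

`reconcile_dl()` implements duplication–loss parsimony with unit costs
under the LCA map: every gene leaf maps to its genome, every internal
node to the MRCA of its children's images. A node is a duplication iff it
maps to the same species node as one of its children. Losses on a gene
edge (u, v) count `d − 1` when u is a speciation and `d` when u is a
duplication (d = species-tree path length between the images), and each
loss is charged to the sibling branch pruned at the corresponding
intermediate node. Duplications are charged to the species branch
entering their image; duplications mapping to the species root go to a
virtual root branch, so pre-root copy numbers (the "MRCA of all fungi"
style rows) are well defined. Copy numbers then follow from the
conservation law, starting from one copy entering the branch above the
gene root's image; the implementation asserts that the law reproduces the
observed leaf counts. An exhaustive sweep over all gene trees with ≤6
leaves against species trees with ≤4 leaves (1446 cases) shows the cost
equals the minimum over every ancestor-consistent map computed by an
independent dynamic program.

Duplications mapping to a species *leaf* happen within that species; they
stay in the cost and the conservation bookkeeping but are reported
separately (`within_dups`) so per-branch D/L reports can exclude them,
following the convention that within-species events are not counted in
branch annotations.

`root_min_dl()` tries every edge of an unrooted gene tree as the root,
keeps the minimum-cost rooting, and breaks ties by fewer duplications,
then by the lexicographically smallest root bipartition — deterministic
by construction. Whether the original study rooted by outgroup or by
cost is unstated; cost-minimal rooting is the default here.

`rearrange_weak()` collapses internal edges with support strictly below
the threshold (default 70%) into polytomies and re-resolves them to the
cost-minimal binary topology. The search enumerates all joint resolutions
when their count is at most 20,000 (this covers polytomies up to degree
8, 10,395 resolutions); beyond that it hill-climbs over NNI moves on the
weak edges and flags the result heuristic. The input tree is always among
the candidates, so the output cost never exceeds the input cost.
`bootstrap_average()` reconciles each replicate tree independently
(optionally through `rearrange_weak`) and averages per-branch duplication
counts and exiting copy numbers arithmetically — the liberal counterpart
to the conservative rearranged estimate; presentation layers round copy
numbers to one decimal and duplication means to two.

One convention is worth flagging: the loss-attribution and copy-number
reporting of the reference reconciliation tool are not printed in its
accompanying text, so the conservation-law convention used here is
self-consistent and exhaustively tested, but may differ in formatting
from that tool's reports.

## Penalized-likelihood dating

`pl_objective()` scores a dated tree with branch rates by
`Σ_e [x_e log μ_e − μ_e − log Γ(x_e + 1)] − λ P`, where `x_e` is the
branch's observed substitutions (`length × sites`, treated as continuous
Poisson data since lengths arrive as real-valued substitutions/site),
`μ_e = r_e t_e`, and `P` penalizes rate differences across neighboring
branches (raw rates by default — the classical additive penalty — with a
`log_rates` option) plus the variance of the root-children rates.

`fit_chronogram()` parameterizes each free internal node's age as a
relative position between the largest fixed/min calibration in its
subtree and its parent's age (capped by any max calibration), so age
order and every calibration hold *by construction* — a fixed calibration
is returned bit-exactly, which the tests assert. Rates are optimized on
the log scale; the optimizer is bounded L-BFGS-B with an analytic
gradient obtained by a reverse sweep through the recursive age
parameterization, with seeded random restarts (default 5) and the best
objective kept. The convergence flag reports whether the projected
gradient norm at the optimum is below 1e−6. Identifiability requires at
least one fixed calibration or a max calibration at the root; infeasible
calibration sets (a lower bound above an upper bound on some path) are
rejected before optimization.

The `sites` option (default 10,000 in `fit_chronogram`; the literal
`pl_objective` formula keeps its neutral default of 1) states the
alignment width the branch lengths are treated as coming from, exactly as
one supplies the site count to classical penalized-likelihood dating
software. It sets the information content of the Poisson term relative to
the penalty: with per-site rates around 5e−4 substitutions/site/Ma, a
10k-site matrix makes branch data informative enough that strict-clock
simulations are recovered to well under 1% while the cross-validated λ
still controls smoothing on relaxed-clock data. Reported rates are
converted back to substitutions/site/Ma.

`cross_validate()` prunes one terminal at a time, refits, and predicts
the pruned branch's substitutions as the fitted rate of the branch it
attached to times the fitted age of its nearest surviving ancestor,
scoring `(x − x̂)² / max(x̂, 1e−6)` and summing over terminals; the λ
with the smallest score wins, ties to the smaller λ. The predicted
duration uses the nearest *surviving* ancestor because the pruned leaf's
own parent node does not exist in the pruned tree; this overestimates the
duration by a λ-independent amount, which cancels when comparing λ
values. On exactly clock-like noiseless data every λ admits the same
global optimum, so the CV curve is flat at large λ up to optimizer noise;
the tests therefore assert non-increase between the grid ends and an
upper-half selection rather than strict monotonicity. CV fits use one
optimizer start (the fits are convex in practice near the deterministic
start) to keep the 12-leaf × grid sweep fast.

## CAZy survey

`filter_hits()` applies the inclusive e-value cutoff (`≤ 1e−5` by
default: a hit exactly at the threshold passes) and drops hits without
the predicted functional domain, collapsing duplicate rows.
`copy_number_matrix()` counts distinct proteins per genome × family over
the full 20-family catalog (`cazy_catalog()`), with explicit zero rows
for genomes without hits; a protein assigned to two families counts once
per family and is flagged, since families are searched independently. The
catalog flags all nine pectin-specific families even though two of them
do not appear in the deep-ancestor copy-number table of the source;
reports can subset. Shrinking the e-value cutoff can only shrink matrix
entries, which is tested as a monotonicity property.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → survey → reconcile → date → report
with every stage seeded from one master seed by fixed offsets, halting
with the stage name on failure and writing a manifest with MD5 hashes of
every artifact; reruns under the same configuration are bit-identical.
The `analysis/` scripts are the narrative version of the same chain.

Default problem sizes were chosen once as the smallest that exercise the
statistics meaningfully: 10–12 genome species trees; 200–1000 simulated
families for event-recovery and conservation checks; 50 relaxed-clock
replicates (σ = 0.2, 12 taxa) for the dating study; 5000-site alignments
and 8 sampled quartets for likelihood mapping; 300 planted clusters and
200 planted genome×family counts for the filter chain.

## Known limitations

* Reconciliation assumes a binary, rooted species tree and ignores
  transfer events; gene trees containing genomes absent from the species
  tree are an error, not silently pruned.
* Parsimony reconciliation cannot see duplications whose descendants all
  died; simulated-truth comparisons therefore assert a one-sided bound
  (reconciled ≤ truth) plus high cross-branch correlation, not equality.
* The NNI fallback in `rearrange_weak()` is a local search; it is flagged
  heuristic, and the exhaustive path covers every polytomy the default
  cap admits.
* The dating model treats branch lengths as independent Poisson data;
  shared estimation error across branches (as arises from a single real
  alignment) is outside the model.
* The quartet engine assumes stationarity and reversibility; the Dayhoff
  recoding reduces but does not remove compositional artifacts.
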