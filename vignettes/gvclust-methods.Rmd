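---
title: "Methods: structure-informed orthogroup clustering and IP-MS interactome analysis"
author: "gvclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-informed orthogroup clustering and IP-MS interactome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvclust)
```

# Scope

`gvclust` analyses giant-virus proteomes along two axes: evolutionary
classification and physical interaction. It consumes *precomputed* tabular
outputs — pairwise sequence/structure similarity tables, taxonomy tables,
label-free MS abundance matrices, transmembrane predictor calls, PDB homology
hits and chain coordinates — and never runs an aligner, folding model or
search tool itself. Everything the package computes can be validated against
synthetic inputs with planted ground truth (`simulate_orthogroups()`,
`simulate_ipms()`, `simulate_complexes()`).

# Two-stage clustering and the connectivity merge

## Model

Orthogroups are built in two stages. Stage 1 clusters protein sequences on
identity >= 0.2 with coverage >= 0.7 *of both query and target* — the
stringent both-ways coverage rule that deliberately trades partial-homology
sensitivity for low false merging. Stage 2 clusters the predicted structures
of the stage-1 representatives at TM-score >= 0.4 and the same coverage rule;
every protein then inherits the structural cluster of its representative
(`compose_two_stage()`), so the cluster count can only shrink.

Because structural comparison of a single representative can miss clusters
that are in fact densely interconnected (the RNA-polymerase-subunit situation
that motivates the method), a third step re-examines *all* proteins: given an
all-vs-all structural search retained at TM-score > 0.4 and coverage > 0.7,
two clusters are merged when **more than 65%** of the members of one cluster
have at least one hit into the other (`link_fraction()`, `merge_clusters()`).

## Design choices

* **Clustering algorithm.** The upstream tools' internal clustering is not
  part of the tabular contract, so the package provides a deterministic
  greedy set-cover: candidates ordered by retained-edge degree (ties: longer
  protein if lengths are supplied, then lexicographic id), each representative
  claiming its unclaimed neighbours. This mimics the default behaviour of the
  cited cascade-clustering tools; a connected-components mode
  (`method = "components"`) gives the coarser alternative. Set-cover always
  refines components, which the suite checks as a property.
* **Strict threshold.** "Over 65%" is read as a strict inequality
  (`fraction > 0.65`). The smallest fraction that must still merge in the
  motivating four-pair example is 0.69, compatible with either reading;
  strictness makes the boundary case testable.
* **One-directional eligibility.** A pair merges if *either* direction
  exceeds the threshold, since the criterion speaks of the members of *one*
  cluster.
* **Single-pass eligibility + transitive closure.** Link fractions are
  evaluated once on the original clusters; eligible pairs are then closed
  transitively with union–find. Merging is therefore order-independent and
  matches a brute-force transitive-closure oracle on random instances. Note
  that the operation is *not* idempotent in general: after a union A∪B, the
  fraction of a third cluster C linked into the union can exceed the
  threshold even though neither pairwise fraction did. `iterate = TRUE`
  exposes the fixed-point variant for users who want that behaviour; the
  default single pass is the reference semantics.
* **Representative of a merged cluster** is the representative of its
  largest constituent (ties broken lexicographically), keeping labels stable.
* **E-values are not a clustering criterion**: only score and coverage
  thresholds are applied; e-values are carried through for reciprocal-best-hit
  mapping only.

## Comparing partitions

`compare_clusterings_nmi()` computes normalised mutual information with
arithmetic-mean normalisation `I(U;V) / ((H(U)+H(V))/2)`, restricted to the
proteins present in both clusterings — the default of the scikit-learn
implementation that is the de-facto standard for this comparison, and
identical to the definition used by `igraph::compare(method = "nmi")`, which
the test suite uses as an independent oracle. Two zero-entropy partitions
score 1 by convention; an informative vs a trivial partition scores 0.

# LCA taxonomic annotation

The LCA level of a cluster is the deepest of the eight ranks
(species < genus < subfamily < family < order < class < phylum <
superkingdom) at which all member genomes carry one identical, **non-absent**
taxon. Ranks that were never annotated (subfamily outside the one family
where it is assigned) can never be the LCA level — claiming conservation at a
rank nobody annotated would be vacuous. If even the superkingdom differs the
sentinel `"none"` is returned. A cluster is a *genus ORFan* when its LCA rank
is genus or species and the shared genus is the focal genus. Paralog counts
bin the focal genome's members per cluster into 1 / 2–5 / 6–10 / 11–20 / 21+.
`check_taxonomy_consistency()` warns when the input taxonomy is not
tree-shaped, which would make LCA levels ambiguous. No correction for
horizontal gene transfer is attempted.

# IP-MS differential enrichment

## Pre-processing

`preprocess_abundance()` applies, in order: contaminant removal; the
replicate filter (keep a protein quantified in >= 3 replicates of **at least
one** condition — the reading consistent with downstream imputation of values
"totally absent in the condition"; the stricter both-conditions reading is
available via `replicate_rule = "both"`); log2 transformation; per-sample
normalisation; imputation.

Normalisation `median_mad` centres every sample at median 0 and equalises
the per-sample spread at the **median MAD across samples** rather than at 1.
Scaling every sample to unit MAD would divide all log2 fold changes by the
cross-protein spread (several log2 units in typical MS1 data), silently
redefining the downstream `log2FC >= 1` selection rule; the variance-
stabilising normalisation it stands in for is approximately scale-preserving
on the log2 scale, and so is this. The `bait_median` variant centres every
sample on a reference protein (the bait), for experiments where bait levels
define the comparable scale.

Imputation distinguishes two missingness regimes per protein and condition:

* *partially observed in the condition* — predicted from the `k = 10` most
  correlated fully observed proteins (correlation over the columns where the
  target is observed), reading the missing cell off the neighbours' mean
  profile after a least-squares offset fit. With three replicates per
  condition a free-slope regression on one or two observed points is
  ill-posed, so the slope is fixed at 1 and only the intercept is fitted;
  this is the well-posed special case of neighbour-regression imputation.
* *totally absent in the condition* — the deterministic 2.5th percentile of
  each sample's observed values (multiplier 1), encoding the left-censoring
  interpretation of condition-wide absence.

## Testing and selection

`moderated_t_test()` is an empirical-Bayes two-sample test: per-protein
pooled variances `s2` on `d = n1+n2-2` degrees of freedom are shrunk toward a
prior, `s2_post = (d0 s0^2 + d s2)/(d0 + d)`, and the moderated t statistic
is referred to `d0 + d` degrees of freedom. `(d0, s0^2)` are estimated by
the classical method of moments on `log s2` (matching digamma/trigamma
moments of the log-F distribution, trigamma inverted by Newton iteration);
when the observed spread of `log s2` does not exceed the sampling spread,
`d0` is capped at `1e6` to represent complete shrinkage, with
`s0^2 = mean(s2)`. The test suite verifies exact agreement (1e-10) with both
a from-the-formulas re-derivation and the reference empirical-Bayes
implementation in `limma`, and that forcing `d0 = 0` recovers the ordinary
pooled t-test.

Selection applies `log2FC >= 1` and raw `p < 0.01`; any selected protein
quantified (pre-imputation) in fewer than 3 replicates of its more-abundant
condition is invalidated — p reset to 1, deselected. Benjamini–Hochberg
adjusted p-values are reported for audit only; they play no role in
selection.

# Bait networks and communities

The bait summary graph weights each bait pair as `Nc + 10 * Ndc`: `Nc` shared
selected interactors, `Ndc` in {0, 1, 2} the number of directions in which
one bait is itself found among the other's interactors (post-invalidation
sets by default). Zero-weight edges are absent. Community detection is
weighted Louvain (`igraph::cluster_louvain`) under a caller-supplied seed
(default 0); labels are canonicalised to the smallest member id, and the
suite checks agreement with exhaustive modularity maximisation on six-node
graphs. The annotated global network attaches per-node origin, region,
functional category and expression cluster; viral proteins with several
region labels resolve by the precedence membrane > nucleoid > vf_il >
virion, host proteins are always region `host`, and unlabelled viral preys
are `virion_unassigned`.

# Enrichment machinery

`fisher_exact_2x2()` reports the *sample* odds ratio `ad/bc` (`Inf` when
`bc = 0 < ad`, `NaN` when both diagonals vanish) with the exact conditional
p-value computed from the hypergeometric distribution; the two-sided p sums
all fixed-margin tables whose probability does not exceed the observed
table's (relative tolerance 1e-7, the usual guard against floating-point
ties). GO enrichment runs a one-sided (greater) test per term against the
background with Bonferroni correction over tested terms, using annotations
exactly as supplied — no ontology propagation; pre-expanded annotation
tables plug in unchanged. Consensus transmembrane calling requires >= 2 of
the configured predictors. The nucleoid spectral-count filter requires >= 2
peptides and either nucleoid-only detection or a nucleoid/virion ratio >= 2,
evaluated separately for pellet and supernatant and OR-ed; a zero virion
count is handled by the "only detected in nucleoid" branch, avoiding the
division. Reciprocal best hits take the unique lowest-e-value hit in each
direction, with deterministic tie-breaks (higher score, then lexicographic
id) since upstream tools do not document their tie handling.

# PDB complex mapping

Complex hits are ranked by the number of chains with at least one query
homolog and greedily grouped by cosine similarity of binary homolog-set
incidence vectors (`|a∩b|/sqrt(|a||b|)`); the grouping threshold defaults to
0.8 — not specified upstream, exposed as a parameter — and the group
representative is the highest-ranked member. Interface contacts connect
homolog-labelled chains whose *minimum inter-chain point distance* is
strictly below 8 Å. "Interface surface distance" is implemented as that
minimum over the supplied points (all-atom or C-alpha; no surface is
computed). The scan is exact and vectorised in blocks, with a coarse-grid
prefilter for clouds above ~25 million point pairs; the suite checks it
against the O(n·m) loop and under joint rigid motions.

# What the generators emulate — and what they do not

`simulate_orthogroups()` plants orthogroups over a tree-consistent random
taxonomy (subfamily annotated in a single family, reproducing the
partial-rank situation), with within-group similarity above the clustering
thresholds and between-group background below them. Planted splits cut a
group into two halves connected only in the merge-search table, at a link
fraction drawn strictly above 0.65 in one direction, so the merge step must
rejoin exactly those pairs. Noise is modelled as independent dropout of
within-group sequence edges plus optional spurious above-threshold
between-group edges; structure tables stay clean, so dropout specifically
exercises the rescue of fragmented sequence clusters by the structure stage.
Score distributions are placed above/below thresholds uniformly — no attempt
is made to mimic real TM-score or identity distributions, so passing tests
demonstrate the *logic* of the pipeline, not calibration against real
structural data.

`simulate_ipms()` draws protein baselines uniformly on log2 [20, 30]
(spanning a typical MS1 dynamic range) with log-normal replicate noise at
CV 20%, a 3 vs 3 design, spikes shifted by +2 log2 units in the bait
condition, and missingness as left-censoring below log2 intensity 21
(roughly the bottom tenth of the range) plus 2% completely-random dropout.
It does not model peptide-level effects, shared peptides, protein groups or
intensity-dependent variance, so FDR/sensitivity results transfer to real
data only to the extent that the moderated test's assumptions hold there.

`simulate_complexes()` places compact ~30-point chain clouds with planted
contacts at 4.5–7.5 Å and all other chain pairs beyond 10 Å; it checks
geometric feasibility and fails loudly rather than silently violating the
planted truth.

All generators are pure functions of their parameters and a single integer
seed.

# Validation problem sizes

The test suite and the acceptance script run, by design, at desk scale:
orthogroup recovery on 20–30 genomes and 15–30 groups (20 seeds for the 10%
dropout condition), the null calibration on 10,000 proteins in a 3 vs 3
design, spike-in recovery on 1,000 proteins with 50 spikes over 20 seeds,
brute-force oracle sweeps on instances up to 200 proteins (merge), 40
genomes (LCA), table totals up to 40 (Fisher) and six-node graphs
(exhaustive modularity). These sizes were chosen to make every oracle
exhaustive or near-exhaustive while keeping a full validation run in the
low minutes on a single core.

# Known limitations

* The greedy set-cover is a stand-in for the (unspecified) internal
  clustering of the upstream tools; on identical edge sets different
  cascade implementations can produce different partitions, which is exactly
  what the NMI comparison is for.
* LCA annotation inherits every bias of the input taxonomy and is blind to
  horizontal transfer.
* The moderated test assumes exchangeable per-protein variances around one
  prior; intensity-dependent variance trends are not modelled (no covariate
  trend fitting).
* Louvain is seed-dependent on graphs with near-degenerate modularity
  optima; the seed is part of the configuration and recorded in run reports.
* Cosine grouping of complexes is greedy, not agglomerative; with highly
  overlapping homolog sets the grouping depends on rank order, which is
  deterministic but threshold-sensitive.
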