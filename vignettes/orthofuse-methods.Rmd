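---
title: "Ensemble ortholog integration: model, metrics, and design choices"
author: "orthofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble ortholog integration: model, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthofuse)
```

## The problem

Ortholog detection (OD) methods — tree-based, graph-based, synteny-aware,
alignment-based — disagree. For a given reference gene (say, a human
protein), each method proposes at most one ortholog per target species, and
no single method dominates: each one misses genes the others find and
occasionally returns an in-paralog or an unrelated sequence. For downstream
comparative analyses (alignment quality, gene trees, tests of positive
selection) what matters is the *set* of sequences entering the multiple
sequence alignment, so pooling the methods and selecting the best candidate
per species can outperform every individual method.

orthofuse casts this selection as cluster optimization on a graph. For one
reference gene:

1. every proposed candidate becomes a node, annotated with its species and
   proposing method;
2. edges carry pairwise sequence similarities (candidate-to-reference
   always; candidate-to-candidate only when the weighting requires them);
3. clearly non-orthologous nodes are removed with species-specific
   similarity cutoffs;
4. at most one node per species is selected so that the weighted sum of
   pairwise similarities among the selected sequences (reference included)
   is maximal.

## The objective and its weighting

Let $C$ be a selection containing the reference $r$ and at most one
candidate per species. The objective is

$$ f(C) \;=\; \sum_{\{i,j\} \subseteq C} w(s_i, s_j)\, \mathrm{sim}(i, j), $$

where $s_i$ is the species of sequence $i$ and $w$ is a non-negative
species-pair weight. Three weighting modes are provided:

* **reference_only** (the default): $w(r, s) = 1$ and all other weights 0.
  The objective then decomposes per species, and optimization reduces to
  independently taking, for each species, the candidate most similar to
  the reference. This is the mode used for the shipped defaults: it needs
  no candidate-candidate alignments, which is what keeps genome-scale runs
  (tens of thousands of reference genes) affordable.
* **uniform_pairwise**: all cross-species pairs weigh 1, i.e. the total
  (equivalently, average) intra-cluster similarity is maximized.
* **custom**: explicit per-pair weights.

Similarity is pluggable (`register_scorer()`): any function from an aligned
pair to $[0,1]$ is accepted. The default `perID` scorer is
reference-denominated percent identity.

## Percent identity, precisely

Given a global alignment of reference and candidate, percent identity is
the fraction of *reference* residues whose aligned partner is the identical
residue. Columns where the reference row carries a gap — deletions in the
reference or insertions in the candidate — are ignored; a candidate gap
opposite a reference residue is a mismatch. For example:

```{r}
percent_identity(aligned_pair("AWVA-TFD", "-WVRYTFD"))
```

Five of the seven reference residues match (the leading candidate gap and
the `A`/`R` substitution are the two mismatches; the `-`/`Y` column is
ignored), i.e. 71% to the nearest percent. The score is intentionally
asymmetric: the pipeline always denominates in the configured reference
species. Where a symmetric quantity is unavoidable — candidate-candidate
edges under pairwise weighting — the edge takes the mean of the two
directed scores, which stays in $[0,1]$.

Pairwise global alignment itself is standard machinery and is delegated to
Biostrings' Needleman–Wunsch implementation. The parameters live in
configuration (`align_params()`), defaulting to BLOSUM62 with affine gaps
(opening 10, extension 0.5, the familiar protein-alignment defaults). The
dynamic program resolves co-optimal tracebacks by a fixed rule, so results
are reproducible; the test suite verifies returned alignments against an
exhaustive enumeration oracle on short strings.

For *assessment* (as opposed to optimization), `msa_percent_identity()`
scores two rows of a full MSA exactly as aligned — no pairwise realignment
— so that the quality metric reflects the MSA the downstream analyses
actually consume and stays separated from the quantity being optimized.

## Pre-integration cutoffs

Gene loss and duplication mean some proposals are not orthologs at all.
Before optimization, every node whose similarity to the reference falls
below its species' cutoff is removed. The shipped defaults
(`cutoff_table()`) are percent-identity thresholds for a human reference —
chimp 0.82, gorilla 0.77, orangutan 0.75, rhesus 0.73, and 0.70 for any
other species — chosen from genome-wide divergence levels; they are plain
configuration and should be re-derived (e.g. against the quality metrics
below) for other clades. A node exactly at its cutoff is **retained**: the
filter removes what is *below* the threshold. A species whose nodes are all
filtered out is simply absent from the integrated cluster; because all
similarities are non-negative, inclusion of a surviving node can never
lower the objective, so absence is never offered as an optimizer move when
nodes exist.

## Cyclic coordinate descent

With $m$ methods and $s$ species there are up to $m^s$ selections
(`search_space_size(4, 10)` is 1,048,576 — over a million per reference
gene), so exhaustive search is infeasible at genome scale. `ccd_optimize()`
instead improves one coordinate (one species' choice) at a time:

1. draw a random initial node per species;
2. sweep the species in a freshly drawn random order, replacing each
   species' choice with the node maximizing the objective given all other
   current choices;
3. stop when a full sweep changes nothing;
4. repeat from new random starts (default 20 restarts) and keep the best.

Every accepted move strictly increases the objective and the state space is
finite, so convergence is guaranteed — the implementation asserts the
monotone trace rather than imposing a timeout, and returns the trace for
inspection. Under reference-only weighting every restart lands on the
per-species argmax, and the suite verifies that best-of-20-restarts attains
the exhaustive optimum on random pairwise-weighted instances.

Numerical choices: objective comparisons use an absolute tolerance of
$10^{-12}$; ties among equal-objective candidates are broken by a
configurable method-priority list and then lexicographic sequence id. At
numerically equal gain the optimizer still moves toward the tie-break
winner (never away from it), which makes the selected node deterministic —
independent of the random initialization — without breaking monotonicity.
With a fixed seed the entire procedure is bit-identical across runs.

## Quality metrics

* `head_to_head()` — method A beats method B on an ortholog slot when its
  percent identity is at least five percentage points higher (boundary
  inclusive; a $10^{-9}$ guard absorbs binary floating-point noise);
  anything closer is a tie.
* `normalized_rf()` — gene-tree/species-tree concordance. Both trees are
  treated as unrooted, pruned to their shared leaves (at least four
  required), and compared by the unweighted Robinson–Foulds distance: the
  number of non-trivial splits present in exactly one tree, normalized by
  the sum of the two trees' split counts. Trivial (single-leaf) splits are
  not counted. Pruning is the only well-defined treatment when a species is
  missing from a gene tree; rooted inputs are accepted and unrooted
  internally since gene trees from standard ML software carry no meaningful
  root.
* `rf_cdf_auc()` — a genome-wide summary: the exact area under the
  right-continuous empirical CDF of normalized RF distances over
  $[0, 0.4)$. Relative to "fraction of genes below a threshold" this
  up-weights small distances instead of weighting everything below the
  cutoff equally; beyond 0.4 the curves of competing methods barely differ,
  hence the limit.
* `functional_concordance()` — binary agreement of top protein-family
  annotations (e.g. Pfam top hits), `UNDEFINED` when either sequence lacks
  one.
* `pss_overlap()` — Jaccard overlap of (gene, site) sets of positively
  selected sites; undefined on two empty sets.

## Selection-analysis post-filters

Site-level selection estimates (dN/dS per site, from external sitewise
likelihood software) are post-processed as follows:

* `mask_low_confidence()` keeps MSA columns whose alignment confidence is
  at least 0.95 and maps kept columns to ungapped reference coordinates;
* `call_pss()` calls a positively selected site when it is flagged, its
  estimate carries confidence of at least 0.95, and it lies in a kept
  column — raising either threshold can only shrink the called set;
* `exclude_dnds_outliers()` drops gene-level dN/dS estimates strictly
  greater than 3, where model fits occasionally concentrate implausible
  selection on a handful of sites;
* `aic_select()` picks among non-nested codon models by
  $\mathrm{AIC} = 2k - 2\ln L$, ties to fewer parameters.

Boundary conventions are deliberately explicit because only the strict side
of each rule is commonly stated: confidence exactly 0.95 is kept, dN/dS
exactly 3 is kept, similarity exactly at a cutoff is kept. The stored
`confidence` column is a generic $[0,1]$ score; for sitewise
likelihood-ratio outputs it may equally encode $1 - p$ from the
significance test — the filters are agnostic to that reading.

`match_species()` intersects the species sets of two alignments so that
matched-taxon comparisons between two ortholog sets feed identical samples
to the external model fitting.

## The synthetic generator

Real proposal sets require running four external OD pipelines over whole
proteomes, so the package ships a seeded generator (`sim_config()`,
`simulate_family()`) that emulates the pipeline's inputs with planted
ground truth. A random reference protein is drawn; each species' true
ortholog is derived by i.i.d. per-site substitution at the species'
divergence, and an in-paralog decoy at divergence plus
`decoy_extra_divergence`; each mock method then independently returns the
true ortholog, the decoy (probability `p_decoy`), or nothing (`p_miss`).

Defaults, chosen once as a realistic mammalian scenario with a human
reference: nine species at divergences 0.02 (chimp) through 0.20 (cow,
horse) — bracketing typical protein-level divergence from human across
primates and laurasiatherians — four methods, `p_miss = 0.1`,
`p_decoy = 0.2`, `decoy_extra_divergence = 0.15`, 200-residue proteins.
`recovery_rate()` runs the full pipeline over many families and reports the
fraction of slots where the planted ortholog was selected, among slots
where it was proposed and survived the cutoffs; under the defaults (200
families in the acceptance suite) recovery exceeds 95%.

The i.i.d. substitution model (uniform over the 19 alternative residues,
no rate heterogeneity) is chosen for determinism and analyzability —
expected identity is simply $1 -$ divergence, which the suite checks at
1000 sites. An optional geometric-indel mode exercises the alignment path.
What the generator does *not* emulate: realistic substitution processes and
codon structure, rate variation across sites, domain-level events, shared
evolutionary history among decoys, alignment-confidence structure, or the
error modes of real OD pipelines. Passing tests therefore demonstrate that
the machinery — graph construction, filtering, optimization, bookkeeping —
is correct and that selection-by-similarity resolves paralogy when the true
ortholog really is closer; they do not certify genome-scale accuracy on
real proteomes.

One subtlety the tests make explicit: with `decoy_extra_divergence = 0`
the true ortholog and the decoy are statistically identical, so in slots
where both actually compete the selection is a coin flip (recovery about
0.5 there); slots where every method happened to return the true ortholog
are won trivially and pull the marginal rate above one half.

## Problem sizes and runtime

The test suite keeps exhaustive oracles exhaustive but small: alignment
enumeration on strings of length at most four, brute-force cluster
enumeration on up to four species and three methods (at most $3^4 = 81$
selections), 100 random instances for the optimizer-equivalence check, all
105 pairs of five-leaf unrooted topologies for the RF oracle, and 200
simulated families for the end-to-end recovery check. These sizes give the
properties room to fail while keeping a full run in minutes on one core.

## Known limitations

* Percent identity saturates for distant species; substitution-matrix or
  profile-HMM scorers are preferable there and are supported via the
  scorer registry, but none is shipped beyond `perID`.
* The optimizer never drops a surviving node, which is optimal for the sum
  objective but would not be for a normalized (per-pair averaged)
  objective; such an objective is not provided.
* Gene loss, duplication histories, horizontal transfer and incomplete
  lineage sorting are out of scope: the similarity cutoffs are the only
  guard against non-orthologs, and reconciliation belongs to dedicated
  tools downstream.
* `read_proposals()` treats each reference transcript as an independent
  gene; mapping between transcripts of the same locus is left to the
  caller.
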