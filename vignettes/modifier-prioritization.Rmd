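---
title: "Prioritizing phenotype-modifier genes with heterogeneous network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing phenotype-modifier genes with heterogeneous network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Monogenic diseases such as neurofibromatosis type 1 (NF1) show wide
expressivity: patients carrying the same causal mutation range from mild to
severe presentations. Part of that variability is attributed to
*phenotype-modifier genes* — genes whose variation alters the severity of the
phenotype without causing the disease. Direct discovery (family studies,
GWAS, animal models) is slow and expensive; `modnet` implements an in-silico
prioritization pipeline that triangulates candidate modifiers from public
resources:

1. **Ontology selection.** Gene sets are assembled from two complementary
   directions: gene-function annotations (GO biological process, read from
   GAF files) for a *forward genetics* view, and phenotype annotations (HPO
   `genes_to_phenotype` tables) for a *reverse genetics* view. Term choice is
   an explicit curated ID list; the package deliberately does not do
   ontology-graph reasoning — a curated list of upper-level terms stands in
   for ancestor closure.
2. **Network statistics.** Protein–protein interaction networks are built
   from STRING-dialect links tables, restricted to each selection (plus the
   disease gene's first neighbors), and candidates are ranked by centrality.
3. **Expression evidence.** A differential-expression contrast of
   disease-gene knockdown data is combined with a phenotype-aware network
   propagation to find *active subnetworks*, and direct interactors of the
   disease gene with perturbed expression become additional candidates.
4. **Random-walk ranking.** All candidates are ranked against the phenotype
   node of a heterogeneous gene–phenotype network by minimum interaction
   steps and random-walk-with-restart (RWR) proximity.
5. **Variant summaries.** Published variant-classification count tables
   (gnomAD annotation classes, ClinVar clinical-significance classes) are
   summarized with totals, truncated percentages and per-class top genes.

## Models and statistics

### Centralities and the selection rule

Betweenness is Brandes' accumulation over unweighted shortest paths with
pair normalization $2/((N-1)(N-2))$; closeness is the Wasserman–Faust
composite $\frac{r-1}{\sum d}\cdot\frac{r-1}{N-1}$ (with $r$ the reachable
set including the vertex itself), which penalizes small components and gives
isolated nodes 0. Path computations are always unweighted — the convention
of the desktop network-analysis tools this pipeline mirrors — and STRING
combined scores are kept only as edge metadata. HITS hub/authority scores
are computed per connected component and L2-normalized; on an undirected
graph the two coincide analytically, but both are reported because the
upstream literature reports them separately.

The published analysis selected six genes per strategy from centrality
plots without stating a rule. The package operationalizes this as: rank
genes by the mean of the two centralities' min–max-scaled *ranks*
(descending), break ties by higher degree and then lexicographic symbol,
and take the top `k` (default 6). Using ranks rather than raw values makes
the selection invariant to any monotone rescaling of either centrality,
which a rule based on the raw values would not be.

### Differential expression

`dge_contrast()` offers two statistics on log2 expression. The default,
`method = "moderated"`, is limma's empirical-Bayes moderated t — the
standard choice at the n = 5-per-group scale of knockdown assays, where
variance moderation is what makes per-gene tests usable.
`method = "welch"` is a plain Welch two-sample t with Welch–Satterthwaite
degrees of freedom, kept as a closed-form reference implementation that is
cross-checked against `stats::t.test` in the test suite. Both report
logFC = case − control and Benjamini–Hochberg q-values via
`stats::p.adjust`. At the calibration conditions used throughout the tests
(planted log2 effect 2, noise sd 0.5, 5 samples per group, 50 genes) the
moderated test recovers essentially all planted genes at FDR 0.05 while the
Welch test loses roughly a quarter of runs to the BH threshold; that
difference is why moderation is the default rather than an option.

### Phenotype propagation and active subnetworks

`propagate_phenotype()` runs an RWR from the uniform distribution over
phenotype-associated genes on the column-normalized adjacency: $p \leftarrow
(1-r)\,W p + r\,p_0$, iterated to an L1 tolerance of $10^{-10}$; mass in
dangling (isolated) columns is returned to the restart distribution so the
iterate is exactly L1-normalized at every step. The default restart 0.7
follows the disease-gene-prioritization literature.

Per-gene DE evidence is the signed normal quantile
$z = \Phi^{-1}(1-p/2)\,\mathrm{sign}(\mathrm{logFC})$ (genes missing from
the DGE table get $z = 0$); the reported `combined` column is
$z \cdot \text{relevance}$, whose sign encodes up/down regulation for
attribute exports. The subnetwork *search*, however, aggregates an unsigned
weight $w_i = |z_i| \cdot \mathrm{rank01}(\text{relevance}_i)$. Two design
choices deserve explanation:

* **Unsigned aggregation.** The scenario the rule must detect is a
  down-regulated disease gene surrounded by up-regulated responders; a
  signed sum cancels exactly there, so module coherence is defined by
  perturbation magnitude, not direction (direction is still reported).
* **Ordinal relevance gating.** RWR probabilities decay exponentially with
  distance from the phenotype genes: used raw, the phenotype gene alone
  carries ~85% of any module's score, the other members become noise, and a
  permutation that happens to drop a large $|z|$ on any high-relevance node
  reproduces the observed score — destroying both recovery and power. The
  min–max-scaled average rank keeps phenotype proximity as a soft gate
  while letting every perturbed member contribute comparably.

The greedy search starts from each top-decile node by weight and adds the
neighbor maximizing $S = \sum_i w_i / \sqrt{|S|}$; growth is unconditional
up to `min_size` (default 3) and then continues only while $S$ improves, up
to `max_size` (default 30). The unconditional phase matters: with the
$\sqrt{|S|}$ penalty, a dominant first node would otherwise veto all growth
and no subnetwork could ever reach the minimum size.

Significance uses a max-statistic permutation null: the $z$ column is
shuffled across nodes (`n_perm` times, default 1000; relevance and the
network are held fixed), the full search is re-run, and the best score per
permutation forms the null. A subnetwork's empirical p is
$(1 + \#\{\text{null} \ge S\})/(n_\text{perm}+1)$. Re-running the search —
rather than re-scoring the observed gene set — is what makes the p-value
honest for a greedily *selected* set; on null data the top module's p is
uniform (Kolmogorov–Smirnov p ≈ 0.9 in the calibration tests). Retained
subnetworks (p < `alpha`) with Jaccard overlap > 0.5 are merged.
Permutation of node scores (not expression columns) is deliberate: it tests
the exceptionality of the subnetwork score given the DGE results, not the
validity of the DGE itself.

An *expression-derived candidate* must satisfy three conditions at once:
significant differential expression, membership in a retained subnetwork,
and a direct interaction with the disease gene.

### Heterogeneous random walk and step counts

`build_hetero()` assembles the column-stochastic supra-transition matrix of
a two-layer walk: from any node with at least one bipartite gene–phenotype
link the walker crosses layers with probability `jump` (uniform over its
links) and otherwise moves uniformly within its layer; nodes with only one
kind of move use it with probability 1. The defaults `jump = 0.5` and
`restart = 0.7` follow the multiplex-heterogeneous RWR literature; both are
exposed in the configuration. `rwr_scores()` power-iterates the restart
fixed point to L1 tolerance $10^{-10}$ (it agrees with the dense solve
$(I-(1-r)W)^{-1} r\,p_0$ to $10^{-8}$ in the tests) and accepts any node —
gene or phenotype — as the restart seed; ranking candidates *against the
phenotype* seeds the walk at the phenotype node. "Steps" are unweighted
breadth-first path lengths in the heterogeneous graph, matching the
"one interaction = one step" reading; candidates sort by (steps ascending,
RWR score descending, symbol).

### Variant-count arithmetic

Percentages are *truncated* toward zero at one decimal, not rounded: this
is the unique convention consistent with all published figures given their
printed counts (e.g. 2425/5216 = 46.49% printed as 46.4, and 80/334 =
23.95% printed as 23.9). Missing cells ("-") are absent, not zero, and are
excluded from totals and denominators — a gene absent from a database must
not deflate its percentages.

## The synthetic-data generator

Because the original database snapshots (2020-era STRING, GO, HPO, GEO)
are not reproducible, every stage is validated on synthetic data with
planted ground truth:

* `gen_ppi_network()` builds preferential-attachment communities joined
  *only* through designated bridge nodes (each anchored to `attach` nodes
  per side), guaranteeing by construction that a bridge mediates every
  cross-community shortest path and therefore dominates betweenness —
  the structural contrast the forward/reverse selection exploits. A seed
  (disease) gene is the first community's hub; planted neighbor-modifiers
  are wired directly to it.
* `gen_annotations()` draws two namespaces whose gene unions have a
  controlled Jaccard overlap: union size $u = \min(\lfloor N(1+f)/2\rfloor,
  \text{terms}\times\text{size})$ with a shared block of $s = 2uf/(1+f)$
  genes gives Jaccard exactly $s/(2u-s) = f$ up to integer rounding. An
  `include` argument forces designated genes (the disease gene and planted
  modifiers) into both unions, mirroring the fact that curated disease
  ontologies necessarily cover the disease gene.
* `gen_expression()` simulates log2 expression with gene-specific baselines
  (uniform 5–10), Gaussian noise, a planted group-mean difference for the
  modifier genes, and a *down*-shift of the seed gene in the knockdown
  group. Defaults (effect 2, sd 0.5, 5 per group) are calibration settings,
  not estimates from any real assay; no count model or normalization step
  is emulated.
* `gen_pheno_links()` links the seed gene to the true phenotype and adds
  decoy phenotype links.

All generators are pure functions of their arguments including `rng_seed`
(the caller's RNG state is saved and restored). What the generator does
*not* emulate — somatic mutation calls, tumor heterogeneity,
tissue-specific expression, annotation bias, literature-curation noise —
bounds what passing tests show: they demonstrate that the pipeline recovers
the structures it is designed to find when those structures are present,
not that such structures are detectable in any particular real cohort.

## Problem sizes and numerical choices

The test-suite batteries use: 200 random graphs of 4–8 nodes for the
brute-force centrality oracles; 20 heterogeneous instances of ≤ 20 nodes
for the dense RWR solve; 1000 random p-vectors for the BH step-up oracle;
and 100 independent synthetic studies (50 genes, 2 neighbor-modifiers,
1 bridge, 5 samples per group) with 199 permutations per subnetwork search
for the recovery and calibration checks. These sizes were chosen so each
battery pins down its property while the whole suite stays interactive
(~1 minute). Convergence tolerances are $10^{-10}$ (L1) for all fixed-point
iterations with a 10^4^ iteration cap and an error, not a silent result, on
non-convergence. Ties are always broken deterministically (degree, then
symbol) so runs are bit-for-bit reproducible given a configuration.

## Known limitations

* Gene identity is the upper-cased symbol; no alias or cross-reference
  resolution is attempted, so inputs must already agree on symbols.
* The STRING channel filter follows the UI semantics (evidence channel
  strictly positive, cutoff on the combined score, inclusive at the
  threshold); a `cut_on = "channel"` switch covers the other reading, since
  the upstream description is ambiguous.
* Hub and authority cannot genuinely differ on an undirected PPI network;
  reported differences in upstream tools presumably reflect implementation
  details that are not reproduced here, and no attempt is made to force
  distinct leaders.
* The active-subnetwork stage is this package's own defined, testable
  procedure standing in for a desktop application invoked "with default
  settings" upstream; it is parameterized so each piece (propagation,
  search, null) is independently checkable, but it is not a re-implementation
  of that application.
* Whether published step counts derive from BFS or thresholded RWR
  neighborhoods is not documented upstream; BFS is the package's documented
  choice, with the RWR score as tie-breaker.
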