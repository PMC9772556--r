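---
title: "Methods: linking lectin-microarray glycomics to glycogene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking lectin-microarray glycomics to glycogene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycolink)
```

## The problem

Protein glycosylation is shaped by the balance of the enzymes that build,
trim and decorate glycans, and is read out experimentally in two very
different ways: *lectin microarrays*, where carbohydrate-binding proteins
report the abundance of the glycan motifs they recognize, and
*transcriptomics*, where the expression of glycosyltransferases (GTs),
glycoside hydrolases (GHs) and glycan-binding proteins is measured
directly. In two-group designs — here modelled on the prenatal
valproic-acid (VPA) rat model of autism, with a VPA-exposed and a
saline-control group — the interesting question is whether the two layers
move together: does a drop in a sialyltransferase transcript coincide with
less sialylated Gal/GalNAc on the arrays?

glycolink implements that integration end to end: array normalization and
fold-change calling, curated glycan-gene list assembly, identification of
differentially expressed glycan-related genes (DEGGs), motif-level
concordance between the two layers, and the supporting statistics
(over-representation analysis, Markov network clustering, behavioural
two-group tests). Every stage can also be driven by seeded synthetic data
with known ground truth.

## Lectin microarray model

Each slide carries blocks in which every lectin is printed in triplicate.
The processing chain per block is:

1. **Detection filter.** With block background mean $\bar b$ and standard
   deviation $s_b$ (computed from the spots' local-background channel), a
   spot is *effective* iff its foreground $F \ge \bar b + 2 s_b$; effective
   values are $F - \bar b$. We read the published "average background ± 2
   SD" rule as this one-sided detection floor: the lower branch
   ($\bar b - 2 s_b$) would never remove anything the upper branch keeps.
   Equality survives the filter. A lectin whose spots are all removed is
   flagged below detection, carries no NFI, and is excluded from the
   normalization denominator rather than zero-filled.
2. **Median-ratio normalization.** The normalized fluorescence intensity
   (NFI) of lectin $\ell$ is
   $\mathrm{NFI}_\ell = m_\ell / \sum_{k} m_k$, where $m_\ell$ is the
   median of the lectin's effective values and the sum runs over the
   lectins present in the block. Block NFIs therefore sum to 1 and are
   invariant to rescaling all intensities of a block.
3. **Aggregation.** Slide NFI (mean over blocks) → sample NFI (mean over
   the sample's replicate slides, three in the reference design) → group
   NFI (mean over samples). Background statistics are computed per block,
   matching the per-block scope of the normalization.
4. **Signed fold change.** With group means $c$ (control) and $v$ (case),
   $\mathrm{FC} = v/c$ if $v/c \ge 1$, else $-c/v$; there is no value in
   $(-1, 1)$, $\mathrm{FC}(a,a) = 1$, and the statistic is antisymmetric
   under swapping the groups. Lectins are called up at
   $\mathrm{FC} \ge 1.2$ and down at $\mathrm{FC} \le -1.2$ (inclusive,
   matching the published wording).

The packaged reference table (`lectin_nfi_vpa.tsv`) carries the 14
significantly regulated lectins of the VPA study with their printed group
NFIs and fold changes. Several printed fold changes are not exactly
reproducible from the rounded NFIs (e.g. MAL-I: $0.014/0.024$ gives
$-1.71$ where $-1.72$ is printed), so significance calls on this table use
the printed fold-change column; recomputation from the NFI pair is exact to
two decimals for ConA, GSL-II, DSA, PTL-I and Jacalin.

## The curated glycan-gene list

The reference list contains 961 unique rat genes in eight groups — 259
GTs, 94 GHs and 7 carbohydrate-binding modules from CAZy; 125 other
anabolic-pathway enzymes, 128 lectins, 116 GPI-anchored proteins, 48
proteoglycans and 184 glycosaminoglycan-binding proteins from KEGG.
Assembly (`assemble_gene_list()`) validates the group vocabulary,
deduplicates by NCBI GeneID (first-listed group kept, families and sources
merged — multi-function enzymes are grouped by catalytic activity rather
than listed twice), and recomputes category totals from the deduplicated
set, so totals always conserve the record count and assembly is
idempotent.

The full membership of the CAZy/KEGG category enumerations is not public
at the level of a reprintable table, so the packaged fixture is
deliberately two-part: the genes named in the published DEGG tables keep
their printed GeneIDs and functional families, and the remaining category
slots are filled with clearly synthetic placeholders (GeneIDs ≥ 9,000,000,
symbols `GLYnnnn`) generated deterministically by `build_gene_table()`.
Per-family counts are fixed where the published organization table states
them (the KEGG-derived groups); the CAZy groups state only group totals.

## DEGG identification

A DEGG is a gene of the curated list with FDR-adjusted $p < 0.05$
(strict, per the published wording) in the two-group comparison.
External DE tables are trusted as-is; `readjust = TRUE` recomputes the BH
adjustment from the raw p-values. Identifier resolution tries GeneID
first, then case-insensitive symbol. Signed fold changes are derived from
$\log_2$ fold changes by the bijection $2^{x}$ / $-2^{-x}$, and the
1.5-fold filter is inclusive on both sides.

For synthetic runs the package provides a minimal two-group
negative-binomial Wald test (`nb_de_test()`): median-of-ratios size
factors, method-of-moments dispersion, and a delta-method Wald statistic
on the log ratio of normalized group means. At $n = 3$ per group the
per-gene moment estimator of dispersion is far too noisy to use alone —
the plain per-gene version is visibly anticonservative — so the working
dispersion is the maximum of the per-gene estimate and the across-gene
median (floored at $10^{-8}$), after which the empirical type-I error at
$\alpha = 0.05$ sits near nominal (0.04–0.05 in the packaged null
simulations). This estimator is a deliberately small, transparent stand-in
for a full shrinkage-based DE framework and is intended for generator
validation, not for real data; a test cross-checks its fold changes and
calls against DESeq2 on a common synthetic dataset.

Expression heatmaps are ordered by agglomerative clustering with distance
$1 - r$ (Pearson, across samples, rows standardized by default) and
average linkage; the cited heatmap software does not state its defaults,
so these common ones were chosen and are verified in the tests against a
naive $O(n^3)$ agglomeration oracle. A constant row has no defined
correlation and is placed at the maximum distance 2 with a warning. qRT-PCR
verification values use the standard $\Delta\Delta C_t$ statistic with
relative expression $2^{-\Delta\Delta C_t}$.

## Motif concordance

The two layers meet on a controlled vocabulary of 15 glycan motif terms
(`glyco_motifs()`), distilled from the free-text binding-structure
descriptions of the 14-lectin panel. The lectin catalog maps each lectin
to the motifs it recognizes; the enzyme-action map states whether a gene's
enzyme *adds* or *removes* a motif (mannosidases remove branched
high-mannose; St6gal2 adds sialylated Gal/GalNAc).

For one enzyme with signed fold change $f$ and significance floor 1.2:
removal + down-regulation predicts motif accumulation (+1), removal + up
predicts depletion (−1), addition follows the gene's own sign, and
$|f| < 1.2$ contributes nothing. Per motif, the observed direction is the
unweighted majority sign of the calls of the lectins recognizing it, the
predicted direction the majority sign of the contributor predictions (ties
give 0 in both cases — the published argument is qualitative, so no
weighting scheme is imposed). A motif is *concordant* when both directions
are nonzero and equal; motifs lacking either layer are reported
unevaluable and excluded from the summary fraction's denominator (an
empty DEGG set therefore yields a not-applicable summary, not zero).

The packaged action map is intentionally conservative: it contains the
enzyme–motif links the integration narrative itself uses
(Man1a2/Man2a2 → branched high-mannose, St6gal2 → sialylated Gal/GalNAc),
one further clear-cut link (B4galnt1 → terminal GalNAc), and entries whose
motifs the panel cannot observe (Fut9 → Lewis-x, St8sia3/5 → poly-Sia),
which exercise the unevaluable path.

## Enrichment and network clustering

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for overlap $k$ between the query and a term's genes within
the universe (default: the union of the annotation's gene sets, since the
original analysis' universe is database-dependent), BH-adjusted across
terms; conventions give $p = 1$ at $k = 0$ and when the query equals the
universe.

Markov clustering is implemented directly (expansion = matrix squaring,
inflation = entrywise power with column renormalization; inflation 2.0,
pruning $10^{-6}$, convergence when the largest entry change falls below
$10^{-8}$ or after 200 iterations — standard defaults, unstated in the
original analysis). Edges below the 0.4 confidence cutoff are dropped
before iteration while their nodes remain, so a fully sub-cutoff
neighbourhood decomposes into singletons; self-loops carry each node's
maximum incident weight. Clusters are the connected components of the
limit matrix's nonzero structure and always partition the node set. The
original network's edge list is not published, so cluster identities are
not reproducible — only the algorithm and its properties are.

## Behavioural statistics

The sociability index is stranger-side time over empty-side time
(scale-invariant, undefined at zero empty time). Group comparisons run a
Shapiro–Wilk gate per group and then the standard pooled-variance unpaired
t-test ($\mathrm{df} = n_1 + n_2 - 2$); Welch's correction is available
behind a flag. A failed normality gate warns rather than switching tests,
because the original analysis specifies no fallback. Identical constant
groups return $t = 0$, $p = 1$, flagged degenerate. The published t
statistics themselves are not reproducible from the printed group
summaries under either an SD or an SEM reading of the "±" values, so they
are not asserted anywhere; only the statistic's definition is tested.

## Synthetic data: what it emulates, and what it does not

`simulate_lectin_slides()` reproduces the assay geometry (triplicate spots,
three replicate slides per sample, three samples per group, a 37-lectin
panel whose 14 reference lectins carry base intensities proportional to
their published control NFIs). Spot signal is base intensity ×
multiplicative lognormal noise (CV parameter) over an additive Gaussian
background — lognormal multiplicative noise matches fluorescence behaviour
and gives the ±2 SD floor something real to remove. Planted fold changes
live on the compositional (NFI) scale: case intensities of unplanted
lectins are rescaled by a common factor so the block total is preserved,
which makes planted NFI fold changes exact in the noiseless limit and
unbiased under noise. The generator does not emulate spatial artefacts,
print-tip effects, dye chemistry or saturation, so recovery tests validate
the arithmetic of the chain, not robustness to scanner pathology.

`simulate_counts()` emulates the 3-vs-3 RNA-seq design: negative-binomial
counts, lognormal baselines (meanlog $\log 200$, sdlog 1 — a realistic
spread for a bulk brain library scaled to a few thousand genes), planted
effects split symmetrically ($2^{\pm \log_2\!\mathrm{fc}/2}$) so average
expression is preserved, default dispersion 0.05. The recovery study
plants 30 four-fold effects (the magnitude used by the design's own
examples; at two-fold the Wald detection boundary makes ≥90% recovery
unattainable at $n = 3$ regardless of method) in glycan-list genes among
2,000 total. It does not emulate GC or length bias, outlier samples, or
correlated genes. Behavioural durations are truncated normal draws; the
network generator plants modules as dense within-module cliques with
sparse weaker between-module edges.

Every generator is a pure function of its parameters and seed, and truth
objects survive JSON round-trips via `write_truth_json()`.

## Problem sizes and numerical choices

The packaged validation runs use 200 seeded replicates for the two
recovery studies (lectin chain and DEGG chain), 1,000 replicates for the
behavioural type-I simulation, 2,000-gene count matrices, and exact
enumeration oracles at $N \le 25$ for the hypergeometric tail — sizes
chosen so the full suite exercises every stage in about a minute on one
CPU while keeping Monte-Carlo error well inside the asserted margins.
Ties in majority votes resolve to 0 (no direction); hierarchical
clustering inherits `hclust`'s deterministic tie handling; MCL determinism
follows from its purely algebraic iteration.

## Known limitations

* The curated list reproduces published category *totals* and all
  published member genes, not the unpublished full membership; synthetic
  placeholder records are clearly marked and should be replaced by a real
  enumeration when one is available.
* The concordance score is qualitative (majority signs, unweighted); it
  does not model pathway stoichiometry, enzyme redundancy, or substrate
  competition.
* `nb_de_test()` is intentionally minimal; real count data should be
  analysed with a full DE framework and the results ingested via
  `read_de_table()`.
* One lectin can recognize several structures; motif-level aggregation
  inherits that ambiguity from the assay.
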