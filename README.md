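# glycolink

Integrated analysis of **lectin-microarray glycomics** and **glycogene
transcriptomics** for two-group designs, modelled on the prenatal
valproic-acid (VPA) rat model of autism. The package is for researchers
who profile glycan structures with lectin arrays, measure expression of
glycan-related genes (RNA-seq or qRT-PCR), and want to ask whether the two
layers change *consistently* — e.g. whether reduced mannosidase transcripts
coincide with accumulated branched high-mannose glycans.

## What it computes

**Lectin arrays.** Spots below the detection floor
`mean(background) + 2·SD(background)` are removed; each lectin's
normalized fluorescence intensity (NFI) in a block is the median of its
effective (background-subtracted) spots over the sum of all lectin medians,
so block NFIs sum to 1. NFIs average over replicate slides, then samples.
Group comparison uses the signed fold change

```
FC = v/c        if v/c >= 1        (case v, control c)
FC = -c/v       otherwise          (no values inside (-1, 1))
```

with lectins called regulated at `FC >= 1.2` or `FC <= -1.2`.

**Glycan-gene list and DEGGs.** A curated list of 961 rat glycan-related
genes in eight CAZy/KEGG groups (glycosyltransferases, glycoside
hydrolases, carbohydrate-binding modules, other anabolic enzymes, lectins,
GPI-anchored proteins, proteoglycans, glycosaminoglycan-binding proteins)
is assembled with GeneID deduplication and validated category totals.
Differentially expressed glycan-related genes (DEGGs) are list members
with FDR-adjusted `p < 0.05`; a 1.5-fold filter (inclusive) splits them
into up/down sets.

**Integration.** Lectin specificities and enzyme actions (adds/removes a
motif) meet on a controlled vocabulary of glycan motifs. Per motif, the
direction observed by lectins (majority of calls) is compared with the
direction predicted from enzyme fold changes (removal + down ⇒
accumulation, addition follows the gene's sign); the concordance report
states the agreeing fraction. Hypergeometric over-representation analysis
and Markov clustering (MCL) of confidence-weighted networks support
functional follow-up. Behavioural validation (sociability index,
Shapiro–Wilk-gated pooled t-tests) and seeded synthetic-data generators
with ground truth round out the pipeline.

## Worked example

```r
library(glycolink)

# published NFI table of the 14 regulated lectins in the VPA model
nfi <- read.delim(glycolink_extdata("lectin_nfi_vpa.tsv"))
res <- run_lectin(nfi)
head(res$fc_table[order(-abs(res$fc_table$fc)), ], 5)
#>  lectin nfi_control nfi_case    fc call
#>     GNA       0.020    0.006 -3.34 down
#>     WGA       0.083    0.031 -2.63 down
#>  RCA120       0.024    0.009 -2.50 down
#>     VVA       0.071    0.029 -2.47 down
#>     BPL       0.049    0.024 -2.06 down
res$summary$n_significant
#> [1] 14        # 8 up, 6 down

# curated glycan-related gene list
gl <- assemble_gene_list(build_gene_table())
gl
#> Glycan-related gene list: 961 unique genes in 8 groups
#>   Glycosyltransferases                  259
#>   Glycoside hydrolases                   94
#>   ...

# concordance of the two omic layers
deggs <- read.delim(glycolink_extdata("degg_published.tsv"))
conc <- concordance_report(
  call_significant_lectins(nfi, 1.2), deggs,
  load_enzyme_actions(glycolink_extdata("enzyme_actions.tsv")),
  load_lectin_catalog(glycolink_extdata("lectin_catalog.tsv")))
conc
#> Glycan-motif concordance report: 15 motifs
#>   evaluable (lectin + enzyme evidence): 3
#>   concordant: 3
#>   summary fraction: 1
conc$records[conc$records$evaluable, c("motif", "lectins", "genes")]
#>                  motif       lectins         genes
#>  high-mannose-branched          ConA Man1a2;Man2a2
#>      sialyl-Gal-GalNAc     WGA;MAL-I       St6gal2
#>        terminal-GalNAc PTL-I;VVA;BPL      B4galnt1
```

Reading: reduced mannosidase expression (Man1a2/Man2a2 down) predicts
accumulation of branched high-mannose, and ConA indeed rises; reduced
St6gal2 predicts loss of sialylated Gal/GalNAc, and WGA/MAL-I indeed fall.

A full synthetic run — simulated slides, counts with planted glycan-gene
effects, behaviour — is one call:

```r
res <- run_all(glyco_config(seed = 1, out_dir = "out"))
```

or from the shell via the thin CLI:

```sh
Rscript inst/cli/glycolink.R all --seed 1 --out out
```

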