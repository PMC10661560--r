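# epibuffr

Tools for dissecting **epigenetic buffering of subgenome diversity in
allopolyploids** — the inference chain that starts from genome-wide
trans-factor binding and ends at a master chromatin repressor of
subgenome-diversified genes, together with the quantitative evidence
that its repression is released by mutation or pathogen infection.

It is written for computational biologists working on polyploid
epigenomics (wheat, cotton, *Brassica*) who have: orthogroup tables in
the OrthoFinder dialect, factor/mark peaks (BED) and per-gene densities
(TSV), spike-in ChIP libraries, count matrices, population VCFs and
pairwise subgenome alignments — and who want the whole chain as tested,
composable functions rather than one-off scripts.

## What it computes

* **Homoeolog catalog** — per-subgenome copy counts classified into the
  copy-number grammar over slots {0, 1, N}: `1:1:1` sc-triads versus
  unbalanced non-sc groups (`N:0:N`, `0:1:N`, ...), plus strand-agnostic
  peak-to-gene target assignment.
* **Regulator selection** — L1-penalized logistic regression of the
  non-sc indicator on the genes x factors binding matrix,

  $$\tfrac{1}{N}\textstyle\sum_i\big[\log(1+e^{\eta_i}) - y_i \eta_i\big]
    + \lambda\lVert\beta\rVert_1,\qquad
    \eta_i = \gamma + \sum_j A_{ij}\beta_j,$$

  solved by coordinate descent with 10-fold cross-validated penalty
  selection; factors ranked by coefficient in both outcome orientations.
* **Phylostratigraphy** — gene-age strata from ordered ortholog presence
  (PS1 = oldest), with per-stratum enrichment of mark targets.
* **Diversity landscape** — subgenome region classes from reciprocal
  alignments (> 400 bp rule), 100 bp sliding-window nucleotide diversity
  pi, captured divergence between subgenomes, joint quadrant labels and
  per-quadrant binding/mark enrichment.
* **Differential signal** — spike-in RRPM normalization
  (`counts * 1e6 / spike-in total`) with the |log2FC| > 1 & RRPM > 5
  rule, M-value calls (|M| > 1 & p < 0.05) with A-binned pooled
  variance, overdispersed expression calls (|log2FC| > 1 & BH FDR <
  0.05), and direct-target labeling (mark down AND expression up).
* **Enrichment & reporting** — exact hypergeometric gene-set enrichment
  with explicit backgrounds, contrast matching of a mutant signature
  against pathogen-response up-sets, descriptive phenotype statistics
  (mean/median/SD/SEM), and consolidated TSV/JSON run reports.
* **Synthetic world** — a seeded allopolyploid genome with planted
  ground truth (binding preference, mark co-localization, mutant and
  infection release, divergence-coupled population diversity), written
  and re-read in GFF3/BED/TSV/VCF plus a JSON manifest, used to validate
  every step.

## Worked example

```r
library(epibuffr)

w <- simulate_world(world_config(seed = 1))

head(w$orthogroup_classes, 3)   # classify_orthogroups() on parsed tables

#>   orthogroup_id label is_sc_triad counts
#> 1       OG00001 1:1:1        TRUE  1,1,1
#> 2       OG00002 0:1:1       FALSE  0,1,1
#> 3       OG00003 N:N:0       FALSE  2,3,0

cv <- cross_validate_select(w$binding, as.numeric(w$genes$is_non_sc),
                            k = 10, seed = 1)
head(rank_factors(cv), 3)
#>   factor_id     beta selected aliased rank_non_sc rank_sc
#> 1     TF001 1.342513     TRUE   FALSE           1      50
#> 2     TF002 0.000000    FALSE   FALSE           2       2
#> 3     TF003 0.000000    FALSE   FALSE           3       3
```

The planted factor (TF001) is the only selected coefficient: it binds
non-sc homoeologs with a +1.34 log-odds preference while all 49 decoys
shrink to exactly zero. Calling mark loss in the knockout from spike-in
densities, expression gain from counts, and matching the induced
signature against contrast up-sets:

```r
sam <- w$mark_samples
rr  <- rrpm_normalize(w$mark_counts,
                      setNames(sam$spikein_total, sam$sample_id))
d   <- call_differential_spikein(rr[, sam$condition == "wt"],
                                 rr[, sam$condition == "mut"])
table(d$call)
#>      down unchanged        up
#>      2068      4897        38

de <- call_differential_expression(w$expr_counts[, 1:4],
                                   c("wt", "wt", "mut", "mut"))
length(label_direct_targets(d, de))
#> [1] 675

head(match_contrasts(de$feature_id[de$call == "up"], w$contrasts,
                     w$genes$gene_id)[, c("contrast_id", "overlap", "fold", "p", "rank")], 2)
#>   contrast_id overlap     fold            p rank
#> 1 contrast_04     168 3.057840 1.539863e-45    1
#> 2 contrast_11      73 1.198357 5.334587e-02    2
```

2,068 genes lose the repressive mark in the mutant (the manifest plants
2,021 marked targets), 675 are direct targets (mark down and expression
up), and the infection-matched contrast (`contrast_04`, built from the
planted defense genes) ranks first by a 44-order-of-magnitude margin.
Phenotype legends round-trip too:

```r
standard_error(472, 40)
#> $sem
#> [1] 74.62975
#> $sem_rounded
#> [1] 75
```

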