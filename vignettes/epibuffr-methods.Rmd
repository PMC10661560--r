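---
title: "Methods: dissecting epigenetic buffering of subgenome diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting epigenetic buffering of subgenome diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibuffr)
```

## The problem

Allopolyploids such as hexaploid wheat carry several diverged parental
genomes (subgenomes A, B and D) in one nucleus. Most genes exist as
homoeolog groups, and the groups split into balanced single-copy triads
(one copy per subgenome, "1:1:1") and unbalanced non-sc groups in which
copies were lost or duplicated. The analysis chain in this package asks,
in order:

1. which trans-factor preferentially binds the unbalanced,
   subgenome-diversified groups (regulator selection);
2. whether that factor co-localizes with a repressive chromatin mark and
   whether knocking it out releases the mark and the expression of its
   targets (buffering and release);
3. whether the buffered genes are evolutionarily young and whether their
   genomic neighbourhoods carry both high inherited ("captured")
   divergence between subgenomes and high ongoing population diversity
   (phylostratigraphy and diversity quadrants);
4. whether an external stress (pathogen infection) releases the same
   targets, identified by matching the mutant-induced expression
   signature against public resistant-vs-susceptible contrasts.

Every step is implemented against a seeded synthetic allopolyploid world
with planted ground truth, so the whole chain is testable end to end
without the original sequencing data.

## Homoeolog grammar

Orthogroups are read from a tab-separated table in the OrthoFinder
output dialect, with each subgenome treated as a separate "species"
column. Copy counts map to slot symbols 0, 1 and N (N = two or more
copies), joined in subgenome order: `1:1:1` is the sc-triad class,
`N:0:N`, `0:1:N`, ... are the unbalanced classes. Exact counts are kept
alongside the label so copy-number trends remain analysable. The
classification is pure arithmetic and is tested against an exhaustive
64-case truth table.

Peak-to-gene assignment is strand-agnostic: a gene is a target when a
peak overlaps the window from `upstream` bp before the gene start to
`downstream` bp past its end (defaults 2,000 and 500 bp). Real data
rarely state this rule, so it is an explicit, reported parameter; for
the tightly packed synthetic genome the tests use windows smaller than
the intergenic pitch so a peak maps only to its own gene.

## Regulator selection

The binding matrix `A` (genes x factors, binary) and the outcome `y`
(1 = member of a non-sc group) feed an L1-penalized logistic
regression with unpenalized intercept:

$$\min_{\beta,\gamma}\; \frac{1}{N}\sum_{i=1}^{N}
  \Big[\log\big(1+e^{\eta_i}\big) - y_i\,\eta_i\Big]
  \;+\; \lambda \lVert \beta \rVert_1,
  \qquad \eta_i = \gamma + \sum_{j=1}^{M} A_{ij}\beta_j .$$

The solver is an iteratively reweighted least squares scheme with cyclic
coordinate descent on the working response (soft-thresholding updates),
warm starts down a 100-value log-spaced penalty grid from
$\lambda_{max}$ to $10^{-4}\lambda_{max}$, and a backtracking safeguard
so the penalized objective never increases. Convergence is verified by
KKT residuals (< 1e-6 in all tests; typically ~1e-14). Binary incidence
columns share a scale, so columns are not standardized by default; a
standardization flag exists and its coefficients back-transform exactly.

Penalty selection uses stratified 10-fold cross-validation on held-out
binomial deviance, choosing the minimizing penalty (`lambda_min`).
Design notes:

* `lambda_min` maximizes sensitivity for *ranking* factors, which is the
  goal here; the conservative one-SE rule is available via
  `one_se = TRUE`.
* On label-permuted (null) data the CV curve is minimized at or near
  `lambda_max` and the chosen model is usually exactly null; selection
  noise admits one small spurious coefficient in a minority of seeds
  (the reference cross-validated solver in `glmnet` behaves the same),
  so null calibration is assessed as the across-seed mean of the largest
  coefficient magnitude. With `one_se = TRUE` null fits are strictly
  empty.
* Ties in coefficients are broken by factor id; identical binding
  columns are resolved deterministically by column order (the earlier
  column absorbs the shared effect) and flagged `aliased` in the
  ranking.
* Degenerate all-0/all-1 columns are dropped with a warning before
  fitting.
* The sc-triad orientation of the ranking is the same model with the
  outcome inverted, which for a logistic model exactly negates every
  coefficient; both orientations are reported from one fit.

## Differential signal calling

Three callers share one table contract (`feature_id, wt_mean, mut_mean,
M, A, log2FC, p, fdr, call`):

* **Spike-in (RRPM) path.** Densities are `counts * 1e6 / spike-in
  total`; exogenous chromatin is added in fixed proportion before
  immunoprecipitation, so this scale survives global occupancy loss.
  Replicates are averaged per condition, then a feature is called when
  `|log2FC| > 1` and the larger condition mean exceeds 5 RRPM. The
  abundance gate uses the *maximum* of the two means (permissive
  reading; configurable). A pseudocount of 1 bounds ratios at zero
  signal.
* **M-value path.** `M = log2(mut_mean + c) - log2(wt_mean + c)`, `A`
  the mean of the two logs. With duplicate-level replication a
  per-feature variance is uninformative, so the variance of replicate
  log2 densities is pooled within 20 equal-occupancy A-bins and a z-test
  is applied; calls need `|M| > 1` and `p < 0.05`. This is a defined,
  deterministic test — not a re-implementation of any external
  hierarchical normalization model.
* **Expression path.** Counts are normalized per million (per kilobase
  per million when exon lengths are given), all-zero rows dropped and
  reported, and the log2 fold change tested with a normal approximation
  using a single moment-matched overdispersion `phi` shared across genes
  (`var = mu + phi mu^2`); calls need `|log2FC| > 1` and BH FDR < 0.05.
  Per-million scaling is composition-sensitive: a large induced fraction
  shifts null genes' apparent fold change (visible in the synthetic
  mutant, where ~29% of genes are induced). The stated thresholds are
  kept; this is a known limitation of the normalization convention, not
  of the test.

Direct targets are the conjunction *mark called down and expression
called up* in the mutant. BH adjustment delegates to
`stats::p.adjust(method = "BH")` behind `bh_adjust()`; note the step-up
transform is *not* idempotent.

## Diversity landscape

Alignment segments between subgenomes count as homologous only when
reciprocal and strictly longer than 400 bp. Per base of the focal
subgenome: homologous to both partners = `homo3`, to exactly one =
`homo2`, otherwise `specific`; `homo3` inside synteny blocks is
additionally `homoeo3`. "Reciprocal" is consumed as a segment flag
(mutual-best criteria belong to the upstream aligner); synteny blocks
are consumed as a TSV.

Population diversity uses non-overlapping 100 bp windows (step = width):
$\pi$ is the sum over sites of `2 p q n/(n-1)` divided by the window
length, which equals the all-pairs average per-bp difference exactly —
the windowed convention of standard VCF tooling. Windows with no
segregating site are monomorphic ($\pi = 0$); windows are missing only
when genotypes are absent. Captured divergence pools substitution
columns (`mismatched / (matched + mismatched)`, gaps excluded) of the
homologous segments overlapping a window, prorating partial overlaps by
covered fraction.

Quadrants binarize the two metrics at per-metric medians by default;
"high" requires strict exceedance, so a window exactly at a threshold is
"low". Only the jointly high quadrant carries a numeric alias (region 2,
the compartment that kept diversifying after polyploidization); the
other quadrants are referred to descriptively. Enrichment of a factor's
windows per quadrant is hypergeometric against the labeled windows, with
BH adjustment within each feature.

## Phylostratigraphy

Gene age is the earliest node of an ordered species ladder whose species
set contains a detectable ortholog, with presence derived from
orthogroup membership. The default nine-step ladder runs Arabidopsis
(PS1), maize, rice, *Brachypodium*, barley, rye, *T. urartu* + *Ae.
tauschii*, *T. turgidum*, focal-only (PS9); the mapping of species to
the deeper strata is configuration, not code, because published ladders
list the species without pinning every node (and descriptions vary
between nine groups and eight internodes — both are expressible).
Per-stratum target enrichment reuses the hypergeometric engine.

## Enrichment and contrast matching

`fold = (overlap/query) / (annotation/background)` with an exact
upper-tail hypergeometric p; the "enrichment score" reported throughout
is `log2(fold)`, and the background is always explicit in the output.
Contrast matching ranks resistant-vs-susceptible up-sets by the
enrichment of the mutant-induced set, ties broken by fold then contrast
id, BH across contrasts. A rank-correlation variant of signature
similarity would also be defensible; set-overlap ranking was chosen
because it is exact, assumption-free and oracle-checkable.

## The synthetic world

`world_config()` fixes the study conditions; `simulate_world()` draws
everything from one master seed with deterministic per-component
sub-seeds (adding a component never perturbs earlier draws), and
`write_world()`/`read_world()` round-trip the bundle through GFF3, BED6,
TSV, VCF 4.2 and a JSON truth manifest.

Default conditions (chosen once, flagged as calibration choices in the
manifest): 2,000 orthogroups over 3 subgenomes x 2 chromosomes, 1 kb
genes at 500 bp spacing, one third sc-triads, non-sc copy weights
(.25, .40, .25, .10) over 0-3 copies; 50 factors with baseline binding
0.15 and a planted +1.5 log-odds preference for non-sc genes; mark
co-localization 0.8 at planted-bound genes; mutant mark drop -2 log2
with +1.5 log2 expression gain at marked targets; 30% of marked targets
labeled defense, released (same effect sizes) post-infection; 20 phased
diploid accessions with per-window mutation rate
`base_theta * (1 + 3 * divergence)`, `base_theta = 0.002`/bp; alignment
tiles mixed 35/15/50 specific/homo2/homo3 with synteny covering 32% of
each chromosome, mirroring the genome-wide fractions reported for wheat
(35/15/51/16%); negative-binomial counts with dispersion 0.05 and
nominal 1e6 spike-in reads per library, duplicates per condition.

What the generator emulates: preferential binding at non-sc genes,
factor-mark co-localization, mark loss plus expression gain in the
mutant, infection-released defense targets, and the positive coupling
between captured divergence and population diversity (elevated around
marked targets). What it does not: sequence-level reads, TEs/repeats,
recombination, linkage disequilibrium, unequal library compositions
beyond lognormal jitter, or realistic gene length/spacing distributions.
Passing recovery tests therefore demonstrates the chain's correctness
and calibration under these generative assumptions — not performance on
real wheat data, whose normalization and confounding structure is
harsher.

Null worlds (all planted effects and the divergence coupling set to 0)
calibrate false-call rates at the stated thresholds and verify that the
divergence-diversity correlation vanishes.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 is written 1-based
  closed and BED 0-based half-open.
* Copy counts are capped at 3 per subgenome in the generator, enough to
  exercise every `N` case of the grammar.
* Pseudocount 1 on normalized densities for all log ratios (exposed).
* Solver tolerances: coordinate tolerance 1e-9, KKT residuals < 1e-6
  asserted in tests.
* Empty quadrants yield NA rows with a warning; windows without
  homologous coverage have missing captured divergence and are excluded
  from quadrant labels and correlations.
* All-zero genotype draws, single-haplotype panels and empty peak sets
  degrade to empty/NA results rather than errors where a value is
  well-defined, and to errors naming the offending field where it is
  not.

## Problem sizes

The test suite and the acceptance script run the regulator screen on
ten 2,000-orthogroup worlds (~6,800 genes x 50 factors each, 10-fold CV
over a 100-step penalty path), the differential callers on full worlds
(~6,900 genes, duplicates), and the diversity stack on ~34,000 windows
with ~24,000 segregating sites across 40 haplotypes — sizes at which
every recovery statistic in the suite is stable across seeds while the
whole chain remains quick to re-run.

## Known limitations

* The expression caller inherits the composition sensitivity of
  per-million normalization (documented above).
* The M-value test's binned pooled variance assumes exchangeable noise
  within abundance bins; strong mean-variance structure inside a bin
  would miscalibrate p slightly (calls are still gated by `|M| > 1`).
* Phylostratum assignment is presence-based; it cannot distinguish gene
  loss from detection failure in an outgroup.
* The contrast matcher treats up-sets as unordered sets; graded evidence
  (fold-change correlation) is out of scope.
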