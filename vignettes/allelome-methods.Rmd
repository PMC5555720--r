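---
title: "Classifying allelic expression in F1 reciprocal crosses"
author: "allelome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying allelic expression in F1 reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelome)
```

## The problem

Crossing two inbred mouse strains (here CAST/EiJ and FVB/NJ) in both
directions — CAST mother x FVB father and the reciprocal — produces F1
hybrids in which every transcript can be assigned to its parental allele at
strain-distinguishing SNPs. With replicates of both cross orientations,
strain effects (the CAST allele is always more active) can be separated from
parental effects (the maternal allele is always more active, i.e. genomic
imprinting). The same logic applies to allele-resolved ChIP-seq read counts
in sliding genomic windows, giving allele-specific histone-mark calls.

This package classifies every annotated gene in a tissue into one of seven
categories — biallelic (BAE), strain-biased toward CAST or FVB, imprinted
maternal (MAT) or paternal (PAT), not informative (NI, too little SNP-covered
expression), or no SNPs (NS) — and builds the downstream analyses on those
calls: X-inactivation escaper detection, allele-specific enhancer-mark
statistics, transcriptional-versus-post-transcriptional attribution of
strain bias, and validation and cluster sizing of imprinted candidates.

## The allelic score and its empirical FDR

For summed allele-resolved counts $(a, b)$ at a gene's retained SNPs, the
allelic score is

$$ S = -\log_{10} \min\!\big(1,\; 2\,P(X \ge \max(a,b))\big), \qquad
   X \sim \mathrm{Binomial}(a+b,\ 0.5), $$

the two-sided binomial surprise of the deviation from a balanced 0.5 ratio.
Two signed scores are kept per gene and replicate: the strain score
(positive toward CAST) and the imprinted score (positive toward maternal);
both share the magnitude $S$ and differ only by the orientation mapping.
The two-sided p-value is defined as twice the upper tail capped at 1: the
score is used symmetrically for both directions, so doubling the tail is the
natural two-sided convention. Scores are computed in log space, so they
remain exact at arbitrarily deep coverage.

A gene is called monoallelic when all replicates agree in direction, every
replicate's score passes a score cutoff, and the median allelic ratio toward
the favoured allele is at or above the ratio cutoff (default 0.7). The
score cutoff is not a fixed constant but is set empirically per cohort and
comparison by **mock comparisons**: relabelling the two alleles in exactly
one replicate of each reciprocal cross cancels both consistent strain signal
and consistent imprinted signal (the flipped replicate reverses direction,
destroying the required all-replicate agreement), so the pooled summary
scores of all single-flip patterns behave as a null cohort. The cutoff is
the smallest value $c$ at which

$$ \widehat{\mathrm{FDR}}(c) =
   \frac{\text{mean mock genes with summary score} \ge c}
        {\text{real genes with summary score} \ge c} \le \text{target}, $$

with a 1% default target. Candidate cutoffs include every observed real and
mock score *and a point just above each*: scores are continuous, and the
optimal cutoff frequently sits immediately above the largest mock score,
where the estimated FDR drops to zero. Restricting candidates to observed
real scores would overshoot to the smallest signal score and drag the
derived coverage threshold far above its intended level.

The summary score per gene is the minimum replicate magnitude when all
replicates share a direction and 0 otherwise, so at most one of the two
summary scores is nonzero.

### Informative coverage

A gene is informative when every replicate's retained SNP coverage reaches
the smallest total $n$ at which a gene sitting exactly at the ratio cutoff
would still pass the score cutoff
(`min_informative_coverage()`). This ties "informative" to the empirical
FDR instead of an arbitrary expression cutoff. Because the score at a fixed
ratio is not pointwise monotone in $n$ (the rounded-up biased count jumps),
the implementation scans $n$ exhaustively rather than bisecting. Two
derived cutoffs exist (strain and imprinted); the coverage bar uses the
stricter finite one — an infinite cutoff means that comparison can produce
no calls at all (e.g. no imprinted signal exists on a skewed X) and must
not render every gene NI.

### Choices worth knowing

* `minread` (default 2) filters on a SNP's **total** coverage within one
  replicate; the per-allele reading would retain asymmetrically covered
  SNPs on one side only.
* Imprinted classification is evaluated before strain classification. With
  both cross orientations present the two cannot genuinely conflict (strain
  consistency forces parental disagreement and vice versa), so precedence
  only resolves boundary noise deterministically.
* Median ratios are per-replicate medians (mean of the two central order
  statistics for four replicates); ties at exactly the cutoff pass.
* Biallelic genes are subtyped by their replicate strain ratios: consistent
  direction below the cutoff, fluctuating below it, or fluctuating with at
  least one replicate above it.

## X-inactivation escapers

In CAST/FVB F1 mice, epiblast-derived tissues show skewed random XCI (the
FVB X is preferentially inactivated, expected CAST ratio near 0.7), and
extra-embryonic tissues show imprinted XCI (paternal X silenced, expected
maternal ratio near 1). An informative X-linked gene in a female tissue is
a **non-escaper** when it shows the expected category, and an **escaper**
when it is biallelic or biased the unexpected way (Xist itself, paternally
expressed under imprinted XCI, is the canonical unexpected-bias escaper).
The escaper analysis uses a reduced ratio cutoff of 0.6 — biallelic calls
are conservative escapers under a lower bar. One guard matters: a gene
classified biallelic although *all* replicates lean the expected way with a
median ratio at or above the cutoff failed only the FDR score cutoff
through low expression; such genes are **excluded** (reported, not called),
which avoids an arbitrary expression cutoff. Percent escaping is always
escapers over informative genes (escapers plus non-escapers), one decimal.

## Enhancer-mark statistics

Three window-level analyses run on allele-specific histone-mark calls (4 kb
windows, 2 kb step), all after removing windows within 2 kb of any
annotated TSS:

* **TSS profiles**: windows are assigned to every gene with a TSS within
  50 kb of the window midpoint, binned by signed distance (25 bins of
  4 kb), and observed per-category counts are divided by the mean of 100
  label permutations. Shuffles permute the category labels across windows
  without replacement, preserving the frequency spectrum exactly, so the
  per-bin totals are conserved and the per-category expectation is the
  category frequency times the bin total. Significance is a one-sample
  t-test of the 25 observed bin counts against the grand shuffled mean —
  a test of profile-wide enrichment, deliberately insensitive to a single
  spiked bin.
* **Escaper distances**: for each maternally biased window on the X, the
  distance to the nearest escaper and nearest non-escaper gene (window to
  gene, midpoint to body edge, zero if inside; distances above 500 kb are
  dropped). The class imbalance is corrected by subsampling the
  non-escapers to the escaper count 10 times; each iteration gives a Welch
  t-test p-value and the ten are combined by Fisher's sumlog method,
  $X = -2\sum \ln p_i \sim \chi^2_{2k}$. The reverse direction (gene to
  nearest window) is available behind a flag. Distances are pure linear
  functions of the coordinates — no gap convention — so scaling all
  coordinates scales all distances.
* **Imprinted-region enrichment**: parental-specific windows are counted in
  non-overlapping 100 kb tiles (by midpoint); tiles with at least one count
  are compared inside versus outside the supplied imprinted regions (Welch
  t, Cohen's d), and the maximum count outside defines a background cutoff
  above which inside tiles are reported.

A calibration caveat the package's own tests document: the ten subsample
p-values of the distance test all share the fixed escaper distance vector,
so they are strongly positively dependent and the sumlog combination is
anti-conservative under the null (empirically ~0.6 rejection at a nominal
0.05 across simulated null cohorts). The procedure is implemented as
designed; its combined p-values should be read as a ranking device, not as
calibrated tail probabilities.

## Transcriptional versus post-transcriptional strain bias

Intronic SNPs report the nascent transcript, exonic SNPs the mature one.
Running the full classification separately on each SNP subset and adding
the allelic status of the promoter H3K4me3 mark yields a mechanism call for
strain-biased genes: biallelic promoter + biallelic introns + biased exons
is **post-transcriptional** (equal transcription, allele-specific
transcript fate); matching monoallelic promoter + bias in both subsets is
**transcriptional**. Everything else — including an absent or mismatching
promoter call — is reported **ambiguous**; a mismatching promoter is kept
as its own diagnostic state rather than silently folded in. Genes
uninformative in either subset (intronless genes in particular) are dropped
with a recorded reason rather than defaulted to a mechanism.

## Imprinted-candidate validation and clusters

Maternal transcripts from decidua and blood contaminate dissected placenta,
mimicking maternal imprinted expression. The screen flags placental
maternal candidates with mean decidua/placenta RPKM ratio above 5 or
blood-specific expression. The embryo-transfer design (CAST x FVB conceptus
in an FVB host) is decisive: true imprinted expression keeps the CAST bias,
contamination carries the host's FVB alleles. The imprint-control-element
deletion check calls a candidate *regulated* when the wild-type maternal
bias collapses to biallelic in the deletion cross and/or expression rises
significantly — the differential test is a Welch t on log2(RPKM+1) with
Benjamini–Hochberg adjustment, a deliberately self-contained replacement
for an external differential-expression engine.

Candidates then fall into a deterministic precedence:
`maternal_contamination` (screen positive, no direct validation) >
`validated` (any of: deletion-regulated, parental promoter H3K4me3,
embryo-transfer confirmation, second-cross confirmation) > `supported`
(two or more tissues, or within 7 Mb of a gDMR/imprinted-region anchor, or
DMR overlap) > `candidate`. Non-coding candidates without their own
promoter peak that share direction with a neighbouring known imprinted
nc-gene are prefixed `fragment_`. The 7 Mb radius is a configurable
constant defaulting to the largest anchor distance observed in an expanded
imprinted cluster.

Cluster extents per tissue span the most proximal to most distal member
gene called imprinted there, so the per-tissue series exposes expansion in
extra-embryonic tissues. Fold variation of per-tissue counts is max/min,
presented at one decimal (round-half-even) with the exact rational kept.

## The synthetic-data generator

Every stage is testable without external sequencing data through a seeded
generator that emulates the study design: two reciprocal crosses with two
replicates each; autosomal genes biallelic, strain-biased, or imprinted;
X-linked genes under skewed (0.7 toward CAST) or imprinted (maternal ratio
1) XCI with planted escapers at 0.5; Poisson SNP counts per gene with a
configurable SNP-free fraction (exercising NS); negative-binomial SNP
coverage (creating realistic NI genes — the coverage model is a design
choice, not a literature value); and a beta-binomial allelic split whose
intra-class correlation `rho` recovers the pure binomial at 0, letting
tests probe FDR behaviour with and without overdispersion. ChIP windows
tile the genome at 4 kb/2 kb with planted biased windows near designated
TSSs, planted parental windows inside designated regions, and promoter
peaks matching each gene's true category. An optional antisense
bleed-through fraction leaks a partner gene's reads into its host,
emulating incomplete strand specificity (off by default).

All randomness flows from one master seed through derived per-stage
streams; the global RNG state is saved and restored, and identical
configurations reproduce byte-identical outputs.

What the generator does *not* model: alignment and mappability bias,
read-level artifacts, subsampling of raw reads to equalise library sizes,
and correlated SNP-to-SNP noise within a replicate beyond the shared gene
ratio. Passing tests therefore demonstrate the statistical machinery under
the stated noise model, not robustness to alignment artifacts.

### Default study conditions and problem sizes

Defaults mirror the study design: 4 replicates (2 per cross), ratio cutoff
0.7 (0.6 for escapers), FDR target 1%, `minread` 2 for expression (1 for
window calls), mean 10 SNPs per gene, mean SNP coverage 50, `rho` 0 for
calibration cohorts. The package's FDR-control study uses 10,000 genes
(9,500 biallelic, 500 monoallelic at ratio 0.9) averaged over 20 seeds;
recovery cohorts use 2,000–4,000 genes; calibration suites use 200
simulated cohorts. These sizes make every property statistically decisive
while keeping a full run in minutes on one CPU.

## Worked example

```{r example}
cfg <- sim_config(n_autosomal_genes = 400, n_x_genes = 0,
                  frac_strain_biased = 0.05, frac_imprinted = 0.02,
                  true_biased_ratio = 0.9, seed = 7)
sim <- simulate_allelome(cfg)
fit <- allelome_classify(sim$counts, snps = sim$snps,
                         gene_ids = sim$annotation$genes$gene_id,
                         tissue = "demo")
fit
table(called = fit$calls$category,
      truth = sim$truth$true_category[match(fit$calls$gene_id,
                                            sim$truth$gene_id)])
```

## Known limitations

* The mock-comparison scheme assumes a balanced reciprocal design with at
  least two replicates per orientation; other designs need a different
  null construction.
* The distance test's combined p-value is anti-conservative (above).
* RPKM-based screens inherit RPKM's length and library-size caveats.
* Window calls treat each window independently; adjacent 4 kb windows
  overlap by half and are not deduplicated before counting, exactly as in
  the sliding-window design they emulate.
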