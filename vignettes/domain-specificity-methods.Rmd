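---
title: "Methods: domain-specificity analysis of TRAP-seq translatomes"
author: "apexdomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-specificity analysis of TRAP-seq translatomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexdomains)
```

## The problem

Translating ribosome affinity purification (TRAP) followed by RNA-seq
measures, for each promoter-defined cell domain, the population of
ribosome-associated mRNAs — a translatome snapshot of that domain. The
reference design this package targets profiles nine domains of the plant
shoot apex (stem-cell, organizing-center, boundary, leaf and epidermal
reporters: CLV3, WUS, UFO', AS1, AS2, FIL, ATML1, LAS, PTL) with three
biological replicates each. The scientific questions are comparative: which
genes are active where, which are *enriched* in a single domain, which
co-expression programs span domains, and which isoforms, lncRNAs and
pseudogenes behave domain-specifically.

`apexdomains` implements this analysis end to end on a gene x sample count
matrix, and ships a synthetic-data generator with planted ground truth so
that every caller can be validated quantitatively.

## Normalization and expressed-gene calls

Counts are normalized to RPKM,
$\mathrm{RPKM}_{gs} = 10^9 c_{gs} / (L_g N_s)$, with $L_g$ a single
effective gene length (union-exon length recommended) and $N_s$ the library
size (column sums by default; aligner-reported totals can override). All
domain-level statistics operate on the replicate-mean RPKM per domain. A
gene is *expressed* in a domain when that mean exceeds 1 RPKM (strict `>`);
isoform-level analyses use the inclusive `>=` 1 convention. Both cutoffs
are configurable; the defaults follow the two conventions' usual phrasing.
Expressed-set overlaps across the nine domains (genes expressed in exactly
$k$ domains) are tallied by `overlap_groups()`.

## Pairwise differential expression

The pairwise specificity screen needs a DE test between every pair of
domains. The package uses a self-contained exact conditional
negative-binomial test, deliberately *edgeR-like but not edgeR-identical*:

* counts are scaled to the geometric-mean library size and rounded;
* per-gene dispersion is estimated by method of moments,
  $\hat\varphi = \max(0, (s^2 - m)/m^2)$, from the pooled within-group
  variance, then shrunk: each gene keeps weight 0.3 on its own estimate and
  0.7 on the trimmed mean (10%) of all genes' estimates. A 3 vs 3 design
  leaves 4 residual df, so per-gene estimates alone are nearly worthless;
  the 0.3/0.7 split mirrors the effective weighting that empirical-Bayes
  exact-test tools apply at this replicate number. On the package's null
  simulation this calibration gives a type-I rate of ~0.057 at
  $\alpha = 0.05$ and near-uniform p-values (KS distance < 0.05);
* conditioning on the total $t$ of the two group sums, the probability of a
  split $(y, t-y)$ is proportional to
  $f(y;\mu_a,\varphi/n_a)\,f(t-y;\mu_b,\varphi/n_b)$ with $\mu_a$
  apportioned by replicate numbers. The two-sided p-value sums all splits
  no more likely than the observed one (minimum-likelihood rule, ties
  within relative slack $10^{-12}$). At $\varphi = 0$ the test reduces
  exactly to the two-sided exact binomial test — the 0/10 split at equal
  group sizes gives $p = 2/1024$;
* enumeration is windowed to the splits carrying all but $\sim 10^{-16}$
  of the conditional mass (the observed split is always included), which
  keeps a 36-contrast, 2000-gene analysis under two minutes on one CPU;
* log2 fold changes are computed on domain-mean RPKM with a pseudocount of
  0.1 to avoid infinities; BH adjustment is applied within each contrast.

Genes below the expressed cutoff in both domains of a contrast are not
tested.

## Three specificity callers and the union rule

**Pairwise screen.** A gene is pairwise-specific to a domain when it beats
*every* other domain with log2FC > 1 at FDR < 0.05 (the fold change must
favor the focal domain). The stricter FDR < 0.01 / FC > 2 combination used
for global DE summaries, and a raw-p variant of the screen, are exposed as
configuration; the package defaults to the FDR-based rule because adjusted
thresholds are the defensible choice when eight contrasts are combined.

**z-score.** Expression values are standardized per gene and the score is
evaluated at each domain mean,
$z_{ij} = (\bar x_{ij} - \mu_i)/\sigma_i$. The package computes
$\mu_i, \sigma_i$ from **all samples** (population sd), not from the nine
domain means. The two references agree whenever replicates agree — in
particular the useful closed form survives: a gene expressed at one level
in eight domains and any higher level in the ninth scores exactly
$\sqrt{D-1} = \sqrt 8 \approx 2.83$ there. But their noise behavior
differs sharply: standardizing $D = 9$ i.i.d. noisy values fires
$z \ge 2$ on roughly a fifth of completely flat genes (with nine values,
one of them sits far from the others surprisingly often, whatever the
noise scale), whereas referencing the sample-level scatter lets replicate
averaging shrink the domain mean's noise relative to $\sigma_i$ and drops
the flat-gene rate to ~0.1%. Multi-domain enrichment also stays
representable: a pure domain-mean z with nine domains can never place two
domains at $z \ge 2$ simultaneously (the row constraint
$\sum_j z_{ij}^2 = D$ forbids it), while the sample-referenced score is
not so constrained. `domain_zscores(..., z_on = "domain_means")` selects
the pure domain-mean standardization; `zscore_matrix()` exposes the raw
row-standardization operation. Genes with zero scatter get $z = 0$ so set
algebra stays total. The $z \ge 2$ cutoff is inclusive.

**CS score.** $CS(i,j) = 1 - \max_{k \ne j}(EV^i_k / EV^i_j)$: 1 means
exclusive expression, 0 uniform, negative values mark domains that are not
the maximum. A zero focal denominator (or an all-zero gene) yields NA
rather than $-\infty$. CS > 0.3 serves as a cross-check caller; on the
default synthetic study its calls overlap the union set with Jaccard
~0.5.

**Union rule.** The domain-enriched set of a domain is the union of the
$z \ge 2$ genes and the pairwise-specific genes, restricted to genes
expressed in at least one domain. The pairwise member additionally must
pass the expressed filter in its focal domain. On the default synthetic
study (planted truth: 50 genes per domain at 8-fold) the union caller
reaches precision ~0.99 and recall ~0.94–0.96.

A restricted variant (`sam_restricted_specific()`) reruns the screen among
a domain subset — e.g. the three meristem domains — at FC >= 2,
FDR <= 0.01 against both other domains, matching the stricter convention
used for within-meristem comparisons.

## Category enrichment

`lr_enrichment()` is annotation-agnostic: any flat gene -> category table
(hormone-responsive sets, TF families, modules) works. For a query of size
$k$ in a universe of $t$ expressed genes, with $m$ category members and
$q$ hits, the effect size is $\mathrm{LR} = \log_2((q/k)/(m/t))$ and
significance is the upper-tail hypergeometric $P(X \ge q)$ (observed count
included — the standard over-representation convention). BH families are
all categories of one kind for one query; the module–domain association
matrix is corrected across all cells — the whole-matrix family is the
more conservative choice for a display in which every cell competes. Cells reaching FDR < 0.01 are flagged.
`significance_filter()` retains categories at FDR <= 0.05 (inclusive).

## Co-expression network modules

Network construction follows the weighted-GCN recipe: retain genes with
domain-mean CV >= 0.7 (sample sd / mean, computed on the nine domain means
— "variation among domains"), correlate log2(RPKM + 1) across all 27
samples, raise |cor| to the soft power beta = 9 (unsigned network; the
power can be re-derived from the scale-free fit table emitted by
`pick_soft_threshold()`), and transform to the topological overlap matrix

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i,k_j) + 1 - a_{ij}}.$$

Modules come from average-linkage clustering on $1 - \mathrm{TOM}$ with an
adaptive branch cut: candidate cut heights (midpoints of merge heights, at
most 60) are scanned and the height yielding the most *valid* modules wins,
a valid module needing >= 30 genes and a coherent eigengene (mean squared
gene–eigengene correlation >= 0.25; random clusters of admissible size at
27 samples sit near 0.09–0.14 by the Marchenko–Pastur bound, so shapeless
branches are rejected and pure noise yields zero modules). Genes stranded
above the chosen cut join the module whose eigengene they track at
|kME| >= 0.5 — the analogue of the dynamic hybrid method's assignment
stage, without which a single global cut fragments genuine modules.
Finally, modules whose eigengenes are closer than dissimilarity 0.20
(correlation > 0.80) merge iteratively, closest pair first. The 0.20 value
is read as the eigengene merge height — the standard meaning of a merge
cutoff — rather than as the initial branch-cut parameter; the initial cut
has its own adaptive rule as described. Eigengenes are first principal
components of the gene-standardized module submatrix, sign-oriented so the
mean gene–eigengene correlation is non-negative.

Module–domain association reuses the hypergeometric engine on the overlap
between module memberships and domain-enriched sets.

## Isoform-level splicing and noncoding transcripts

Genes with two or more isoforms expressed (max domain mean >= 1 RPKM) are
screened for domain-specific alternative splicing. The default call
requires *disagreement*: at least one expressed isoform enriched
($z \ge 2$) somewhere, and the sets of enriched domains differing between
at least two expressed isoforms — isoforms that simply share the gene's
domain pattern are the negative case. The permissive one-enriched-isoform
rule is available as `rule = "any"` since the gene-level definition could
be read either way.

Assembled transcripts are classified against an annotation with coding,
known-lncRNA and transposon records: (i) any exon overlap with a coding
gene rejects; (ii) an exact coordinate match to a known lncRNA is `known`,
and identical internal splice structure with a 5' and/or 3' extension of
at least 1 bp is `known_extended` (partial overlaps with different
structure fall through to the novel criteria); (iii) the rest are `novel`
if spliced length > 200 nt, the genomic gap to the nearest coding-gene
span is >= 500 bp (strand-ignorant — the criterion guards against
assembly bleed-through from either strand), no exon overlaps a transposon,
and the longest sense-strand ORF is <= 300 nt. Rejections carry the first
failing criterion in that order. The ORF scan is a deterministic
three-frame ATG-to-stop search on the spliced sense strand (stop codon
included in the length); it replaces gene-predictor-based ORF calls, so
novel-lncRNA tallies from this classifier are not expected to match
predictor-based ones. Coordinates are 1-based closed internally and GTF on
disk.

Pseudogene profiling reuses the expressed-set and z-score machinery on an
annotated id list.

## The synthetic-data generator

`simulate_counts()` emulates the study design: 9 domains x 3 replicates,
2000 genes, library size ~1e6 with ±10% jitter, NB dispersion 0.1,
baseline abundances log-normal (sdlog 1.5, so ~99% of genes clear the
1-RPKM cutoff, as in deeply sequenced translatomes), gene lengths uniform
on 500–5000 bp so RPKM and count scales decouple. Fifty genes per domain
are planted at 8-fold; five modules of 100 genes each receive
`amplitude * (loading * f_s + sqrt(1 - loading^2) * e_gs)` on the log2
scale with a per-sample latent factor `f`, loading 0.8 and amplitude 3
log2 units. The amplitude is what makes module genes clear the CV >= 0.7
network filter (the loading alone yields cross-domain CV ~0.33 and the
filter would discard entire modules); 3 log2 units of coordinated swing is
typical of the high-CV gene stratum that co-expression networks are built
on. `simulate_isoforms()` plants two-isoform genes in three equal classes
(disagreeing, same-domain, flat); `simulate_genome()` builds an ~85 kb
ATG-free chromosome with planted coding genes, transposon, known lncRNA
and ten assembled transcripts covering every verdict class and every
decision boundary (length 200/201, gap 499/500, ORF 300/303).

What the generator does *not* model: biological covariance beyond the
planted factors, GC/length biases, isoform-level read assignment
uncertainty, batch structure, or assembly artifacts. Passing the planted-
truth checks therefore demonstrates the callers' statistical behavior
under the stated noise model, not performance on any particular real
dataset.

Planted-truth scoring conventions: precision/recall for the union caller
count (gene, domain) pairs against the planted domains; module recovery is
the adjusted Rand index computed over genes carrying a planted module
label, because planted domain-specific genes legitimately form their own
co-expression clusters (their shared domain profile is real signal, not a
detection error) and would otherwise be conflated with module errors.

## Problem sizes, runtimes and numerical choices

The default validation study (2000 genes, 27 samples, all 36 pairwise
contrasts, network on ~950 high-CV genes) runs in about two minutes on one
CPU; the test suite completes in about six. Tolerances: z/CS/TOM oracles
at 1e-9–1e-12; the exact-test enumeration window discards ~1e-16 of
conditional mass; eigengene computations standardize genes and zero out
non-finite rows. Ties in the minimum-likelihood p-value rule are included
with relative slack 1e-12; BH families are stated per use above. Degenerate
inputs are defined rather than left to chance: zero-scatter genes get
z = 0, zero CS denominators give NA, all-zero contrasts give p = 1, and a
gene set smaller than the module minimum yields an all-unassigned result
with a warning.

## Known limitations

* The DE test is a single-dispersion exact conditional test; it does not
  implement tagwise empirical-Bayes dispersion or quasi-likelihood GLMs,
  and its p-values will differ in detail from any specific external tool.
* The branch cut is adaptive but single-height-per-tree plus a kME rescue;
  a full recursive dynamic tree cut can resolve nested modules that this
  procedure merges or drops.
* The lncRNA classifier's ORF criterion is a literal scan; transcripts
  whose coding potential rests on non-ATG starts or frameshifts are out of
  scope, as are coding-potential scores.
* Expressed calls use replicate-mean RPKM; an any-replicate variant would
  admit more genes at the same threshold and is intentionally not the
  default (domain statistics all operate on the mean).
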