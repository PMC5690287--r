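---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stagecourse` re-implements, as a tested and reusable pipeline, the
computational analyses used to characterise a whole-embryo developmental
RNA-seq time course: 18 stages of zebrafish embryogenesis, five
biological replicates per stage, profiled from fertilisation to five
days post-fertilisation. This vignette documents the statistical models,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where the procedure was genuinely open.

## Normalisation and detectability

Counts are converted to transcripts per million (TPM): counts are first
divided by the gene's annotated exonic length (in nt) and each sample is
then rescaled to sum to $10^6$,
$$\mathrm{TPM}_{gs} = 10^6\,\frac{c_{gs}/\ell_g}{\sum_h c_{hs}/\ell_h}.$$
The exonic (union-exon) length is taken from the annotation table; no
effective-length correction is attempted. A gene is *detectable* when
there is at least one stage at which every replicate has TPM above zero
— a deliberately permissive rule that admits genes expressed in a
narrow developmental window while rejecting sporadic single-replicate
signal. The *stage of maximum expression* is the stage with the highest
replicate-mean TPM; exact ties resolve to the earliest stage in
developmental order (ties essentially never arise on real or noisy
synthetic data, so the tie-break only matters for degenerate inputs).

Because TPM is a relative (compositional) measure, a gene's TPM profile
is its absolute profile divided by the per-sample transcriptome total.
Two consequences recur throughout the package and its tests: a dataset
in which all genes share one temporal shape has *constant* TPM for every
gene, and hand-built test fixtures must hold column sums constant for
TPM to remain proportional to counts.

## Sample structure: correlation matrix and PCA

Sample-to-sample agreement is summarised by the Spearman rank
correlation of TPM over all genes (midrank ties), which is robust to the
handful of extremely abundant transcripts that dominate early embryonic
samples. Principal component analysis treats samples as observations
and genes as variables (`prcomp`, centred, not rescaled), projecting the
data from gene-space down to sample-space. The contribution of gene $g$
to component $k$ is its squared loading normalised over genes; genes
contributing more than 0.01% (`pca_contribution_threshold = 1e-4`) form
the component's top-contributor set. By default the PCA uses all genes
with any non-zero TPM; a `detectable`-only variant is available in the
configuration.

## Co-expression graph and Markov clustering

Genes with non-zero TPM variance become nodes; an edge links two genes
when the Pearson correlation of their TPM profiles across all samples
(not stage means) reaches `cor_threshold = 0.94`. The graph is
partitioned with an in-package implementation of the standard Markov
Cluster Algorithm: the weighted adjacency matrix plus self-loops is made
column-stochastic, then *expansion* (matrix power, default 2) and
*inflation* (entrywise power followed by column renormalisation, default
2.2) alternate, pruning entries below $10^{-5}$, until the largest
entry change falls below the tolerance. Clusters are read off the
attractor structure; nodes attracted to several systems go to the one
holding the most probability mass. Clusters with fewer than
`min_cluster_size = 6` genes are dissolved into an unassigned pool, and
survivors are relabelled by decreasing size.

Design notes:

* Inflation 2.2 with expansion 2 follows the documented defaults of the
  graph-clustering tool conventionally used for this analysis; the
  inflation actually used for published cluster counts is not stated
  anywhere, so cluster counts on real data are not a validation surface.
  Both parameters are exposed in the configuration.
* Self-loops are set to each node's maximum incident edge weight rather
  than 1, the common MCL practice for weighted graphs; it stabilises
  attractors when edge weights are all close to the threshold.
* Edge weights (correlations) are used in the stochastic matrix rather
  than a binarised adjacency.
* On graphs whose components are cliques, the output equals connected
  components for any inflation above 1 — a property the tests exercise
  along with exact recovery of a planted three-block graph.

Cluster expression profiles are the per-sample mean of member genes'
z-scored TPM (each gene centred to mean 0 and scaled to unit variance
across samples), so clusters of genes with the same shape but very
different absolute levels display the shared shape.

## Chromosome enrichment

For each cluster and each chromosome contributing more than five genes
to it (`enrich_min_count = 6`), the member count $k$ is compared with
the expectation $e = n p$ under random assignment, where $n$ is the
cluster size and $p$ the chromosome's share of the gene universe. The
raw p-value is the one-tailed binomial tail $P(X \ge k \mid n, p)$;
p-values are Benjamini–Hochberg adjusted across all tested (cluster,
chromosome) pairs and a pair is reported when the adjusted p-value is
below 0.05 *and* $\log_2(k/e) > 1$. BH is used as the multiple-testing
correction: it is deterministic and dependency-free, and controls the
FDR at the same level as the q-value procedure it stands in for. The
gene universe defining $p$ defaults to detectable genes and can be
switched to all annotated genes or to clustered genes only — the
published table's exact universe is not fully specified, so both are
implemented and the choice is recorded in provenance.

## Chromosomal co-expression domains

Genes are ordered along each chromosome by start coordinate and scanned
with overlapping windows of `window_size = 10` genes advancing one gene
at a time (unit stride is the maximal-information reading of
"overlapping windows"). Each window is scored by the mean of all
$\binom{10}{2} = 45$ pairwise Pearson correlations of TPM; windows
scoring above `window_cor_threshold = 0.5` are selected, and selected
windows sharing at least one gene are merged into maximal regions
(merging by genomic-span overlap is available behind the `domain_merge`
flag). Zero-variance genes are dropped before windowing and chromosomes
with fewer than 10 eligible genes are skipped. Every reported region
carries its peak window statistic, which the tests recompute from TPM.

## Promoters and peak overlap

Promoters span 1000 nt upstream to 200 nt downstream of the TSS
(strand-aware; the TSS of a minus-strand gene is its annotated end),
clipped at chromosome bounds. A gene's promoter *overlaps* a peak set
when it shares at least one base with at least one peak (interval
arithmetic via `GenomicRanges`). At a given stage, *expressed* genes
have replicate-mean TPM at or above 1 and *silent* genes have 0 TPM in
every replicate; genes between the two thresholds belong to neither
class. Percentages are reported to one decimal place.

## Paralogue divergence

Each paralogous pair receives the Pearson correlation of TPM across all
samples; pairs with a zero-variance member are flagged and excluded
from summaries. The null distribution comes from an equal number of
distinct gene pairs sampled uniformly without replacement from
detectable genes, excluding the true pairs. Spatial divergence is
summarised from anatomy-ontology annotation: each gene's annotation is
its set of (stage id, anatomy term) items, and the per-pair
intersection fraction is the Jaccard index
$|A \cap B| / |A \cup B|$ — symmetric and bounded — with
intersection-over-smaller-set available behind a flag, since the
published summary does not state its denominator. The headline summary
is the share of evaluated pairs whose fraction falls below 0.5.

## Transcript filter cascades

**pri-miRNA models.** Candidate primary-microRNA transcript models pass
five rules in order: multi-exon; span overlaps an annotated miRNA locus
on the same strand by at least one base; first and last exon at least
20 nt; no intron longer than 100,000 nt; every intron flanked by GT-AG
or GC-AG on the transcript strand. Removed models are attributed to the
first failing rule, so per-rule counts plus the kept count equal the
input.

**3' ends.** The DeTCT-style cascade removes putative polyadenylation
sites that look like internal-priming or context artefacts. The
`stricter` mode applies all rules: an end must lie within 5000 nt
downstream of protein-coding annotation or within 50 nt of non-coding
annotation (antisense, lincRNA, misc_RNA, processed_transcript biotypes;
distances strand-aware), must not have A-enriched sequence immediately
downstream, must not lie within 14 bp of an N, nor within coding
sequence, a simple repeat or a transposon, and must have a primary
hexamer upstream. The `strict` mode applies only the in-CDS,
in-transposon, A-enrichment and hexamer rules, so its kept set is a
superset of the stricter keeps. Two tests are parameterised stand-ins,
since the published description names neither windows nor thresholds:
"enriched for As" means at least 70% A (transcript-strand sense) in the
10 bases immediately downstream, and "near a primary hexamer" means
AATAAA or ATTAAA on the transcript strand within 40 nt upstream —
canonical poly(A)-signal conventions, both exposed in the
configuration and recorded in provenance. Rule order for attribution
(annotation distance, A-enrichment, N proximity, CDS, repeat,
transposon, hexamer) follows the order the rules are conventionally
described in; it affects only the per-rule accounting, never the kept
set. Simple repeats and transposons are supplied as interval inputs; no
repeat-finding is implemented.

## The synthetic-data generator

The generator produces the study's data *structure* with known ground
truth; it does not simulate reads, alignment or spatial expression.

**Temporal archetypes.** Each gene's mean profile follows one of five
shapes over the 18 stages: `rising` (zero until a zygotic onset a
quarter of the way through the course, then a power-law increase),
`falling` (its mirror — a maternal transcript fully degraded by three
quarters of the course), `double-peak` (a blastula/gastrula bump and a
lower bump late in the course), `zga-spike` (a narrow Gaussian centred
on the zygotic genome activation stage, stage 5 of 18), and
`flat-noise`. The default mixture is 25% rising, 25% falling, 15%
double-peak, 10% zga-spike and 25% flat-noise. The hard onsets give the
dataset genuinely silent genes (exact zeros), which the
detectability and expressed/silent classifications need.

**Counts.** Per-gene amplitudes are log-normal (median 100, sdlog 0.4);
expected counts split each sample's library size by relative transcript
abundance weighted by exonic length, so TPM recovers the planted
relative profiles exactly. Library sizes are log-normal around
3.8 million reads scaled by `library_scale` (default 0.01, i.e. 38,000
reads — desk scale). Counts are negative binomial with dispersion
`dispersion` (default 0.05; variance $\mu + \phi\mu^2$); at
`dispersion = 0` counts are the rounded means, a noiseless limit in
which the stage-of-max assignment recovers every peaked gene's
archetype peak exactly — the recovery property the tests assert.
`flat-noise` genes have no defined peak (their TPM varies only through
the transcriptome total) and are excluded from that check.

**Planted structure.** Domains occupy contiguous gene positions on a
named chromosome and share the domain archetype, so member genes are
mutually correlated; chromosomes of flat-noise genes provide the
pure-noise negative control. Paralogue pairs are planted at a target
stage-level Pearson correlation using an exact orthogonal-blend
construction in *relative* units: with background transcriptome sum
$A(t)$ and relative pair profiles $u_g(t)$ (capped at a 20% share), raw
profiles $u_g \cdot A/(1 - \sum u)$ make the expected TPM exactly
proportional to $u_g$, so at zero dispersion the realised correlation
equals the target to rounding error. Counting noise attenuates
correlations toward zero (by roughly the factor
$1/\sqrt{(1+\lambda_a)(1+\lambda_b)}$ with $\lambda$ the noise-to-signal
variance ratio), so the generator-recovery test runs at
`library_scale = 0.05` and `dispersion = 0.005`, where 50 pairs planted
at $r = 0.9$ are recovered within $\pm 0.05$; at the default desk-scale
depth the same construction recovers $\approx 0.75$–$0.8$, which the
analysis scripts report as-is.

**Genome fixture.** A two-chromosome genome carries one transcript per
pri-miRNA rule (including a 19-nt terminal exon, a 100,001-nt intron
and a CT-AC splice) with splice dinucleotides planted in the sequence,
and one 3' end per artefact class with hexamers, an A-tract and an N
run planted and accidental signals scrubbed from each end's windows.
Every verdict is therefore known by construction, and reversing and
complementing the whole fixture must leave all verdicts unchanged — the
strand mirror-symmetry test.

**What passing tests do and do not show.** The generator emulates the
design (stage count, replication, archetype structure, planted blocks
and pairs) but not real data's mean–variance trends, batch structure,
annotation errors, multi-mapping artefacts or spatially restricted
expression. Recovery of planted structure validates the *code paths*,
not the published biological findings; the headline counts of the real
study depend on the full sequencing data and genome annotation and are
out of reach at desk scale by design.

## Problem sizes and reproducibility

The analysis scripts and the acceptance script use 500 genes, 18 stages
and 3–5 replicates with a 15-gene planted block and 10 paralogue pairs;
the test suite uses 40–500 genes per case and 100 seeded replicates for
the domain-detector error-rate suite. These sizes give stable,
seed-robust behaviour while keeping any single run in seconds. One
master seed (configuration `seed`) fans out to fixed per-stage seeds so
stages can be rerun in isolation; identical seed and spec give
byte-identical outputs, which the pipeline manifest verifies by md5
checksum.

The `pipeline_cli` surface of this package is deliberately thin: the
exported functions, the numbered scripts under `analysis/` and
`run_pipeline()` *are* the interface; no shell wrapper is provided
because every consumer of this analysis works from R.
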