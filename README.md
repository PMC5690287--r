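# stagecourse

Analysis pipeline for a whole-embryo developmental RNA-seq time course:
18 stages of zebrafish embryogenesis, five biological replicates per
stage, from fertilisation to five days post-fertilisation. The package
implements, as tested and reusable functions, the bespoke computations
such a study needs beyond standard differential expression:

* **Normalisation & detectability** — TPM
  ($\mathrm{TPM}_{gs} = 10^6 (c_{gs}/\ell_g) / \sum_h c_{hs}/\ell_h$),
  the detectability rule (>0 TPM in all replicates of at least one
  stage), stage-of-maximum-expression assignment, and named/unnamed
  gene classification from clone-id name patterns.
* **Sample structure** — Spearman sample-correlation matrix and
  sample-space PCA with per-gene component contributions (squared
  loadings, 0.01% reporting threshold).
* **Co-expression clustering** — Pearson correlation graph at
  $r \ge 0.94$ partitioned with an in-package Markov Cluster Algorithm
  (inflation 2.2, expansion 2); clusters under 6 genes dissolved.
* **Chromosome enrichment** — per-cluster one-tailed binomial test
  ($P(X \ge k \mid n, p)$, tested where a chromosome contributes more
  than 5 genes), BH-adjusted, reported at adjusted $p < 0.05$ and
  $\log_2(k/e) > 1$.
* **Chromosomal co-expression domains** — sliding 10-gene windows
  scored by the mean of all 45 pairwise Pearson correlations; windows
  above 0.5 merged into regions.
* **Promoter/peak overlap** — promoters (TSS −1000/+200 nt,
  strand-aware) intersected with peak intervals for expressed
  (≥1 TPM) vs silent (0 TPM) genes.
* **Paralogue divergence** — pair correlations against a seeded
  random-pair null, and anatomy-annotation Jaccard intersection
  summaries.
* **Transcript filter cascades** — pri-miRNA model validation
  (multi-exon, miRNA-locus overlap, terminal exons ≥20 nt, introns
  ≤100,000 nt, GT-AG/GC-AG splice motifs) and DeTCT-style 3'-end
  filtering in `strict`/`stricter` modes with per-rule accounting.
* **Synthetic data** — a seeded generator planting temporal archetypes,
  chromosomal co-expression blocks, paralogue pairs with controlled
  correlation, and genome/annotation fixtures with known ground truth
  for every stage above.

Every threshold lives in one validated configuration
(`pipeline_config()`); `run_pipeline()` executes all stages from a
single seed and writes a checksummed manifest. See
`vignettes/stagecourse-methods.Rmd` for the models, parameter
rationale and limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic design (500 genes, 18 stages × 5 replicates, a 15-gene
ZGA-spike block planted on chr4, 10 paralogue pairs at target
$r = 0.9$):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_expression.R
Rscript analysis/03_clustering.R
Rscript analysis/04_genome_structure.R
Rscript analysis/05_paralogues.R
Rscript analysis/06_transcript_filters.R
```

Output of steps 3–4 on the default seed:

```
Graph at r >= 0.94: 500 nodes, 1107 edges (0 zero-variance genes dropped).
MCL: 6 clusters of >= 6 genes (sizes 68, 11, 10, 8, 8, 6); 389 genes unassigned.
Chromosome enrichment: 1 (cluster, chromosome) pairs tested, 1 reported.
  cluster 1 on chr4: 16 genes vs 2.72 expected, log2FE 2.56, adj p 8.65e-09
Co-expression domains (w = 10, mean r > 0.5): 1 region(s).
  planted block recovery: 15/15 member genes found.
Promoter-mark overlap at dome: 80.1% of 386 expressed vs 13.2% of 114 silent genes.
```

Reading this: the largest MCL cluster captures the ZGA-spike genes; 16
of its members sit on chr4 against an expectation of 2.72 under random
assignment (a $2^{2.56} \approx 5.9$-fold over-representation,
binomial adjusted $p \approx 10^{-8}$), so the planted chromosome-4
block is recovered, as is the full 15-gene co-expression domain by the
sliding-window scan. The promoter-mark overlap separates expressed from
silent genes exactly as the peak fixture planted it. Step 5 reports the
planted paralogue pairs' median correlation (≈0.76 at desk-scale
sequencing depth; counting noise attenuates the planted 0.9) against a
random-pair null centred on zero, and step 6 prints the two filter
cascades' flow tables, each rule removing exactly the one planted
violation.

All tables land under `results/` as TSV/BED/GTF/FASTA.

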