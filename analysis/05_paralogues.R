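#!/usr/bin/env Rscript

# Step 5 -- temporal divergence of paralogous pairs: planted-pair
# correlations against a random-pair null, and anatomy-annotation
# intersection.

source("analysis/00_setup.R")
ds <- read_dataset(data_dir)

fx <- generate_paralogue_fixture(spec, ds)
real <- pair_correlations(ds, fx$pairs)
null <- pair_correlations(
  ds, random_pair_null(ds, nrow(real), exclusions = real,
                       gene_ids = detectable_genes(ds),
                       seed = stagecourse:::derive_seed(config$seed,
                                                        "null_pairs")))
summ <- correlation_summary(real$pearson, null$pearson,
                            cuts = c(0, 0.45, 0.5))
cat(sprintf("Planted pairs (target r = %.1f): median %.2f; random-pair null median %.2f.\n",
            fx$pairs$target_cor[1],
            summ$quantiles["real", "50%"], summ$quantiles["null", "50%"]))
cat(sprintf("Fraction of real pairs below r = 0.45: %.2f (null: %.2f).\n",
            summ$fraction_below["real", "0.45"],
            summ$fraction_below["null", "0.45"]))

anat <- anatomy_overlap(real, fx$anatomy, cut = config$anatomy_cut,
                        denominator = config$anatomy_denominator)
cat(sprintf("Anatomy annotation: %.1f%% of %d evaluated pairs intersect below %.0f%%.\n",
            anat$percent_below, anat$n_evaluated, 100 * config$anatomy_cut))

stagecourse:::write_tsv_file(anat$pairs,
                             file.path(results_dir, "paralogue_pairs.tsv"))
stagecourse:::write_tsv_file(
  data.frame(distribution = rownames(summ$quantiles),
             round(summ$quantiles, 4), check.names = FALSE),
  file.path(results_dir, "paralogue_summary.tsv"))
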