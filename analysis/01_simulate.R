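#!/usr/bin/env Rscript

# Step 1 -- generate the synthetic developmental time course.
# Writes the count matrix, annotation, sample table and the generator's
# ground truth under results/.

source("analysis/00_setup.R")

sim <- generate_timecourse(spec)
write_dataset(sim$dataset, data_dir)
write_tsv_file <- stagecourse:::write_tsv_file
write_tsv_file(sim$truth$genes, file.path(results_dir, "truth_genes.tsv"))
write_tsv_file(sim$truth$domains, file.path(results_dir, "truth_domains.tsv"))
write_tsv_file(sim$truth$paralogues,
               file.path(results_dir, "truth_paralogues.tsv"))

cat(sprintf(
  "Simulated %d genes x %d samples (%d stages x %d replicates).\n",
  nrow(sim$dataset$counts), ncol(sim$dataset$counts),
  length(spec$stages), spec$replicates_per_stage))
cat(sprintf("Planted: %d-gene ZGA-spike block on chr4, %d paralogue pairs.\n",
            nrow(sim$truth$domains), nrow(sim$truth$paralogues)))
cat(sprintf("Archetype composition: %s.\n",
            paste(names(table(sim$truth$genes$archetype)),
                  table(sim$truth$genes$archetype), collapse = ", ")))
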