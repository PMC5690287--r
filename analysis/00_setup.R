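# Shared study design for the analysis scripts: one master seed, the
# published thresholds, and a synthetic 18-stage x 5-replicate embryo
# time course with a planted ZGA-spike block on chromosome 4 (a
# ZnF-like co-expression cluster) and 10 paralogue pairs planted at a
# stage-level correlation of 0.9.

library(stagecourse)

config <- pipeline_config(seed = 20260928L)
spec <- simulation_spec(
  n_genes = 500,
  replicates_per_stage = 5,
  planted_domains = list(list(chromosome = "chr4", start_index = 2,
                              n_genes = 15, archetype = "zga-spike")),
  paralogue_spec = list(list(target_cor = 0.9, n_pairs = 10)),
  seed = config$seed)

results_dir <- "results"
data_dir <- file.path(results_dir, "dataset")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
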