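#!/usr/bin/env Rscript

# Step 6 -- rule-based transcript filter cascades on the genome fixture:
# pri-miRNA model validation and DeTCT-style 3'-end filtering in strict
# and stricter modes, with per-rule accounting.

source("analysis/00_setup.R")

fx <- generate_genome_fixture(spec)
write_genome_fasta(fx$genome, file.path(results_dir, "genome.fasta"))
write_transcripts_gtf(fx$transcripts, file.path(results_dir,
                                                "transcripts.gtf"))

pri <- filter_pri_mirna(fx$transcripts, fx$mirna_loci, fx$genome,
                        min_terminal_exon = config$mirna_min_terminal_exon,
                        max_intron = config$mirna_max_intron)
flow <- end_filter_report(pri$n_input, pri$counts, length(pri$kept))
stagecourse:::write_tsv_file(flow, file.path(results_dir,
                                             "pri_mirna_filter_flow.tsv"))
cat(sprintf("pri-miRNA cascade: %d of %d candidate models kept.\n",
            length(pri$kept), pri$n_input))
print(flow)

for (mode in c("strict", "stricter")) {
  res <- detct_filter(fx$ends, fx$genes, fx$cds, fx$genome, fx$repeats,
                      fx$transposons, mode = mode,
                      coding_distance = config$detct_coding_distance,
                      noncoding_distance = config$detct_noncoding_distance,
                      n_distance = config$detct_n_distance,
                      polya_window = config$detct_polya_window,
                      polya_fraction = config$detct_polya_fraction,
                      hexamer_window = config$detct_hexamer_window,
                      hexamers = config$detct_hexamers)
  flow <- end_filter_report(res$n_input, res$counts, nrow(res$kept))
  stagecourse:::write_tsv_file(
    flow, file.path(results_dir, paste0("end_filter_flow_", mode, ".tsv")))
  cat(sprintf("\n3'-end cascade (--%s): %d of %d ends kept, %d of %d regions retained.\n",
              mode, nrow(res$kept), res$n_input,
              length(res$kept_regions),
              length(res$kept_regions) + length(res$removed_regions)))
  print(flow)
}
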