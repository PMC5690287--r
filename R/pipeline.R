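#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates every stage from a single configuration and simulation
#' spec: data generation, normalisation and PCA, correlation-graph MCL
#' clustering, chromosome enrichment, co-expression domains,
#' promoter/peak overlap, paralogue divergence and the transcript/3'-end
#' filter cascades. All stage outputs are written under `out_dir` and
#' registered, with checksums, in a run manifest (`manifest.json`). Any
#' stage failure halts the run with the stage name; the partial manifest
#' is still written.
#'
#' @param config A [pipeline_config()].
#' @param spec A [simulation_spec()]; its seed is overridden by the
#'   config seed so that one master seed governs the run.
#' @param out_dir Output directory.
#' @return The manifest, invisibly: config and spec snapshots, per-stage
#'   status, output file registry with md5 checksums, and the in-memory
#'   stage results in `$results`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         spec = simulation_spec(),
                         out_dir = "stagecourse_run") {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(spec, "simulation_spec"))
  spec$seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = paste0("stagecourse ",
                  as.character(utils::packageVersion("stagecourse"))),
    seed = config$seed,
    config = unclass(config),
    spec = unclass(spec)[c("n_genes", "replicates_per_stage", "dispersion",
                           "library_scale", "n_chromosomes", "seed")],
    stages = list(), files = character(0))
  results <- list()
  out <- function(name) file.path(out_dir, name)

  run_stage <- function(name, fun) {
    status <- tryCatch({
      fun()
      "ok"
    }, error = function(e) {
      manifest$stages[[name]] <<- "failed"
      write_manifest(manifest, out("manifest.json"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- status
  }

  ## ---- synthetic data -------------------------------------------------
  run_stage("synthetic_data", function() {
    sim <- generate_timecourse(spec)
    results$sim <<- sim
    write_dataset(sim$dataset, out("dataset"))
    write_tsv_file(sim$truth$genes, out("truth_genes.tsv"))
    write_tsv_file(sim$truth$domains, out("truth_domains.tsv"))
    write_tsv_file(sim$truth$paralogues, out("truth_paralogues.tsv"))
    jsonlite::write_json(manifest$spec, out("simulation_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  ## ---- expression core ------------------------------------------------
  run_stage("expression_core", function() {
    ds <- results$sim$dataset
    det <- detectable_genes(ds)
    som <- stage_of_max(ds)
    results$detectable <<- det
    results$stage_of_max <<- som
    results$name_summary <<- stage_name_summary(ds)
    write_tsv_file(results$name_summary, out("stage_name_summary.tsv"))
    cm <- sample_correlation_matrix(ds)
    write_matrix_tsv(round(cm, 4), out("sample_correlation.tsv"),
                     id_col = "sample_id")
    pca <- pca_samples(ds, gene_set = config$pca_gene_set,
                       contribution_threshold =
                         config$pca_contribution_threshold)
    results$pca <<- pca
    write_matrix_tsv(round(pca$scores, 4), out("pca_scores.tsv"),
                     id_col = "sample_id")
    write_tsv_file(
      data.frame(component = seq_along(pca$variance_fraction),
                 variance_fraction = pca$variance_fraction,
                 n_top_contributors = lengths(pca$top_contributors)),
      out("pca_variance.tsv"))
  })

  ## ---- network clustering --------------------------------------------
  run_stage("network_clustering", function() {
    ds <- results$sim$dataset
    graph <- build_correlation_graph(ds, config$cor_threshold,
                                     gene_ids = results$detectable)
    results$graph <<- graph
    write_tsv_file(graph$edges, out("coexpression_edges.tsv"))
    raw <- mcl(graph, inflation = config$mcl_inflation,
               expansion = config$mcl_expansion, tol = config$mcl_tol,
               prune = config$mcl_prune, max_iter = config$mcl_max_iter)
    clusters <- filter_clusters(raw, config$min_cluster_size)
    results$clusters <<- clusters
    write_tsv_file(cluster_table(clusters), out("clusters.tsv"))
    profiles <- vapply(clusters$clusters, cluster_profile, dataset = ds,
                       numeric(ncol(ds$tpm)))
    if (length(clusters$clusters) > 0) {
      write_matrix_tsv(round(t(profiles), 4), out("cluster_profiles.tsv"),
                       id_col = "cluster")
    }
  })

  ## ---- genome structure -----------------------------------------------
  run_stage("genome_structure", function() {
    ds <- results$sim$dataset
    universe <- switch(config$enrich_universe,
      detectable = results$detectable,
      all = ds$genes$gene_id,
      clustered = unlist(results$clusters$clusters, use.names = FALSE))
    enr <- chromosome_enrichment(results$clusters, ds$genes,
                                 universe = universe,
                                 alpha = config$enrich_fdr,
                                 min_count = config$enrich_min_count,
                                 log2fe_threshold = config$enrich_log2fe)
    results$enrichment <<- enr
    write_tsv_file(enr, out("chromosome_enrichment.tsv"))
    dom <- sliding_window_domains(ds, w = config$window_size,
                                  threshold = config$window_cor_threshold,
                                  gene_ids = results$detectable,
                                  merge = config$domain_merge)
    results$domains <<- dom
    if (nrow(dom) > 0) {
      write_bed(data.frame(chromosome = dom$chromosome, start = dom$start,
                           end = dom$end,
                           name = paste0("domain", seq_len(nrow(dom))),
                           score = round(100 * dom$peak_window_cor)),
                out("domains.bed"))
    }
    prom <- promoter_intervals(ds$genes, up = config$promoter_upstream,
                               down = config$promoter_downstream)
    write_bed(data.frame(prom[, c("chromosome", "start", "end")],
                         name = prom$gene_id, strand = prom$strand),
              out("promoters.bed"))
    stage <- stage_levels(ds)[zga_stage_index(length(stage_levels(ds)))]
    cls <- expression_classes(ds, stage, config$expressed_tpm)
    pk <- generate_peak_fixture(ds, stage,
                                seed = derive_seed(config$seed, "pipeline"))
    results$peak_overlap <<- peak_overlap_summary(prom, pk$peaks,
                                                  cls$expressed, cls$silent)
    write_tsv_file(results$peak_overlap, out("peak_overlap.tsv"))
  })

  ## ---- paralogue divergence -------------------------------------------
  run_stage("paralogue_divergence", function() {
    ds <- results$sim$dataset
    fx <- generate_paralogue_fixture(spec, ds)
    if (nrow(fx$pairs) == 0) {
      results$paralogues <<- NULL
      return(invisible(NULL))
    }
    real <- pair_correlations(ds, fx$pairs)
    null_pairs <- random_pair_null(
      ds, n = nrow(real), exclusions = real,
      gene_ids = results$detectable,
      seed = derive_seed(config$seed, "null_pairs"))
    null <- pair_correlations(ds, null_pairs)
    summ <- correlation_summary(real$pearson, null$pearson,
                                cuts = c(0, 0.45, config$anatomy_cut))
    anat <- anatomy_overlap(real, fx$anatomy, cut = config$anatomy_cut,
                            denominator = config$anatomy_denominator)
    results$paralogues <<- list(real = real, null = null, summary = summ,
                                anatomy = anat)
    write_tsv_file(anat$pairs, out("paralogue_pairs.tsv"))
    write_tsv_file(
      data.frame(distribution = rownames(summ$quantiles),
                 round(summ$quantiles, 4), check.names = FALSE),
      out("paralogue_summary.tsv"))
  })

  ## ---- transcript filters ---------------------------------------------
  run_stage("transcript_filters", function() {
    fx <- generate_genome_fixture(spec)
    results$genome_fixture <<- fx
    write_genome_fasta(fx$genome, out("genome.fasta"))
    write_transcripts_gtf(fx$transcripts, out("transcripts.gtf"))
    pri <- filter_pri_mirna(fx$transcripts, fx$mirna_loci, fx$genome,
                            min_terminal_exon = config$mirna_min_terminal_exon,
                            max_intron = config$mirna_max_intron,
                            motifs = paste(config$mirna_splice_motifs))
    results$pri_mirna <<- pri
    write_tsv_file(end_filter_report(pri$n_input, pri$counts,
                                     length(pri$kept)),
                   out("pri_mirna_filter_flow.tsv"))
    for (mode in c("strict", "stricter")) {
      res <- detct_filter(
        fx$ends, fx$genes, fx$cds, fx$genome, fx$repeats, fx$transposons,
        mode = mode,
        coding_distance = config$detct_coding_distance,
        noncoding_distance = config$detct_noncoding_distance,
        n_distance = config$detct_n_distance,
        polya_window = config$detct_polya_window,
        polya_fraction = config$detct_polya_fraction,
        hexamer_window = config$detct_hexamer_window,
        hexamers = config$detct_hexamers)
      results[[paste0("detct_", mode)]] <<- res
      write_tsv_file(end_filter_report(res$n_input, res$counts,
                                       nrow(res$kept)),
                     out(paste0("end_filter_flow_", mode, ".tsv")))
    }
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- stats::setNames(as.character(tools::md5sum(files)),
                                    sub(paste0("^", out_dir, "/?"), "",
                                        files))
  write_manifest(manifest, out("manifest.json"))
  manifest$results <- results
  invisible(manifest)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest[setdiff(names(manifest), "results")], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
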