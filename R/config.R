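#' Pipeline configuration
#'
#' Builds the single validated record that holds every threshold and seed
#' used by the pipeline. Defaults follow the published analysis of the
#' zebrafish developmental time course: a Pearson correlation cut-off of
#' 0.94 for the co-expression graph, a minimum cluster size of 6,
#' chromosome-enrichment testing only where a cluster holds more than 5
#' genes from a chromosome at FDR 0.05 with a log2 fold-enrichment report
#' threshold of 1, 10-gene sliding windows with a mean-correlation cut of
#' 0.5, promoters from 1000 nt upstream to 200 nt downstream of the TSS,
#' expressed/silent calls at 1 TPM / 0 TPM, a PCA gene-contribution
#' threshold of 0.01%, 3'-end distance limits of 5000 nt (protein-coding),
#' 50 nt (non-coding) and 14 nt (to an N), and pri-miRNA limits of a 20 nt
#' minimum terminal exon, a 100,000 nt maximum intron and GT-AG/GC-AG
#' splice motifs.
#'
#' @param ... named overrides of any default listed in
#'   [default_pipeline_config()].
#' @return A validated list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(mcl_inflation = 2.0)
#' cfg$cor_threshold
pipeline_config <- function(...) {
  overrides <- list(...)
  cfg <- default_pipeline_config()
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  validate_pipeline_config(cfg)
}

#' Default configuration values
#'
#' @return Named list of all tunable thresholds and seeds with their
#'   default values.
#' @export
default_pipeline_config <- function() {
  list(
    # co-expression graph / clustering
    cor_threshold       = 0.94,
    min_cluster_size    = 6L,
    mcl_inflation       = 2.2,
    mcl_expansion       = 2L,
    mcl_tol             = 1e-6,
    mcl_prune           = 1e-5,
    mcl_max_iter        = 100L,
    # chromosome enrichment
    enrich_min_count    = 6L,      # tested when count > 5
    enrich_fdr          = 0.05,
    enrich_log2fe       = 1,
    enrich_universe     = "detectable",  # or "all", "clustered"
    # chromosomal co-expression domains
    window_size         = 10L,
    window_cor_threshold = 0.5,
    domain_merge        = "gene",  # or "span"
    # promoters / expression classes
    promoter_upstream   = 1000L,
    promoter_downstream = 200L,
    expressed_tpm       = 1,
    # PCA
    pca_contribution_threshold = 1e-4,   # 0.01 %
    pca_gene_set        = "nonzero",     # or "detectable", "all"
    # paralogue anatomy intersection
    anatomy_cut         = 0.5,
    anatomy_denominator = "union",       # Jaccard; or "min"
    # DeTCT-style 3' end filtering
    detct_coding_distance    = 5000L,
    detct_noncoding_distance = 50L,
    detct_n_distance         = 14L,
    detct_polya_window       = 10L,
    detct_polya_fraction     = 0.7,
    detct_hexamer_window     = 40L,
    detct_hexamers           = c("AATAAA", "ATTAAA"),
    # pri-miRNA transcript filtering
    mirna_min_terminal_exon = 20L,
    mirna_max_intron        = 100000L,
    mirna_splice_motifs     = c("GT-AG", "GC-AG"),
    # seeds
    seed = 1L
  )
}

# legal range for each numeric scalar key (closed bounds unless noted)
config_ranges <- function() {
  list(
    cor_threshold        = c(0, 1, FALSE),   # open interval (0,1)
    min_cluster_size     = c(1, Inf, TRUE),
    mcl_inflation        = c(1, Inf, FALSE),
    mcl_expansion        = c(2, 10, TRUE),
    mcl_tol              = c(0, 1, FALSE),
    mcl_prune            = c(0, 1, FALSE),
    mcl_max_iter         = c(1, Inf, TRUE),
    enrich_min_count     = c(1, Inf, TRUE),
    enrich_fdr           = c(0, 1, FALSE),
    enrich_log2fe        = c(0, Inf, TRUE),
    window_size          = c(2, Inf, TRUE),
    window_cor_threshold = c(-1, 1, TRUE),
    promoter_upstream    = c(0, Inf, TRUE),
    promoter_downstream  = c(0, Inf, TRUE),
    expressed_tpm        = c(0, Inf, TRUE),
    pca_contribution_threshold = c(0, 1, TRUE),
    anatomy_cut          = c(0, 1, TRUE),
    detct_coding_distance    = c(0, Inf, TRUE),
    detct_noncoding_distance = c(0, Inf, TRUE),
    detct_n_distance         = c(0, Inf, TRUE),
    detct_polya_window       = c(1, Inf, TRUE),
    detct_polya_fraction     = c(0, 1, TRUE),
    detct_hexamer_window     = c(1, Inf, TRUE),
    mirna_min_terminal_exon  = c(1, Inf, TRUE),
    mirna_max_intron         = c(1, Inf, TRUE),
    seed = c(-2^31 + 1, 2^31 - 1, TRUE)
  )
}

validate_pipeline_config <- function(cfg) {
  errors <- character(0)
  ranges <- config_ranges()
  for (key in names(ranges)) {
    val <- cfg[[key]]
    rng <- ranges[[key]]
    ok <- is.numeric(val) && length(val) == 1 && is.finite(val) || key %in%
      c("min_cluster_size", "mcl_max_iter") && is.numeric(val)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
      errors <- c(errors, sprintf("%s: must be a single finite number", key))
      next
    }
    inside <- if (rng[3] == 1) val >= rng[1] && val <= rng[2] else
      val > rng[1] && val < rng[2]
    if (!inside) {
      errors <- c(errors, sprintf(
        "%s: value %s outside legal range %s%s, %s%s", key, format(val),
        if (rng[3] == 1) "[" else "(", format(rng[1]), format(rng[2]),
        if (rng[3] == 1) "]" else ")"))
    }
  }
  for (key in c("enrich_universe", "domain_merge", "pca_gene_set",
                "anatomy_denominator")) {
    allowed <- switch(key,
      enrich_universe = c("detectable", "all", "clustered"),
      domain_merge = c("gene", "span"),
      pca_gene_set = c("nonzero", "detectable", "all"),
      anatomy_denominator = c("union", "min"))
    if (!is.character(cfg[[key]]) || length(cfg[[key]]) != 1 ||
        !cfg[[key]] %in% allowed) {
      errors <- c(errors, sprintf("%s: must be one of %s", key,
                                  paste(allowed, collapse = ", ")))
    }
  }
  if (!is.character(cfg$detct_hexamers) || length(cfg$detct_hexamers) < 1 ||
      !all(grepl("^[ACGT]+$", cfg$detct_hexamers))) {
    errors <- c(errors, "detct_hexamers: must be DNA motifs (ACGT)")
  }
  if (!all(cfg$mirna_splice_motifs %in% c("GT-AG", "GC-AG", "AT-AC"))) {
    errors <- c(errors, "mirna_splice_motifs: unknown motif label")
  }
  if (length(errors) > 0) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  }
  # coerce integer-valued keys so serialisation round-trips losslessly
  int_keys <- c("min_cluster_size", "mcl_expansion", "mcl_max_iter",
                "enrich_min_count", "window_size", "promoter_upstream",
                "promoter_downstream", "detct_coding_distance",
                "detct_noncoding_distance", "detct_n_distance",
                "detct_polya_window", "detct_hexamer_window",
                "mirna_min_terminal_exon", "mirna_max_intron", "seed")
  for (key in int_keys) cfg[[key]] <- as.integer(cfg[[key]])
  structure(cfg, class = "pipeline_config")
}

#' Read and validate a configuration file
#'
#' Reads a YAML (or JSON, a YAML subset) config file, fills defaults for
#' missing keys, rejects unknown keys and range-checks every threshold.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a YAML config file.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a mapping of keys")
  do.call(pipeline_config, raw)
}

#' Write a configuration to a YAML file
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config with", length(x), "settings\n")
  for (key in names(x)) {
    cat(sprintf("  %-28s %s\n", key, paste(format(x[[key]]), collapse = ", ")))
  }
  invisible(x)
}
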