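#' Detectable genes
#'
#' A gene is detectable if there is at least one stage at which every
#' replicate has TPM above zero. This tolerates genes expressed only in a
#' narrow developmental window while excluding genes never consistently
#' observed.
#'
#' @param dataset An [expression_dataset()].
#' @return Character vector of detectable gene ids.
#' @export
detectable_genes <- function(dataset) {
  stage <- dataset$samples$stage
  pos <- dataset$tpm > 0
  by_stage <- vapply(unique(stage), function(s) {
    rowSums(pos[, stage == s, drop = FALSE]) == sum(stage == s)
  }, logical(nrow(pos)))
  rownames(dataset$tpm)[rowSums(by_stage) > 0]
}

#' Stage of maximum expression
#'
#' For each requested (detectable) gene, the stage whose mean TPM across
#' replicates is highest; exact ties resolve to the earliest stage in
#' developmental order.
#'
#' @param dataset An [expression_dataset()].
#' @param gene_ids Genes to map; defaults to [detectable_genes()].
#' @return Named character vector gene id -> stage label.
#' @export
stage_of_max <- function(dataset, gene_ids = detectable_genes(dataset)) {
  missing <- setdiff(gene_ids, rownames(dataset$tpm))
  if (length(missing) > 0) {
    stop("unknown gene id(s): ", paste(utils::head(missing, 5),
                                       collapse = ", "))
  }
  undet <- setdiff(gene_ids, detectable_genes(dataset))
  if (length(undet) > 0) {
    stop("stage_of_max requested for undetectable gene(s): ",
         paste(utils::head(undet, 5), collapse = ", "))
  }
  lv <- stage_levels(dataset)
  means <- stage_means(dataset)[gene_ids, lv, drop = FALSE]
  stats::setNames(lv[apply(means, 1, which.max)], gene_ids)
}

#' Per-stage mean TPM
#'
#' @param dataset An [expression_dataset()].
#' @return Gene x stage matrix of replicate-mean TPM, stages in
#'   developmental order.
#' @export
stage_means <- function(dataset) {
  lv <- stage_levels(dataset)
  out <- vapply(lv, function(s) {
    rowMeans(dataset$tpm[, dataset$samples$stage == s, drop = FALSE])
  }, numeric(nrow(dataset$tpm)))
  rownames(out) <- rownames(dataset$tpm)
  out
}

#' Classify a gene name as named or unnamed
#'
#' Unnamed genes carry automatically generated identifiers derived from
#' clone ids or genebuild accessions rather than curated symbols. A name
#' is unnamed iff it fully matches one of:
#' `[A-Z][A-Z][0-9]{6}\.[0-9]+`, `CABZ[0-9]{8}\.[0-9]+`, `im:[0-9]{7}`,
#' `si:.*`, `wu:.*`, `zgc:[0-9]{5,6}`.
#'
#' @param name Character vector of gene names.
#' @return Character vector, each element `"named"` or `"unnamed"`.
#' @export
#' @examples
#' classify_gene_name(c("ndr2", "zgc:77112", "si:ch211-222l21.1"))
classify_gene_name <- function(name) {
  if (any(!nzchar(name))) stop("gene names must be non-empty")
  patterns <- c("[A-Z][A-Z][0-9]{6}\\.[0-9]+", "CABZ[0-9]{8}\\.[0-9]+",
                "im:[0-9]{7}", "si:.*", "wu:.*", "zgc:[0-9]{5,6}")
  full <- paste0("^(", paste(patterns, collapse = "|"), ")$")
  ifelse(grepl(full, name), "unnamed", "named")
}

#' Sample-sample Spearman correlation matrix
#'
#' Rank correlation of TPM between every pair of samples; Spearman is
#' preferred over Pearson here for its robustness to a handful of very
#' highly expressed genes. Ties receive average (midrank) ranks. A sample
#' with identical values for all genes has no defined rank correlation;
#' its entries are `NA` with a warning.
#'
#' @param dataset An [expression_dataset()].
#' @return Symmetric sample x sample matrix with unit diagonal.
#' @export
sample_correlation_matrix <- function(dataset) {
  if (ncol(dataset$tpm) < 2) stop("need at least two samples")
  sds <- row_sds(t(dataset$tpm))
  cc <- suppressWarnings(stats::cor(dataset$tpm, method = "spearman"))
  if (any(sds == 0)) {
    warning("constant sample(s), correlation undefined: ",
            paste(colnames(dataset$tpm)[sds == 0], collapse = ", "))
  }
  diag(cc) <- 1
  cc
}

#' Principal component analysis of samples
#'
#' Samples are the observations and genes the variables (the data are
#' projected from gene-space down to sample-space); variables are centred
#' but not rescaled, matching `prcomp`'s default. Per-gene contributions
#' to a component are the squared loadings normalised to sum to 1 over
#' genes; "top contributors" are genes whose contribution exceeds
#' `contribution_threshold` (default 0.01%).
#'
#' @param dataset An [expression_dataset()].
#' @param gene_set Which genes enter the PCA: `"nonzero"` (any non-zero
#'   TPM; default), `"detectable"`, or `"all"`.
#' @param contribution_threshold Proportion-of-variance cut for the
#'   top-contributor sets.
#' @return List with `scores` (sample x component), `variance_fraction`,
#'   `contributions` (gene x component), `top_contributors` (list of gene
#'   id vectors per component), `gene_ids`.
#' @export
pca_samples <- function(dataset, gene_set = c("nonzero", "detectable", "all"),
                        contribution_threshold = 1e-4) {
  gene_set <- match.arg(gene_set)
  if (ncol(dataset$tpm) < 2) stop("need at least two samples")
  keep <- switch(gene_set,
    nonzero = rownames(dataset$tpm)[rowSums(dataset$tpm) > 0],
    detectable = detectable_genes(dataset),
    all = rownames(dataset$tpm))
  x <- t(dataset$tpm[keep, , drop = FALSE])
  if (sum(apply(x, 2, stats::sd) > 0) < 2) {
    stop("need at least two genes with non-zero variance")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  contrib <- sweep(fit$rotation^2, 2, colSums(fit$rotation^2), "/")
  top <- lapply(seq_len(ncol(contrib)), function(k) {
    rownames(contrib)[contrib[, k] > contribution_threshold]
  })
  names(top) <- colnames(contrib)
  list(scores = fit$x, variance_fraction = vf, contributions = contrib,
       top_contributors = top, gene_ids = keep)
}

#' Named/unnamed gene counts per stage of maximum expression
#'
#' @param dataset An [expression_dataset()].
#' @return Data frame with one row per stage (developmental order) and
#'   counts of named and unnamed detectable genes peaking at that stage.
#' @export
stage_name_summary <- function(dataset) {
  som <- stage_of_max(dataset)
  cls <- classify_gene_name(
    dataset$genes$name[match(names(som), dataset$genes$gene_id)])
  lv <- stage_levels(dataset)
  tab <- table(factor(som, lv), factor(cls, c("named", "unnamed")))
  data.frame(stage = lv, named = as.integer(tab[, "named"]),
             unnamed = as.integer(tab[, "unnamed"]),
             row.names = NULL, stringsAsFactors = FALSE)
}
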