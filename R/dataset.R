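#' Convert raw counts to transcripts per million (TPM)
#'
#' TPM first divides each gene's count by its exonic length (giving a
#' quantity proportional to transcript abundance) and then rescales each
#' sample so the values sum to one million:
#' \deqn{TPM_{gs} = 10^6 \frac{c_{gs}/\ell_g}{\sum_h c_{hs}/\ell_h}}
#' Columns whose counts are all zero yield all-zero TPM.
#'
#' @param counts Non-negative gene x sample matrix.
#' @param lengths Strictly positive per-gene exonic lengths (nt), in row
#'   order of `counts`.
#' @return A gene x sample TPM matrix with the same dimnames.
#' @export
#' @examples
#' counts_to_tpm(matrix(c(10, 10), 2, 1), lengths = c(100, 200))
counts_to_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) {
    stop("lengths must have one entry per gene (row of counts)")
  }
  bad <- which(!is.finite(lengths) | lengths <= 0)
  if (length(bad) > 0) {
    ids <- rownames(counts)[bad] %||% as.character(bad)
    stop("non-positive exonic length for gene(s): ",
         paste(utils::head(ids, 5), collapse = ", "))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom == 0, 1, denom), "/") * 1e6
  tpm[, denom == 0] <- 0
  dimnames(tpm) <- dimnames(counts)
  tpm
}

#' Construct an expression dataset
#'
#' The container consumed by every analysis stage: a counts matrix, the
#' derived TPM matrix, gene annotation and sample metadata. Sample ids are
#' expected to be unique; each sample belongs to exactly one stage and
#' stages carry an explicit developmental order.
#'
#' @param counts Non-negative integer gene x sample matrix with gene ids
#'   as rownames and sample ids as colnames.
#' @param genes Annotation data frame with columns `gene_id`, `name`,
#'   `chromosome`, `strand`, `start`, `end`, `exonic_length`, `biotype`,
#'   one row per counts row, in the same order.
#' @param samples Data frame with columns `sample_id`, `stage`,
#'   `stage_index` (developmental order, 1-based), `replicate`, one row per
#'   counts column, in the same order.
#' @return An object of class `expression_dataset` with elements `counts`,
#'   `tpm`, `genes`, `samples`.
#' @export
expression_dataset <- function(counts, genes, samples) {
  counts <- as.matrix(counts)
  need_g <- c("gene_id", "name", "chromosome", "strand", "start", "end",
              "exonic_length", "biotype")
  need_s <- c("sample_id", "stage", "stage_index", "replicate")
  if (!all(need_g %in% names(genes))) {
    stop("genes annotation missing column(s): ",
         paste(setdiff(need_g, names(genes)), collapse = ", "))
  }
  if (!all(need_s %in% names(samples))) {
    stop("samples table missing column(s): ",
         paste(setdiff(need_s, names(samples)), collapse = ", "))
  }
  if (nrow(genes) != nrow(counts)) stop("genes rows must match counts rows")
  if (nrow(samples) != ncol(counts)) {
    stop("samples rows must match counts columns")
  }
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  rownames(counts) <- genes$gene_id
  colnames(counts) <- samples$sample_id
  # stage_index must be consistent: one index per stage, non-decreasing
  # when samples are sorted by index
  idx <- tapply(samples$stage_index, samples$stage, function(x)
    length(unique(x)))
  if (any(idx != 1)) stop("each stage must map to a single stage_index")
  structure(
    list(counts = counts,
         tpm = counts_to_tpm(counts, genes$exonic_length),
         genes = as.data.frame(genes),
         samples = as.data.frame(samples)),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d samples (%d stages x up to %d replicates)\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$samples$stage)),
    max(x$samples$replicate)))
  invisible(x)
}

#' Ordered stage labels of a dataset
#'
#' @param dataset An `expression_dataset`.
#' @return Character vector of stage labels in developmental order.
#' @export
stage_levels <- function(dataset) {
  s <- unique(dataset$samples[, c("stage", "stage_index")])
  s$stage[order(s$stage_index)]
}
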