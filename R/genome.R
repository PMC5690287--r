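#' Log2 fold enrichment
#'
#' @param k Observed count.
#' @param expected Expected count under the null.
#' @return `log2(k / expected)`.
#' @export
log2_fold_enrichment <- function(k, expected) {
  if (any(expected <= 0)) stop("expected count must be positive")
  log2(k / expected)
}

#' Chromosome over-representation within clusters
#'
#' For every (cluster, chromosome) combination where the cluster holds at
#' least `min_count` genes from that chromosome, tests whether the count
#' exceeds the expectation under random assignment. With cluster size `n`
#' and genome-wide chromosome gene fraction `p`, the expected count is
#' `n * p` and the raw p-value is the one-tailed binomial tail
#' `P(X >= k | n, p)`. P-values are Benjamini-Hochberg adjusted across all
#' tested combinations.
#'
#' @param clusters A `cluster_set`.
#' @param genes Gene annotation data frame (`gene_id`, `chromosome`).
#' @param universe Gene ids defining the background fraction `p`;
#'   defaults to all annotated genes.
#' @param alpha FDR level for the `significant` flag.
#' @param min_count A chromosome is tested in a cluster only when its
#'   count reaches this value (default 6, i.e. more than five genes).
#' @param log2fe_threshold Fold-enrichment report threshold.
#' @return Data frame with columns `cluster`, `chromosome`, `count`,
#'   `expected`, `log2_fe`, `p_value`, `adjusted_p`, `significant`
#'   (adjusted p below `alpha` and log2 FE above `log2fe_threshold`).
#' @export
chromosome_enrichment <- function(clusters, genes, universe = genes$gene_id,
                                  alpha = 0.05, min_count = 6,
                                  log2fe_threshold = 1) {
  chrom_of <- stats::setNames(genes$chromosome, genes$gene_id)
  uni_chrom <- chrom_of[universe]
  if (anyNA(uni_chrom)) stop("universe contains genes without annotation")
  frac <- table(uni_chrom) / length(uni_chrom)
  rows <- list()
  for (lab in names(clusters$clusters)) {
    members <- clusters$clusters[[lab]]
    if (anyNA(chrom_of[members])) {
      stop("clustered gene(s) lack chromosome annotation")
    }
    n <- length(members)
    counts <- table(chrom_of[members])
    for (chrom in names(counts)) {
      k <- as.integer(counts[[chrom]])
      if (k < min_count) next
      p <- as.numeric(frac[chrom])
      if (is.na(p) || p <= 0 || p >= 1) {
        stop("degenerate background fraction for chromosome ", chrom)
      }
      rows[[length(rows) + 1]] <- data.frame(
        cluster = as.integer(lab), chromosome = chrom, count = k,
        expected = n * p,
        log2_fe = log2_fold_enrichment(k, n * p),
        p_value = stats::pbinom(k - 1, n, p, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(cluster = integer(0), chromosome = character(0),
                      count = integer(0), expected = numeric(0),
                      log2_fe = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < alpha & out$log2_fe > log2fe_threshold
  out[order(out$adjusted_p), ]
}

#' Number of gene pairs per sliding window
#' @param w Window size in genes.
#' @return `choose(w, 2)`.
#' @export
window_pair_count <- function(w) choose(w, 2)

#' Sliding-window chromosomal co-expression domains
#'
#' Orders genes along each chromosome by start coordinate, slides a
#' window of `w` genes one gene at a time, and scores each window by the
#' mean of all `choose(w, 2)` pairwise Pearson correlations of TPM across
#' samples. Windows scoring above the threshold are selected and
#' overlapping selected windows (sharing at least one gene) are merged
#' into maximal regions. Zero-variance genes are dropped before
#' windowing; chromosomes with fewer than `w` eligible genes are skipped.
#'
#' @param dataset An [expression_dataset()].
#' @param w Window size in genes.
#' @param threshold Mean-correlation selection threshold.
#' @param gene_ids Gene universe; defaults to all genes.
#' @param merge Whether overlapping selected windows are merged when they
#'   share a gene (default) or when their genomic spans intersect.
#' @return Data frame, one row per merged region: `chromosome`,
#'   `first_gene`, `last_gene`, `start`, `end`, `n_genes`,
#'   `peak_window_cor`, plus attribute `members` (list of gene id
#'   vectors).
#' @export
sliding_window_domains <- function(dataset, w = 10, threshold = 0.5,
                                   gene_ids = rownames(dataset$tpm),
                                   merge = c("gene", "span")) {
  merge <- match.arg(merge)
  ann <- dataset$genes[match(gene_ids, dataset$genes$gene_id), ]
  if (anyNA(ann$start)) stop("genes lack coordinates")
  x <- dataset$tpm[gene_ids, , drop = FALSE]
  keep <- row_sds(x) > 0
  ann <- ann[keep, ]
  regions <- list()
  members <- list()
  for (chrom in unique(ann$chromosome)) {
    sub <- ann[ann$chromosome == chrom, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) < w) next
    cc <- stats::cor(t(dataset$tpm[sub$gene_id, , drop = FALSE]))
    n_win <- nrow(sub) - w + 1
    stat <- vapply(seq_len(n_win), function(i) {
      block <- cc[i:(i + w - 1), i:(i + w - 1)]
      mean(block[upper.tri(block)])
    }, numeric(1))
    sel <- which(stat > threshold)
    if (length(sel) == 0) next
    grp <- if (merge == "gene") {
      # windows sharing >= 1 gene: starts within w-1 of each other
      cumsum(c(1, diff(sel) > (w - 1)))
    } else {
      # genomic-span overlap between consecutive selected windows
      span_s <- vapply(sel, function(i) min(sub$start[i:(i + w - 1)]),
                       numeric(1))
      span_e <- vapply(sel, function(i) max(sub$end[i:(i + w - 1)]),
                       numeric(1))
      if (length(sel) == 1) 1 else
        cumsum(c(1, span_s[-1] > cummax(span_e)[-length(sel)]))
    }
    for (g in unique(grp)) {
      win <- sel[grp == g]
      first <- min(win)
      last <- max(win) + w - 1
      ids <- sub$gene_id[first:last]
      regions[[length(regions) + 1]] <- data.frame(
        chromosome = chrom,
        first_gene = ids[1], last_gene = ids[length(ids)],
        start = min(sub$start[first:last]),
        end = max(sub$end[first:last]),
        n_genes = length(ids),
        peak_window_cor = max(stat[win]),
        stringsAsFactors = FALSE)
      members[[length(members) + 1]] <- ids
    }
  }
  out <- if (length(regions) == 0) {
    data.frame(chromosome = character(0), first_gene = character(0),
               last_gene = character(0), start = integer(0), end = integer(0),
               n_genes = integer(0), peak_window_cor = numeric(0))
  } else {
    do.call(rbind, regions)
  }
  attr(out, "members") <- members
  out
}

#' Promoter intervals around transcription start sites
#'
#' The TSS of a `+` strand gene is its annotated start, of a `-` strand
#' gene its annotated end. The promoter spans `up` nt upstream to `down`
#' nt downstream of the TSS (strand-aware) and is clipped at position 1
#' and, when chromosome lengths are supplied, at the chromosome end.
#'
#' @param genes Annotation data frame (`gene_id`, `chromosome`, `strand`,
#'   `start`, `end`).
#' @param up,down Extent upstream/downstream of the TSS in nt.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Data frame `gene_id`, `chromosome`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates).
#' @export
promoter_intervals <- function(genes, up = 1000, down = 200,
                               chrom_lengths = NULL) {
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("promoters require stranded genes (+ or -)")
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  start <- ifelse(genes$strand == "+", tss - up, tss - down)
  end <- ifelse(genes$strand == "+", tss + down, tss + up)
  start <- pmax(start, 1)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chromosome]
    if (anyNA(lim)) stop("chromosome missing from lengths: ",
                         paste(unique(genes$chromosome[is.na(lim)]),
                               collapse = ", "))
    end <- pmin(end, lim)
  }
  data.frame(gene_id = genes$gene_id, chromosome = genes$chromosome,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Overlap between promoters and peaks for expressed vs silent genes
#'
#' A gene's promoter overlaps iff it shares at least one base with at
#' least one peak. Expressed and silent gene sets must be disjoint.
#'
#' @param promoters Data frame from [promoter_intervals()].
#' @param peaks Interval data frame (`chromosome`, `start`, `end`),
#'   1-based inclusive.
#' @param expressed,silent Character vectors of gene ids.
#' @return Data frame with one row per class: `class`, `overlapping`,
#'   `total`, `percent` (1 decimal place).
#' @export
peak_overlap_summary <- function(promoters, peaks, expressed, silent) {
  if (length(intersect(expressed, silent)) > 0) {
    stop("gene(s) in both expressed and silent classes: ",
         paste(utils::head(intersect(expressed, silent), 5), collapse = ", "))
  }
  prom_gr <- GenomicRanges::GRanges(
    promoters$chromosome,
    IRanges::IRanges(promoters$start, promoters$end))
  hit_ids <- if (nrow(peaks) == 0) character(0) else {
    peak_gr <- GenomicRanges::GRanges(
      peaks$chromosome, IRanges::IRanges(peaks$start, peaks$end))
    promoters$gene_id[
      unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(prom_gr, peak_gr)))]
  }
  mk <- function(class, ids) {
    ov <- sum(ids %in% hit_ids)
    data.frame(class = class, overlapping = ov, total = length(ids),
               percent = overlap_percent(ov, length(ids)),
               stringsAsFactors = FALSE)
  }
  rbind(mk("expressed", expressed), mk("silent", silent))
}

#' Overlap percentage to one decimal place
#'
#' @param overlapping,total Counts.
#' @return `100 * overlapping / total` rounded to 1 decimal place (0 when
#'   `total` is 0).
#' @export
#' @examples
#' overlap_percent(10747, 12950)
overlap_percent <- function(overlapping, total) {
  ifelse(total == 0, 0, round(100 * overlapping / total, 1))
}

#' Genes expressed / silent at a stage
#'
#' Expressed genes have replicate-mean TPM at or above `tpm_threshold` at
#' the stage; silent genes have 0 TPM in every sample of that stage.
#'
#' @param dataset An [expression_dataset()].
#' @param stage Stage label.
#' @param tpm_threshold Expression threshold (TPM).
#' @return List with character vectors `expressed` and `silent`.
#' @export
expression_classes <- function(dataset, stage, tpm_threshold = 1) {
  if (!stage %in% dataset$samples$stage) stop("unknown stage: ", stage)
  cols <- dataset$samples$stage == stage
  x <- dataset$tpm[, cols, drop = FALSE]
  list(expressed = rownames(x)[rowMeans(x) >= tpm_threshold],
       silent = rownames(x)[rowSums(x > 0) == 0])
}
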