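# Readers and writers for the pipeline's on-disk formats. Tabular data
# is TSV; sequence FASTA (Biostrings); transcripts GTF and intervals BED
# (rtracklayer, which performs the 1-based/0-based conversion on BED).

#' Write an expression dataset to a directory
#'
#' Emits `counts.tsv`, `tpm.tsv`, `genes.tsv` and `samples.tsv`.
#'
#' @param dataset An [expression_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(dataset$counts, file.path(dir, "counts.tsv"))
  write_matrix_tsv(round(dataset$tpm, 4), file.path(dir, "tpm.tsv"))
  write_tsv_file(dataset$genes, file.path(dir, "genes.tsv"))
  write_tsv_file(dataset$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' Read an expression dataset written by [write_dataset()]
#'
#' TPM is recomputed from the counts rather than read back.
#'
#' @param dir Directory containing `counts.tsv`, `genes.tsv`,
#'   `samples.tsv`.
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(dir) {
  expression_dataset(read_matrix_tsv(file.path(dir, "counts.tsv")),
                     read_tsv_file(file.path(dir, "genes.tsv")),
                     read_tsv_file(file.path(dir, "samples.tsv")))
}

#' Write chromosome sequences as FASTA
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read chromosome sequences from FASTA
#' @param path FASTA file.
#' @return Named [Biostrings::DNAStringSet] (names truncated at the
#'   first whitespace).
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Write exon-level transcript models as GTF
#'
#' @param transcripts Data frame (`transcript_id`, `gene_id`,
#'   `chromosome`, `strand`, `start`, `end`), one row per exon.
#' @param path Output `.gtf` file.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  gr <- GenomicRanges::GRanges(
    transcripts$chromosome,
    IRanges::IRanges(transcripts$start, transcripts$end),
    strand = transcripts$strand,
    type = "exon",
    source = "stagecourse",
    transcript_id = transcripts$transcript_id,
    gene_id = transcripts$gene_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read exon-level transcript models from GTF
#' @param path GTF file.
#' @return Data frame in the shape accepted by [filter_pri_mirna()].
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  data.frame(transcript_id = gr$transcript_id, gene_id = gr$gene_id,
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write an interval table as BED
#'
#' Internal coordinates are 1-based inclusive; the writer converts to
#' BED's 0-based half-open convention.
#'
#' @param intervals Data frame with `chromosome`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output `.bed` file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  strand <- intervals$strand %||% rep("*", nrow(intervals))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    intervals$chromosome,
    IRanges::IRanges(intervals$start, intervals$end),
    strand = strand)
  if (!is.null(intervals$name)) gr$name <- intervals$name
  if (!is.null(intervals$score)) gr$score <- intervals$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file as a 1-based interval table
#' @param path BED file.
#' @return Data frame `chromosome`, `start`, `end`, `name`, `score`,
#'   `strand` (columns present when in the file).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st %in% c("+", "-"))) out$strand <- st
  out
}
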