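# shared fixture builders (everything is generated in code at test time)

# hand-built dataset: counts is gene x sample, stages recycle over columns
toy_dataset <- function(counts, stages, lengths = NULL, strand = NULL,
                        chromosome = NULL, names = NULL) {
  n <- nrow(counts)
  m <- ncol(counts)
  if (is.null(lengths)) lengths <- rep(1000L, n)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    name = names %||% sprintf("gene%d", seq_len(n)),
    chromosome = chromosome %||% rep("chr1", n),
    strand = strand %||% rep("+", n),
    start = seq_len(n) * 10000L,
    end = seq_len(n) * 10000L + 5000L,
    exonic_length = lengths,
    biotype = "protein_coding",
    stringsAsFactors = FALSE)
  reps <- as.integer(ave(seq_len(m), rep(stages, length.out = m),
                         FUN = seq_along))
  samples <- data.frame(
    sample_id = paste(rep(stages, length.out = m), reps, sep = "_"),
    stage = rep(stages, length.out = m),
    stage_index = match(rep(stages, length.out = m), unique(stages)),
    replicate = reps,
    stringsAsFactors = FALSE)
  expression_dataset(counts, genes, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# weighted graph of disjoint cliques, in the shape build_correlation_graph
# produces
clique_graph <- function(sizes, weight = 1) {
  nodes <- unlist(lapply(seq_along(sizes), function(i) {
    paste0("c", i, "_", seq_len(sizes[i]))
  }))
  edges <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    ids <- paste0("c", i, "_", seq_len(sizes[i]))
    if (length(ids) < 2) return(NULL)
    as.data.frame(t(utils::combn(ids, 2)), stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(V1 = character(0), V2 = character(0))
  }
  list(nodes = nodes,
       edges = data.frame(gene_a = edges$V1, gene_b = edges$V2,
                          weight = weight, stringsAsFactors = FALSE))
}

# reverse-complement an entire genome fixture: sequences are reverse
# complemented, all coordinates reflected, all strands flipped
mirror_fixture <- function(fx) {
  lens <- vapply(seq_along(fx$genome), function(i) length(fx$genome[[i]]),
                 integer(1))
  names(lens) <- names(fx$genome)
  flip_iv <- function(df) {
    L <- lens[df$chromosome]
    s <- L - df$end + 1L
    e <- L - df$start + 1L
    df$start <- as.integer(s)
    df$end <- as.integer(e)
    if (!is.null(df$strand)) df$strand <- chartr("+-", "-+", df$strand)
    df
  }
  fx$genome <- Biostrings::reverseComplement(fx$genome)
  for (nm in c("transcripts", "mirna_loci", "genes", "cds", "repeats",
               "transposons")) {
    fx[[nm]] <- flip_iv(fx[[nm]])
  }
  fx$ends$position <- as.integer(lens[fx$ends$chromosome] -
                                   fx$ends$position + 1L)
  fx$ends$strand <- chartr("+-", "-+", fx$ends$strand)
  fx
}
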