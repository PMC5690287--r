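# Seeded genome + annotation fixtures with known ground truth for the
# transcript and 3'-end filter cascades.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

# overwrite seq[start..end] (plus-strand coordinates) with the plus-strand
# representation of `motif` given the strand it should read on
plant <- function(seq_chars, start, motif, strand = "+") {
  if (strand == "-") {
    motif <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
  }
  bases <- strsplit(motif, "")[[1]]
  seq_chars[start:(start + length(bases) - 1)] <- bases
  seq_chars
}

# remove every occurrence of the motifs within [start, end] by mutating
# one base of each occurrence
scrub_motifs <- function(seq_chars, start, end, motifs) {
  repeat {
    window <- paste(seq_chars[start:end], collapse = "")
    hit <- NULL
    for (m in motifs) {
      at <- regexpr(m, window, fixed = TRUE)
      if (at > 0) { hit <- c(at, nchar(m)); break }
    }
    if (is.null(hit)) break
    pos <- start + hit[1] - 1
    seq_chars[pos] <- if (seq_chars[pos] == "A") "C" else "A"
  }
  seq_chars
}

# scrub A-rich windows: cap the A fraction by replacing surplus As
scrub_polya <- function(seq_chars, start, end, max_a = 5) {
  idx <- start:end
  a_at <- idx[seq_chars[idx] == "A"]
  if (length(a_at) > max_a) {
    seq_chars[a_at[(max_a + 1):length(a_at)]] <- "G"
  }
  seq_chars
}

# intron flank planting: donor/acceptor dinucleotides on the transcript
# strand ("GT-AG" etc.); non-canonical request plants "CT-AC"
plant_intron_flanks <- function(seq_chars, start, end, strand, motif) {
  parts <- strsplit(motif, "-")[[1]]
  if (strand == "+") {
    seq_chars <- plant(seq_chars, start, parts[1], "+")
    seq_chars <- plant(seq_chars, end - 1, parts[2], "+")
  } else {
    seq_chars <- plant(seq_chars, end - 1, parts[1], "-")
    seq_chars <- plant(seq_chars, start, parts[2], "-")
  }
  seq_chars
}

#' Generate a genome and annotation fixture for the filter cascades
#'
#' Builds a two-chromosome synthetic genome with fully controlled
#' features and the matching annotation: `chrT` carries candidate
#' pri-miRNA transcript models covering every validation rule (a clean
#' multi-exon model on each strand, a single-exon model, models with a
#' 19-nt terminal exon, a >100,000-nt intron, non-canonical splice
#' flanks, and a model missing its miRNA locus), with planted splice
#' dinucleotides; `chrE` carries protein-coding and lincRNA genes plus
#' planted 3' ends, one per artefact class (genuine, internal poly(A),
#' in-CDS, near-N, in-repeat, in-transposon, no-hexamer), with planted
#' hexamers, an A-tract and an N run, and scrubbed of accidental signals
#' around each end.
#'
#' @param spec A [simulation_spec()]; only its seed is used.
#' @return List with `genome` (named [Biostrings::DNAStringSet]),
#'   `transcripts`, `mirna_loci`, `genes`, `cds`, `repeats`,
#'   `transposons`, `ends`, and `truth` (`transcripts`: expected verdict
#'   and rule; `ends`: artefact class per end).
#' @export
generate_genome_fixture <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(derive_seed(spec$seed, "genome"), {
    ## ----- chrT: transcript cases ------------------------------------
    len_t <- 150000L
    chrT <- strsplit(random_dna(len_t), "")[[1]]
    tx_rows <- list()
    loci_rows <- list()
    truth_tx <- list()
    cursor <- 1000L

    add_tx <- function(id, strand, exon_lens, intron_lens, motifs,
                       with_locus, verdict, rule) {
      starts <- integer(length(exon_lens))
      ends <- integer(length(exon_lens))
      pos <- cursor
      for (i in seq_along(exon_lens)) {
        starts[i] <- pos
        ends[i] <- pos + exon_lens[i] - 1L
        pos <- ends[i] + 1L
        if (i < length(exon_lens)) {
          is <- pos
          ie <- pos + intron_lens[i] - 1L
          chrT <<- plant_intron_flanks(chrT, is, ie, strand, motifs[i])
          pos <- ie + 1L
        }
      }
      cursor <<- pos + 1000L
      tx_rows[[length(tx_rows) + 1]] <<- data.frame(
        transcript_id = id, gene_id = paste0("g_", id), chromosome = "chrT",
        strand = strand, start = starts, end = ends,
        stringsAsFactors = FALSE)
      if (with_locus) {
        # an 80-nt miRNA locus inside the transcript span
        loci_rows[[length(loci_rows) + 1]] <<- data.frame(
          chromosome = "chrT", start = starts[1] + 5L,
          end = starts[1] + 84L, strand = strand, stringsAsFactors = FALSE)
      }
      truth_tx[[length(truth_tx) + 1]] <<- data.frame(
        transcript_id = id, verdict = verdict, rule = rule,
        stringsAsFactors = FALSE)
    }

    add_tx("tx_keep_plus", "+", c(150, 120, 200), c(500, 800),
           c("GT-AG", "GC-AG"), TRUE, "kept", NA)
    add_tx("tx_keep_minus", "-", c(150, 120, 200), c(500, 800),
           c("GT-AG", "GT-AG"), TRUE, "kept", NA)
    add_tx("tx_single_exon", "+", 400, integer(0), character(0), TRUE,
           "removed", "single-exon")
    add_tx("tx_no_locus", "+", c(150, 200), 600, "GT-AG", FALSE,
           "removed", "no-mirna-overlap")
    add_tx("tx_short_first", "+", c(19, 200), 600, "GT-AG", TRUE,
           "removed", "short-terminal-exon")
    add_tx("tx_short_last", "-", c(200, 19), 600, "GT-AG", TRUE,
           "removed", "short-terminal-exon")
    add_tx("tx_long_intron", "+", c(150, 200), 100001L, "GT-AG", TRUE,
           "removed", "long-intron")
    add_tx("tx_noncanonical", "+", c(150, 200), 600, "CT-AC", TRUE,
           "removed", "non-canonical-splice")
    if (cursor > len_t) stop("transcript layout exceeds chromosome")

    ## ----- chrE: 3'-end cases ----------------------------------------
    len_e <- 30000L
    chrE <- strsplit(random_dna(len_e), "")[[1]]
    genes <- data.frame(
      gene_id = c("pc_plus", "linc_plus", "pc_minus"),
      chromosome = "chrE",
      strand = c("+", "+", "-"),
      start = c(2000L, 10000L, 20000L),
      end = c(6000L, 11000L, 23000L),
      biotype = c("protein_coding", "lincRNA", "protein_coding"),
      stringsAsFactors = FALSE)
    cds <- data.frame(chromosome = "chrE", strand = c("+", "-"),
                      start = c(2100L, 20200L), end = c(5800L, 22800L),
                      stringsAsFactors = FALSE)
    repeats <- data.frame(chromosome = "chrE", start = 6880L, end = 6920L)
    transposons <- data.frame(chromosome = "chrE", start = 7050L,
                              end = 7150L)

    ends <- data.frame(
      end_id = c("end_genuine", "end_genuine_minus", "end_noncoding",
                 "end_polya", "end_near_n", "end_in_cds", "end_in_repeat",
                 "end_in_transposon", "end_no_hexamer"),
      region_id = c("region01", "region02", "region03", "region04",
                    "region05", "region06", "region07", "region08",
                    "region09"),
      chromosome = "chrE",
      strand = c("+", "-", "+", "+", "+", "+", "+", "+", "+"),
      position = c(6500L, 19500L, 11030L, 6600L, 6700L, 4000L, 6900L,
                   7100L, 7300L),
      stringsAsFactors = FALSE)
    truth_ends <- data.frame(
      end_id = ends$end_id,
      class = c("genuine", "genuine", "genuine", "internal-polyA",
                "near-N", "in-CDS", "repeat", "transposon", "no-hexamer"),
      stringsAsFactors = FALSE)

    hexamers <- c("AATAAA", "ATTAAA")
    for (i in seq_len(nrow(ends))) {
      pos <- ends$position[i]
      strand <- ends$strand[i]
      cls <- truth_ends$class[i]
      up <- if (strand == "+") c(pos - 40L, pos - 1L) else
        c(pos + 1L, pos + 40L)
      down <- if (strand == "+") c(pos + 1L, pos + 10L) else
        c(pos - 10L, pos - 1L)
      # hexamer: plant 30 nt upstream unless this end tests its absence
      chrE <- scrub_motifs(chrE, up[1], up[2],
                           c(hexamers, as.character(Biostrings::reverseComplement(
                             Biostrings::DNAStringSet(hexamers)))))
      if (cls != "no-hexamer") {
        at <- if (strand == "+") pos - 30L else pos + 25L
        chrE <- plant(chrE, at, "AATAAA", strand)
      }
      # downstream A window: clean unless this end tests internal priming
      if (cls == "internal-polyA") {
        chrE <- plant(chrE, down[1], paste(rep("A", 10), collapse = ""),
                      "+")
        if (strand == "-") {
          chrE <- plant(chrE, down[1], paste(rep("T", 10), collapse = ""),
                        "+")
        }
      } else {
        chrE <- scrub_polya(chrE, down[1], down[2])
        if (strand == "-") {
          # A on the minus strand is T on the reference
          idx <- down[1]:down[2]
          t_at <- idx[chrE[idx] == "T"]
          if (length(t_at) > 5) chrE[t_at[6:length(t_at)]] <- "G"
        }
      }
      if (cls == "near-N") chrE <- plant(chrE, pos + 14L, "NNN", "+")
    }

    genome <- Biostrings::DNAStringSet(c(
      chrT = paste(chrT, collapse = ""),
      chrE = paste(chrE, collapse = "")))
    list(genome = genome,
         transcripts = do.call(rbind, tx_rows),
         mirna_loci = do.call(rbind, loci_rows),
         genes = genes, cds = cds, repeats = repeats,
         transposons = transposons, ends = ends,
         truth = list(transcripts = do.call(rbind, truth_tx),
                      ends = truth_ends))
  })
}

#' Generate a promoter-mark peak fixture for a dataset
#'
#' Emulates an active-promoter histone-mark (H3K4me3-like) peak set:
#' peaks are placed over the TSS of a seeded fraction of the genes
#' expressed at the given stage and a small fraction of silent genes.
#'
#' @param dataset An [expression_dataset()].
#' @param stage Stage label defining expressed/silent classes.
#' @param frac_expressed,frac_silent Fraction of each class receiving a
#'   peak.
#' @param half_width Peak half-width (nt) around the TSS.
#' @param seed Integer seed.
#' @return List with `peaks` (interval data frame) and `truth` (gene ids
#'   given a peak).
#' @export
generate_peak_fixture <- function(dataset, stage, frac_expressed = 0.8,
                                  frac_silent = 0.1, half_width = 500,
                                  seed = 1) {
  cls <- expression_classes(dataset, stage)
  with_seed(seed, {
    take <- function(ids, frac) ids[stats::runif(length(ids)) < frac]
    marked <- c(take(cls$expressed, frac_expressed),
                take(cls$silent, frac_silent))
    ann <- dataset$genes[match(marked, dataset$genes$gene_id), ]
    tss <- ifelse(ann$strand == "+", ann$start, ann$end)
    peaks <- data.frame(chromosome = ann$chromosome,
                        start = pmax(1, tss - half_width),
                        end = tss + half_width,
                        stringsAsFactors = FALSE)
    list(peaks = peaks, truth = marked)
  })
}
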