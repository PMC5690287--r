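# Transcript models are data frames with one row per exon:
#   transcript_id, gene_id, chromosome, strand, start, end
# (1-based inclusive). Exon order within a transcript is positional;
# 5'->3' order on the minus strand is descending coordinates.

#' Introns of transcript models
#'
#' @param transcripts Exon-level transcript data frame (see
#'   [filter_pri_mirna()]).
#' @return Data frame `transcript_id`, `chromosome`, `strand`, `start`,
#'   `end`, `length` with one row per intron (gaps between consecutive
#'   exons).
#' @export
transcript_introns <- function(transcripts) {
  out <- lapply(split(transcripts, transcripts$transcript_id), function(tx) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) < 2) return(NULL)
    s <- tx$end[-nrow(tx)] + 1L
    e <- tx$start[-1] - 1L
    if (any(e < s)) stop("overlapping exons in transcript ",
                         tx$transcript_id[1])
    data.frame(transcript_id = tx$transcript_id[1],
               chromosome = tx$chromosome[1], strand = tx$strand[1],
               start = s, end = e, length = e - s + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), chromosome = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), length = integer(0))
  }
  rownames(out) <- NULL
  out
}

# strand-oriented sequence of [start, end], clipped at chromosome bounds;
# returns "" when the window is entirely off-chromosome
strand_window <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- length(genome[[chrom]])
  s <- max(1L, as.integer(start))
  e <- min(len, as.integer(end))
  if (s > e) return("")
  seq <- Biostrings::subseq(genome[[chrom]], s, e)
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(seq)
}

# transcript-strand flanking dinucleotides of an intron, e.g. "GT-AG"
intron_motif <- function(genome, chrom, start, end, strand) {
  if (strand == "+") {
    paste(strand_window(genome, chrom, start, start + 1, "+"),
          strand_window(genome, chrom, end - 1, end, "+"), sep = "-")
  } else {
    paste(strand_window(genome, chrom, end - 1, end, "-"),
          strand_window(genome, chrom, start, start + 1, "-"), sep = "-")
  }
}

#' Filter assembled pri-miRNA transcript models
#'
#' Applies the post-assembly validation cascade for candidate primary
#' microRNA transcripts, in order: (1) drop single-exon models; (2) keep
#' only models whose span overlaps at least one annotated miRNA locus on
#' the same strand by at least one base; (3) drop models whose first or
#' last exon is shorter than `min_terminal_exon` nt; (4) drop models
#' containing an intron longer than `max_intron` nt; (5) drop models with
#' an intron whose strand-oriented flanking dinucleotides are not among
#' `motifs` (canonically GT-AG or GC-AG). Each removed transcript is
#' attributed to the first rule it fails; kept + removed = input.
#'
#' @param transcripts Exon-level data frame (`transcript_id`, `gene_id`,
#'   `chromosome`, `strand`, `start`, `end`).
#' @param mirna_loci Interval data frame (`chromosome`, `start`, `end`,
#'   `strand`).
#' @param genome A named [Biostrings::DNAStringSet] of chromosome
#'   sequences.
#' @param min_terminal_exon Minimum first/last exon length (nt).
#' @param max_intron Maximum intron length (nt).
#' @param motifs Allowed splice motifs, `"donor-acceptor"` dinucleotides.
#' @return List with `kept` (transcript ids), `removed` (data frame
#'   `transcript_id`, `rule`), `counts` (named removal counts in rule
#'   order), `n_input`.
#' @export
filter_pri_mirna <- function(transcripts, mirna_loci, genome,
                             min_terminal_exon = 20, max_intron = 100000,
                             motifs = c("GT-AG", "GC-AG")) {
  txs <- split(transcripts, transcripts$transcript_id)
  for (tx in txs) {
    len <- length(genome[[tx$chromosome[1]]])
    if (any(tx$end > len) || any(tx$start < 1)) {
      stop("exon outside chromosome bounds in transcript ",
           tx$transcript_id[1])
    }
  }
  rules <- c("single-exon", "no-mirna-overlap", "short-terminal-exon",
             "long-intron", "non-canonical-splice")
  verdict <- vapply(txs, function(tx) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) == 1) return("single-exon")
    span_s <- min(tx$start); span_e <- max(tx$end)
    hit <- any(mirna_loci$chromosome == tx$chromosome[1] &
                 mirna_loci$strand == tx$strand[1] &
                 mirna_loci$start <= span_e & mirna_loci$end >= span_s)
    if (!hit) return("no-mirna-overlap")
    exon_len <- tx$end - tx$start + 1L
    if (exon_len[1] < min_terminal_exon ||
        exon_len[length(exon_len)] < min_terminal_exon) {
      return("short-terminal-exon")
    }
    intr <- transcript_introns(tx)
    if (any(intr$length > max_intron)) return("long-intron")
    mot <- vapply(seq_len(nrow(intr)), function(i) {
      intron_motif(genome, intr$chromosome[i], intr$start[i], intr$end[i],
                   intr$strand[i])
    }, character(1))
    if (any(!mot %in% motifs)) return("non-canonical-splice")
    "kept"
  }, character(1))
  removed <- data.frame(transcript_id = names(verdict)[verdict != "kept"],
                        rule = unname(verdict[verdict != "kept"]),
                        stringsAsFactors = FALSE)
  counts <- vapply(rules, function(r) sum(verdict == r), integer(1))
  list(kept = names(verdict)[verdict == "kept"], removed = removed,
       counts = counts, n_input = length(txs))
}

detct_rule_order <- c("annotation-distance", "polya-enriched", "near-n",
                      "in-cds", "in-repeat", "in-transposon", "no-hexamer")

detct_noncoding_biotypes <- c("antisense", "lincRNA", "misc_RNA",
                              "processed_transcript")

# position inside any interval (optionally strand-matched)
in_interval <- function(chrom, pos, strand, intervals, stranded = FALSE) {
  vapply(seq_along(pos), function(i) {
    hit <- intervals$chromosome == chrom[i] &
      intervals$start <= pos[i] & intervals$end >= pos[i]
    if (stranded) hit <- hit & intervals$strand == strand[i]
    any(hit)
  }, logical(1))
}

#' Filter putative 3' ends (DeTCT-style cascade)
#'
#' Removes artefactual polyadenylation sites from a list of candidate
#' 3' ends. `mode = "stricter"` applies every rule: an end is removed if
#' it is more than `coding_distance` nt downstream of protein-coding
#' annotation and more than `noncoding_distance` nt from non-coding
#' annotation (antisense, lincRNA, misc_RNA, processed_transcript), if
#' the nearby downstream sequence is enriched for As (internal-priming
#' signature), if it lies within `n_distance` bp of an N, within coding
#' sequence, within a simple repeat or a transposon, or if no primary
#' hexamer (AATAAA/ATTAAA by default) occurs on the transcript strand
#' within `hexamer_window` nt upstream. `mode = "strict"` applies only
#' the in-CDS, in-transposon, A-enrichment and hexamer rules. Distance
#' rules are strand-aware (downstream means 3' of the gene on its
#' strand). Regions left without any surviving end are removed.
#'
#' @param ends Data frame with columns `end_id`, `region_id`,
#'   `chromosome`, `strand`, `position` (1-based).
#' @param genes Gene annotation (`gene_id`, `chromosome`, `strand`,
#'   `start`, `end`, `biotype`).
#' @param cds CDS interval data frame (`chromosome`, `strand`, `start`,
#'   `end`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param repeats,transposons Interval data frames (`chromosome`,
#'   `start`, `end`).
#' @param mode `"stricter"` or `"strict"`.
#' @param coding_distance,noncoding_distance,n_distance Distance limits
#'   (nt).
#' @param polya_window,polya_fraction A-enrichment test: fraction of As
#'   on the transcript strand in this many bases immediately downstream.
#' @param hexamer_window,hexamers Primary-hexamer search window (nt
#'   upstream) and motif set.
#' @return List with `kept` (data frame of surviving ends), `removed`
#'   (data frame `end_id`, `rule`: first failing rule in cascade order),
#'   `counts` (named per-rule removal counts), `n_input`,
#'   `kept_regions`, `removed_regions`.
#' @export
detct_filter <- function(ends, genes, cds, genome, repeats, transposons,
                         mode = c("stricter", "strict"),
                         coding_distance = 5000, noncoding_distance = 50,
                         n_distance = 14, polya_window = 10,
                         polya_fraction = 0.7, hexamer_window = 40,
                         hexamers = c("AATAAA", "ATTAAA")) {
  mode <- match.arg(mode)
  bad <- setdiff(genes$biotype, c("protein_coding", detct_noncoding_biotypes))
  if (length(bad) > 0) {
    stop("unknown biotype label(s): ", paste(bad, collapse = ", "),
         "; allowed: protein_coding, ",
         paste(detct_noncoding_biotypes, collapse = ", "))
  }
  n <- nrow(ends)
  viol <- matrix(FALSE, n, length(detct_rule_order),
                 dimnames = list(ends$end_id, detct_rule_order))

  # --- annotation distance (strand-aware) ------------------------------
  near_annotation <- vapply(seq_len(n), function(i) {
    g <- genes[genes$chromosome == ends$chromosome[i] &
                 genes$strand == ends$strand[i], , drop = FALSE]
    if (nrow(g) == 0) return(FALSE)
    pos <- ends$position[i]
    coding <- g[g$biotype == "protein_coding", , drop = FALSE]
    ok_coding <- FALSE
    if (nrow(coding) > 0) {
      inside <- coding$start <= pos & coding$end >= pos
      down <- if (ends$strand[i] == "+") {
        pos > coding$end & pos - coding$end <= coding_distance
      } else {
        pos < coding$start & coding$start - pos <= coding_distance
      }
      ok_coding <- any(inside | down)
    }
    nc <- g[g$biotype %in% detct_noncoding_biotypes, , drop = FALSE]
    ok_nc <- nrow(nc) > 0 &&
      any(pmax(nc$start - pos, pos - nc$end, 0) <= noncoding_distance)
    ok_coding || ok_nc
  }, logical(1))
  viol[, "annotation-distance"] <- !near_annotation

  # --- A-enrichment just downstream (internal priming) -----------------
  viol[, "polya-enriched"] <- vapply(seq_len(n), function(i) {
    win <- if (ends$strand[i] == "+") {
      strand_window(genome, ends$chromosome[i], ends$position[i] + 1,
                    ends$position[i] + polya_window, "+")
    } else {
      strand_window(genome, ends$chromosome[i],
                    ends$position[i] - polya_window,
                    ends$position[i] - 1, "-")
    }
    if (nchar(win) == 0) return(FALSE)
    bases <- strsplit(win, "")[[1]]
    mean(bases == "A") >= polya_fraction
  }, logical(1))

  # --- proximity to an N -----------------------------------------------
  viol[, "near-n"] <- vapply(seq_len(n), function(i) {
    win <- strand_window(genome, ends$chromosome[i],
                         ends$position[i] - n_distance,
                         ends$position[i] + n_distance, "+")
    grepl("N", win, fixed = TRUE)
  }, logical(1))

  # --- interval memberships --------------------------------------------
  viol[, "in-cds"] <- in_interval(ends$chromosome, ends$position,
                                  ends$strand, cds, stranded = TRUE)
  viol[, "in-repeat"] <- in_interval(ends$chromosome, ends$position,
                                     ends$strand, repeats)
  viol[, "in-transposon"] <- in_interval(ends$chromosome, ends$position,
                                         ends$strand, transposons)

  # --- primary hexamer upstream ----------------------------------------
  viol[, "no-hexamer"] <- vapply(seq_len(n), function(i) {
    win <- if (ends$strand[i] == "+") {
      strand_window(genome, ends$chromosome[i],
                    ends$position[i] - hexamer_window,
                    ends$position[i] - 1, "+")
    } else {
      strand_window(genome, ends$chromosome[i], ends$position[i] + 1,
                    ends$position[i] + hexamer_window, "-")
    }
    !any(vapply(hexamers, grepl, logical(1), x = win, fixed = TRUE))
  }, logical(1))

  active <- if (mode == "stricter") detct_rule_order else
    c("polya-enriched", "in-cds", "in-transposon", "no-hexamer")
  act <- viol[, active, drop = FALSE]
  removed_any <- rowSums(act) > 0
  first_rule <- rep(NA_character_, n)
  first_rule[removed_any] <- active[apply(
    act[removed_any, , drop = FALSE], 1, which.max)]

  kept <- ends[!removed_any, , drop = FALSE]
  removed <- data.frame(end_id = ends$end_id[removed_any],
                        rule = first_rule[removed_any],
                        stringsAsFactors = FALSE)
  counts <- vapply(active, function(r) sum(removed$rule == r), integer(1))
  kept_regions <- unique(kept$region_id)
  list(kept = kept, removed = removed, counts = counts, n_input = n,
       kept_regions = kept_regions,
       removed_regions = setdiff(unique(ends$region_id), kept_regions),
       mode = mode)
}

#' Flow summary of a filter cascade
#'
#' Formats per-rule removal counts as a flow table with a running total
#' of surviving items, checking conservation (input = kept + removed).
#'
#' @param n_input Number of items entering the cascade.
#' @param counts Named per-rule removal counts, in cascade order.
#' @param n_kept Number of items kept.
#' @return Data frame `rule`, `removed`, `remaining`.
#' @export
end_filter_report <- function(n_input, counts, n_kept) {
  if (n_input != n_kept + sum(counts)) {
    stop("conservation violated: input ", n_input, " != kept ", n_kept,
         " + removed ", sum(counts))
  }
  data.frame(rule = names(counts), removed = as.integer(counts),
             remaining = n_input - cumsum(as.integer(counts)),
             row.names = NULL, stringsAsFactors = FALSE)
}
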