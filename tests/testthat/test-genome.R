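test_that("binomial enrichment matches exact enumeration", {
  # one cluster of 10 genes, 7 on chrA where the universe fraction is 0.3
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:100),
    chromosome = rep(c("chrA", "chrB"), times = c(30, 70)),
    stringsAsFactors = FALSE)
  members <- c(sprintf("g%03d", 1:7), sprintf("g%03d", 31:33))
  cs <- structure(list(clusters = list(`1` = members),
                       unassigned = character(0), provenance = list()),
                  class = "cluster_set")
  out <- chromosome_enrichment(cs, genes, min_count = 3)
  rowA <- out[out$chromosome == "chrA", ]
  # oracle: exhaustive binomial tail P(X >= 7 | n = 10, p = 0.3)
  tail_p <- sum(vapply(7:10, function(i) {
    choose(10, i) * 0.3^i * 0.7^(10 - i)
  }, numeric(1)))
  expect_equal(rowA$p_value, tail_p, tolerance = 1e-12)
  expect_equal(rowA$expected, 3)
  expect_equal(rowA$log2_fe, log2(7 / 3), tolerance = 1e-12)
  # counts over chromosomes sum to cluster size; BH never below raw
  expect_equal(sum(out$count), length(members))
  expect_true(all(out$adjusted_p >= out$p_value - 1e-15))
  expect_true(all(out$p_value > 0 & out$p_value <= 1))
})

test_that("enrichment respects the minimum-count rule and flags reports", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      chromosome = rep(c("chrA", "chrB", "chrC"), each = 20),
                      stringsAsFactors = FALSE)
  members <- c(sprintf("g%03d", 1:12), sprintf("g%03d", 21:25))
  cs <- structure(list(clusters = list(`1` = members),
                       unassigned = character(0), provenance = list()),
                  class = "cluster_set")
  out <- chromosome_enrichment(cs, genes, min_count = 6)
  # chrB appears 5 times: not tested
  expect_false("chrB" %in% out$chromosome)
  expect_true(all(out$count >= 6))
  expect_equal(out$significant, out$adjusted_p < 0.05 & out$log2_fe > 1)
})

test_that("every window scores the mean of its pairwise correlations", {
  # one chromosome whose genes all share a noiseless profile; a filler
  # gene on another chromosome keeps column sums (hence TPM) proportional
  base <- c(1, 4, 9, 2, 7, 5)
  counts <- outer(seq(2, 30, length.out = 15), base)
  counts <- rbind(counts, 2500 - colSums(counts))
  dimnames(counts) <- list(NULL, paste0("s", 1:6, "_1"))
  ds <- toy_dataset(counts, stages = paste0("s", 1:6),
                    chromosome = c(rep("chr1", 15), "chr2"))
  dom <- sliding_window_domains(ds, w = 10, threshold = 0.5)
  expect_equal(nrow(dom), 1)
  expect_equal(dom$n_genes, 15)
  expect_equal(dom$peak_window_cor, 1, tolerance = 1e-9)
  # chromosomes with fewer genes than the window are skipped
  dom2 <- sliding_window_domains(ds, w = 20, threshold = 0.5)
  expect_equal(nrow(dom2), 0)
})

test_that("domain detection recovers a planted block with edge tolerance", {
  spec <- simulation_spec(
    n_genes = 60, seed = 31, n_chromosomes = 2,
    archetype_mix = c("flat-noise" = 1),
    planted_domains = list(list(chromosome = "chr1", start_index = 8,
                                n_genes = 15, archetype = "zga-spike")))
  sim <- generate_timecourse(spec)
  dom <- sliding_window_domains(sim$dataset, w = 10, threshold = 0.5)
  expect_equal(dom$chromosome, "chr1")
  members <- attr(dom, "members")[[1]]
  planted <- sim$truth$domains$gene_id
  ann <- sim$dataset$genes
  chr1 <- ann$gene_id[ann$chromosome == "chr1"][
    order(ann$start[ann$chromosome == "chr1"])]
  lo <- max(1, min(match(planted, chr1)) - 9)
  hi <- min(length(chr1), max(match(planted, chr1)) + 9)
  expect_true(all(planted %in% members))
  expect_true(all(members %in% chr1[lo:hi]))
  # raising the threshold never enlarges a region
  dom2 <- sliding_window_domains(sim$dataset, w = 10, threshold = 0.8)
  if (nrow(dom2) > 0) {
    expect_lte(dom2$n_genes[1], dom$n_genes[1])
  }
})

test_that("reported regions reproduce their peak window statistic", {
  spec <- simulation_spec(
    n_genes = 80, seed = 33, n_chromosomes = 2,
    archetype_mix = c("flat-noise" = 0.6, "rising" = 0.4),
    planted_domains = list(list(chromosome = "chr2", start_index = 5,
                                n_genes = 12, archetype = "falling")))
  sim <- generate_timecourse(spec)
  ds <- sim$dataset
  dom <- sliding_window_domains(ds, w = 10, threshold = 0.5)
  for (i in seq_len(nrow(dom))) {
    ids <- attr(dom, "members")[[i]]
    w <- 10
    stats_w <- vapply(seq_len(length(ids) - w + 1), function(j) {
      cc <- cor(t(ds$tpm[ids[j:(j + w - 1)], ]))
      mean(cc[upper.tri(cc)])
    }, numeric(1))
    expect_equal(max(stats_w), dom$peak_window_cor[i], tolerance = 1e-9)
  }
})

test_that("promoter intervals follow strand and clip at bounds", {
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      chromosome = "chr1",
                      strand = c("+", "-", "+"),
                      start = c(10000L, 5000L, 500L),
                      end = c(12000L, 10000L, 900L),
                      stringsAsFactors = FALSE)
  prom <- promoter_intervals(genes, up = 1000, down = 200)
  expect_equal(prom$start, c(9000L, 9800L, 1L))
  expect_equal(prom$end, c(10200L, 11000L, 700L))
  # width is up + down + 1 when unclipped
  expect_equal(prom$end[1] - prom$start[1] + 1, 1201)
  expect_error(promoter_intervals(transform(genes, strand = "."), 1000, 200),
               "strand")
})

test_that("peak overlap counts match manual inspection", {
  genes <- data.frame(gene_id = c("a", "b", "c"), chromosome = "chr1",
                      strand = "+", start = c(10000L, 30000L, 50000L),
                      end = c(12000L, 32000L, 52000L),
                      stringsAsFactors = FALSE)
  prom <- promoter_intervals(genes, 1000, 200)
  # peak over a's promoter edge, one inside b's promoter, none near c
  peaks <- data.frame(chromosome = "chr1",
                      start = c(8500L, 29500L), end = c(9000L, 29600L))
  out <- peak_overlap_summary(prom, peaks, expressed = c("a", "c"),
                              silent = "b")
  expect_equal(out$overlapping, c(1L, 1L))
  expect_equal(out$percent, c(50.0, 100.0))
  # zero peaks: zero percent everywhere
  none <- peak_overlap_summary(prom, peaks[0, ], c("a", "c"), "b")
  expect_equal(none$percent, c(0, 0))
  expect_error(peak_overlap_summary(prom, peaks, c("a", "b"), c("b")),
               "both")
})

test_that("expression classes split expressed from silent at a stage", {
  counts <- rbind(g1 = c(100, 120, 0, 0),
                  g2 = c(0, 0, 50, 60),
                  g3 = c(0, 1, 0, 0))
  dimnames(counts) <- list(NULL, c("A_1", "A_2", "B_1", "B_2"))
  ds <- toy_dataset(counts, stages = c("A", "A", "B", "B"))
  cls <- expression_classes(ds, "A", tpm_threshold = 1)
  expect_true("g001" %in% cls$expressed)
  expect_true("g002" %in% cls$silent)
  expect_false("g003" %in% cls$silent)  # one positive replicate
})
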