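test_that("pair correlations hit the exact limits", {
  base <- c(2, 4, 8, 16, 8, 4)
  counts <- rbind(g1 = base,
                  g2 = 3 * base,                 # duplicated profile
                  g3 = max(base) + min(base) - base,  # negation about mean
                  g4 = rep(5, 6))
  # filler keeps column sums constant so TPM is proportional to counts
  counts <- rbind(counts, g5 = 120 - colSums(counts))
  dimnames(counts) <- list(NULL, paste0("s", 1:6, "_1"))
  ds <- toy_dataset(counts, stages = paste0("s", 1:6))
  pairs <- data.frame(gene_a = c("g001", "g001", "g001"),
                      gene_b = c("g002", "g003", "g004"))
  out <- pair_correlations(ds, pairs)
  expect_equal(out$pearson[1], 1, tolerance = 1e-9)
  expect_equal(out$pearson[2], -1, tolerance = 1e-9)
  expect_false(out$evaluable[3])  # zero-variance member flagged
  expect_error(pair_correlations(ds, data.frame(gene_a = "g001",
                                                gene_b = "nope")),
               "unknown gene")
  expect_error(pair_correlations(ds, data.frame(gene_a = "g001",
                                                gene_b = "g001")),
               "distinct")
})

test_that("random pair null is seeded, exclusion-aware and exhaustive", {
  sim <- generate_timecourse(simulation_spec(n_genes = 30, seed = 41,
                                             replicates_per_stage = 2))
  ds <- sim$dataset
  a <- random_pair_null(ds, 50, seed = 5)
  b <- random_pair_null(ds, 50, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$gene_a != a$gene_b))
  expect_equal(anyDuplicated(paste(a$gene_a, a$gene_b)), 0)
  # exclusions are never drawn
  excl <- a[1:10, ]
  c <- random_pair_null(ds, 50, exclusions = excl, seed = 6)
  expect_false(any(paste(c$gene_a, c$gene_b) %in%
                     paste(excl$gene_a, excl$gene_b)))
  # n = C(m, 2) returns the complete pair set
  ids <- sprintf("g%05d", 1:8)  # subset of gene ids
  full <- random_pair_null(ds, choose(8, 2), gene_ids = rownames(ds$tpm)[1:8],
                           seed = 7)
  expect_equal(nrow(full), 28)
  expect_equal(anyDuplicated(paste(full$gene_a, full$gene_b)), 0)
  expect_error(random_pair_null(ds, choose(8, 2) + 1,
                                gene_ids = rownames(ds$tpm)[1:8], seed = 1),
               "available")
})

test_that("null correlations on independent noise centre on zero", {
  spec <- simulation_spec(n_genes = 200, seed = 43,
                          archetype_mix = c("flat-noise" = 1))
  sim <- generate_timecourse(spec)
  null <- pair_correlations(
    sim$dataset, random_pair_null(sim$dataset, 200, seed = 44))
  r <- null$pearson[null$evaluable]
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r)), 3 * se + 0.01)
})

test_that("correlation summaries report quantiles and tail fractions", {
  s <- correlation_summary(c(0.1, 0.5, 0.9), c(-0.2, 0, 0.2),
                           cuts = c(-1.01, 0.45, 1.01))
  expect_equal(unname(s$quantiles["real", "50%"]), 0.5)
  expect_equal(unname(s$fraction_below["real", "-1.01"]), 0)
  expect_equal(unname(s$fraction_below["real", "1.01"]), 1)
  expect_equal(unname(s$fraction_below["null", "0.45"]), 1)
  # all-equal list: all quantiles equal
  s2 <- correlation_summary(rep(0.3, 5), c(0, 0.1))
  expect_true(all(s2$quantiles["real", ] == 0.3))
  expect_error(correlation_summary(numeric(0), c(0.1)), "non-empty")
})

test_that("anatomy intersection is Jaccard with a min-set option", {
  ann <- data.frame(
    gene_id = c(rep("a", 4), rep("b", 4), rep("c", 2), rep("d", 2)),
    stage_id = "ZFS:1",
    anatomy_term = c(paste0("ZFA:", 1:4), paste0("ZFA:", 3:6),
                     paste0("ZFA:", 1:2), paste0("ZFA:", 7:8)),
    stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = c("a", "a", "c"), gene_b = c("b", "a", "d"))
  pairs$gene_b[2] <- "a2"  # unannotated gene
  out <- anatomy_overlap(pairs, ann, cut = 0.5)
  # |{3,4}| / |{1..6}| = 2/6
  expect_equal(out$pairs$intersection[1], 2 / 6, tolerance = 1e-12)
  expect_true(is.na(out$pairs$intersection[2]))
  expect_equal(out$pairs$intersection[3], 0)  # disjoint sets
  expect_equal(out$n_excluded, 1)
  expect_equal(out$n_evaluated, 2)
  # identical sets give 1 under both denominators
  p2 <- data.frame(gene_a = "a", gene_b = "a2")
  ann2 <- rbind(ann, transform(ann[ann$gene_id == "a", ], gene_id = "a2"))
  expect_equal(anatomy_overlap(p2, ann2)$pairs$intersection, 1)
  # min denominator: |{3,4}| / min(4, 4)
  out_min <- anatomy_overlap(pairs[1, ], ann, denominator = "min")
  expect_equal(out_min$pairs$intersection, 0.5)
})

test_that("planted pairs stochastically dominate the random null", {
  spec <- simulation_spec(
    n_genes = 300, seed = 45, dispersion = 0.01, library_scale = 0.05,
    paralogue_spec = list(list(target_cor = 0.9, n_pairs = 30)))
  sim <- generate_timecourse(spec)
  real <- pair_correlations(sim$dataset, sim$truth$paralogues)
  null <- pair_correlations(
    sim$dataset,
    random_pair_null(sim$dataset, 30, exclusions = sim$truth$paralogues,
                     seed = 46))
  wt <- stats::wilcox.test(real$pearson, null$pearson,
                           alternative = "greater")
  expect_lt(wt$p.value, 0.001)
})
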