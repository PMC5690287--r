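test_that("counts_to_tpm matches the definition", {
  # single gene: normalisation forces one million
  expect_equal(as.numeric(counts_to_tpm(matrix(7, 1, 1), 1000)), 1e6)
  # equal counts, equal lengths: symmetric split
  expect_equal(as.numeric(counts_to_tpm(matrix(c(5, 5), 2, 1),
                                        c(300, 300))),
               c(5e5, 5e5))
  # hand arithmetic: rates 0.1 and 0.05
  expect_equal(as.numeric(counts_to_tpm(matrix(c(10, 10), 2, 1),
                                        c(100, 200))),
               c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # all-zero column stays zero
  expect_equal(as.numeric(counts_to_tpm(matrix(0, 2, 1), c(100, 200))),
               c(0, 0))
  expect_error(counts_to_tpm(matrix(1, 2, 1), c(100, 0)), "length")
})

test_that("TPM columns sum to one million on generated data", {
  sim <- generate_timecourse(simulation_spec(n_genes = 150, seed = 4))
  expect_true(all(abs(colSums(sim$dataset$tpm) - 1e6) < 1e-3))
})

test_that("detectability requires every replicate positive at one stage", {
  # 2 stages x 3 replicates
  counts <- rbind(
    g1 = c(3, 2, 5, 0, 0, 0),   # positive in all reps of stage A
    g2 = c(3, 2, 0, 4, 0, 2),   # never positive in all reps of a stage
    g3 = c(0, 0, 0, 0, 0, 0),   # silent
    g4 = c(1, 1, 1, 1, 1, 1))   # positive everywhere
  ds <- toy_dataset(counts, stages = rep(c("A", "B"), each = 3))
  expect_setequal(detectable_genes(ds), c("g001", "g004"))

  # monotone: adding a positive value never removes a gene
  counts2 <- counts
  counts2["g2", ] <- c(3, 2, 1, 4, 0, 2)
  ds2 <- toy_dataset(counts2, stages = rep(c("A", "B"), each = 3))
  expect_true(all(detectable_genes(ds) %in% detectable_genes(ds2)))
})

test_that("stage_of_max uses replicate means and breaks ties early", {
  counts <- rbind(
    g1 = c(1, 1, 10, 10, 2, 2),  # peaks at stage B
    g2 = c(5, 5, 5, 5, 5, 5),    # exact tie: earliest stage
    g3 = c(2, 4, 9, 1, 3, 3))    # stage means 3, 5, 3: stage B
  # filler keeps column sums constant so TPM is proportional to counts
  counts <- rbind(counts, g4 = 30 - colSums(counts))
  ds <- toy_dataset(counts, stages = rep(c("A", "B", "C"), each = 2))
  som <- stage_of_max(ds)
  expect_equal(unname(som[c("g001", "g002", "g003")]), c("B", "A", "B"))
  expect_error(stage_of_max(ds, "g999"), "unknown gene")
})

test_that("stage_of_max recovers archetype peaks exactly without noise", {
  spec <- simulation_spec(n_genes = 400, seed = 7, dispersion = 0)
  sim <- generate_timecourse(spec)
  truth <- sim$truth$genes
  peaked <- !is.na(truth$peak_stage)
  som <- stage_of_max(sim$dataset, truth$gene_id[peaked])
  expect_equal(mean(som == truth$peak_stage[peaked]), 1)
})

test_that("gene names are classified by the clone-id patterns", {
  expect_equal(classify_gene_name("zgc:77112"), "unnamed")
  expect_equal(classify_gene_name("si:ch211-222l21.1"), "unnamed")
  expect_equal(classify_gene_name("ndr2"), "named")
  expect_equal(
    classify_gene_name(c("BX123456.1", "CABZ01234567.2", "im:1234567",
                         "wu:fb12a34", "zgc:1234", "sox2", "zgc:123456")),
    c("unnamed", "unnamed", "unnamed", "unnamed", "named", "named",
      "unnamed"))
  expect_error(classify_gene_name(""), "non-empty")
})

test_that("sample correlation matrix is Spearman with unit diagonal", {
  counts <- cbind(a_1 = c(10, 20, 30, 40, 50),
                  a_2 = c(10, 20, 30, 40, 50),
                  b_1 = c(50, 40, 30, 20, 10),
                  b_2 = c(13, 29, 28, 41, 55))
  rownames(counts) <- paste0("g", 1:5)
  ds <- toy_dataset(counts, stages = c("a", "a", "b", "b"))
  cm <- sample_correlation_matrix(ds)
  expect_equal(diag(cm), setNames(rep(1, 4), colnames(counts)))
  expect_equal(cm, t(cm))
  # duplicated column correlates perfectly; reversed ranks give -1
  expect_equal(cm["a_1", "a_2"], 1)
  expect_equal(cm["a_1", "b_1"], -1)
  # constant sample: undefined, flagged
  counts[, "b_2"] <- 7
  ds2 <- toy_dataset(counts, stages = c("a", "a", "b", "b"))
  expect_warning(cm2 <- sample_correlation_matrix(ds2), "constant")
  expect_true(is.na(cm2["a_1", "b_2"]))
})

test_that("sample PCA matches an independent eigendecomposition", {
  counts <- matrix(c(12, 5, 31, 2,
                     40, 19, 3, 28,
                     7, 26, 14, 33), nrow = 3, byrow = TRUE)
  rownames(counts) <- paste0("g", 1:3)
  colnames(counts) <- paste0("s", 1:4, "_1")
  ds <- toy_dataset(counts, stages = paste0("s", 1:4))
  pca <- pca_samples(ds)
  # oracle: eigenvalues of the sample-space covariance of centred TPM
  x <- scale(t(ds$tpm), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  ev <- ev[ev > 1e-8]
  expect_equal(pca$variance_fraction[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-9)
  # contributions are normalised squared loadings
  expect_equal(unname(colSums(pca$contributions)),
               rep(1, ncol(pca$contributions)))
})

test_that("PCA is invariant under gene reordering and rank-1 data", {
  sim <- generate_timecourse(simulation_spec(n_genes = 60, seed = 9,
                                             replicates_per_stage = 2))
  ds <- sim$dataset
  p1 <- pca_samples(ds)
  perm <- rev(seq_len(nrow(ds$counts)))
  ds2 <- expression_dataset(ds$counts[perm, ], ds$genes[perm, ],
                            ds$samples)
  p2 <- pca_samples(ds2)
  expect_equal(p1$variance_fraction, p2$variance_fraction,
               tolerance = 1e-9)
  # scores equal up to sign per component
  for (k in 1:3) {
    expect_true(isTRUE(all.equal(p1$scores[, k], p2$scores[, k],
                                 tolerance = 1e-6)) ||
                isTRUE(all.equal(p1$scores[, k], -p2$scores[, k],
                                 tolerance = 1e-6)))
  }
  # rank-1 variation: two genes moving along one opposed direction (TPM
  # is compositional, so constant column sums keep it proportional)
  tvec <- c(0, 1, 2, 3)
  counts <- rbind(g1 = 400 + 10 * tvec, g2 = 600 - 10 * tvec)
  colnames(counts) <- paste0("s", 1:4, "_1")
  ds3 <- toy_dataset(counts, stages = paste0("s", 1:4))
  expect_equal(pca_samples(ds3)$variance_fraction[1], 1, tolerance = 1e-9)
})

test_that("stage name summary counts named and unnamed peaks", {
  sim <- generate_timecourse(simulation_spec(n_genes = 120, seed = 10))
  summ <- stage_name_summary(sim$dataset)
  expect_equal(summ$stage, default_stages())
  expect_equal(sum(summ$named) + sum(summ$unnamed),
               length(detectable_genes(sim$dataset)))
})
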