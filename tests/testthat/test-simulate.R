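test_that("simulation specs are validated", {
  expect_error(simulation_spec(archetype_mix = c(rising = 0.5)),
               "sum to 1")
  expect_error(simulation_spec(archetype_mix = c(sideways = 1)),
               "unknown archetype")
  expect_error(simulation_spec(n_genes = 0), "positive")
  expect_error(simulation_spec(
    planted_domains = list(list(chromosome = "chr1", start_index = 1,
                                n_genes = 5, archetype = "spiral"))),
    "unknown archetype")
  expect_error(simulation_spec(
    paralogue_spec = list(list(target_cor = 1.2, n_pairs = 5))),
    "outside \\[-1, 1\\]")
})

test_that("generated matrices have the specified shape and are seeded", {
  spec <- simulation_spec(n_genes = 100, seed = 1)
  sim <- generate_timecourse(spec)
  expect_equal(dim(sim$dataset$counts), c(100, 18 * 5))
  expect_true(all(sim$dataset$counts >= 0))
  expect_true(is.integer(sim$dataset$counts))
  # determinism: identical spec and seed give identical output
  sim2 <- generate_timecourse(spec)
  expect_identical(sim$dataset$counts, sim2$dataset$counts)
  expect_identical(sim$truth, sim2$truth)
  # a different seed changes the draw
  sim3 <- generate_timecourse(simulation_spec(n_genes = 100, seed = 2))
  expect_false(identical(sim$dataset$counts, sim3$dataset$counts))
})

test_that("ground truth enumerates exactly the generated entities", {
  spec <- simulation_spec(
    n_genes = 200, seed = 5,
    planted_domains = list(list(chromosome = "chr2", start_index = 1,
                                n_genes = 8, archetype = "rising")),
    paralogue_spec = list(list(target_cor = 0.5, n_pairs = 4)))
  sim <- generate_timecourse(spec)
  expect_setequal(sim$truth$genes$gene_id, rownames(sim$dataset$counts))
  expect_equal(nrow(sim$truth$domains), 8)
  expect_true(all(sim$truth$domains$gene_id %in% sim$truth$genes$gene_id))
  expect_equal(nrow(sim$truth$paralogues), 4)
  expect_equal(sum(sim$truth$genes$is_paralogue), 8)
  # domain genes are contiguous on their chromosome and carry its archetype
  ann <- sim$dataset$genes
  dom <- sim$truth$domains$gene_id
  chr2 <- ann$gene_id[ann$chromosome == "chr2"][order(
    ann$start[ann$chromosome == "chr2"])]
  expect_identical(chr2[1:8], dom)
  expect_true(all(
    sim$truth$genes$archetype[match(dom, sim$truth$genes$gene_id)] ==
      "rising"))
})

test_that("noiseless spike-only profiles peak at the ZGA stage", {
  spec <- simulation_spec(n_genes = 40, seed = 3, dispersion = 0,
                          archetype_mix = c("zga-spike" = 1),
                          paralogue_spec = list())
  sim <- generate_timecourse(spec)
  peak <- apply(sim$truth$mean_profile, 1, which.max)
  expect_true(all(peak == zga_stage_index(18)))
  expect_true(all(sim$truth$genes$peak_stage == default_stages()[5]))
})

test_that("genome fixture plants the requested transcript structures", {
  fx <- generate_genome_fixture(simulation_spec(seed = 2))
  tx <- split(fx$transcripts, fx$transcripts$transcript_id)
  short <- tx[["tx_short_first"]]
  expect_equal(short$end[1] - short$start[1] + 1, 19)
  introns <- transcript_introns(tx[["tx_long_intron"]])
  expect_equal(sum(introns$length == 100001), 1)
  # every intron of the kept transcripts reads a canonical motif on the
  # transcript strand, extracted from the generated sequence
  for (id in c("tx_keep_plus", "tx_keep_minus")) {
    intr <- transcript_introns(tx[[id]])
    for (i in seq_len(nrow(intr))) {
      motif <- stagecourse:::intron_motif(fx$genome, intr$chromosome[i],
                                          intr$start[i], intr$end[i],
                                          intr$strand[i])
      expect_true(motif %in% c("GT-AG", "GC-AG"))
    }
  }
  # determinism
  fx2 <- generate_genome_fixture(simulation_spec(seed = 2))
  expect_identical(as.character(fx$genome), as.character(fx2$genome))
})

test_that("paralogue fixture controls correlation and anatomy intersection", {
  spec <- simulation_spec(
    n_genes = 200, seed = 8, dispersion = 0,
    paralogue_spec = list(list(target_cor = 1.0, n_pairs = 3),
                          list(target_cor = 0.0, n_pairs = 3)))
  sim <- generate_timecourse(spec)
  fx <- generate_paralogue_fixture(spec, sim$dataset)
  pr <- pair_correlations(sim$dataset, fx$pairs)
  # zero noise, target 1: realised correlation is 1 (library rounding only)
  expect_true(all(abs(pr$pearson[pr$target_cor == 1] - 1) < 0.01))
  expect_true(all(abs(pr$pearson[pr$target_cor == 0]) < 0.2))
  # anatomy: realised Jaccard equals the constructed target exactly
  ov <- anatomy_overlap(fx$pairs, fx$anatomy, cut = 0.5)
  expect_equal(ov$pairs$intersection, fx$pairs$target_intersection,
               tolerance = 1e-12)
  # disjoint annotation (target intersection 0) gives fraction 0
  zero <- ov$pairs$intersection[fx$pairs$target_intersection == 0]
  expect_true(all(zero == 0))
})
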