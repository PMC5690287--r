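test_that("correlation graph matches a brute-force pairwise oracle", {
  sim <- generate_timecourse(simulation_spec(n_genes = 20, seed = 21,
                                             replicates_per_stage = 2))
  ds <- sim$dataset
  g <- build_correlation_graph(ds, r_threshold = 0.9)
  # oracle: exhaustive O(n^2) loop over gene pairs
  ids <- g$nodes
  expected <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      r <- cor(ds$tpm[ids[i], ], ds$tpm[ids[j], ])
      if (r >= 0.9) {
        expected[[length(expected) + 1]] <-
          paste(sort(c(ids[i], ids[j])), collapse = "|")
      }
    }
  }
  got <- paste(pmin(g$edges$gene_a, g$edges$gene_b),
               pmax(g$edges$gene_a, g$edges$gene_b), sep = "|")
  expect_setequal(got, unlist(expected))
  expect_true(all(g$edges$weight >= 0.9 & g$edges$weight <= 1))
  expect_true(all(g$edges$gene_a != g$edges$gene_b))
  expect_error(build_correlation_graph(ds, r_threshold = 1.2), "threshold")
})

test_that("lowering the threshold never removes edges", {
  sim <- generate_timecourse(simulation_spec(n_genes = 40, seed = 22,
                                             replicates_per_stage = 2))
  e_hi <- build_correlation_graph(sim$dataset, 0.95)$edges
  e_lo <- build_correlation_graph(sim$dataset, 0.7)$edges
  key <- function(e) paste(e$gene_a, e$gene_b)
  expect_true(all(key(e_hi) %in% key(e_lo)))
})

test_that("identical and anti-correlated profiles behave at the threshold", {
  counts <- rbind(g1 = c(1, 5, 9, 2),
                  g2 = c(2, 10, 18, 4),    # identical shape: r = 1
                  g3 = c(9, 5, 1, 8))      # strongly negative
  dimnames(counts) <- list(NULL, paste0("s", 1:4, "_1"))
  ds <- toy_dataset(counts, stages = paste0("s", 1:4))
  g <- build_correlation_graph(ds, 0.9)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 1, tolerance = 1e-9)
})

test_that("MCL on clique components returns the components", {
  for (infl in c(1.5, 2.2, 4)) {
    cs <- mcl(clique_graph(c(5, 5)), inflation = infl)
    expect_length(cs$clusters, 2)
    expect_setequal(lengths(cs$clusters), c(5, 5))
    got <- lapply(cs$clusters, function(m) sort(sub("_.*", "", m)))
    expect_true(all(vapply(got, function(m) length(unique(m)) == 1,
                           logical(1))))
  }
  # isolated node forms a singleton
  g <- list(nodes = c("a", "b", "c"),
            edges = data.frame(gene_a = "a", gene_b = "b", weight = 1))
  cs <- mcl(g)
  expect_setequal(lengths(cs$clusters), c(2, 1))
  expect_error(mcl(clique_graph(5), inflation = 1), "inflation")
})

test_that("MCL recovers a planted three-block graph", {
  set.seed(42)
  n_per <- 12
  blocks <- rep(1:3, each = n_per)
  nodes <- sprintf("n%02d", seq_len(3 * n_per))
  pairs <- t(utils::combn(length(nodes), 2))
  p <- ifelse(blocks[pairs[, 1]] == blocks[pairs[, 2]], 0.9, 0.02)
  keep <- stats::runif(nrow(pairs)) < p
  g <- list(nodes = nodes,
            edges = data.frame(gene_a = nodes[pairs[keep, 1]],
                               gene_b = nodes[pairs[keep, 2]],
                               weight = 1, stringsAsFactors = FALSE))
  cs <- mcl(g, inflation = 2.2)
  planted <- vapply(split(nodes, blocks),
                    function(m) paste(sort(m), collapse = ","),
                    character(1))
  got <- vapply(cs$clusters, function(m) paste(sort(m), collapse = ","),
                character(1))
  expect_setequal(unname(got), unname(planted))
})

test_that("size filtering moves small clusters to unassigned", {
  cs <- structure(list(
    clusters = list(`1` = paste0("a", 1:10), `2` = paste0("b", 1:6),
                    `3` = paste0("c", 1:5)),
    unassigned = character(0), provenance = list()),
    class = "cluster_set")
  out <- filter_clusters(cs, min_size = 6)
  expect_length(out$clusters, 2)
  expect_length(out$unassigned, 5)
  expect_equal(names(out$clusters), c("1", "2"))
  # conservation
  expect_setequal(unname(c(unlist(out$clusters), out$unassigned)),
                  unname(unlist(cs$clusters)))
  # empty input
  empty <- structure(list(clusters = list(), unassigned = character(0),
                          provenance = list()), class = "cluster_set")
  expect_length(filter_clusters(empty, 6)$clusters, 0)
})

test_that("cluster profiles are means of per-gene z-scores", {
  counts <- rbind(g1 = c(2, 4, 8, 6),
                  g2 = c(20, 40, 80, 60),   # same shape, 10x scale
                  g3 = c(5, 5, 5, 5))       # zero variance
  # filler keeps column sums constant so TPM stays proportional to counts
  counts <- rbind(counts, g4 = 100 - colSums(counts))
  dimnames(counts) <- list(NULL, paste0("s", 1:4, "_1"))
  ds <- toy_dataset(counts, stages = paste0("s", 1:4))
  z1 <- as.numeric(scale(ds$tpm["g001", ]))
  # single-gene cluster: its own z-scores
  expect_equal(unname(cluster_profile("g001", ds)), z1)
  # same shape at different scale: profile equals either gene's z-scores
  expect_equal(unname(cluster_profile(c("g001", "g002"), ds)), z1)
  # profile is centred
  expect_lt(abs(mean(cluster_profile(c("g001", "g002"), ds))), 1e-9)
  expect_warning(cluster_profile(c("g001", "g003"), ds), "zero-variance")
})

test_that("mcl output partitions the node set", {
  sim <- generate_timecourse(simulation_spec(n_genes = 80, seed = 23,
                                             replicates_per_stage = 2))
  g <- build_correlation_graph(sim$dataset, 0.9)
  cs <- filter_clusters(mcl(g), min_size = 6)
  assigned <- unlist(cs$clusters, use.names = FALSE)
  expect_setequal(c(assigned, cs$unassigned), g$nodes)
  expect_equal(anyDuplicated(assigned), 0)
  tab <- cluster_table(cs)
  expect_equal(nrow(tab), length(assigned))
})
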