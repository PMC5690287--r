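#' Canonical stage labels for the 18-stage embryonic time course
#'
#' Four stages before or at the onset of zygotic transcription, four
#' during gastrulation, three during somitogenesis, three prim stages and
#' daily samples from 2 to 5 days post-fertilisation.
#'
#' @return Character vector of 18 stage labels in developmental order.
#' @export
default_stages <- function() {
  c("zygote", "cleavage_2cell", "blastula_128cell", "blastula_1kcell",
    "dome", "epiboly_50", "shield", "epiboly_75",
    "somites_1_4", "somites_14_19", "somites_20_25",
    "prim_5", "prim_15", "prim_25",
    "day_2", "day_3", "day_4", "day_5")
}

#' Names of the temporal expression archetypes
#' @return Character vector of valid archetype names.
#' @export
archetype_names <- function() {
  c("rising", "falling", "double-peak", "zga-spike", "flat-noise")
}

#' Mean expression shape of a temporal archetype
#'
#' Shapes are defined on the stage index `t = 1..S` and scaled to a
#' maximum of 1: `rising` is zero until a zygotic onset about a quarter
#' of the way through the course and then grows as a power law (a purely
#' zygotic gene), `falling` is its mirror (a maternal transcript fully
#' degraded by three quarters of the course), `double-peak` has a
#' blastula/gastrula bump and a lower late bump, `zga-spike` is a narrow
#' Gaussian centred on the zygotic genome activation stage (truncated to
#' exact zero in its far tails), and `flat-noise` is constant.
#'
#' @param archetype One of [archetype_names()].
#' @param n_stages Number of stages.
#' @param zga_stage Stage index of the zygotic-genome-activation spike.
#' @return Numeric vector of length `n_stages` in `[0, 1]`.
#' @export
archetype_shape <- function(archetype, n_stages, zga_stage = zga_stage_index(n_stages)) {
  t <- seq_len(n_stages)
  s <- (t - 1) / (n_stages - 1)
  shape <- switch(archetype,
    "rising"      = pmax(0, (s - 0.25) / 0.75)^1.5,
    "falling"     = pmax(0, (0.75 - s) / 0.75)^1.5,
    "double-peak" = {
      p1 <- ceiling(0.39 * n_stages)
      p2 <- ceiling(0.89 * n_stages)
      exp(-(t - p1)^2 / (2 * 1.2^2)) + 0.75 * exp(-(t - p2)^2 / (2 * 1.2^2))
    },
    "zga-spike"   = {
      g <- exp(-(t - zga_stage)^2 / (2 * 0.75^2))
      ifelse(g < 1e-4, 0, g)
    },
    "flat-noise"  = rep(1, n_stages),
    stop("unknown archetype: ", archetype)
  )
  shape / max(shape)
}

#' Stage index at which the zygotic-genome-activation spike peaks
#' @param n_stages Number of stages.
#' @return Integer stage index (stage 5, "dome", for the 18-stage course).
#' @export
zga_stage_index <- function(n_stages) {
  max(2L, min(n_stages, round(0.28 * n_stages)))
}

#' Specification of a synthetic time-course dataset
#'
#' Describes an experiment of `n_genes` genes measured over `stages` with
#' `replicates_per_stage` biological replicates per stage. Each gene is
#' assigned a temporal archetype according to `archetype_mix`; genes in
#' `planted_domains` are placed at contiguous positions on one chromosome
#' and share the domain archetype (a chromosomal co-expression block);
#' `paralogue_spec` reserves pairs of genes whose stage-level profiles are
#' constructed with a given Pearson correlation.
#'
#' @param n_genes Positive number of genes.
#' @param stages Ordered character vector of stage labels.
#' @param replicates_per_stage Positive number of replicates per stage.
#' @param archetype_mix Named numeric vector/list of archetype fractions
#'   summing to 1.
#' @param planted_domains List of domains, each a list with elements
#'   `chromosome`, `start_index` (1-based gene index within that
#'   chromosome), `n_genes`, `archetype`.
#' @param paralogue_spec List of blocks, each a list with elements
#'   `target_cor` in `[-1, 1]` and `n_pairs`.
#' @param dispersion Negative-binomial dispersion of counts (variance =
#'   mu + dispersion * mu^2); 0 gives deterministic rounded counts.
#' @param library_scale Factor applied to the reference mean library size
#'   of 3.8 million reads; the default 0.01 gives desk-scale libraries.
#' @param library_sdlog Log-normal sd of library sizes.
#' @param n_chromosomes Number of chromosomes genes are laid out on.
#' @param unnamed_fraction Fraction of genes given clone-derived
#'   (unnamed-style) names.
#' @param seed Integer master seed.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 300,
                            stages = default_stages(),
                            replicates_per_stage = 5,
                            archetype_mix = c("rising" = 0.25,
                                              "falling" = 0.25,
                                              "double-peak" = 0.15,
                                              "zga-spike" = 0.10,
                                              "flat-noise" = 0.25),
                            planted_domains = list(),
                            paralogue_spec = list(),
                            dispersion = 0.05,
                            library_scale = 0.01,
                            library_sdlog = 0.15,
                            n_chromosomes = 25,
                            unnamed_fraction = 0.2,
                            seed = 1) {
  mix <- unlist(archetype_mix)
  if (is.null(names(mix)) || any(names(mix) == "")) {
    stop("archetype_mix must be named")
  }
  unknown <- setdiff(names(mix), archetype_names())
  if (length(unknown) > 0) stop("unknown archetype name(s): ",
                                paste(unknown, collapse = ", "))
  if (abs(sum(mix) - 1) > 1e-9) stop("archetype fractions must sum to 1")
  if (any(mix < 0)) stop("archetype fractions must be non-negative")
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be positive")
  if (!is.numeric(replicates_per_stage) || replicates_per_stage < 1) {
    stop("replicates_per_stage must be positive")
  }
  if (length(stages) < 2) stop("at least two stages required")
  if (anyDuplicated(stages)) stop("stage labels must be unique")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_chromosomes < 1) stop("n_chromosomes must be positive")
  for (d in planted_domains) {
    need <- c("chromosome", "start_index", "n_genes", "archetype")
    if (!all(need %in% names(d))) {
      stop("each planted domain needs: ", paste(need, collapse = ", "))
    }
    if (!d$archetype %in% archetype_names()) {
      stop("unknown archetype name(s): ", d$archetype)
    }
    if (d$n_genes < 1 || d$start_index < 1) {
      stop("domain dimensions must be positive")
    }
  }
  for (p in paralogue_spec) {
    if (!all(c("target_cor", "n_pairs") %in% names(p))) {
      stop("each paralogue block needs target_cor and n_pairs")
    }
    if (p$target_cor < -1 || p$target_cor > 1) {
      stop("target correlation outside [-1, 1]")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), stages = as.character(stages),
         replicates_per_stage = as.integer(replicates_per_stage),
         archetype_mix = mix, planted_domains = planted_domains,
         paralogue_spec = paralogue_spec, dispersion = dispersion,
         library_scale = library_scale, library_sdlog = library_sdlog,
         n_chromosomes = as.integer(n_chromosomes),
         unnamed_fraction = unnamed_fraction, seed = as.integer(seed)),
    class = "simulation_spec")
}

# deterministic integer allocation of n items to fractions (largest remainder)
allocate_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# synthetic gene names: a mix of conventional symbols and clone-id styles
simulate_gene_names <- function(n, unnamed_fraction) {
  n_unnamed <- round(n * unnamed_fraction)
  named <- replicate(n - n_unnamed, paste0(
    paste(sample(letters, sample(3:4, 1), replace = TRUE), collapse = ""),
    sample(1:9, 1)))
  styles <- sample(1:3, n_unnamed, replace = TRUE)
  unnamed <- vapply(styles, function(s) {
    switch(s,
      sprintf("zgc:%06d", sample(100000:999999, 1)),
      sprintf("si:ch211-%d%s.%d", sample(100:999, 1),
              paste(sample(letters, 2), collapse = ""), sample(1:9, 1)),
      sprintf("CABZ%08d.%d", sample(1e7:(1e8 - 1), 1), sample(1:9, 1)))
  }, character(1))
  nm <- c(named, unnamed)[sample.int(n)]
  make.unique(nm, sep = "_")
}

#' Generate a synthetic developmental time course
#'
#' Builds a seeded count matrix whose per-gene mean profiles follow the
#' assigned temporal archetypes, together with gene annotation (chromosome
#' layout with planted co-expression domains) and full ground truth.
#' Counts are negative-binomial around `mean profile x library-size
#' factor`; at `dispersion = 0` counts are the rounded means, giving a
#' noiseless dataset.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (gene archetype/peak-stage table, the generator's mean
#'   profiles in abundance units and as expected TPM, domain membership,
#'   paralogue pairs, library sizes).
#' @export
generate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(derive_seed(spec$seed, "timecourse"), {
    S <- length(spec$stages)
    n <- spec$n_genes
    n_para <- 2L * sum(vapply(spec$paralogue_spec, function(p)
      as.integer(p$n_pairs), integer(1)))
    if (n_para > 0 && n_para > n / 2) {
      stop("paralogue_spec reserves more than half of all genes")
    }

    # --- chromosome layout: contiguous slices of the gene index ---------
    chrom_sizes <- allocate_counts(rep(1 / spec$n_chromosomes,
                                       spec$n_chromosomes), n)
    chroms <- rep(paste0("chr", seq_len(spec$n_chromosomes)),
                  times = chrom_sizes)
    within_idx <- unlist(lapply(chrom_sizes, seq_len), use.names = FALSE)

    # --- archetype assignment ------------------------------------------
    counts_per <- allocate_counts(spec$archetype_mix, n)
    archetypes <- sample(rep(names(spec$archetype_mix), counts_per))

    # planted domains override the archetype of their member genes
    domain_members <- list()
    for (i in seq_along(spec$planted_domains)) {
      d <- spec$planted_domains[[i]]
      on_chrom <- which(chroms == d$chromosome)
      if (length(on_chrom) < d$start_index + d$n_genes - 1) {
        stop("domain exceeds genes available on ", d$chromosome)
      }
      members <- on_chrom[d$start_index:(d$start_index + d$n_genes - 1)]
      archetypes[members] <- d$archetype
      domain_members[[i]] <- members
    }

    # paralogue genes are scattered over the genome (outside planted
    # domains); their profiles are constructed below rather than drawn
    # from an archetype
    para_idx <- if (n_para > 0) {
      sort(sample(setdiff(seq_len(n), unlist(domain_members)), n_para))
    } else {
      integer(0)
    }

    # --- mean stage profiles (relative abundance units) -----------------
    zga <- zga_stage_index(S)
    shapes <- vapply(archetype_names(), archetype_shape, numeric(S),
                     n_stages = S, zga_stage = zga)
    amplitude <- stats::rlnorm(n, meanlog = log(100), sdlog = 0.4)
    raw <- matrix(0, n, S)
    for (g in seq_len(n)) {
      raw[g, ] <- amplitude[g] * shapes[, archetypes[g]]
    }

    pair_table <- NULL
    if (n_para > 0) {
      # TPM is a relative measure: a gene's realised TPM profile is its
      # raw profile divided by the per-stage transcriptome sum, so pair
      # profiles are planted in relative units. With background sum A(t)
      # and relative pair profiles u_g(t), setting
      #   raw_g = u_g * D,  D(t) = A(t) / (1 - sum_g u_g(t))
      # makes the total equal D and the expected TPM exactly
      # proportional to u_g, so the stage-level TPM correlation equals
      # the target.
      blocks <- spec$paralogue_spec
      k <- 0L
      rows <- list()
      profiles <- matrix(0, n_para, S)
      structured <- setdiff(archetype_names(), "flat-noise")
      amp <- stats::rlnorm(n_para, meanlog = log(400), sdlog = 0.3)
      for (b in seq_along(blocks)) {
        for (j in seq_len(blocks[[b]]$n_pairs)) {
          rho <- blocks[[b]]$target_cor
          base <- archetype_shape(sample(structured, 1), S, zga)
          za <- as.numeric(scale(base + stats::rnorm(S, 0, 0.05)))
          zr <- as.numeric(scale(stats::rnorm(S)))
          zr <- as.numeric(scale(zr - za * sum(zr * za) / sum(za * za)))
          zb <- rho * za + sqrt(1 - rho^2) * zr
          mm <- function(z) (z - min(z)) / (max(z) - min(z) + 1e-12)
          profiles[2L * k + 1L, ] <- amp[2L * k + 1L] * (0.05 + mm(za))
          profiles[2L * k + 2L, ] <- amp[2L * k + 2L] * (0.05 + mm(zb))
          rows[[k + 1L]] <- data.frame(
            pair_id = sprintf("pair%04d", k + 1L),
            gene_a = para_idx[2L * k + 1L],
            gene_b = para_idx[2L * k + 2L], target_cor = rho)
          k <- k + 1L
        }
      }
      # cap the pair genes' transcriptome share at 20%
      share <- 0.2
      u <- profiles * (share / max(colSums(profiles)))
      bg <- colSums(raw[-para_idx, , drop = FALSE])
      total <- bg / (1 - colSums(u))
      raw[para_idx, ] <- u * rep(total, each = n_para)
      archetypes[para_idx] <- "flat-noise"
      pair_table <- do.call(rbind, rows)
    }

    # --- annotation ----------------------------------------------------
    gene_id <- sprintf("gene%05d", seq_len(n))
    exonic_length <- sample(500:5000, n, replace = TRUE)
    gene_span <- exonic_length + sample(0:20000, n, replace = TRUE)
    start <- unlist(lapply(split(gene_span, factor(chroms, unique(chroms))),
                           function(sp) {
                             gaps <- sample(1000:10000, length(sp),
                                            replace = TRUE)
                             utils::head(cumsum(c(1, sp + gaps)),
                                         length(sp))
                           }), use.names = FALSE)
    genes <- data.frame(
      gene_id = gene_id,
      name = simulate_gene_names(n, spec$unnamed_fraction),
      chromosome = chroms,
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = start,
      end = start + gene_span - 1,
      exonic_length = exonic_length,
      biotype = "protein_coding",
      stringsAsFactors = FALSE)

    # --- samples and counts --------------------------------------------
    R <- spec$replicates_per_stage
    samples <- data.frame(
      sample_id = paste(rep(spec$stages, each = R),
                        rep(seq_len(R), times = S), sep = "_"),
      stage = rep(spec$stages, each = R),
      stage_index = rep(seq_len(S), each = R),
      replicate = rep(seq_len(R), times = S),
      stringsAsFactors = FALSE)
    lib <- stats::rlnorm(nrow(samples),
                         meanlog = log(3.8e6 * spec$library_scale),
                         sdlog = spec$library_sdlog)
    # expected counts: library size split by relative transcript
    # abundance (raw) weighted by exonic length
    weights <- raw * exonic_length
    wsum <- colSums(weights)
    weights <- sweep(weights, 2, ifelse(wsum == 0, 1, wsum), "/")
    mu <- weights[, samples$stage_index, drop = FALSE] *
      rep(lib, each = n)
    counts <- if (spec$dispersion == 0) {
      round(mu)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
             nrow = n)
    }
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(gene_id, samples$sample_id)

    dataset <- expression_dataset(counts, genes, samples)

    # --- ground truth ---------------------------------------------------
    rsum <- colSums(raw)
    expected_tpm <- sweep(raw, 2, ifelse(rsum == 0, 1, rsum), "/") * 1e6
    dimnames(expected_tpm) <- list(gene_id, spec$stages)
    mean_profile <- raw
    dimnames(mean_profile) <- list(gene_id, spec$stages)
    peak_idx <- apply(raw, 1, which.max)
    truth_genes <- data.frame(
      gene_id = gene_id,
      archetype = archetypes,
      peak_stage = ifelse(archetypes == "flat-noise", NA_character_,
                          spec$stages[peak_idx]),
      is_paralogue = seq_len(n) %in% para_idx,
      stringsAsFactors = FALSE)
    truth_domains <- if (length(domain_members) > 0) {
      do.call(rbind, lapply(seq_along(domain_members), function(i) {
        data.frame(domain_id = sprintf("domain%02d", i),
                   chromosome = spec$planted_domains[[i]]$chromosome,
                   archetype = spec$planted_domains[[i]]$archetype,
                   gene_id = gene_id[domain_members[[i]]],
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(domain_id = character(0), chromosome = character(0),
                 archetype = character(0), gene_id = character(0))
    }
    if (!is.null(pair_table)) {
      pair_table$gene_a <- gene_id[pair_table$gene_a]
      pair_table$gene_b <- gene_id[pair_table$gene_b]
    } else {
      pair_table <- data.frame(pair_id = character(0), gene_a = character(0),
                               gene_b = character(0), target_cor = numeric(0))
    }
    truth <- list(genes = truth_genes, expected_tpm = expected_tpm,
                  mean_profile = mean_profile,
                  domains = truth_domains, paralogues = pair_table,
                  library_sizes = stats::setNames(lib, samples$sample_id))
    list(dataset = dataset, truth = truth)
  })
}

#' Generate a paralogue-pair fixture with anatomy annotations
#'
#' Returns the paralogue pair list reserved by the simulation spec (the
#' pairs whose expression profiles [generate_timecourse()] constructed at the target
#' correlations) together with a synthetic anatomy-ontology annotation
#' table in which each pair's (stage id, anatomy term) sets realise a
#' controlled Jaccard intersection drawn uniformly on `[0, 1]`.
#'
#' @param spec The [simulation_spec()] used to build `dataset`.
#' @param dataset The generated [expression_dataset()].
#' @param terms_per_gene Number of (stage, term) annotation items per gene.
#' @return List with `pairs` (pair_id, gene_a, gene_b, target_cor,
#'   target_intersection) and `anatomy` (gene_id, stage_id, anatomy_term).
#' @export
generate_paralogue_fixture <- function(spec, dataset, terms_per_gene = 20) {
  stopifnot(inherits(spec, "simulation_spec"))
  sim <- generate_timecourse(spec)  # deterministic; recover pair identities
  pairs <- sim$truth$paralogues
  if (nrow(pairs) == 0) {
    return(list(pairs = pairs,
                anatomy = data.frame(gene_id = character(0),
                                     stage_id = character(0),
                                     anatomy_term = character(0))))
  }
  with_seed(derive_seed(spec$seed, "anatomy"), {
    m <- as.integer(terms_per_gene)
    target_j <- stats::runif(nrow(pairs))
    item_counter <- 0L
    rows <- vector("list", 2L * nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      # shared k of m items each gives Jaccard k / (2m - k)
      k <- round(target_j[i] * 2 * m / (1 + target_j[i]))
      shared <- item_counter + seq_len(k)
      only_a <- item_counter + k + seq_len(m - k)
      only_b <- item_counter + m + seq_len(m - k)
      item_counter <- item_counter + 2L * m - k
      mk <- function(ids, gene) data.frame(
        gene_id = gene,
        stage_id = sprintf("ZFS:%07d", 100 + (ids %% 50)),
        anatomy_term = sprintf("ZFA:%07d", ids),
        stringsAsFactors = FALSE)
      rows[[2 * i - 1]] <- mk(c(shared, only_a), pairs$gene_a[i])
      rows[[2 * i]] <- mk(c(shared, only_b), pairs$gene_b[i])
    }
    k_real <- round(target_j * 2 * m / (1 + target_j))
    pairs$target_intersection <- k_real / (2 * m - k_real)
    list(pairs = pairs, anatomy = do.call(rbind, rows))
  })
}
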