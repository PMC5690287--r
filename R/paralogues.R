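#' Pearson correlation of paralogous pairs
#'
#' Computes, for each pair, the Pearson correlation of TPM across all
#' samples. Pairs in which either member has zero variance are flagged
#' (`evaluable = FALSE`, coefficient `NA`) and excluded from downstream
#' summaries.
#'
#' @param dataset An [expression_dataset()].
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @return `pairs` with added columns `pearson` and `evaluable`.
#' @export
pair_correlations <- function(dataset, pairs) {
  ids <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(ids, rownames(dataset$tpm))
  if (length(missing) > 0) {
    stop("unknown gene id(s): ", paste(utils::head(missing, 5),
                                       collapse = ", "))
  }
  if (any(pairs$gene_a == pairs$gene_b)) {
    stop("a paralogous pair must consist of two distinct genes")
  }
  x <- dataset$tpm
  sds <- row_sds(x[ids, , drop = FALSE])
  ok <- stats::setNames(sds > 0, ids)
  pairs$evaluable <- ok[pairs$gene_a] & ok[pairs$gene_b]
  pairs$pearson <- NA_real_
  ev <- which(pairs$evaluable)
  pairs$pearson[ev] <- vapply(ev, function(i) {
    stats::cor(x[pairs$gene_a[i], ], x[pairs$gene_b[i], ])
  }, numeric(1))
  pairs
}

#' Random gene-pair null sample
#'
#' Draws `n` distinct unordered gene pairs uniformly without replacement
#' from the supplied gene universe, excluding a given pair set (the true
#' paralogue pairs), reproducibly under a seed.
#'
#' @param dataset An [expression_dataset()].
#' @param n Number of pairs to draw.
#' @param exclusions Data frame with columns `gene_a`, `gene_b` of pairs
#'   never to sample.
#' @param gene_ids Gene universe; defaults to [detectable_genes()].
#' @param seed Integer seed.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
random_pair_null <- function(dataset, n, exclusions = NULL,
                             gene_ids = detectable_genes(dataset),
                             seed = 1) {
  m <- length(gene_ids)
  if (m < 2) stop("need at least two genes to sample pairs")
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  banned <- if (is.null(exclusions) || nrow(exclusions) == 0) character(0)
            else pair_key(exclusions$gene_a, exclusions$gene_b)
  total <- choose(m, 2) - length(unique(banned))
  if (n > total) {
    stop("requested ", n, " pairs but only ", total, " are available")
  }
  with_seed(seed, {
    chosen <- character(0)
    out_a <- character(0)
    out_b <- character(0)
    while (length(out_a) < n) {
      need <- n - length(out_a)
      a <- gene_ids[sample.int(m, 2 * need + 10, replace = TRUE)]
      b <- gene_ids[sample.int(m, 2 * need + 10, replace = TRUE)]
      keep <- a != b
      a <- a[keep]; b <- b[keep]
      key <- pair_key(a, b)
      fresh <- !key %in% banned & !key %in% chosen & !duplicated(key)
      a <- a[fresh]; b <- b[fresh]; key <- key[fresh]
      take <- seq_len(min(need, length(a)))
      out_a <- c(out_a, pmin(a, b)[take])
      out_b <- c(out_b, pmax(a, b)[take])
      chosen <- c(chosen, key[take])
    }
    data.frame(gene_a = out_a, gene_b = out_b, stringsAsFactors = FALSE)
  })
}

#' Summarise real vs null correlation distributions
#'
#' @param real,null Numeric coefficient vectors (NAs dropped).
#' @param cuts Thresholds at which the fraction of coefficients below is
#'   reported.
#' @return List with `quantiles` (2 x 5 matrix of min/quartiles/max for
#'   both distributions), `fraction_below` (distribution x cut matrix)
#'   and `n` per distribution.
#' @export
correlation_summary <- function(real, null, cuts = c(0, 0.45, 0.5)) {
  real <- real[!is.na(real)]
  null <- null[!is.na(null)]
  if (length(real) == 0 || length(null) == 0) {
    stop("both coefficient lists must be non-empty")
  }
  qs <- rbind(real = stats::quantile(real, c(0, 0.25, 0.5, 0.75, 1)),
              null = stats::quantile(null, c(0, 0.25, 0.5, 0.75, 1)))
  fb <- rbind(real = vapply(cuts, function(ct) mean(real < ct), numeric(1)),
              null = vapply(cuts, function(ct) mean(null < ct), numeric(1)))
  colnames(fb) <- as.character(cuts)
  list(quantiles = qs, fraction_below = fb,
       n = c(real = length(real), null = length(null)))
}

#' Anatomy-annotation intersection of paralogous pairs
#'
#' Each gene's annotation is its set of (stage id, anatomy term) items.
#' The per-pair intersection fraction is the Jaccard index
#' `|A intersect B| / |A union B|` by default, or the intersection over
#' the smaller set when `denominator = "min"`. Pairs in which either gene
#' has no annotation are excluded (and counted).
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param annotations Data frame with columns `gene_id`, `stage_id`,
#'   `anatomy_term`.
#' @param cut Fraction threshold for the headline summary.
#' @param denominator `"union"` (Jaccard) or `"min"`.
#' @return List with `pairs` (with added `intersection` column, NA when
#'   unevaluable), `n_evaluated`, `n_excluded`, `n_below`,
#'   `percent_below` (share of evaluated pairs with fraction < `cut`,
#'   1 decimal place).
#' @export
anatomy_overlap <- function(pairs, annotations, cut = 0.5,
                            denominator = c("union", "min")) {
  denominator <- match.arg(denominator)
  items <- split(paste(annotations$stage_id, annotations$anatomy_term,
                       sep = "\r"),
                 annotations$gene_id)
  items <- lapply(items, unique)
  frac <- vapply(seq_len(nrow(pairs)), function(i) {
    sa <- items[[pairs$gene_a[i]]]
    sb <- items[[pairs$gene_b[i]]]
    if (is.null(sa) || is.null(sb) || length(sa) == 0 || length(sb) == 0) {
      return(NA_real_)
    }
    inter <- length(intersect(sa, sb))
    denom <- if (denominator == "union") length(union(sa, sb))
             else min(length(sa), length(sb))
    inter / denom
  }, numeric(1))
  pairs$intersection <- frac
  n_eval <- sum(!is.na(frac))
  n_below <- sum(frac < cut, na.rm = TRUE)
  list(pairs = pairs, n_evaluated = n_eval,
       n_excluded = sum(is.na(frac)), n_below = n_below,
       percent_below = overlap_percent(n_below, n_eval))
}
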