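#' Build a thresholded Pearson co-expression graph
#'
#' Nodes are genes with non-zero TPM variance across samples; an
#' undirected edge links two genes iff the Pearson correlation of their
#' TPM profiles across all samples reaches the threshold. Edge weights
#' carry the correlation coefficient.
#'
#' @param dataset An [expression_dataset()].
#' @param r_threshold Correlation cut-off in (0, 1).
#' @param gene_ids Gene universe considered; defaults to all genes.
#' @return List of class `coexpression_graph` with `nodes` (gene ids),
#'   `edges` (data frame `gene_a`, `gene_b`, `weight`), `r_threshold`,
#'   `n_zero_variance` (genes excluded).
#' @export
build_correlation_graph <- function(dataset, r_threshold = 0.94,
                                    gene_ids = rownames(dataset$tpm)) {
  if (r_threshold <= 0 || r_threshold >= 1) {
    stop("correlation threshold must lie in (0, 1)")
  }
  x <- dataset$tpm[gene_ids, , drop = FALSE]
  sds <- row_sds(x)
  dropped <- sum(sds == 0)
  x <- x[sds > 0, , drop = FALSE]
  cc <- stats::cor(t(x))
  hits <- which(cc >= r_threshold & upper.tri(cc), arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(cc)[hits[, 1]],
                      gene_b = rownames(cc)[hits[, 2]],
                      weight = cc[hits],
                      stringsAsFactors = FALSE)
  structure(list(nodes = rownames(x), edges = edges,
                 r_threshold = r_threshold, n_zero_variance = dropped,
                 universe_size = length(gene_ids)),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat(sprintf(
    "coexpression_graph: %d nodes, %d edges (r >= %.3g; %d zero-variance genes dropped)\n",
    length(x$nodes), nrow(x$edges), x$r_threshold, x$n_zero_variance))
  invisible(x)
}

#' Markov Cluster Algorithm on a weighted graph
#'
#' Standard MCL: a column-stochastic matrix is built from the edge
#' weights plus self-loops (each node's self-loop is its maximum incident
#' edge weight, which stabilises attractors on weighted graphs), then
#' expansion (matrix power) and inflation (entrywise power followed by
#' column renormalisation) alternate, pruning entries below `prune`,
#' until the largest column change falls below `tol` or `max_iter` is
#' reached. Clusters are read from the attractor structure; a node drawn
#' to several attractor systems is assigned to the one holding more of
#' its probability mass, ties to the lower cluster label.
#'
#' @param graph A `coexpression_graph` (or any list with `nodes` and
#'   `edges` of the same shape).
#' @param inflation Inflation exponent (> 1).
#' @param expansion Expansion power (integer >= 2).
#' @param tol Convergence tolerance.
#' @param prune Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap.
#' @return List of class `cluster_set`: `clusters` (list of gene id
#'   vectors, labelled by decreasing size), `unassigned` (empty here;
#'   filled by [filter_clusters()]), `provenance`.
#' @export
mcl <- function(graph, inflation = 2.2, expansion = 2, tol = 1e-6,
                prune = 1e-5, max_iter = 100) {
  if (length(graph$nodes) == 0) stop("graph has no nodes")
  if (inflation <= 1) stop("inflation must exceed 1")
  nodes <- graph$nodes
  n <- length(nodes)
  m <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges) > 0) {
    ia <- match(graph$edges$gene_a, nodes)
    ib <- match(graph$edges$gene_b, nodes)
    w <- graph$edges$weight
    m[cbind(ia, ib)] <- w
    m[cbind(ib, ia)] <- w
  }
  loop <- apply(m, 2, max)
  diag(m) <- ifelse(loop > 0, loop, 1)
  m <- sweep(m, 2, colSums(m), "/")

  converged <- FALSE
  iters <- 0L
  for (i in seq_len(max_iter)) {
    iters <- i
    prev <- m
    for (e in seq_len(expansion - 1)) m <- m %*% prev  # matrix power
    m <- m^inflation
    m[m < prune] <- 0
    cs <- colSums(m)
    dead <- cs == 0  # fully pruned column: restore self-loop
    if (any(dead)) {
      m[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    m <- sweep(m, 2, cs, "/")
    if (max(abs(m - prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter,
            " iterations; returning best-effort clusters")
  }

  # attractors: nodes retaining mass on their own row
  attractors <- which(diag(m) > prune)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # attractor systems: connected components among attractors via residual
  # mass between them
  sys_id <- seq_along(attractors)
  amat <- m[attractors, attractors, drop = FALSE]
  link <- (amat > prune) | (t(amat) > prune)
  repeat {
    changed <- FALSE
    for (i in seq_along(attractors)) {
      nb <- which(link[i, ])
      if (length(nb) > 0) {
        new <- min(sys_id[c(i, nb)])
        if (any(sys_id[c(i, nb)] != new)) {
          sys_id[c(i, nb)] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # assign every node to the attractor system holding most of its mass
  mass <- rowsum(m[attractors, , drop = FALSE], group = sys_id)
  assign_sys <- as.integer(rownames(mass))[apply(mass, 2, which.max)]
  unreached <- colSums(mass) == 0
  if (any(unreached)) {  # isolated after pruning: own singleton
    assign_sys[unreached] <- -seq_len(sum(unreached))
  }
  members <- split(nodes, assign_sys)
  members <- members[order(lengths(members), decreasing = TRUE)]
  names(members) <- seq_along(members)
  structure(list(clusters = members, unassigned = character(0),
                 provenance = list(inflation = inflation,
                                   expansion = expansion, tol = tol,
                                   prune = prune, iterations = iters,
                                   converged = converged,
                                   r_threshold = graph$r_threshold %||% NA)),
            class = "cluster_set")
}

#' Remove clusters below a minimum size
#'
#' Clusters with fewer than `min_size` members are dissolved and their
#' genes recorded as unassigned; the survivors are relabelled 1, 2, ...
#' by decreasing size.
#'
#' @param clusters A `cluster_set`.
#' @param min_size Minimum member count to retain a cluster.
#' @return A `cluster_set` with `unassigned` filled.
#' @export
filter_clusters <- function(clusters, min_size = 6) {
  keep <- lengths(clusters$clusters) >= min_size
  removed <- unlist(clusters$clusters[!keep], use.names = FALSE)
  kept <- clusters$clusters[keep]
  kept <- kept[order(lengths(kept), decreasing = TRUE)]
  names(kept) <- seq_along(kept)
  structure(list(clusters = kept,
                 unassigned = c(clusters$unassigned, removed),
                 provenance = c(clusters$provenance,
                                list(min_cluster_size = min_size))),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (%d genes), %d unassigned\n",
              length(x$clusters), sum(lengths(x$clusters)),
              length(x$unassigned)))
  invisible(x)
}

#' Mean z-scored expression profile of a cluster
#'
#' Each member gene's TPM vector is centred to mean 0 and scaled to unit
#' variance across samples, then the per-sample mean over genes is taken.
#' Zero-variance members cannot be z-scored and are excluded with a
#' warning.
#'
#' @param cluster Character vector of member gene ids.
#' @param dataset An [expression_dataset()].
#' @return Named numeric vector, one value per sample.
#' @export
cluster_profile <- function(cluster, dataset) {
  if (length(cluster) == 0) stop("cluster is empty")
  x <- dataset$tpm[cluster, , drop = FALSE]
  sds <- row_sds(x)
  if (any(sds == 0)) {
    warning("excluding zero-variance member(s): ",
            paste(cluster[sds == 0], collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) == 0) stop("no members with non-zero variance")
  }
  z <- t(scale(t(x)))
  colMeans(z)
}

#' Cluster membership as a data frame
#'
#' @param clusters A `cluster_set`.
#' @return Data frame with columns `gene_id`, `cluster`.
#' @export
cluster_table <- function(clusters) {
  data.frame(
    gene_id = unlist(clusters$clusters, use.names = FALSE),
    cluster = rep(as.integer(names(clusters$clusters)),
                  lengths(clusters$clusters)),
    stringsAsFactors = FALSE)
}
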