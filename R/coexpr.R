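#' Remove additive batch effects by per-gene mean centring
#'
#' For each gene, subtracts the batch-wise mean and adds back the gene's
#' grand mean. A deliberately simple linear correction: it removes additive
#' batch shifts only, not batch-specific variance.
#'
#' @param expr Genes x samples numeric matrix.
#' @param batch Vector of batch labels, one per sample (column).
#' @return Corrected matrix, same shape.
#' @export
batch_regress <- function(expr, batch) {
  if (length(batch) != ncol(expr)) abort("One batch label per sample required.")
  batch <- as.factor(batch)
  if (nlevels(droplevels(batch)) < 2) {
    warn("Single batch: returning the input unchanged.")
    return(expr)
  }
  grand <- rowMeans(expr)
  out <- expr
  for (b in levels(batch)) {
    cols <- which(batch == b)
    bm <- rowMeans(expr[, cols, drop = FALSE])
    out[, cols] <- expr[, cols, drop = FALSE] - bm + grand
  }
  out
}

#' Select genes for co-expression analysis
#'
#' Keeps genes that are well expressed (`mean > min_mean`) and not dominated
#' by technical variability (coefficient of variation `sd/mean < max_cv`).
#'
#' @param expr Genes x samples matrix on a positive expression scale.
#' @param min_mean Mean expression that must be exceeded (default 10).
#' @param max_cv Upper bound on sd/mean (default 0.15).
#' @return The filtered expression matrix.
#' @export
filter_coexpression_genes <- function(expr, min_mean = 10, max_cv = 0.15) {
  m <- rowMeans(expr)
  cv <- sqrt(row_vars(expr)) / m
  keep <- m > min_mean & cv < max_cv
  if (!any(keep)) abort("No genes pass the co-expression filter.")
  expr[keep, , drop = FALSE]
}

#' Topological overlap matrix
#'
#' Unsigned adjacency `a_ij = |cor(g_i, g_j)|^beta` (Pearson, zero diagonal),
#' then `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is 1.
#' Values lie in `[0, 1]`; `1 - TOM` is the clustering dissimilarity.
#'
#' The default soft-threshold power of 6 is the usual unsigned-network
#' choice. With `beta = 1` the background adjacency of uncorrelated genes
#' scales like `1/sqrt(n_samples)`, which places null-pair dissimilarities
#' right at a 0.95 tree cut and makes the clustering unstable; `beta = 6`
#' drives null-pair overlap to zero while leaving strongly correlated blocks
#' intact.
#'
#' @param expr Genes x samples matrix.
#' @param genes Optional subset of gene ids.
#' @param beta Soft-threshold power on the absolute correlation (default 6).
#' @return Symmetric genes x genes matrix in `[0, 1]`.
#' @export
tom_matrix <- function(expr, genes = NULL, beta = 6) {
  if (!is.null(genes)) expr <- expr[genes, , drop = FALSE]
  if (nrow(expr) < 3 || ncol(expr) < 3) {
    abort("TOM needs at least 3 genes and 3 samples.")
  }
  sds <- sqrt(row_vars(expr))
  if (any(sds == 0)) {
    abort(sprintf("Constant gene(s) have undefined correlation: %s",
                  paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", ")))
  }
  A <- abs(cor(t(expr)))^beta
  diag(A) <- 0
  tom_from_adjacency(A)
}

# TOM from an adjacency matrix with zero diagonal (split out so tests can
# feed hand-built adjacencies).
tom_from_adjacency <- function(A) {
  L <- A %*% A
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  (tom + t(tom)) / 2
}

#' Cut a TOM dendrogram into gene clusters
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at `cut_height`; clusters smaller than `min_size` are discarded.
#' Surviving clusters are relabelled `C01, C02, ...` by decreasing size.
#'
#' @param tom Symmetric TOM matrix from [tom_matrix()].
#' @param cut_height Tree cut height on `1 - TOM` (default 0.95).
#' @param min_size Minimum cluster size (default 50).
#' @return A `txage_clusters` object: `clusters` (named list id -> gene ids),
#'   `assignments` tibble, `cut_height`, `min_size`.
#' @export
cut_clusters <- function(tom, cut_height = 0.95, min_size = 50) {
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  if (length(keep) == 0) {
    warn("No cluster reaches `min_size`; returning an empty cluster set.")
    clusters <- list()
  } else {
    keep <- keep[order(-sizes[keep])]
    clusters <- setNames(
      lapply(keep, function(k) names(raw)[raw == as.integer(k)]),
      sprintf("C%02d", seq_along(keep))
    )
  }
  assignments <- if (length(clusters)) {
    bind_rows(imap(clusters, function(genes, id) {
      tibble(gene_id = genes, cluster_id = id)
    }))
  } else tibble(gene_id = character(), cluster_id = character())
  structure(list(clusters = clusters, assignments = assignments,
                 cut_height = cut_height, min_size = min_size),
            class = "txage_clusters")
}

#' @export
print.txage_clusters <- function(x, ...) {
  cat(sprintf("%d co-expression cluster(s) (cut height %.2f, min size %d)\n",
              length(x$clusters), x$cut_height, x$min_size))
  if (length(x$clusters)) {
    print(tibble(cluster_id = names(x$clusters),
                 n_genes = lengths(x$clusters)))
  }
  invisible(x)
}

#' Collapse clusters to metagenes
#'
#' Each gene is z-scored across samples (sample standard deviation, n - 1);
#' the metagene of a cluster is the per-sample mean of its member genes'
#' z-scores. Zero-variance genes are excluded from their cluster's mean with
#' a warning. By construction every metagene has grand mean ~0.
#'
#' @param expr Genes x samples matrix containing the cluster members.
#' @param clusters A `txage_clusters` object (or a named list of gene ids).
#' @return A `txage_metagenes` object wrapping the clusters x samples matrix.
#' @export
metagenes <- function(expr, clusters) {
  cl <- if (inherits(clusters, "txage_clusters")) clusters$clusters else clusters
  if (length(cl) == 0) abort("No clusters to collapse.")
  members <- unique(unlist(cl))
  missing <- setdiff(members, rownames(expr))
  if (length(missing) > 0) {
    abort(sprintf("Cluster member(s) absent from `expr`: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  sub <- expr[members, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- sqrt(row_vars(sub))
  degenerate <- sdv == 0
  if (any(degenerate)) {
    warn(sprintf("%d zero-variance gene(s) excluded from metagenes.",
                 sum(degenerate)))
  }
  Z <- (sub - mu) / ifelse(sdv == 0, 1, sdv)
  mg <- t(vapply(cl, function(genes) {
    genes <- genes[!degenerate[match(genes, members)]]
    if (length(genes) == 0) return(rep(NA_real_, ncol(expr)))
    colMeans(Z[genes, , drop = FALSE])
  }, numeric(ncol(expr))))
  colnames(mg) <- colnames(expr)
  structure(list(matrix = mg, clusters = cl), class = "txage_metagenes")
}

#' Test metagene differences between two sample groups
#'
#' Per cluster, an unpaired two-tailed Welch t-test of the metagene values in
#' `group_a` samples against `group_b` samples, with Benjamini-Hochberg
#' adjustment across clusters. By default group b is every non-`group_a`
#' sample (i.e. HC vs all MDD).
#'
#' @param mg A `txage_metagenes` object.
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @param group_a First group label (default `"HC"`).
#' @param group_b Second group label(s); default: all other groups pooled.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param alpha Adjusted-p threshold reported in the `significant` column
#'   (default 0.25, reported, not asserted).
#' @return Tibble with per-cluster `t`, `p`, `p_adj`, `significant`.
#' @export
cluster_group_test <- function(mg, metadata, group_a = "HC", group_b = NULL,
                               var_equal = FALSE, alpha = 0.25) {
  M <- mg$matrix
  metadata <- align_metadata(metadata, colnames(M))
  g <- as.character(metadata$group)
  in_a <- g %in% group_a
  in_b <- if (is.null(group_b)) !in_a else g %in% group_b
  if (sum(in_a) < 2 || sum(in_b) < 2) {
    abort("Both groups need at least 2 samples.")
  }
  res <- purrr::imap(asplit(M, 1), function(v, id) {
    tt <- t.test(v[in_a], v[in_b], var.equal = var_equal)
    tibble(cluster_id = id, n_genes = length(mg$clusters[[id]]),
           mean_a = mean(v[in_a]), mean_b = mean(v[in_b]),
           t = unname(tt$statistic), p = tt$p.value)
  })
  out <- bind_rows(res)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  arrange(out, .data$p)
}
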