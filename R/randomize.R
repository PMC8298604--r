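#' Randomly split samples into pseudo-cases and pseudo-controls
#'
#' A uniform random partition of the sample ids into disjoint, exhaustive
#' sets of sizes `n_case` and `total - n_case`, reproducible from `seed`.
#'
#' @param sample_ids Character vector of sample ids.
#' @param n_case Size of the pseudo-case set.
#' @param seed Integer seed.
#' @return List with `case` and `control` id vectors.
#' @export
random_split <- function(sample_ids, n_case, seed) {
  n <- length(sample_ids)
  if (n_case <= 0 || n_case >= n) {
    abort("`n_case` must be strictly between 0 and the number of samples.")
  }
  ids <- sort(sample_ids)   # partition depends on the id set, not input order
  case <- with_seed(seed, sample(ids, n_case))
  list(case = sort(case), control = sort(setdiff(ids, case)))
}

#' Expected false positives from randomised case/control comparisons
#'
#' Repeats the full differential-expression contrast on randomly assigned
#' case/control labels (no adjustment covariates), recording per-threshold
#' significant-gene counts and each gene's raw p-value, then aggregates the
#' median and maximum count per threshold and the per-gene mean p across
#' iterations. One master seed deterministically spawns per-iteration seeds.
#'
#' Size factors and dispersions do not depend on the labels, so they are
#' computed once and shared by all iterations.
#'
#' @param counts Genes x samples matrix, pre-filtered with
#'   [filter_genes_for_de()].
#' @param metadata Sample metadata (only the sample ids are used).
#' @param n_case Pseudo-case group size (the remaining samples are controls).
#' @param n_iter Number of randomised comparisons (>= 2; default 50).
#' @param thresholds Adjusted-p cutoffs at which to count significant genes.
#' @param seed Master seed.
#' @param cooks_cutoff Passed to [fit_nb_wald()].
#' @return A `txage_randnull` object: `summary` (per-threshold median/max),
#'   `per_iteration` (long counts), `gene_mean_p`, and the run parameters.
#' @export
fp_expectation <- function(counts, metadata, n_case, n_iter = 50,
                           thresholds = c(0.01, 0.05, 0.1, 0.25), seed = 1,
                           cooks_cutoff = 0.2) {
  if (n_iter < 2) abort("`n_iter` must be at least 2.")
  metadata <- align_metadata(metadata, colnames(counts))
  thresholds <- sort(thresholds)
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf)
  seeds <- spawn_seeds(seed, n_iter)
  ids <- colnames(counts)

  counts_tab <- matrix(NA_integer_, n_iter, length(thresholds),
                       dimnames = list(NULL, as.character(thresholds)))
  p_sum <- setNames(numeric(nrow(counts)), rownames(counts))
  p_n <- setNames(integer(nrow(counts)), rownames(counts))

  for (i in seq_len(n_iter)) {
    split <- random_split(ids, n_case, seeds[i])
    md <- mutate(metadata, .pseudo = factor(
      ifelse(.data$sample_id %in% split$case, "case", "control"),
      levels = c("control", "case")
    ))
    de <- fit_nb_wald(counts, md,
                      contrast_spec(".pseudo", mode = "binary",
                                    levels = c("control", "case")),
                      sf = sf, dispersions = disp,
                      cooks_cutoff = cooks_cutoff)
    counts_tab[i, ] <- vapply(
      thresholds, function(t) sum(de$p_adj < t, na.rm = TRUE), integer(1)
    )
    ok <- !is.na(de$p)
    p_sum[de$gene_id[ok]] <- p_sum[de$gene_id[ok]] + de$p[ok]
    p_n[de$gene_id[ok]] <- p_n[de$gene_id[ok]] + 1L
  }

  per_iteration <- tibble(
    iteration = rep(seq_len(n_iter), times = length(thresholds)),
    threshold = rep(thresholds, each = n_iter),
    n_significant = as.vector(counts_tab)
  )
  summary <- tibble(
    threshold = thresholds,
    median_significant = unname(apply(counts_tab, 2, median)),
    max_significant = unname(apply(counts_tab, 2, max))
  )
  gene_mean_p <- tibble(
    gene_id = names(p_sum),
    mean_p = ifelse(p_n > 0, p_sum / p_n, NA_real_),
    n_iterations_tested = p_n
  )
  structure(
    list(summary = summary, per_iteration = per_iteration,
         gene_mean_p = gene_mean_p, thresholds = thresholds,
         n_iterations = n_iter, n_case = n_case,
         n_control = length(ids) - n_case, seed = seed),
    class = "txage_randnull"
  )
}

#' @export
print.txage_randnull <- function(x, ...) {
  cat(sprintf(
    "Randomisation null: %d iterations of %d vs %d pseudo-groups\n",
    x$n_iterations, x$n_case, x$n_control
  ))
  print(x$summary)
  invisible(x)
}

#' Recurrent false-positive genes
#'
#' The `k` genes with the smallest mean raw p-value across the randomised
#' comparisons; ties at the cut are broken by lexicographic gene id.
#'
#' @param summary A `txage_randnull` object.
#' @param k Number of genes to return (default 50).
#' @return Character vector of gene ids, most significant first.
#' @export
recurrent_fp_genes <- function(summary, k = 50) {
  gp <- summary$gene_mean_p
  gp <- filter(gp, !is.na(.data$mean_p))
  if (k > nrow(gp)) abort(sprintf("k = %d exceeds the %d genes with a mean p.",
                                  k, nrow(gp)))
  gp <- gp[order(gp$mean_p, gp$gene_id), ]
  gp$gene_id[seq_len(k)]
}

#' Hypergeometric over-representation analysis
#'
#' One-sided over-representation of a query gene list in each gene set:
#' upper-tail hypergeometric `P(X >= k)` with population `N = |background|`,
#' successes `K = |set  background|` and draws `n = |query|`, followed by
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param query Character vector of gene ids (must lie in `background`).
#' @param sets Named list of gene-id vectors, e.g. from [read_gmt()].
#' @param background Character vector: the expressed-gene universe.
#' @param fdr Adjusted-p cutoff for the `significant` column (default 0.05).
#' @return An `ORATable` tibble, one row per set, sorted by p.
#' @export
hypergeom_ora <- function(query, sets, background, fdr = 0.05) {
  background <- unique(background)
  if (length(background) == 0) abort("Empty background.")
  extra <- setdiff(query, background)
  if (length(extra) > 0) {
    warn(sprintf("%d query gene(s) outside the background were dropped.",
                 length(extra)))
  }
  query <- unique(intersect(query, background))
  N <- length(background)
  n <- length(query)
  res <- purrr::imap(sets, function(members, nm) {
    set_bg <- intersect(unique(members), background)
    K <- length(set_bg)
    k <- length(intersect(set_bg, query))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_name = nm, overlap = k, set_size = K,
           query_size = n, background_size = N, p = p)
  })
  out <- bind_rows(res)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < fdr
  arrange(out, .data$p, .data$set_name)
}
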