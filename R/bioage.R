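#' Age-quartile differential expression
#'
#' Compares the samples in the lowest age quartile to those in the highest,
#' with no adjustment covariates. Positive log2 fold change means higher
#' expression in the older samples, so the sign of the coefficient is the
#' sign of the age association.
#'
#' @param counts Filtered genes x samples matrix.
#' @param metadata Sample metadata with an `age` column covering all samples.
#' @param sf,dispersions Optional precomputed size factors / dispersions.
#' @param cooks_cutoff Passed to [fit_nb_wald()].
#' @return A `txage_de` tibble.
#' @export
age_de <- function(counts, metadata, sf = NULL, dispersions = NULL,
                   cooks_cutoff = 0.2) {
  md <- align_metadata(metadata, colnames(counts))
  if (any(is.na(md$age))) abort("Every sample needs an age for age DE.")
  fit_nb_wald(counts, metadata,
              contrast_spec("age", mode = "quartile", alpha = 0.05),
              sf = sf, dispersions = dispersions,
              cooks_cutoff = cooks_cutoff)
}

#' Winsorise expression values at a z-score bound
#'
#' Per gene, values beyond `mean ± z_cap * sd` (moments of the input values)
#' are clamped to the boundary.
#'
#' @param expr Genes x samples matrix of finite values.
#' @param z_cap Cap in standard deviations (default 3).
#' @return Capped matrix, same shape.
#' @export
cap_outliers <- function(expr, z_cap = 3) {
  m <- rowMeans(expr)
  s <- sqrt(row_vars(expr))
  lo <- m - z_cap * s
  hi <- m + z_cap * s
  pmin(pmax(expr, lo), hi)
}

#' Build an age signature from a DE table
#'
#' Selects tested genes with `p_adj < p_cutoff` and `|log2fc| > lfc_cutoff`;
#' each carries the sign of its age association (`-1` = down with age).
#'
#' @param de A `txage_de` table from [age_de()].
#' @param p_cutoff Adjusted-p cutoff (default 0.05).
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 0.6).
#' @param min_size Minimum number of genes (default 10).
#' @return A `txage_signature` tibble (`gene_id`, `sign`) with threshold
#'   attributes.
#' @export
age_signature <- function(de, p_cutoff = 0.05, lfc_cutoff = 0.6,
                          min_size = 10) {
  sel <- de$tested_flag & !is.na(de$p_adj) &
    de$p_adj < p_cutoff & abs(de$log2fc) > lfc_cutoff
  sig <- tibble(gene_id = de$gene_id[sel],
                sign = ifelse(de$log2fc[sel] >= 0, 1L, -1L))
  if (nrow(sig) < min_size) {
    abort(sprintf(
      "Signature has %d gene(s) at p_adj < %g, |log2fc| > %g; minimum is %d.",
      nrow(sig), p_cutoff, lfc_cutoff, min_size
    ))
  }
  structure(sig, class = c("txage_signature", class(sig)),
            p_cutoff = p_cutoff, lfc_cutoff = lfc_cutoff,
            n_genes = nrow(sig))
}

#' Transcriptional biological-age scores
#'
#' Each signature gene is z-scored across all samples jointly; the sign is
#' inverted for genes down-regulated with age; a sample's biological age is
#' the mean sign-aligned z-score over the signature genes.
#'
#' @param expr Genes x samples expression matrix (typically size-factor
#'   normalised counts on a log2(x+1) scale, outlier-capped).
#' @param signature A `txage_signature` (or tibble with `gene_id`, `sign`).
#' @param min_size Minimum usable signature genes (default 10).
#' @return Named numeric vector of per-sample scores.
#' @export
bioage_scores <- function(expr, signature, min_size = 10) {
  present <- signature$gene_id %in% rownames(expr)
  sub <- expr[signature$gene_id[present], , drop = FALSE]
  sdv <- sqrt(row_vars(sub))
  usable <- sdv > 0
  if (sum(usable) < min_size) {
    abort(sprintf("Only %d usable signature gene(s) in `expr`; minimum is %d.",
                  sum(usable), min_size))
  }
  sub <- sub[usable, , drop = FALSE]
  z <- (sub - rowMeans(sub)) / sdv[usable]
  signs <- signature$sign[present][usable]
  setNames(colMeans(z * signs), colnames(expr))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (ties averaged); two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `estimate`, `statistic`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs at least 3 pairs.")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) abort("Zero rank variance.")
  r <- cor(rx, ry)
  if (abs(r) >= 1) {
    p <- 0
    stat <- sign(r) * Inf
  } else {
    stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(stat), df = n - 2)
  }
  list(estimate = r, statistic = stat, p_value = p, n = n)
}

#' Optimise signature thresholds against chronological age
#'
#' For every `(p_cutoff, lfc_cutoff)` grid cell, forms the signature, scores
#' the samples and computes the Spearman correlation with chronological age;
#' returns the signature with the greatest coefficient. Ties prefer fewer
#' genes, then the smaller p cutoff. Cells whose signature falls below
#' `min_size` are skipped.
#'
#' @param de A `txage_de` table from [age_de()].
#' @param expr Expression matrix used for scoring.
#' @param metadata Sample metadata with `age`.
#' @param p_grid Adjusted-p cutoffs to try.
#' @param lfc_grid Absolute log2 fold-change cutoffs to try.
#' @param min_size Minimum signature size (default 10).
#' @return The winning `txage_signature`, with a `grid` attribute recording
#'   every evaluated cell (`p_cutoff`, `lfc_cutoff`, `n_genes`, `spearman`)
#'   and a `spearman` attribute with the achieved coefficient.
#' @export
optimize_signature <- function(de, expr, metadata,
                               p_grid = c(0.01, 0.05, 0.1),
                               lfc_grid = c(0, 0.3, 0.6, 1.0),
                               min_size = 10) {
  md <- align_metadata(metadata, colnames(expr))
  grid <- expand.grid(p_cutoff = p_grid, lfc_cutoff = lfc_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    sig <- tryCatch(
      age_signature(de, grid$p_cutoff[i], grid$lfc_cutoff[i], min_size),
      error = function(e) NULL
    )
    if (is.null(sig)) {
      rows[[i]] <- tibble(p_cutoff = grid$p_cutoff[i],
                          lfc_cutoff = grid$lfc_cutoff[i],
                          n_genes = NA_integer_, spearman = NA_real_)
      next
    }
    sc <- tryCatch(bioage_scores(expr, sig, min_size), error = function(e) NULL)
    rho <- if (is.null(sc)) NA_real_ else spearman(sc, md$age)$estimate
    rows[[i]] <- tibble(p_cutoff = grid$p_cutoff[i],
                        lfc_cutoff = grid$lfc_cutoff[i],
                        n_genes = nrow(sig), spearman = rho)
  }
  grid_res <- bind_rows(rows)
  ok <- !is.na(grid_res$spearman)
  if (!any(ok)) abort("Every grid cell fell below the minimum signature size.")
  cand <- grid_res[ok, ]
  cand <- cand[order(-cand$spearman, cand$n_genes, cand$p_cutoff), ]
  best <- cand[1, ]
  sig <- age_signature(de, best$p_cutoff, best$lfc_cutoff, min_size)
  attr(sig, "spearman") <- best$spearman
  attr(sig, "grid") <- grid_res
  sig
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates the hypergeometric support at the observed margins; the
#' two-sided p-value is the sum of the point probabilities of all tables no
#' more probable than the observed one (within relative tolerance 1e-7).
#'
#' @param table 2x2 matrix of non-negative integers with all margins
#'   positive. Rows are groups, columns are outcomes.
#' @return The two-sided p-value in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) abort("A 2x2 table is required.")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("Table entries must be non-negative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("All table margins must be positive.")
  }
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(support, c1, N - c1, r1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Regression-residual asymmetry between groups
#'
#' Fits ordinary least squares of biological-age score on chronological age
#' over all samples pooled; a sample is "above the line" when its residual is
#' strictly positive (a residual of exactly zero counts as below). The
#' groups x below/above 2x2 table is tested with the two-sided Fisher exact
#' test, and the Spearman correlation of score with age is reported.
#'
#' @param scores Per-sample biological-age scores (named or aligned with
#'   `ages`).
#' @param ages Chronological ages, same order.
#' @param groups Two-level factor/character of group labels, same order.
#' @return A `txage_bioage` object: per-sample tibble, regression slope and
#'   intercept, the 2x2 `table`, `fisher_p`, and the Spearman correlation.
#' @export
residual_asymmetry <- function(scores, ages, groups) {
  if (length(scores) != length(ages) || length(ages) != length(groups)) {
    abort("`scores`, `ages` and `groups` must have equal length.")
  }
  if (var(ages) == 0) abort("Degenerate ages: zero variance.")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) abort("`groups` must have exactly two levels.")
  if (any(table(groups) < 2)) abort("Both groups need at least 2 samples.")

  fit <- lm.fit(cbind(1, ages), scores)
  coefs <- fit$coefficients
  resid <- fit$residuals
  above <- resid > 0
  tab <- matrix(
    c(sum(!above & groups == levels(groups)[1]),
      sum(above & groups == levels(groups)[1]),
      sum(!above & groups == levels(groups)[2]),
      sum(above & groups == levels(groups)[2])),
    2, 2, byrow = TRUE,
    dimnames = list(levels(groups), c("below", "above"))
  )
  sp <- spearman(scores, ages)
  samples <- tibble(
    sample_id = names(scores) %||% as.character(seq_along(scores)),
    biological_age = unname(scores), age = ages, group = groups,
    fitted = unname(scores - resid), residual = unname(resid),
    above_line = unname(above)
  )
  structure(
    list(samples = samples, intercept = unname(coefs[1]),
         slope = unname(coefs[2]), table = tab,
         fisher_p = fisher_exact_2x2(tab),
         spearman = sp$estimate, spearman_p = sp$p_value),
    class = "txage_bioage"
  )
}

#' @export
print.txage_bioage <- function(x, ...) {
  cat("Biological vs chronological age\n")
  cat(sprintf("  regression: score = %.4f %+.4f * age\n", x$intercept, x$slope))
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", x$spearman, x$spearman_p))
  cat("  samples below/above the regression line:\n")
  print(x$table)
  cat(sprintf("  Fisher exact p = %.4g\n", x$fisher_p))
  invisible(x)
}

#' End-to-end biological-age analysis of a count cohort
#'
#' Runs the full chain: age-quartile DE, threshold optimisation against
#' chronological age, scoring on outlier-capped log2 normalised counts, and
#' the residual-asymmetry Fisher test of `group_a` vs everything else.
#'
#' @param counts Filtered genes x samples matrix.
#' @param metadata Sample metadata with `age` and `group`.
#' @param group_a Reference group label (default `"HC"`); all other samples
#'   form the comparison group.
#' @param p_grid,lfc_grid Threshold grids for [optimize_signature()].
#' @param z_cap Outlier cap for [cap_outliers()].
#' @param min_size Minimum signature size.
#' @return A `txage_bioage` object with the chosen signature attached as the
#'   `signature` attribute.
#' @export
bioage_analysis <- function(counts, metadata, group_a = "HC",
                            p_grid = c(0.01, 0.05, 0.1),
                            lfc_grid = c(0, 0.3, 0.6, 1.0),
                            z_cap = 3, min_size = 10) {
  md <- align_metadata(metadata, colnames(counts))
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf)
  de <- age_de(counts, metadata, sf = sf, dispersions = disp)
  expr <- cap_outliers(normalized_counts(counts, sf, log2 = TRUE), z_cap)
  sig <- optimize_signature(de, expr, metadata, p_grid, lfc_grid, min_size)
  scores <- bioage_scores(expr, sig, min_size)
  grp <- factor(ifelse(as.character(md$group) %in% group_a, group_a, "case"),
                levels = c(group_a, "case"))
  res <- residual_asymmetry(scores, md$age, grp)
  attr(res, "signature") <- sig
  res
}
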