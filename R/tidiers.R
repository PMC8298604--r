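#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a biological-age result
#'
#' One row per sample: score, age, group, residual and the above-line flag.
#'
#' @param x A `txage_bioage` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.txage_bioage <- function(x, ...) x$samples

#' One-row summary of a biological-age result
#'
#' @inheritParams tidy.txage_bioage
#' @return A tibble with slope, intercept, Spearman rho and the Fisher p.
#' @export
glance.txage_bioage <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    spearman = x$spearman, spearman_p = x$spearman_p,
    fisher_p = x$fisher_p,
    n = nrow(x$samples),
    n_below_a = x$table[1, 1], n_above_a = x$table[1, 2],
    n_below_b = x$table[2, 1], n_above_b = x$table[2, 2]
  )
}

#' Tidy a randomisation-null result
#'
#' @param x A `txage_randnull` object.
#' @param ... Unused.
#' @return Per-iteration, per-threshold significant-gene counts.
#' @export
tidy.txage_randnull <- function(x, ...) x$per_iteration

#' @rdname tidy.txage_randnull
#' @export
glance.txage_randnull <- function(x, ...) {
  out <- tidyr::pivot_wider(
    x$summary,
    names_from = "threshold",
    values_from = c("median_significant", "max_significant")
  )
  mutate(out, n_iterations = x$n_iterations,
         n_case = x$n_case, n_control = x$n_control)
}

#' Tidy an age signature
#'
#' @param x A `txage_signature`.
#' @param ... Unused.
#' @return Tibble of `gene_id` and association `sign`.
#' @export
tidy.txage_signature <- function(x, ...) {
  tibble(gene_id = x$gene_id, sign = x$sign)
}

#' @rdname tidy.txage_signature
#' @export
glance.txage_signature <- function(x, ...) {
  tibble(
    n_genes = attr(x, "n_genes"),
    p_cutoff = attr(x, "p_cutoff"),
    lfc_cutoff = attr(x, "lfc_cutoff"),
    spearman = attr(x, "spearman") %||% NA_real_
  )
}

#' One-row summary of a DE table
#'
#' @param x A `txage_de` table.
#' @param ... Unused.
#' @return Counts of tested, outlier-flagged and significant genes at the
#'   contrast's alpha.
#' @export
glance.txage_de <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.01
  tibble(
    n_genes = nrow(x),
    n_tested = sum(x$tested_flag),
    n_outliers = sum(x$outlier_flag),
    n_significant = sum(x$p_adj < alpha, na.rm = TRUE),
    alpha = alpha,
    level_low = attr(x, "levels")[1],
    level_high = attr(x, "levels")[2]
  )
}
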