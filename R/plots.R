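#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   geom_boxplot geom_density labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot biological vs chronological age
#'
#' Scatter of the per-sample biological-age score against chronological age,
#' coloured by group, with the pooled regression line.
#'
#' @param object A `txage_bioage` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.txage_bioage <- function(object, ...) {
  ggplot(object$samples, aes(x = .data$age, y = .data$biological_age,
                             colour = .data$group)) +
    geom_point(alpha = 0.7) +
    geom_abline(intercept = object$intercept, slope = object$slope) +
    labs(
      x = "Chronological age (years)", y = "Biological age (mean signed z)",
      colour = NULL,
      subtitle = sprintf("Spearman rho = %.2f; asymmetry Fisher p = %.3g",
                         object$spearman, object$fisher_p)
    ) +
    theme_minimal()
}

#' Density of regression residuals by group
#'
#' @param x A `txage_bioage` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_residuals <- function(x, ...) {
  ggplot(x$samples, aes(x = .data$residual, fill = .data$group)) +
    geom_density(alpha = 0.5) +
    labs(x = "Residual from biological ~ chronological age", y = "Density",
         fill = NULL) +
    theme_minimal()
}

#' Plot expected false positives by threshold
#'
#' Median and maximum significant-gene counts over the randomised
#' case/control comparisons.
#'
#' @param object A `txage_randnull` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.txage_randnull <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary, -"threshold",
                              names_to = "statistic", values_to = "count")
  ggplot(long, aes(x = factor(.data$threshold), y = .data$count)) +
    geom_col() +
    facet_wrap(~statistic) +
    labs(x = "Adjusted-p threshold", y = "Significant genes") +
    theme_minimal()
}

#' Plot the confounder screen
#'
#' @param object A `txage_confounders` tibble.
#' @param ... Unused.
#' @return A ggplot of significant-gene counts per covariate.
#' @export
autoplot.txage_confounders <- function(object, ...) {
  df <- mutate(as_tibble(object),
               covariate = stats::reorder(.data$covariate, .data$n_significant))
  ggplot(df, aes(x = .data$covariate, y = .data$n_significant,
                 fill = .data$flagged)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "Significant genes (adjusted p)", fill = "Flagged") +
    theme_minimal()
}

#' Boxplots of metagene expression by group
#'
#' @param mg A `txage_metagenes` object.
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @param clusters Optional subset of cluster ids to show.
#' @return A ggplot.
#' @export
plot_metagenes <- function(mg, metadata, clusters = NULL) {
  M <- mg$matrix
  if (!is.null(clusters)) M <- M[clusters, , drop = FALSE]
  df <- as_tibble(as.table(M), .name_repair = ~c("cluster_id", "sample_id", "metagene"))
  df <- left_join(df, select(metadata, "sample_id", "group"), by = "sample_id")
  ggplot(df, aes(x = .data$group, y = .data$metagene)) +
    geom_boxplot() +
    facet_wrap(~cluster_id) +
    labs(x = NULL, y = "Metagene (mean z-score)") +
    theme_minimal()
}
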