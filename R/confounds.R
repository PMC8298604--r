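#' Screen clinical covariates for confounding
#'
#' Runs one marginal differential-expression comparison per panel covariate —
#' two observed groups for binary covariates, lowest vs highest quartile for
#' continuous ones — with no mutual adjustment, counts the genes significant
#' at adjusted p below `alpha`, and flags covariates with strictly more than
#' `flag_threshold` significant genes as candidate confounders. Categorical
#' covariates with more than two levels and constant covariates are skipped
#' with a warning.
#'
#' Size factors and dispersions are label-independent, so they are estimated
#' once on the full matrix and reused across all screens.
#'
#' @param counts Genes x samples matrix, already filtered with
#'   [filter_genes_for_de()].
#' @param metadata Sample metadata tibble; covariate kinds are taken from its
#'   `covariate_spec` attribute and otherwise inferred (numeric = continuous,
#'   two levels = binary).
#' @param panel Character vector of covariate names to screen.
#' @param alpha Adjusted-p significance threshold (default 0.01).
#' @param flag_threshold Flag covariates with more than this many significant
#'   genes (strict inequality; default 5).
#' @param cooks_cutoff Passed to [fit_nb_wald()].
#' @return A `txage_confounders` tibble with one row per screened covariate,
#'   sorted by `n_significant` descending.
#' @export
screen_covariates <- function(counts, metadata, panel, alpha = 0.01,
                              flag_threshold = 5, cooks_cutoff = 0.2) {
  metadata <- align_metadata(metadata, colnames(counts))
  spec <- attr(metadata, "covariate_spec") %||% character()
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf)

  covariate_kind <- function(nm) {
    if (nm %in% names(spec)) return(spec[[nm]])
    v <- metadata[[nm]]
    if (is.numeric(v)) return("continuous")
    n_lev <- length(unique(stats::na.omit(as.character(v))))
    if (n_lev == 2) "binary" else "categorical"
  }

  rows <- list()
  for (nm in panel) {
    if (!nm %in% colnames(metadata)) {
      abort(sprintf("Panel covariate '%s' not present in metadata.", nm))
    }
    v <- metadata[[nm]]
    vals <- stats::na.omit(if (is.numeric(v)) v else as.character(v))
    if (length(unique(vals)) < 2) {
      warn(sprintf("Covariate '%s' is constant; skipped.", nm))
      next
    }
    kind <- covariate_kind(nm)
    if (kind == "categorical" &&
        length(unique(stats::na.omit(as.character(v)))) > 2) {
      warn(sprintf("Covariate '%s' has >2 levels; skipped.", nm))
      next
    }
    mode <- if (kind == "continuous") "quartile" else "binary"
    de <- tryCatch(
      fit_nb_wald(counts, metadata,
                  contrast_spec(nm, mode = mode, alpha = alpha),
                  sf = sf, dispersions = disp, cooks_cutoff = cooks_cutoff),
      error = function(e) {
        warn(sprintf("Covariate '%s' skipped: %s", nm, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(de)) next
    n_sig <- sum(de$p_adj < alpha, na.rm = TRUE)
    rows[[nm]] <- tibble(
      covariate = nm, kind = kind, mode = mode,
      n_significant = n_sig,
      flagged = n_sig > flag_threshold,
      n_tested_genes = sum(de$tested_flag)
    )
  }
  out <- if (length(rows)) arrange(bind_rows(rows), desc(.data$n_significant))
         else tibble(covariate = character(), kind = character(),
                     mode = character(), n_significant = integer(),
                     flagged = logical(), n_tested_genes = integer())
  structure(out, class = c("txage_confounders", class(out)),
            alpha = alpha, flag_threshold = flag_threshold,
            panel = panel)
}
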