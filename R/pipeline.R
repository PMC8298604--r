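#' Run the full analysis pipeline from one configuration
#'
#' Stage order: coding/expression filter, confounder screen, HC-vs-MDD
#' differential expression (adjusting for the flagged confounders plus
#' batch), randomisation null, co-expression clustering, biological age.
#' Covariates flagged by the screen feed forward automatically into the
#' case/control adjustment set unless `params$adjust` overrides them.
#'
#' The configuration is a named list (or a YAML file with the same shape):
#'
#' * `input`: either paths `counts`, `metadata`, `annotation` (+ optional
#'   `covariate_spec`), or `simulate`: arguments for [sim_config()].
#' * `stages`: logical toggles `confounds`, `de`, `random_null`,
#'   `coexpression`, `biological_age` (all on by default).
#' * `params`: `alpha`, `panel`, `n_case`, `n_iter`, `thresholds`,
#'   `cut_height`, `min_cluster_size`, `p_grid`, `lfc_grid`, `z_cap`,
#'   `adjust`.
#' * `seed`: master seed (required when any stochastic stage is enabled).
#' * `out_dir`: output directory; omit to keep results in memory only.
#'
#' @param config Named list or path to a YAML file.
#' @return A list of stage results plus a `manifest` (parameters, seeds and
#'   canonical result digests), invisibly also written to
#'   `out_dir/manifest.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- utils::modifyList(
    list(confounds = TRUE, de = TRUE, random_null = TRUE,
         coexpression = TRUE, biological_age = TRUE),
    config$stages %||% list()
  )
  params <- utils::modifyList(
    list(alpha = 0.01, panel = NULL, n_case = 44, n_iter = 50,
         thresholds = c(0.01, 0.05, 0.1, 0.25), cut_height = 0.95,
         min_cluster_size = 50, p_grid = c(0.01, 0.05, 0.1),
         lfc_grid = c(0, 0.3, 0.6, 1.0), z_cap = 3, adjust = NULL,
         coexpr_min_mean = 10, coexpr_max_cv = 0.15, tom_beta = 6),
    config$params %||% list()
  )
  seed <- config$seed
  if (is.null(seed) && (stages$random_null || !is.null(config$input$simulate))) {
    abort("A `seed` is required when a stochastic stage is enabled.")
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.table(as.data.frame(df), file.path(out_dir, name),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  log_stage <- function(name, ...) {
    message(sprintf("[txage] %s: %s", name, sprintf(...)))
  }

  ## --- input ---
  input <- config$input %||% list()
  if (!is.null(input$simulate)) {
    sim_args <- input$simulate
    if (!is.null(seed) && is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    counts <- sim$counts
    metadata <- sim$metadata
    annotation <- sim$annotation
  } else {
    counts <- read_counts(input$counts,
                          format = input$format %||% "tsv")
    metadata <- read_metadata(input$metadata,
                              covariate_spec = unlist(input$covariate_spec %||%
                                                        character()))
    annotation <- read_annotation(input$annotation)
  }

  results <- list()
  digests <- list()
  # canonicalise before hashing: floating-point sums depend on sample order,
  # so numeric content is rounded to 7 significant digits and bare of
  # attributes other than names
  canon <- function(x) {
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, canon))
    if (is.data.frame(x)) {
      cols <- lapply(x, function(col) if (is.numeric(col)) signif(col, 7) else col)
      return(data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE))
    }
    if (is.matrix(x) && is.numeric(x)) return(signif(x, 7))
    if (is.numeric(x)) return(signif(x, 7))
    x
  }
  digest <- function(x) rlang::hash(canon(x))

  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  ## --- filter + shared normalisation ---
  filtered <- run_stage("filter", filter_genes_for_de(counts, annotation))
  sf <- size_factors(filtered)
  disp <- estimate_dispersions(filtered, sf)
  log_stage("filter", "%d of %d genes retained", nrow(filtered), nrow(counts))
  digests$filter <- digest(filtered[order(rownames(filtered)),
                                    order(colnames(filtered))])

  ## --- confounder screen ---
  adjust_set <- params$adjust
  if (stages$confounds) {
    panel <- params$panel %||%
      setdiff(colnames(metadata), c("sample_id", "group"))
    conf <- run_stage("confounds",
                      screen_covariates(filtered, metadata, panel,
                                        alpha = params$alpha))
    results$confounders <- conf
    emit(conf, "confounders.tsv")
    digests$confounds <- digest(arrange(as_tibble(conf), .data$covariate))
    log_stage("confounds", "%d of %d covariates flagged",
              sum(conf$flagged), nrow(conf))
    if (is.null(adjust_set)) {
      adjust_set <- conf$covariate[conf$flagged]
      if ("batch" %in% colnames(metadata)) {
        adjust_set <- union(adjust_set, "batch")
      }
    }
  }

  ## --- HC vs MDD DE ---
  if (stages$de) {
    md <- align_metadata(metadata, colnames(filtered))
    md$case_control <- factor(
      ifelse(as.character(md$group) == "HC", "HC", "MDD"),
      levels = c("HC", "MDD")
    )
    de <- run_stage("de", fit_nb_wald(
      filtered, md,
      contrast_spec("case_control", mode = "binary",
                    adjust = adjust_set %||% character(),
                    alpha = params$alpha, levels = c("HC", "MDD")),
      sf = sf, dispersions = disp
    ))
    results$de <- de
    emit(de, "de_hc_vs_mdd.tsv")
    digests$de <- digest(arrange(as_tibble(de), .data$gene_id))
    log_stage("de", "%d significant genes at adjusted p < %g (adjusting for %s)",
              sum(de$p_adj < params$alpha, na.rm = TRUE), params$alpha,
              paste(adjust_set %||% "nothing", collapse = ","))
  }

  ## --- randomisation null ---
  if (stages$random_null) {
    rn <- run_stage("random_null", fp_expectation(
      filtered, metadata, n_case = params$n_case, n_iter = params$n_iter,
      thresholds = params$thresholds, seed = seed
    ))
    results$random_null <- rn
    emit(rn$summary, "random_null_summary.tsv")
    emit(rn$gene_mean_p, "random_null_gene_mean_p.tsv")
    digests$random_null <- digest(list(
      rn$summary, arrange(rn$gene_mean_p, .data$gene_id)
    ))
    log_stage("random_null", "median %g significant at adjusted p < 0.01",
              rn$summary$median_significant[rn$summary$threshold == 0.01])
  }

  ## --- co-expression ---
  if (stages$coexpression) {
    results$coexpression <- run_stage("coexpression", {
      expr <- normalized_counts(filtered, sf)
      if ("batch" %in% colnames(metadata)) {
        md <- align_metadata(metadata, colnames(expr))
        expr <- batch_regress(expr, md$batch)
      }
      expr <- filter_coexpression_genes(expr, params$coexpr_min_mean,
                                        params$coexpr_max_cv)
      tom <- tom_matrix(expr, beta = params$tom_beta)
      clusters <- cut_clusters(tom, params$cut_height, params$min_cluster_size)
      if (length(clusters$clusters) == 0) {
        list(clusters = clusters, metagenes = NULL, tests = NULL)
      } else {
        mg <- metagenes(expr, clusters)
        tests <- cluster_group_test(mg, metadata)
        emit(clusters$assignments, "clusters.tsv")
        emit(tests, "cluster_tests.tsv")
        list(clusters = clusters, metagenes = mg, tests = tests)
      }
    })
    cx <- results$coexpression
    digests$coexpression <- digest(list(
      arrange(cx$clusters$assignments, .data$gene_id),
      if (!is.null(cx$tests)) arrange(cx$tests, .data$cluster_id)
    ))
    log_stage("coexpression", "%d cluster(s) of >= %d genes",
              length(cx$clusters$clusters), params$min_cluster_size)
  }

  ## --- biological age ---
  if (stages$biological_age) {
    if (any(is.na(metadata$age))) {
      abort("Pipeline stage 'biological_age' failed: samples missing age.")
    }
    ba <- run_stage("biological_age", bioage_analysis(
      filtered, metadata, p_grid = params$p_grid,
      lfc_grid = params$lfc_grid, z_cap = params$z_cap
    ))
    results$biological_age <- ba
    emit(ba$samples, "bioage_scores.tsv")
    emit(attr(ba, "signature"), "bioage_signature.tsv")
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(table = ba$table, fisher_p = ba$fisher_p, slope = ba$slope,
             intercept = ba$intercept, spearman = ba$spearman),
        file.path(out_dir, "bioage_contingency.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    digests$biological_age <- digest(list(
      arrange(ba$samples, .data$sample_id), ba$table, ba$fisher_p
    ))
    log_stage("biological_age",
              "Spearman rho = %.3f, asymmetry Fisher p = %.4g",
              ba$spearman, ba$fisher_p)
  }

  manifest <- list(
    package = "txage",
    version = as.character(utils::packageVersion("txage")),
    seed = seed,
    stages = stages[vapply(stages, isTRUE, logical(1))],
    parameters = params[!vapply(params, is.null, logical(1))],
    adjust_set = adjust_set,
    n_genes = nrow(counts), n_genes_filtered = nrow(filtered),
    n_samples = ncol(counts),
    digests = digests
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  results$manifest <- manifest
  invisible(results)
}
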