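#' Configure a synthetic PBMC-style count simulation
#'
#' Defines the cohort and the planted structure for [simulate_dataset()]. The
#' defaults reproduce the study conditions the downstream analyses assume: a
#' 231-sample cohort (44 healthy controls, 94 treatment-resistant, 47
#' treatment-responsive, 46 untreated), negative-binomial counts with
#' sample-specific size factors, age/sex/BMI/batch covariate effects, planted
#' co-expression blocks, and an optional accelerated-ageing offset applied
#' only to the case (non-HC) samples.
#'
#' Gene effects are expressed on the log2 scale. The age effect is
#' parameterised per decade of (effective) age so that planted fold changes
#' are on the same scale as a lowest-vs-highest age-quartile contrast. The
#' ageing offset shifts the *effective* age feeding the age-gene term of case
#' samples while the recorded metadata keeps chronological age — exactly the
#' alternative hypothesis probed by the residual-asymmetry test.
#'
#' @param n_genes Total genes simulated.
#' @param group_sizes Named integer vector of samples per group.
#' @param age_range Chronological age range (years), sampled uniformly.
#' @param n_age_genes Genes carrying an age effect (half up-, half
#'   down-regulated with age).
#' @param age_log2fc_per_decade Log2 fold change per 10 years of effective age.
#' @param n_cluster_blocks,cluster_block_size,cluster_loading Planted
#'   co-expression blocks: each block shares a standard-normal per-sample
#'   latent factor entering the log2 mean with weight `cluster_loading`.
#' @param ageing_offset_years Years added to the effective age of all non-HC
#'   samples (0 = null).
#' @param covariate_effects Data frame with columns `covariate`
#'   (`"sex"`, `"BMI"`, `"batch"`), `n_genes`, `log2fc`. Sex and batch effects
#'   are level offsets; the BMI effect is per population-SD of BMI.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   per-gene NB dispersion.
#' @param baseline_log2_range Range of per-gene baseline log2 mean counts.
#' @param size_factor_range Range of per-sample size factors (uniform).
#' @param noncoding_fraction Fraction of genes annotated non-coding; drawn
#'   only from genes with no planted effect so planted truths survive the
#'   coding filter.
#' @param n_extra_null_covariates Number of additional null covariates (half
#'   binary, half continuous) added to the metadata, for confounder-screen
#'   calibration experiments.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       group_sizes = c(HC = 44, MDD_resistant = 94,
                                       MDD_responsive = 47, MDD_untreated = 46),
                       age_range = c(25, 50),
                       n_age_genes = 500,
                       age_log2fc_per_decade = 0.5,
                       n_cluster_blocks = 2,
                       cluster_block_size = 60,
                       cluster_loading = 1,
                       ageing_offset_years = 0,
                       covariate_effects = data.frame(
                         covariate = c("sex", "BMI", "batch"),
                         n_genes = c(100, 100, 100),
                         log2fc = c(1, 0.5, 0.5)
                       ),
                       dispersion_meanlog = log(0.05),
                       dispersion_sdlog = 0.5,
                       baseline_log2_range = c(3, 9),
                       size_factor_range = c(0.7, 1.4),
                       noncoding_fraction = 0.1,
                       n_extra_null_covariates = 0,
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), group_sizes = group_sizes,
    age_range = age_range, n_age_genes = as.integer(n_age_genes),
    age_log2fc_per_decade = age_log2fc_per_decade,
    n_cluster_blocks = as.integer(n_cluster_blocks),
    cluster_block_size = as.integer(cluster_block_size),
    cluster_loading = cluster_loading,
    ageing_offset_years = ageing_offset_years,
    covariate_effects = as_tibble(covariate_effects),
    dispersion_meanlog = dispersion_meanlog,
    dispersion_sdlog = dispersion_sdlog,
    baseline_log2_range = baseline_log2_range,
    size_factor_range = size_factor_range,
    noncoding_fraction = noncoding_fraction,
    n_extra_null_covariates = as.integer(n_extra_null_covariates),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if_not_scalar_count(cfg$n_genes, "n_genes")
  if (any(cfg$group_sizes <= 0)) abort("All group sizes must be positive.")
  if (is.null(names(cfg$group_sizes))) abort("`group_sizes` must be named.")
  unknown <- setdiff(names(cfg$group_sizes), GROUP_LEVELS)
  if (length(unknown)) abort(sprintf("Unknown group(s): %s", paste(unknown, collapse = ", ")))
  for (rng in list(cfg$age_range, cfg$baseline_log2_range, cfg$size_factor_range)) {
    if (length(rng) != 2 || rng[1] > rng[2]) abort("Ranges must be ordered [min, max].")
  }
  planted <- cfg$n_age_genes + sum(cfg$covariate_effects$n_genes) +
    cfg$n_cluster_blocks * cfg$cluster_block_size
  if (planted > cfg$n_genes) {
    abort(sprintf(
      "Infeasible gene budget: %d planted-effect genes exceed n_genes = %d.",
      planted, cfg$n_genes
    ))
  }
  if (cfg$noncoding_fraction < 0 || cfg$noncoding_fraction >= 1) {
    abort("`noncoding_fraction` must be in [0, 1).")
  }
  n_noncoding <- round(cfg$noncoding_fraction * cfg$n_genes)
  if (planted + n_noncoding > cfg$n_genes) {
    abort("Gene budget infeasible: planted genes plus non-coding genes exceed n_genes.")
  }
  invisible(cfg)
}

#' Simulate a seeded synthetic count dataset with known ground truth
#'
#' Draws counts gene-by-gene from a negative binomial whose log2 mean is
#' `baseline + sex effect + BMI effect + batch effect +
#' age_log2fc_per_decade * (effective_age - mid-age)/10 + loading * block factor`,
#' scaled by the sample size factor. The metadata records chronological (not
#' effective) age; the truth ledger records everything planted.
#'
#' @param config A [sim_config()].
#' @return A list of class `txage_sim` with elements `counts` (integer
#'   matrix), `metadata` (tibble), `annotation` (tibble) and `truth` (list of
#'   `genes` and `samples` tibbles).
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n_genes <- cfg$n_genes
  n_samples <- sum(cfg$group_sizes)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  group <- factor(rep(names(cfg$group_sizes), cfg$group_sizes),
                  levels = GROUP_LEVELS)

  ## --- samples ---
  age <- runif(n_samples, cfg$age_range[1], cfg$age_range[2])
  sex <- factor(sample(c("F", "M"), n_samples, replace = TRUE), levels = c("F", "M"))
  bmi <- pmax(16, rnorm(n_samples, 25, 4))
  batch <- factor(sample(c("b1", "b2"), n_samples, replace = TRUE),
                  levels = c("b1", "b2"))
  size_factor <- runif(n_samples, cfg$size_factor_range[1], cfg$size_factor_range[2])
  effective_age <- age + ifelse(group == "HC", 0, cfg$ageing_offset_years)

  metadata <- tibble(
    sample_id = sample_ids, group = group, age = age,
    sex = sex, BMI = bmi, batch = batch
  )
  spec <- c(sex = "binary", BMI = "continuous", batch = "binary")
  if (cfg$n_extra_null_covariates > 0) {
    for (i in seq_len(cfg$n_extra_null_covariates)) {
      nm <- sprintf("cov%02d", i)
      if (i %% 2 == 1) {
        metadata[[nm]] <- rnorm(n_samples)
        spec[[nm]] <- "continuous"
      } else {
        metadata[[nm]] <- factor(sample(c("no", "yes"), n_samples, replace = TRUE))
        spec[[nm]] <- "binary"
      }
    }
  }
  attr(metadata, "covariate_spec") <- spec

  ## --- gene roles: age genes, covariate genes, cluster blocks, the rest ---
  idx <- seq_len(n_genes)
  take <- function(n) {
    out <- idx[seq_len(n)]
    idx <<- idx[-seq_len(n)]
    out
  }
  age_idx <- if (cfg$n_age_genes > 0) take(cfg$n_age_genes) else integer()
  cov_idx <- lapply(seq_len(nrow(cfg$covariate_effects)), function(i) {
    n <- cfg$covariate_effects$n_genes[i]
    if (n > 0) take(n) else integer()
  })
  names(cov_idx) <- cfg$covariate_effects$covariate
  block_idx <- lapply(seq_len(cfg$n_cluster_blocks), function(b) {
    take(cfg$cluster_block_size)
  })

  age_sign <- integer(n_genes)
  if (length(age_idx)) {
    age_sign[age_idx] <- rep_len(c(1L, -1L), length(age_idx))
  }
  covariate_of <- rep(NA_character_, n_genes)
  covariate_lfc <- rep(NA_real_, n_genes)
  for (i in seq_along(cov_idx)) {
    covariate_of[cov_idx[[i]]] <- names(cov_idx)[i]
    covariate_lfc[cov_idx[[i]]] <- cfg$covariate_effects$log2fc[i]
  }
  cluster_of <- rep(NA_integer_, n_genes)
  for (b in seq_along(block_idx)) cluster_of[block_idx[[b]]] <- b

  ## non-coding labels go to effect-free genes only
  n_noncoding <- round(cfg$noncoding_fraction * n_genes)
  free <- which(age_sign == 0 & is.na(covariate_of) & is.na(cluster_of))
  noncoding <- sample(free, n_noncoding)
  biotype <- rep("protein_coding", n_genes)
  biotype[noncoding] <- "lincRNA"

  baseline <- runif(n_genes, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
  dispersion <- rlnorm(n_genes, cfg$dispersion_meanlog, cfg$dispersion_sdlog)

  ## --- log2 mean model ---
  mid_age <- mean(cfg$age_range)
  log2mu <- matrix(baseline, n_genes, n_samples)
  if (length(age_idx)) {
    log2mu[age_idx, ] <- log2mu[age_idx, ] +
      outer(age_sign[age_idx] * cfg$age_log2fc_per_decade,
            (effective_age - mid_age) / 10)
  }
  sex_num <- as.numeric(sex == "M")
  bmi_z <- (bmi - 25) / 4    # population-SD units
  batch_num <- as.numeric(batch == "b2")
  cov_design <- list(sex = sex_num, BMI = bmi_z, batch = batch_num)
  for (nm in names(cov_idx)) {
    gi <- cov_idx[[nm]]
    if (length(gi)) {
      log2mu[gi, ] <- log2mu[gi, ] +
        outer(covariate_lfc[gi], cov_design[[nm]])
    }
  }
  for (b in seq_along(block_idx)) {
    f <- rnorm(n_samples)
    gi <- block_idx[[b]]
    log2mu[gi, ] <- log2mu[gi, ] +
      matrix(cfg$cluster_loading * f, length(gi), n_samples, byrow = TRUE)
  }

  mu <- sweep(2^log2mu, 2, size_factor, `*`)
  counts <- matrix(
    rnbinom(n_genes * n_samples, mu = mu, size = rep(1 / dispersion, n_samples)),
    n_genes, n_samples, dimnames = list(gene_ids, sample_ids)
  )
  storage.mode(counts) <- "integer"

  truth <- list(
    genes = tibble(
      gene_id = gene_ids, baseline_log2 = baseline, dispersion = dispersion,
      is_age_gene = age_sign != 0L, age_sign = age_sign,
      covariate = covariate_of, covariate_log2fc = covariate_lfc,
      cluster = cluster_of, biotype = biotype
    ),
    samples = tibble(
      sample_id = sample_ids, group = group, size_factor = size_factor,
      age = age, effective_age = effective_age
    )
  )
  structure(
    list(
      counts = counts,
      metadata = metadata,
      annotation = tibble(gene_id = gene_ids, biotype = biotype),
      truth = truth,
      config = cfg
    ),
    class = "txage_sim"
  )
}

#' @export
print.txage_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d genes x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s=%d", names(x$config$group_sizes), x$config$group_sizes),
          collapse = ", ")
  ))
  cat(sprintf(
    "  planted: %d age genes, %d cluster blocks of %d, ageing offset %+.1f y\n",
    sum(x$truth$genes$is_age_gene), x$config$n_cluster_blocks,
    x$config$cluster_block_size, x$config$ageing_offset_years
  ))
  invisible(x)
}

#' Write the ground-truth ledger of a simulation
#'
#' One row per gene and per sample in a single long TSV (`record_type`
#' distinguishes the two), carrying every planted parameter needed to score
#' recovery downstream.
#'
#' @param truth The `truth` element of a [simulate_dataset()] result (or the
#'   result itself).
#' @param path Output TSV path.
#' @export
truth_report <- function(truth, path) {
  if (inherits(truth, "txage_sim")) truth <- truth$truth
  g <- mutate(truth$genes, record_type = "gene", id = .data$gene_id)
  s <- mutate(truth$samples, record_type = "sample", id = .data$sample_id)
  long <- bind_rows(g, s)
  long <- long[, c("record_type", "id",
                   setdiff(colnames(long), c("record_type", "id")))]
  utils::write.table(as.data.frame(long), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname truth_report
#' @return `read_truth_report()` returns the `genes`/`samples` tibble pair.
#' @export
read_truth_report <- function(path) {
  long <- as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
  genes <- filter(long, .data$record_type == "gene")
  samples <- filter(long, .data$record_type == "sample")
  drop_all_na <- function(df) df[, colSums(!is.na(df)) > 0 | colnames(df) %in%
                                   c("covariate", "cluster", "covariate_log2fc"),
                                 drop = FALSE]
  list(
    genes = drop_all_na(select(genes, -"record_type", -"id")),
    samples = drop_all_na(select(samples, -"record_type", -"id"))
  )
}
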