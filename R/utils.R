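#' @importFrom rlang %||% abort warn hash
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange desc mutate filter select bind_rows left_join group_by summarise ungroup
#' @importFrom purrr map map_dbl map_int imap
#' @importFrom stats median quantile sd var cor rnorm runif rnbinom rlnorm
#'   pnorm pt phyper dhyper setNames complete.cases hclust cutree as.dist
#'   t.test lm.fit
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Spawn `n` child seeds from one master seed (32-bit safe).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive integer.", name))
  }
}

#' Validate a genes-by-samples count matrix
#'
#' Checks the invariants every downstream stage assumes: a numeric matrix with
#' unique gene row names and unique sample column names, all entries finite
#' non-negative integers.
#'
#' @param counts A matrix with genes in rows and samples in columns.
#' @return The validated matrix (in storage mode `integer`), invisibly usable
#'   in a pipe.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) abort("`counts` must be a matrix (genes x samples).")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene row names and sample column names.")
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicate gene ids in `counts`.")
  if (anyDuplicated(colnames(counts))) abort("Duplicate sample ids in `counts`.")
  if (!is.numeric(counts)) abort("`counts` must be numeric.")
  if (any(!is.finite(counts))) abort("`counts` contains non-finite entries.")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Count for gene '%s', sample '%s' is %s; counts must be non-negative integers.",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])
    ))
  }
  storage.mode(counts) <- "integer"
  counts
}

# Align a metadata tibble to the columns of a count/expression matrix.
align_metadata <- function(metadata, sample_ids) {
  if (!all(sample_ids %in% metadata$sample_id)) {
    missing <- setdiff(sample_ids, metadata$sample_id)
    abort(sprintf(
      "Samples missing from metadata: %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
}

# Row-wise variance of a matrix (sample variance, n - 1).
row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}
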