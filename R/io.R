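#' Read a genes-by-samples count matrix
#'
#' Counts travel as either a TSV (first column gene ids, header row of sample
#' ids) or a MatrixMarket triplet file with sidecar gene/sample name files
#' (one id per line). Orientation is fixed: genes in rows, samples in columns.
#'
#' @param path Path to the counts file.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_path,samples_path Sidecar name files for `format = "mtx"`.
#'   Default to `<path>.genes` and `<path>.samples`.
#' @return A validated integer matrix, genes x samples.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        genes_path = paste0(path, ".genes"),
                        samples_path = paste0(path, ".samples")) {
  format <- match.arg(format)
  if (format == "tsv") {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE)
    if (ncol(raw) < 2) abort("Counts TSV needs a gene-id column plus sample columns.")
    gene_ids <- raw[[1]]
    sample_ids <- colnames(raw)[-1]
    if (anyDuplicated(gene_ids)) abort("Duplicate gene ids in counts file.")
    if (anyDuplicated(sample_ids)) abort("Duplicate sample ids in counts file.")
    vals <- suppressWarnings(
      vapply(raw[-1], as.numeric, numeric(nrow(raw)))
    )
    vals <- matrix(vals, nrow = nrow(raw),
                   dimnames = list(gene_ids, sample_ids))
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf("Non-numeric count at gene '%s', sample '%s'.",
                    gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
    }
    validate_count_matrix(vals)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_path)
    sample_ids <- readLines(samples_path)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(sample_ids)) {
      abort("MTX dimensions do not match sidecar gene/sample name files.")
    }
    dimnames(m) <- list(gene_ids, sample_ids)
    validate_count_matrix(m)
  }
}

#' Write a count matrix
#'
#' @inheritParams read_counts
#' @param counts Validated genes x samples matrix.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx"),
                         genes_path = paste0(path, ".genes"),
                         samples_path = paste0(path, ".samples")) {
  counts <- validate_count_matrix(counts)
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), genes_path)
    writeLines(colnames(counts), samples_path)
  }
  invisible(path)
}

GROUP_LEVELS <- c("HC", "MDD_resistant", "MDD_responsive", "MDD_untreated")

#' Read and type a sample metadata table
#'
#' The TSV must carry a `sample_id` column; a `group` column, when present, is
#' restricted to the cohort labels `HC`, `MDD_resistant`, `MDD_responsive`,
#' `MDD_untreated`; `age` is in years. Every other covariate named in
#' `covariate_spec` is coerced to its declared kind. Missing values are the
#' literal string `NA`; samples with a missing covariate are dropped only from
#' contrasts using that covariate, never globally.
#'
#' @param path Path to a tab-separated metadata table.
#' @param covariate_spec Named character vector mapping covariate name to
#'   `"binary"`, `"continuous"` or `"categorical"`.
#' @return A tibble with one row per sample and a `covariate_spec` attribute.
#' @export
read_metadata <- function(path, covariate_spec = character()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = "NA")
  if (!"sample_id" %in% colnames(df)) abort("Metadata needs a `sample_id` column.")
  if (anyDuplicated(df$sample_id)) abort("Duplicate sample ids in metadata.")
  out <- as_tibble(df)
  if ("group" %in% colnames(out)) {
    unknown <- setdiff(stats::na.omit(unique(out$group)), GROUP_LEVELS)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown group label(s): %s", paste(unknown, collapse = ", ")))
    }
    out$group <- factor(out$group, levels = GROUP_LEVELS)
  }
  if ("age" %in% colnames(out)) {
    out$age <- as.numeric(out$age)
    if (any(!is.na(out$age) & out$age <= 0)) abort("Ages must be positive.")
  }
  for (nm in names(covariate_spec)) {
    if (!nm %in% colnames(out)) abort(sprintf("Covariate '%s' not in metadata.", nm))
    kind <- covariate_spec[[nm]]
    out[[nm]] <- switch(
      kind,
      continuous = as.numeric(out[[nm]]),
      binary = ,
      categorical = factor(out[[nm]]),
      abort(sprintf("Unknown covariate kind '%s' for '%s'.", kind, nm))
    )
    if (kind == "binary") {
      n_lev <- length(unique(stats::na.omit(as.character(out[[nm]]))))
      if (n_lev != 2) {
        abort(sprintf(
          "Covariate '%s' declared binary but %d level(s) observed.", nm, n_lev
        ))
      }
    }
  }
  attr(out, "covariate_spec") <- covariate_spec
  out
}

#' Write a sample metadata table
#' @param metadata Tibble as returned by [read_metadata()] or
#'   [simulate_dataset()].
#' @param path Output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id` and `biotype`.
#' @return Tibble with one row per gene.
#' @export
read_annotation <- function(path) {
  df <- as_tibble(utils::read.delim(path, sep = "\t",
                                    colClasses = "character",
                                    check.names = FALSE))
  if (!all(c("gene_id", "biotype") %in% colnames(df))) {
    abort("Annotation needs `gene_id` and `biotype` columns.")
  }
  if (anyDuplicated(df$gene_id)) abort("Duplicate gene ids in annotation.")
  df
}

#' @rdname read_annotation
#' @param annotation Tibble with `gene_id` and `biotype`.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are dropped with a warning; set
#' order is preserved.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has fewer than 3 fields.", i))
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warn(sprintf("GMT set '%s': duplicate members removed.", fields[1]))
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
    descs[[fields[1]]] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||%
    setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
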