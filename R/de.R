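#' Filter a count matrix for differential expression
#'
#' Keeps protein-coding genes with a mean of strictly more than one raw read
#' per sample, preserving gene order.
#'
#' @param counts Genes x samples integer matrix.
#' @param annotation Tibble with `gene_id`, `biotype` covering all genes.
#' @param min_mean Mean raw count that must be exceeded (default 1).
#' @return The filtered count matrix.
#' @export
filter_genes_for_de <- function(counts, annotation, min_mean = 1) {
  counts <- validate_count_matrix(counts)
  if (!all(rownames(counts) %in% annotation$gene_id)) {
    abort("Annotation does not cover all genes in `counts`.")
  }
  biotype <- annotation$biotype[match(rownames(counts), annotation$gene_id)]
  keep <- biotype == "protein_coding" & rowMeans(counts) > min_mean
  if (!any(keep)) abort("No genes pass the coding/expression filter.")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: the median, over reference genes, of the
#' ratio of the sample's count to the gene's geometric mean across samples.
#' Reference genes are those with strictly positive counts in every sample.
#'
#' @param counts Genes x samples matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    abort(paste(
      "No gene has strictly positive counts in every sample;",
      "median-of-ratios normalisation is undefined",
      "(pseudo-reference fallback is disabled)."
    ))
  }
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc - loggeo, 2, median)
  setNames(exp(sf), colnames(counts))
}

#' Normalise counts by size factors
#'
#' @param counts Genes x samples matrix.
#' @param sf Size factors (computed with [size_factors()] when `NULL`).
#' @param log2 If `TRUE`, return `log2(normalised + 1)`.
#' @return Numeric matrix, same shape as `counts`.
#' @export
normalized_counts <- function(counts, sf = NULL, log2 = FALSE) {
  sf <- sf %||% size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  if (log2) base::log2(norm + 1) else norm
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per gene, `alpha_hat = max(floor, (s2 - m) / m^2)` on size-factor
#' normalised counts, then shrunk toward a fitted mean-dispersion trend
#' `a0 + a1 / m` with weight `shrink_weight`. The trend is fitted to binned
#' medians of the raw estimates (about 20 bins on the log-mean axis), so
#' genes with strong real effects — whose effect variance inflates their
#' marginal moment estimate — cannot drag the trend upwards for everyone
#' else.
#'
#' @param counts Genes x samples matrix (at least 2 samples).
#' @param sf Size factors.
#' @param shrink_weight Weight on the trend in `[0, 1]`.
#' @param floor Lower bound on every estimate.
#' @return Named numeric vector of dispersions (>= `floor`).
#' @export
estimate_dispersions <- function(counts, sf = NULL, shrink_weight = 0.5,
                                 floor = 1e-8) {
  if (ncol(counts) < 2) abort("Dispersion estimation needs at least 2 samples.")
  norm <- normalized_counts(counts, sf)
  m <- rowMeans(norm)
  s2 <- row_vars(norm)
  raw <- ifelse(m > 0, pmax(floor, (s2 - m) / m^2), floor)
  use <- m > 0
  trend <- rep(max(floor, median(raw[use])), length(raw))
  if (sum(use) >= 50) {
    bins <- cut(rank(m[use], ties.method = "first"),
                breaks = 20, labels = FALSE)
    bm <- as.numeric(tapply(m[use], bins, median))
    ba <- as.numeric(tapply(raw[use], bins, median))
    bw <- as.numeric(tapply(raw[use], bins, length))
    fit <- lm.fit(cbind(1, 1 / bm) * sqrt(bw), ba * sqrt(bw))
    a <- fit$coefficients
    cand <- a[1] + a[2] / pmax(m, 1e-8)
    if (all(is.finite(a))) trend <- pmax(floor, cand)
  }
  alpha <- (1 - shrink_weight) * raw + shrink_weight * trend
  setNames(pmax(floor, alpha), rownames(counts))
}

#' Specify a differential-expression contrast
#'
#' @param covariate Metadata column to contrast.
#' @param mode `"binary"` (two observed levels) or `"quartile"` (lowest vs
#'   highest quartile of a continuous covariate).
#' @param adjust Character vector of adjustment covariates (may be empty).
#' @param alpha Adjusted-p significance threshold.
#' @param levels Optional length-2 level ordering for binary mode; the
#'   *second* level is the "treatment": positive log2 fold change means
#'   higher expression in that level. Defaults to lexicographic order.
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(covariate, mode = c("binary", "quartile"),
                          adjust = character(), alpha = 0.01, levels = NULL) {
  mode <- match.arg(mode)
  if (covariate %in% adjust) {
    abort("The contrast covariate cannot also be an adjustment covariate.")
  }
  structure(list(covariate = covariate, mode = mode, adjust = adjust,
                 alpha = alpha, levels = levels),
            class = "contrast_spec")
}

#' Lowest- and highest-quartile sample groups of a continuous covariate
#'
#' Q1 and Q3 use the linear-interpolation quantile convention. `low` holds
#' samples with value `<= Q1`, `high` those with value `>= Q3`; samples with
#' a missing value are excluded.
#'
#' @param metadata Sample metadata tibble.
#' @param covariate Name of a continuous (numeric) column.
#' @return List with `low` and `high` sample-id vectors plus `q1`, `q3`.
#' @export
quartile_groups <- function(metadata, covariate) {
  x <- metadata[[covariate]]
  if (!is.numeric(x)) abort(sprintf("Covariate '%s' is not continuous.", covariate))
  ok <- !is.na(x)
  if (sum(ok) < 8) abort("Quartile grouping needs at least 8 non-missing values.")
  q <- quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    abort(sprintf("Degenerate spread in '%s': Q1 equals Q3.", covariate))
  }
  list(low = metadata$sample_id[ok & x <= q[1]],
       high = metadata$sample_id[ok & x >= q[2]],
       q1 = q[1], q3 = q[2])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, multiplies by `m / rank`, enforces monotonicity
#' by a cumulative minimum from the largest, caps at 1 and restores input
#' order. `NA` entries pass through as `NA` and do not count toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok])
  q <- p[ok][o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out[ok][o] <- pmin(q, 1)
  out
}

## ---------------------------------------------------------------------------
## NB IRLS internals
## ---------------------------------------------------------------------------

MU_MIN <- 1e-10
MU_MAX <- 1e12

# IRLS for one gene under a general design. Log link, known dispersion,
# offset = log size factor. Returns coefficients, SEs, convergence, weights.
nb_irls_gene <- function(y, X, off, alpha, maxit = 50L, tol = 1e-8) {
  p <- ncol(X)
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- qr.solve(qr(X), eta - off)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + off
    mu <- pmin(pmax(exp(eta), MU_MIN), MU_MAX)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    sw <- sqrt(w)
    qrX <- qr(X * sw)
    beta_new <- qr.solve(qrX, z * sw)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta) + off
  mu <- pmin(pmax(exp(eta), MU_MIN), MU_MAX)
  w <- mu / (1 + alpha * mu)
  sw <- sqrt(w)
  qrX <- qr(X * sw)
  R <- qr.R(qrX)
  cov <- tryCatch(chol2inv(R), error = function(e) matrix(NA_real_, p, p))
  # leverages of the weighted fit
  Q <- qr.Q(qrX)
  h <- rowSums(Q[, seq_len(p), drop = FALSE]^2)
  list(beta = beta, se = sqrt(diag(cov)), converged = converged,
       mu = mu, w = w, h = h)
}

# Vectorised IRLS across all genes for the two-column design [1, d] with d
# binary. Y: genes x samples; alpha: per-gene dispersion; off: per-sample
# log size factor.
nb_irls_binary <- function(Y, d, off, alpha, maxit = 50L, tol = 1e-8) {
  G <- nrow(Y)
  n <- ncol(Y)
  OFF <- matrix(off, G, n, byrow = TRUE)
  sf <- exp(off)
  b0 <- log(pmax(rowMeans(sweep(Y, 2, sf, `/`)), 1e-8))
  b1 <- numeric(G)
  active <- rep(TRUE, G)
  converged <- rep(FALSE, G)
  for (it in seq_len(maxit)) {
    ETA <- b0 + outer(b1, d) + OFF
    MU <- pmin(pmax(exp(ETA), MU_MIN), MU_MAX)
    W <- MU / (1 + alpha * MU)
    Z <- (ETA - OFF) + (Y - MU) / MU
    sw <- rowSums(W)
    swd <- drop(W %*% d)
    swz <- rowSums(W * Z)
    swdz <- drop((W * Z) %*% d)
    det <- swd * (sw - swd)
    det[det <= 0] <- NA_real_
    nb0 <- (swd * swz - swd * swdz) / det
    nb1 <- (sw * swdz - swd * swz) / det
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    bad <- !is.finite(nb0) | !is.finite(nb1)
    nb0[bad] <- b0[bad]
    nb1[bad] <- b1[bad]
    upd <- active & !bad
    b0[upd] <- nb0[upd]
    b1[upd] <- nb1[upd]
    newly <- active & !bad &
      delta < tol * (1 + pmax(abs(b0), abs(b1)))
    converged[newly] <- TRUE
    active <- active & !newly & !bad
    if (!any(active)) break
  }
  ETA <- b0 + outer(b1, d) + OFF
  MU <- pmin(pmax(exp(ETA), MU_MIN), MU_MAX)
  W <- MU / (1 + alpha * MU)
  sw <- rowSums(W)
  swd <- drop(W %*% d)
  det <- swd * (sw - swd)
  se1 <- sqrt(ifelse(det > 0, sw / det, NA_real_))
  # leverages: h_i = w_i * x_i' (X'WX)^{-1} x_i with x_i = (1, d_i)
  A11 <- ifelse(det > 0, swd / det, NA_real_)       # (X'WX)^{-1}[1,1] = swd/det
  A12 <- ifelse(det > 0, -swd / det, NA_real_)
  A22 <- ifelse(det > 0, sw / det, NA_real_)
  quad0 <- A11
  quad1 <- A11 + 2 * A12 + A22
  QUAD <- matrix(quad0, G, n) + outer(quad1 - quad0, d)
  H <- W * QUAD
  list(b0 = b0, b1 = b1, se1 = se1, converged = converged, MU = MU, W = W, H = H)
}

# Cook's distance matrix from mu, leverages and dispersion (per gene).
cooks_from_fit <- function(Y, MU, H, alpha, p) {
  V <- MU * (1 + alpha * MU)
  R2 <- (Y - MU)^2 / V
  H <- pmin(pmax(H, 0), 1 - 1e-8)
  R2 * H / (p * (1 - H)^2)
}

#' Per-gene negative-binomial Wald test
#'
#' Fits, for each gene, a negative-binomial log-link regression with fixed
#' gene dispersion and a log size-factor offset by iteratively reweighted
#' least squares, and tests the contrast coefficient with a two-sided Wald
#' test against the standard normal. Positive log2 fold change means higher
#' expression in the second-listed contrast level (binary mode) or in the
#' upper quartile (quartile mode). Genes whose maximum Cook's distance
#' exceeds `cooks_cutoff` are flagged as outliers and excluded from testing;
#' Benjamini-Hochberg adjustment runs across the tested genes only.
#'
#' @param counts Genes x samples matrix (pre-filtered).
#' @param metadata Sample metadata tibble covering all samples in `counts`.
#' @param contrast A [contrast_spec()].
#' @param sf Size factors (computed when `NULL`).
#' @param dispersions Per-gene dispersions (estimated when `NULL`).
#' @param cooks_cutoff Cook's distance cutoff (`Inf` disables flagging).
#' @return A `txage_de` tibble with per-gene `base_mean`, `log2fc`, `se`,
#'   `wald_stat`, `p`, `p_adj`, `outlier_flag`, `tested_flag`.
#' @export
fit_nb_wald <- function(counts, metadata, contrast, sf = NULL,
                        dispersions = NULL, cooks_cutoff = 0.2) {
  stopifnot(inherits(contrast, "contrast_spec"))
  metadata <- align_metadata(metadata, colnames(counts))
  sf <- sf %||% size_factors(counts)
  dispersions <- dispersions %||% estimate_dispersions(counts, sf)
  sf <- sf[colnames(counts)]

  ## -- included samples and the contrast indicator --
  if (contrast$mode == "quartile") {
    qg <- quartile_groups(metadata, contrast$covariate)
    include <- metadata$sample_id %in% c(qg$low, qg$high)
    d_all <- as.numeric(metadata$sample_id %in% qg$high)
    level_names <- c("low_quartile", "high_quartile")
  } else {
    x <- metadata[[contrast$covariate]]
    if (is.null(x)) abort(sprintf("Covariate '%s' not in metadata.", contrast$covariate))
    x <- as.character(x)
    include <- !is.na(x)
    lev <- contrast$levels %||% sort(unique(x[include]))
    if (length(lev) != 2) {
      abort(sprintf("Covariate '%s' must have exactly 2 observed levels, got %d.",
                    contrast$covariate, length(unique(x[include]))))
    }
    include <- include & x %in% lev
    d_all <- as.numeric(x == lev[2])
    level_names <- lev
  }
  for (ad in contrast$adjust) {
    v <- metadata[[ad]]
    if (is.null(v)) abort(sprintf("Adjustment covariate '%s' not in metadata.", ad))
    include <- include & !is.na(v)
  }

  md <- metadata[include, , drop = FALSE]
  Y <- counts[, include, drop = FALSE]
  d <- d_all[include]
  off <- log(sf[include])
  if (length(unique(d)) < 2) abort("Contrast has samples on one side only.")

  ## -- design --
  if (length(contrast$adjust) == 0) {
    X <- cbind(`(Intercept)` = 1, contrast = d)
  } else {
    f <- stats::as.formula(paste("~", paste(contrast$adjust, collapse = " + ")))
    Xadj <- stats::model.matrix(f, data = md)
    X <- cbind(Xadj, contrast = d)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }

  G <- nrow(Y)
  base_mean <- rowMeans(sweep(Y, 2, exp(off), `/`))
  nonzero <- rowSums(Y) > 0
  log2fc <- se <- rep(NA_real_, G)
  converged <- rep(FALSE, G)
  cooks_max <- rep(NA_real_, G)
  p_design <- ncol(X)

  if (p_design == 2 && any(nonzero)) {
    fit <- nb_irls_binary(Y[nonzero, , drop = FALSE], d, off,
                          dispersions[rownames(Y)][nonzero])
    log2fc[nonzero] <- fit$b1 / log(2)
    se[nonzero] <- fit$se1 / log(2)
    converged[nonzero] <- fit$converged & is.finite(fit$se1)
    D <- cooks_from_fit(Y[nonzero, , drop = FALSE], fit$MU, fit$H,
                        dispersions[rownames(Y)][nonzero], p_design)
    cooks_max[nonzero] <- apply(D, 1, max)
  } else if (any(nonzero)) {
    alpha_g <- dispersions[rownames(Y)]
    ci <- which(colnames(X) == "contrast")
    for (g in which(nonzero)) {
      fg <- tryCatch(nb_irls_gene(Y[g, ], X, off, alpha_g[g]),
                     error = function(e) NULL)
      if (is.null(fg)) next
      log2fc[g] <- fg$beta[ci] / log(2)
      se[g] <- fg$se[ci] / log(2)
      converged[g] <- fg$converged && is.finite(fg$se[ci])
      Dg <- cooks_from_fit(matrix(Y[g, ], 1), matrix(fg$mu, 1),
                           matrix(fg$h, 1), alpha_g[g], p_design)
      cooks_max[g] <- max(Dg)
    }
  }

  outlier_flag <- !is.na(cooks_max) & cooks_max > cooks_cutoff
  tested_flag <- nonzero & converged & !outlier_flag & is.finite(se) & se > 0
  wald <- ifelse(tested_flag, (log2fc / se), NA_real_)
  p <- ifelse(tested_flag, 2 * pnorm(-abs(wald)), NA_real_)
  p_adj <- bh_adjust(p)
  log2fc[!nonzero] <- NA_real_
  se[!nonzero] <- NA_real_

  res <- tibble(
    gene_id = rownames(Y), base_mean = base_mean, log2fc = log2fc, se = se,
    wald_stat = wald, p = p, p_adj = p_adj,
    outlier_flag = outlier_flag, tested_flag = tested_flag
  )
  structure(res,
            class = c("txage_de", class(res)),
            contrast = contrast, levels = level_names,
            n_samples = c(sum(d == 0), sum(d == 1)),
            cooks_max = setNames(cooks_max, rownames(Y)),
            cooks_cutoff = cooks_cutoff,
            alpha = contrast$alpha)
}

#' Cook's-distance outlier flags of a fitted DE table
#'
#' Re-applies a cutoff to the per-gene maximum Cook's distances stored on a
#' [fit_nb_wald()] result. A cutoff of `Inf` flags nothing.
#'
#' @param fit A `txage_de` table.
#' @param cutoff Cook's distance cutoff (default 0.2).
#' @return Named logical vector, one entry per gene.
#' @export
cooks_outlier_flag <- function(fit, cutoff = 0.2) {
  cm <- attr(fit, "cooks_max")
  if (is.null(cm)) abort("`fit` carries no Cook's distances.")
  !is.na(cm) & cm > cutoff
}

#' One-call differential expression
#'
#' Convenience wrapper: optional coding/expression filter, median-of-ratios
#' size factors, dispersion estimation, then [fit_nb_wald()].
#'
#' @inheritParams fit_nb_wald
#' @param annotation Optional gene annotation; when given the counts are
#'   passed through [filter_genes_for_de()] first.
#' @return A `txage_de` tibble.
#' @export
run_de <- function(counts, metadata, contrast, annotation = NULL,
                   cooks_cutoff = 0.2) {
  if (!is.null(annotation)) counts <- filter_genes_for_de(counts, annotation)
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf)
  fit_nb_wald(counts, metadata, contrast, sf, disp, cooks_cutoff)
}
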