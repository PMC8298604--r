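make_counts <- function(m, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, samples)
  m
}

test_that("the coding/expression filter applies both rules, order preserved", {
  counts <- make_counts(rbind(c(5L, 5L), c(1L, 1L), c(1L, 2L), c(9L, 9L)))
  ann <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                        biotype = c("lincRNA", "protein_coding",
                                    "protein_coding", "protein_coding"))
  out <- filter_genes_for_de(counts, ann)
  # g1 non-coding, g2 mean exactly 1 (strict >), g3 mean 1.5 kept, g4 kept
  expect_identical(rownames(out), c("g3", "g4"))

  expect_error(
    filter_genes_for_de(counts, dplyr::mutate(ann, biotype = "lincRNA")),
    "No genes"
  )
})

test_that("median-of-ratios size factors match hand computation", {
  expect_equal(unname(size_factors(make_counts(rbind(c(5L, 5L), c(7L, 7L))))),
               c(1, 1))
  # geometric means (2.828, 4.243); per-sample ratio medians sqrt(1/2), sqrt(2)
  sf <- size_factors(make_counts(rbind(c(2L, 4L), c(3L, 6L))))
  expect_equal(unname(sf), c(sqrt(0.5), sqrt(2)), tolerance = 1e-12)

  # scale equivariance up to the overall normalisation: tripling one column
  # triples its size factor relative to every other sample (the scaled column
  # also enters the geometric means, so the common scale shifts by 3^(1/n))
  set.seed(1)
  m <- make_counts(matrix(rpois(200, 50), 20, 10))
  m3 <- m
  m3[, 4] <- m3[, 4] * 3L
  r <- unname(size_factors(m3) / size_factors(m))
  expect_equal(r[4] / r[1], 3, tolerance = 1e-12)
  expect_equal(r[-4], rep(r[1], 9), tolerance = 1e-12)

  # proportional identical columns give all-ones
  prop <- make_counts(matrix(rep(c(10L, 20L, 40L), 6), 3, 6))
  expect_equal(unname(size_factors(prop)), rep(1, 6), tolerance = 1e-12)

  zero <- make_counts(rbind(c(0L, 5L), c(3L, 0L)))
  expect_error(size_factors(zero), "strictly positive")
})

test_that("dispersion estimates recover the truth and floor degenerate genes", {
  # constant normalised counts: zero excess variance -> floor
  m <- make_counts(matrix(10L, 5, 20))
  disp <- estimate_dispersions(m, sf = setNames(rep(1, 20), colnames(m)))
  expect_true(all(disp <= 1e-6))

  set.seed(42)
  pois <- make_counts(matrix(rpois(50 * 1000, 100), 50, 1000))
  dp <- estimate_dispersions(pois)
  expect_true(all(dp < 0.05))

  nb <- make_counts(matrix(rnbinom(50 * 1000, mu = 100, size = 2), 50, 1000))
  dn <- estimate_dispersions(nb)
  expect_true(all(dn > 0.4 & dn < 0.6))

  expect_error(estimate_dispersions(make_counts(matrix(1L, 3, 1))), "2 samples")
})

test_that("quartile grouping uses the interpolated quantile convention", {
  md <- tibble::tibble(sample_id = sprintf("s%d", 1:8), val = 1:8)
  qg <- quartile_groups(md, "val")
  expect_equal(qg$q1, 2.75)
  expect_equal(qg$q3, 6.25)
  expect_identical(qg$low, c("s1", "s2"))
  expect_identical(qg$high, c("s7", "s8"))

  set.seed(3)
  md2 <- tibble::tibble(sample_id = sprintf("s%d", 1:100),
                        val = sample(seq(0, 1, length.out = 100)))
  qg2 <- quartile_groups(md2, "val")
  expect_length(qg2$low, 25)
  expect_length(qg2$high, 25)

  # ties straddling Q1 are all included on the low side
  md3 <- tibble::tibble(sample_id = sprintf("s%d", 1:12),
                        val = c(rep(1, 6), 2:7))
  qg3 <- quartile_groups(md3, "val")
  expect_true(all(md3$sample_id[md3$val == 1] %in% qg3$low))

  expect_error(quartile_groups(tibble::tibble(sample_id = sprintf("s%d", 1:10),
                                              val = rep(5, 10)), "val"),
               "Q1 equals Q3")
})

test_that("BH adjustment equals its step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # NA passthrough, m = number tested
  expect_equal(bh_adjust(c(0.01, NA, 0.5)), c(0.02, NA, 0.5))

  # brute force over a grid, all vectors of length <= 6
  grid <- c(0.01, 0.2, 0.5, 0.8, 1)
  for (len in 1:6) {
    vecs <- as.matrix(expand.grid(rep(list(grid), len)))
    for (r in seq_len(nrow(vecs))) {
      p <- unname(vecs[r, ])
      expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
    }
  }

  # permutation invariance + agreement with stats::p.adjust on random input
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
  }
})

test_that("Wald log2fc is positive when the second level is higher", {
  set.seed(21)
  y <- c(rpois(30, 50), rpois(30, 200))
  m <- make_counts(matrix(as.integer(y), 1))
  md <- tibble::tibble(sample_id = colnames(m),
                       grp = rep(c("a", "b"), each = 30))
  de <- fit_nb_wald(m, md, contrast_spec("grp"),
                    sf = setNames(rep(1, 60), colnames(m)),
                    dispersions = c(g1 = 0.05), cooks_cutoff = Inf)
  expect_gt(de$log2fc, 1.5)
  expect_lt(de$p, 1e-6)

  # flipping the level order flips the sign exactly
  de2 <- fit_nb_wald(m, md, contrast_spec("grp", levels = c("b", "a")),
                     sf = setNames(rep(1, 60), colnames(m)),
                     dispersions = c(g1 = 0.05), cooks_cutoff = Inf)
  expect_equal(de2$log2fc, -de$log2fc, tolerance = 1e-6)
})

test_that("a null gene is rarely called: |log2fc| < 0.2 and p > 0.01 usually", {
  set.seed(77)
  hits <- replicate(100, {
    y <- rnbinom(200, mu = 100, size = 10)
    m <- make_counts(matrix(as.integer(y), 1))
    md <- tibble::tibble(sample_id = colnames(m),
                         grp = rep(c("a", "b"), each = 100))
    de <- fit_nb_wald(m, md, contrast_spec("grp"),
                      sf = setNames(rep(1, 200), colnames(m)),
                      dispersions = c(g1 = 0.1), cooks_cutoff = Inf)
    abs(de$log2fc) < 0.2 && de$p > 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate genes are not tested and designs are rank-checked", {
  m <- make_counts(rbind(rep(0L, 20), c(rep(10L, 10), rep(30L, 10))))
  md <- tibble::tibble(sample_id = colnames(m),
                       grp = rep(c("a", "b"), each = 10),
                       dup = rep(c("a", "b"), each = 10))
  de <- fit_nb_wald(m, md, contrast_spec("grp"),
                    sf = setNames(rep(1, 20), colnames(m)),
                    dispersions = c(g1 = 0.1, g2 = 0.1))
  expect_false(de$tested_flag[1])
  expect_true(is.na(de$p[1]))
  expect_true(de$tested_flag[2])

  expect_error(
    fit_nb_wald(m, md, contrast_spec("grp", adjust = "dup"),
                sf = setNames(rep(1, 20), colnames(m)),
                dispersions = c(g1 = 0.1, g2 = 0.1)),
    "rank deficient"
  )
})

test_that("fast vectorised path agrees with the per-gene IRLS path", {
  set.seed(12)
  G <- 25; n <- 40
  m <- make_counts(matrix(rnbinom(G * n, mu = 80, size = 5), G, n))
  sf <- setNames(runif(n, 0.8, 1.2), colnames(m))
  disp <- setNames(runif(G, 0.02, 0.3), rownames(m))
  d <- rep(c(0, 1), each = n / 2)
  md <- tibble::tibble(sample_id = colnames(m),
                       grp = ifelse(d == 1, "b", "a"))
  fast <- fit_nb_wald(m, md, contrast_spec("grp"), sf, disp, cooks_cutoff = Inf)
  X <- cbind(1, d)
  off <- log(sf)
  for (g in seq_len(G)) {
    ref <- txage:::nb_irls_gene(m[g, ], X, off, disp[g])
    expect_equal(fast$log2fc[g], unname(ref$beta[2]) / log(2), tolerance = 1e-6)
    expect_equal(fast$se[g], unname(ref$se[2]) / log(2), tolerance = 1e-6)
  }
})

test_that("Cook's flagging catches a planted extreme sample", {
  set.seed(5)
  y <- rpois(40, 100)
  y[7] <- 10000L
  m <- make_counts(matrix(as.integer(y), 1))
  md <- tibble::tibble(sample_id = colnames(m),
                       grp = rep(c("a", "b"), each = 20))
  de <- fit_nb_wald(m, md, contrast_spec("grp"),
                    sf = setNames(rep(1, 40), colnames(m)),
                    dispersions = c(g1 = 0.05), cooks_cutoff = 0.2)
  expect_true(de$outlier_flag[1])
  expect_false(de$tested_flag[1])
  expect_true(is.na(de$p[1]))

  # infinite cutoff flags nothing, balanced gene never flagged
  de_inf <- fit_nb_wald(m, md, contrast_spec("grp"),
                        sf = setNames(rep(1, 40), colnames(m)),
                        dispersions = c(g1 = 0.05), cooks_cutoff = Inf)
  expect_false(any(de_inf$outlier_flag))
  expect_false(any(cooks_outlier_flag(de_inf, cutoff = Inf)))
  expect_true(any(cooks_outlier_flag(de_inf, cutoff = 0.2)))

  balanced <- make_counts(matrix(rep(c(95L, 105L), 20), 1))
  deb <- fit_nb_wald(balanced, md, contrast_spec("grp"),
                     sf = setNames(rep(1, 40), colnames(balanced)),
                     dispersions = c(g1 = 0.05), cooks_cutoff = 0.2)
  expect_false(deb$outlier_flag[1])
})

test_that("outlier-flagged genes are excluded from the BH family", {
  set.seed(31)
  G <- 30; n <- 40
  m <- matrix(rpois(G * n, 100), G, n)
  m[3, 5] <- 15000L   # plant an outlier in gene 3
  m <- make_counts(m)
  md <- tibble::tibble(sample_id = colnames(m),
                       grp = rep(c("a", "b"), each = 20))
  de <- fit_nb_wald(m, md, contrast_spec("grp"),
                    sf = setNames(rep(1, n), colnames(m)),
                    dispersions = setNames(rep(0.05, G), rownames(m)))
  expect_true(de$outlier_flag[3])
  tested_p <- de$p[de$tested_flag]
  expect_equal(de$p_adj[de$tested_flag], bh_adjust(tested_p))
  expect_true(all(de$p_adj >= de$p, na.rm = TRUE))
})
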