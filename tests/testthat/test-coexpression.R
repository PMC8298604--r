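test_that("batch regression removes a constant batch shift exactly", {
  set.seed(2)
  expr <- matrix(rnorm(50 * 20, 100), 50, 20,
                 dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:20)))
  batch <- rep(c("A", "B"), each = 10)
  shifted <- expr
  shifted[, batch == "B"] <- shifted[, batch == "B"] + 2
  corrected <- batch_regress(shifted, batch)
  # batch means equalised; each gene's grand mean preserved
  expect_equal(rowMeans(corrected[, batch == "A"]),
               rowMeans(corrected[, batch == "B"]), tolerance = 1e-12)
  expect_equal(rowMeans(corrected), rowMeans(shifted), tolerance = 1e-12)

  expect_warning(same <- batch_regress(expr, rep("A", 20)), "Single batch")
  expect_identical(same, expr)
})

test_that("a planted batch effect is invisible to DE after correction", {
  hits <- vapply(1:3, function(s) {
    cfg <- sim_config(
      n_genes = 300, n_age_genes = 0, n_cluster_blocks = 0,
      covariate_effects = data.frame(covariate = "batch", n_genes = 60,
                                     log2fc = 1),
      noncoding_fraction = 0,
      group_sizes = c(HC = 40, MDD_untreated = 40), seed = 600 + s
    )
    sim <- simulate_dataset(cfg)
    expr <- log2(normalized_counts(sim$counts) + 1)
    corrected <- batch_regress(expr, sim$metadata$batch)
    b <- sim$metadata$batch == "b2"
    p <- apply(corrected, 1, function(v) t.test(v[b], v[!b])$p.value)
    sum(bh_adjust(p) < 0.01)
  }, numeric(1))
  expect_true(all(hits == 0))
})

test_that("the co-expression gene filter keeps mean > 10 and CV < 0.15", {
  mk <- function(mean, sd, n = 100) rnorm(n, mean, sd)
  set.seed(4)
  expr <- rbind(low = mk(5, 0.1), noisy = mk(100, 22), good = mk(100, 10))
  colnames(expr) <- sprintf("s%d", 1:100)
  # empirical CVs straddle the cutoff clearly
  kept <- filter_coexpression_genes(expr)
  expect_identical(rownames(kept), "good")
  expect_error(filter_coexpression_genes(expr[1, , drop = FALSE] * 0 + 1),
               "No genes")
})

test_that("TOM matches hand computations on canonical graphs", {
  # complete triangle, all adjacencies 1
  A <- matrix(1, 3, 3) - diag(3)
  dimnames(A) <- list(letters[1:3], letters[1:3])
  tri <- txage:::tom_from_adjacency(A)
  expect_equal(tri["a", "b"], 1)

  # path graph a-b-c: TOM(a,c) = 1/2
  P <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  P["a", "b"] <- P["b", "a"] <- 1
  P["b", "c"] <- P["c", "b"] <- 1
  tomP <- txage:::tom_from_adjacency(P)
  expect_equal(tomP["a", "c"], 0.5)
  expect_equal(tomP["a", "b"], 1)  # L_ab = 0, k_a = 1: (0+1)/(1+1-1)

  # empty graph: all off-diagonal zero
  Z <- matrix(0, 4, 4)
  tz <- txage:::tom_from_adjacency(Z)
  expect_true(all(tz[upper.tri(tz)] == 0))
  expect_true(all(diag(tz) == 1))
})

test_that("TOM equals the brute-force double loop on random instances", {
  set.seed(6)
  for (i in 1:10) {
    expr <- matrix(rnorm(6 * 12), 6, 12,
                   dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:12)))
    beta <- sample(c(1, 2, 6), 1)
    tom <- tom_matrix(expr, beta = beta)
    A <- abs(cor(t(expr)))^beta
    diag(A) <- 0
    expect_equal(tom, tom_brute(A), tolerance = 1e-10)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  const <- matrix(1, 3, 5, dimnames = list(c("gX", "g2", "g3"), NULL))
  const[2:3, ] <- rnorm(10)
  expect_error(tom_matrix(const), "gX")
})

test_that("tree cutting recovers planted blocks and honours min_size", {
  sim <- simulate_dataset(sim_config(
    n_genes = 320, n_age_genes = 0,
    covariate_effects = data.frame(covariate = character(),
                                   n_genes = integer(), log2fc = numeric()),
    n_cluster_blocks = 2, cluster_block_size = 60, cluster_loading = 1,
    noncoding_fraction = 0, group_sizes = c(HC = 60, MDD_untreated = 60),
    seed = 13
  ))
  expr <- log2(normalized_counts(sim$counts) + 1)
  tom <- tom_matrix(expr)
  cl <- cut_clusters(tom, cut_height = 0.95, min_size = 50)
  expect_length(cl$clusters, 2)
  truth <- sim$truth$genes$cluster
  names(truth) <- sim$truth$genes$gene_id
  pred <- rep(0L, nrow(expr))
  names(pred) <- rownames(expr)
  pred[cl$assignments$gene_id] <- as.integer(factor(cl$assignments$cluster_id))
  tr <- ifelse(is.na(truth[rownames(expr)]), 0L, truth[rownames(expr)])
  expect_gte(mclust::adjustedRandIndex(pred, tr), 0.9)

  # min_size above the gene count: empty set with a warning
  expect_warning(empty <- cut_clusters(tom, min_size = 1000), "min_size")
  expect_length(empty$clusters, 0)

  # identical genes collapse into a single all-gene cluster
  base <- rnorm(10)
  ident <- matrix(rep(base, each = 8), 8, 10, byrow = FALSE,
                  dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:10)))
  ident <- ident + rep(rnorm(8, sd = 1e-6), 10)  # break exact constancy
  tomi <- tom_matrix(ident)
  cli <- cut_clusters(tomi, min_size = 2)
  expect_length(cli$clusters, 1)
  expect_length(cli$clusters[[1]], 8)
})

test_that("metagenes are mean z-scores with the documented conventions", {
  expr <- rbind(
    g1 = c(1, 2, 3),
    g2 = c(3, 2, 1),
    g3 = c(5, 5, 5)      # zero variance
  )
  colnames(expr) <- c("s1", "s2", "s3")

  # single-gene cluster: metagene equals the gene's z-scores; (1,2,3) -> (-1,0,1)
  mg1 <- metagenes(expr, list(C1 = "g1"))
  expect_equal(unname(mg1$matrix["C1", ]), c(-1, 0, 1))

  # zero-variance member excluded with a warning
  expect_warning(mg2 <- metagenes(expr, list(C1 = c("g1", "g3"))),
                 "zero-variance")
  expect_equal(unname(mg2$matrix["C1", ]), c(-1, 0, 1))

  # opposite genes cancel
  mg3 <- metagenes(expr, list(C1 = c("g1", "g2")))
  expect_equal(unname(mg3$matrix["C1", ]), c(0, 0, 0))

  # grand mean of any metagene is ~0
  set.seed(10)
  big <- matrix(rnorm(30 * 50), 30, 50,
                dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:50)))
  mgb <- metagenes(big, list(A = sprintf("g%d", 1:10),
                             B = sprintf("g%d", 11:30)))
  expect_true(all(abs(rowMeans(mgb$matrix)) < 1e-9))
})

test_that("metagene group tests behave under identity and permutation", {
  set.seed(14)
  expr <- matrix(rnorm(40 * 60), 40, 60,
                 dimnames = list(sprintf("g%d", 1:40), sprintf("s%d", 1:60)))
  md <- tibble::tibble(
    sample_id = colnames(expr),
    group = factor(rep(c("HC", "MDD_untreated"), each = 30),
                   levels = txage:::GROUP_LEVELS)
  )
  mg <- metagenes(expr, list(A = sprintf("g%d", 1:20),
                             B = sprintf("g%d", 21:40)))
  res <- cluster_group_test(mg, md)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$p_adj >= res$p))

  # permuting sample order leaves the tests unchanged
  perm <- sample(60)
  mg_p <- metagenes(expr[, perm], list(A = sprintf("g%d", 1:20),
                                       B = sprintf("g%d", 21:40)))
  expect_equal(mg_p$matrix[, colnames(mg$matrix)], mg$matrix, tolerance = 1e-12)
  res_p <- cluster_group_test(mg_p, md)
  expect_equal(res_p$p, res$p, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  mirror <- cbind(expr[, 1:30], expr[, 1:30])
  colnames(mirror) <- sprintf("s%d", 1:60)
  mg_m <- metagenes(mirror, list(A = sprintf("g%d", 1:20)))
  res_m <- cluster_group_test(mg_m, md)
  expect_equal(res_m$t, 0, tolerance = 1e-10)
  expect_equal(res_m$p, 1, tolerance = 1e-10)

  expect_error(
    cluster_group_test(mg, dplyr::mutate(md, group = factor("HC", levels = txage:::GROUP_LEVELS))),
    "at least 2"
  )
})
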