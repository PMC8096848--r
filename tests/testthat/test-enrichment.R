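test_that("enrichment score matches a brute-force running sum exactly", {
  set.seed(21)
  for (rep in 1:20) {
    ids <- sprintf("g%02d", 1:10)
    scores <- sort(rnorm(10), decreasing = TRUE)
    rk <- gene_ranking(ids, scores)
    gs <- sample(ids, sample(2:5, 1))
    for (p in c(0, 1, 2)) {
      es <- enrichment_score(rk, gs, weight = p)
      expect_equal(es$es, brute_es(rk$gene_id, rk$score, gs, p))
      expect_lte(abs(es$es), 1)
    }
  }
})

test_that("a singleton set at the top of the list has ES 1 (weight 0)", {
  rk <- gene_ranking(sprintf("g%02d", 1:10), 10:1)
  es <- enrichment_score(rk, rk$gene_id[1], weight = 0)
  expect_equal(es$es, 1)
  expect_error(enrichment_score(rk, "absent"), "intersect")
})

test_that("weight-0 ES is invariant under monotone score transforms and
           negates under ranking reversal", {
  set.seed(22)
  ids <- sprintf("g%02d", 1:12)
  scores <- sort(rexp(12), decreasing = TRUE)
  gs <- c("g02", "g05", "g11")
  es1 <- enrichment_score(gene_ranking(ids, scores), gs, weight = 0)$es
  es2 <- enrichment_score(gene_ranking(ids, log(scores + 1)), gs,
                          weight = 0)$es
  expect_equal(es1, es2)
  rev_rk <- gene_ranking(ids, -scores)
  expect_equal(enrichment_score(rev_rk, gs, weight = 0)$es, -es1)
})

test_that("internal position-based ES agrees with the profile version", {
  set.seed(23)
  for (rep in 1:25) {
    N <- sample(8:30, 1)
    ids <- sprintf("g%02d", seq_len(N))
    rk <- gene_ranking(ids, sort(rnorm(N), decreasing = TRUE))
    size <- sample(2:min(6, N - 1), 1)
    gs <- sample(ids, size)
    pos <- which(rk$gene_id %in% gs)
    expect_equal(sexnet:::es_from_positions(rk$score, N, pos, 1),
                 enrichment_score(rk, gs, weight = 1)$es)
  }
})

test_that("Monte-Carlo p matches exhaustive enumeration on an 8-gene universe", {
  ids <- sprintf("g%d", 1:8)
  rk <- gene_ranking(ids, c(3.1, 2.0, 1.4, 0.9, -0.3, -0.8, -1.7, -2.5))
  gs <- c("g1", "g3")
  obs <- enrichment_score(rk, gs, weight = 1)$es
  # exhaustive null over all 28 two-gene subsets, same-sign convention
  combos <- utils::combn(8, 2)
  null_es <- apply(combos, 2, function(idx)
    sexnet:::es_from_positions(rk$score, 8, idx, 1))
  same <- null_es[sign(null_es) == sign(obs)]
  p_exact <- sum(abs(same) >= abs(obs)) / length(same)
  res <- gsea_preranked(rk, list(myset = gs), n_perm = 5000, seed = 31)
  # 99% binomial interval around the exact p at 5000 draws
  half <- 2.576 * sqrt(p_exact * (1 - p_exact) / 5000)
  expect_gte(res$pval, max(1 / 5001, p_exact - half - 1 / 5001))
  expect_lte(res$pval, p_exact + half + 2 / 5001)
})

test_that("random sets show calibrated nominal p-values", {
  set.seed(33)
  N <- 200
  rk <- gene_ranking(sprintf("g%03d", 1:N), rnorm(N))
  coll <- lapply(1:100, function(i) sample(rk$gene_id, 15))
  names(coll) <- paste0("set", 1:100)
  res <- gsea_preranked(rk, coll, n_perm = 500, seed = 34)
  expect_true(all(res$pval >= 1 / 501 & res$pval <= 1))
  frac <- mean(res$pval < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
  expect_true(all(res$padj >= res$pval - 1e-12))
})

test_that("GSEA results are deterministic for a fixed seed", {
  set.seed(35)
  rk <- gene_ranking(sprintf("g%02d", 1:40), rnorm(40))
  coll <- list(a = sprintf("g%02d", 1:8), b = sprintf("g%02d", 30:40))
  r1 <- gsea_preranked(rk, coll, n_perm = 300, seed = 7)
  r2 <- gsea_preranked(rk, coll, n_perm = 300, seed = 7)
  expect_identical(r1, r2)
})

test_that("ES agrees with the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(36)
  N <- 60
  ids <- sprintf("g%02d", 1:N)
  stats <- sort(rnorm(N), decreasing = TRUE)
  names(stats) <- ids
  rk <- gene_ranking(ids, stats)
  for (rep in 1:5) {
    gs <- sample(ids, 10)
    es_pkg <- enrichment_score(rk, gs, weight = 1)$es
    es_ref <- suppressWarnings(
      fgsea::fgsea(list(s = gs), stats, nPermSimple = 101,
                   gseaParam = 1))$ES
    expect_equal(es_pkg, es_ref, tolerance = 1e-8)
  }
})
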