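test_that("integrated gradients are exact on a linear scorer", {
  set.seed(4)
  d <- 12
  w <- rnorm(d)
  lin <- ig_scorer(function(X) drop(X %*% w) + 0.3,
                   function(X) matrix(w, nrow(X), d, byrow = TRUE))
  x <- rnorm(d)
  b <- rnorm(d)
  for (m in c(1, 3, 64)) {
    ig <- integrated_gradients(lin, x, b, m = m)
    expect_equal(as.numeric(ig), w * (x - b), tolerance = 1e-6)
  }
  # x = baseline gives exactly zero everywhere
  expect_equal(as.numeric(integrated_gradients(lin, x, x, m = 8)),
               rep(0, d))
})

test_that("completeness holds on a trained net and improves with steps", {
  fx <- toy_trained_net()
  x <- fx$X[, 5]
  ig <- integrated_gradients(fx$trained, x, m = 256)
  expect_lte(attr(ig, "completeness_error"), 1e-3)
  # Riemann error shrinks as m doubles (averaged over samples to damp the
  # per-sample noise in where each error lands)
  errs <- vapply(c(16, 32, 64, 128, 256, 512), function(m) {
    am <- attribution_matrix(fx$trained, fx$X[, 1:10], m = m, chunk = 5)
    mean(am$completeness_error)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
  expect_lt(errs[length(errs)], errs[1] / 4)
})

test_that("batched attribution matrix equals the per-sample computation", {
  fx <- toy_trained_net()
  am <- attribution_matrix(fx$trained, fx$X[, 1:5], m = 32, chunk = 2)
  for (i in 1:5) {
    ig <- integrated_gradients(fx$trained, fx$X[, i], m = 32)
    expect_equal(unname(am$values[i, ]), as.numeric(ig), tolerance = 1e-12)
  }
})

test_that("attribution scores average the chosen group deterministically", {
  set.seed(6)
  v <- matrix(rnorm(24), 6, 4,
              dimnames = list(sprintf("s%d", 1:6), sprintf("g%d", 1:4)))
  sexes <- c("male", "female", "male", "male", "female", "female")
  rk <- attribution_scores(v, sexes)
  expect_equal(sort(rk$score, decreasing = TRUE), rk$score)
  manual <- colMeans(v[sexes == "male", ])
  expect_equal(rk$score[match(names(manual), rk$gene_id)],
               unname(manual)[match(names(manual), names(manual))])
  # single male sample: scores equal that row
  rk1 <- attribution_scores(v[2:1, ], c("female", "male"))
  expect_equal(rk1$score[match(colnames(v), rk1$gene_id)], unname(v[1, ]))
  # permuting samples leaves the ranking unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_identical(attribution_scores(v[perm, ], sexes[perm])$gene_id,
                   rk$gene_id)
  expect_error(attribution_scores(v, rep("female", 6)), "empty")
  # linearity: mean over all males = weighted mean of split groups
  half1 <- colMeans(v[c(1, 3), ])
  half2 <- colMeans(v[4, , drop = FALSE])
  expect_equal((2 * half1 + half2) / 3, colMeans(v[c(1, 3, 4), ]))
})

test_that("top_k respects scores and breaks boundary ties by gene id", {
  rk <- gene_ranking(c("b", "a", "c", "d"), c(3, 1, 1, 0))
  expect_identical(top_k(rk, 4), c("b", "a", "c", "d"))
  expect_identical(top_k(rk, 2), c("b", "a"))  # tie at rank 2: "a" < "c"
  expect_error(top_k(rk, 5), "1..4")
  expect_error(top_k(rk, 0), "1..4")
})

test_that("consensus region counts match brute-force enumeration", {
  # five identical sets intersect fully
  same <- replicate(5, sprintf("g%03d", 1:100), simplify = FALSE)
  expect_length(consensus_sets(same)$intersection, 100)
  # pairwise disjoint sets have no overlap beyond degree 1
  disj <- list(a = c("x1", "x2"), b = c("y1"), c = c("z1", "z2", "z3"))
  cs <- consensus_sets(disj)
  expect_equal(unname(cs$degree_counts), c(6L, 0L, 0L))
  # random sets vs brute force over all membership patterns
  set.seed(12)
  universe <- sprintf("u%03d", 1:100)
  sets <- lapply(1:5, function(i) sample(universe, 20))
  names(sets) <- paste0("s", 1:5)
  cs <- consensus_sets(sets)
  union_genes <- sort(unique(unlist(sets)))
  pat <- vapply(union_genes, function(g)
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = ""), "")
  brute <- table(pat)
  expect_equal(cs$region_counts[names(brute)], c(brute))
  expect_setequal(consensus_genes(sets, 1), union_genes)
})
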