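small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 60, n_genes = 120, n_y_linked = 4,
         n_xist_like = 4, n_xci_escape = 4, seed = 3),
    list(...))
  do.call(cohort_config, args)
}

test_that("cohort generation enforces the configured sex structure", {
  cfg <- small_cfg(male_fraction = 0.5)
  cohorts <- generate_cohorts(cfg, n_cohorts = 3)
  planted <- attr(cohorts, "planted")
  expect_length(cohorts, 3)
  for (co in cohorts) {
    expect_equal(sum(co$samples$sex == "male"), 30)
    v <- co$expr$values
    fem <- co$samples$sample_id[co$samples$sex == "female"]
    mal <- co$samples$sample_id[co$samples$sex == "male"]
    # Y-linked silent in every female, XIST-like silent in every male
    expect_true(all(v[planted$y_linked, fem] == cfg$floor_value))
    expect_true(all(v[planted$xist_like, mal] == cfg$floor_value))
    expect_gt(min(v[planted$y_linked, mal]), cfg$floor_value)
  }
  # same planted identities and annotation across cohorts
  expect_identical(cohorts[[1]]$annotation, cohorts[[2]]$annotation)
  ann <- cohorts[[1]]$annotation
  expect_true(all(ann$chromosome[match(planted$y_linked,
                                       ann$gene_id)] == "Y"))
  expect_true(all(ann$chromosome[match(planted$xci_escape,
                                       ann$gene_id)] == "X"))
})

test_that("XCI-escape genes are shifted up in females by the effect size", {
  cfg <- small_cfg(n_samples = 400, sex_effect_size = 1.5)
  co <- generate_cohorts(cfg, 1)[[1]]
  planted <- attr(generate_cohorts(cfg, 1), "planted")
  fem <- co$samples$sex == "female"
  gap <- rowMeans(co$expr$values[planted$xci_escape, fem]) -
    rowMeans(co$expr$values[planted$xci_escape, !fem])
  expect_equal(unname(gap), rep(1.5, 4), tolerance = 0.4)
})

test_that("generation is deterministic per seed and varies across seeds", {
  cfg <- small_cfg()
  a <- generate_cohorts(cfg, 2, seed = 10)
  b <- generate_cohorts(cfg, 2, seed = 10)
  c <- generate_cohorts(cfg, 2, seed = 11)
  expect_identical(a[[1]]$expr$values, b[[1]]$expr$values)
  expect_identical(a[[2]]$samples, b[[2]]$samples)
  expect_false(identical(a[[1]]$expr$values, c[[1]]$expr$values))
  # cohorts within a run differ
  expect_false(identical(a[[1]]$expr$values[, 1], a[[2]]$expr$values[, 1]))
})

test_that("planted gene counts cannot exceed the gene universe", {
  expect_error(cohort_config(n_genes = 10, n_y_linked = 5, n_xist_like = 5,
                             n_xci_escape = 5), "exceed")
})

test_that("counts mode produces nonnegative integers that normalize", {
  cfg <- small_cfg(scale = "counts")
  co <- generate_cohorts(cfg, 1)[[1]]
  expect_identical(co$expr$scale, "counts")
  expect_true(all(co$expr$values >= 0))
  expect_true(all(co$expr$values == round(co$expr$values)))
  norm <- cpm_log_normalize(co$expr)
  expect_identical(norm$scale, "log2")
})

test_that("a logistic fit on planted genes alone separates the sexes", {
  cfg <- cohort_config(n_samples = 200, n_genes = 300, seed = 8)
  co <- generate_cohorts(cfg, 1)[[1]]
  planted <- attr(generate_cohorts(cfg, 1), "planted")
  genes <- c(planted$y_linked, planted$xist_like, planted$xci_escape)
  df <- data.frame(y = as.integer(co$samples$sex == "male"),
                   t(co$expr$values[genes, ]))
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial))
  acc <- mean((fitted(fit) > 0.5) == df$y)
  expect_gte(acc, 0.95)
})

test_that("hormone module hits its nominal correlation", {
  cfg <- small_cfg()
  co <- generate_cohorts(cfg, 1)[[1]]
  # rho = 1: rows identical up to affine transform
  m1 <- plant_hormone_module(co$expr, "ARlike", "MIRlike",
                             c("HOSTlnc1", "HOSTlnc2"), rho = 1, seed = 2)
  expect_equal(cor(m1$values["ARlike", ], m1$values["MIRlike", ]), 1)
  # rho = 0.5 at n = 10000: Fisher-z 99% interval
  big <- expression_matrix(
    matrix(rnorm(3 * 10000), 3, 10000,
           dimnames = list(c("ar", "mir", "h"),
                           sprintf("s%05d", 1:10000))), "log2")
  m2 <- plant_hormone_module(big, "ar", "mir", "h", rho = 0.5, seed = 4)
  r <- cor(m2$values["ar", ], m2$values["mir", ])
  expect_gte(r, 0.47); expect_lte(r, 0.53)
  expect_lte(abs(r - 0.5), 3 / sqrt(10000) + 0.02)
  # rho = 0: near-zero empirical correlation
  m3 <- plant_hormone_module(big, "ar", "mir", character(), rho = 0,
                             seed = 5)
  expect_lt(abs(cor(m3$values["ar", ], m3$values["mir", ])), 0.05)
  expect_error(plant_hormone_module(co$expr, "nope", "MIRlike"), "unknown")
})

test_that("inverse-target planting yields the requested anticorrelation", {
  big <- expression_matrix(
    matrix(rnorm(4 * 5000, mean = 6), 4, 5000,
           dimnames = list(c("mir", "t1", "t2", "d"),
                           sprintf("s%04d", 1:5000))), "log2")
  m <- plant_inverse_targets(big, c("t1", "t2"), "mir", rho = -0.5,
                             seed = 6)
  expect_lt(cor(m$values["mir", ], m$values["t1", ]), -0.4)
  expect_lt(cor(m$values["mir", ], m$values["t2", ]), -0.4)
  expect_equal(m$values["d", ], big$values["d", ])  # decoys untouched
})

test_that("survival simulation respects censoring targets and hazards", {
  tab <- data.frame(sample_id = sprintf("s%04d", 1:3000))
  x <- rbinom(3000, 1, 0.5)
  # censor_rate = 0: every subject has an event
  s0 <- generate_survival(tab, x, log(1.5), censor_rate = 0, seed = 7)
  expect_true(all(s0$event == 1))
  expect_true(all(s0$time > 0))
  # calibrated censoring within two points of the target
  s1 <- generate_survival(tab, x, log(1.5), censor_rate = 0.3, seed = 7)
  expect_lte(abs(mean(1 - s1$event) - 0.3), 0.02)
  # null effect: log-rank p roughly uniform over replicates
  pvals <- vapply(1:60, function(i) {
    si <- generate_survival(tab[1:150, , drop = FALSE], x[1:150], 0,
                            censor_rate = 0.2, seed = 100 + i)
    si$g <- x[1:150]
    logrank_test(si, si$g)$p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_error(generate_survival(tab, x[1:5], log(1.5)), "align")
})

test_that("synthetic UTRs realize their site plans exactly", {
  plan <- list(tA = c("8mer" = 1), tB = c("7mer-m8" = 2),
               tC = c("8mer" = 1, "6mer" = 1))
  res <- generate_utrs(c("tA", "tB", "tC"), c("d1", "d2"),
                       sites_per_target = plan, utr_length = 400,
                       seed = 9)
  expect_true(all(grepl("^[ACGT]+$", res$sequences)))
  ms <- res$seed_patterns
  for (g in c("tA", "tB", "tC")) {
    found <- scan_utr(res$sequences[[g]], ms)
    want <- res$plan[res$plan$gene_id == g, ]
    expect_equal(found$start, want$start)
    expect_identical(found$site_type, want$site_type)
    expect_identical(sort(found$site_type),
                     sort(rep(names(plan[[g]]), plan[[g]])))
  }
  for (d in c("d1", "d2"))
    expect_equal(nrow(scan_utr(res$sequences[[d]], ms)), 0L)
  # determinism
  res2 <- generate_utrs(c("tA", "tB", "tC"), c("d1", "d2"),
                        sites_per_target = plan, utr_length = 400,
                        seed = 9)
  expect_identical(res$sequences, res2$sequences)
  expect_error(generate_utrs("t", character(), utr_length = 5), "shorter")
})

test_that("synthetic promoters carry the requested half-site counts", {
  pr <- generate_promoters(c("p1", "p2"), n_sites = c(2, 1), span = 500,
                           seed = 10)
  expect_equal(nrow(scan_promoter_halfsites(pr$sequences[["p1"]],
                                            span = 500)), 2L)
  expect_equal(nrow(scan_promoter_halfsites(pr$sequences[["p2"]],
                                            span = 500)), 1L)
  expect_equal(pr$plan$gene_id, c("p1", "p1", "p2"))
})
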