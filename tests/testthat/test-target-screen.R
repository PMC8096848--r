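test_that("seed patterns are the reverse complements of the seed spans", {
  ms <- compile_seed_patterns("UAGCUUAUCAGACUGAUGUUGA")
  expect_identical(ms$seed, "AGCUUAU")
  expect_identical(unname(ms$patterns["7mer-m8"]), "ATAAGCT")
  expect_identical(unname(ms$patterns["8mer"]), "ATAAGCTA")
  expect_identical(unname(ms$patterns["7mer-A1"]), "TAAGCTA")
  expect_identical(unname(ms$patterns["6mer"]), "TAAGCT")
  expect_error(compile_seed_patterns("UAGCUUA"), ">= 8")
  expect_error(compile_seed_patterns("UAGCTTAT"), "ACGU")
  # round-trip: reverse-complementing the 7mer-m8 recovers seed 2-8 in RNA
  expect_identical(chartr("T", "U", rc(ms$patterns[["7mer-m8"]])),
                   ms$seed)
})

test_that("UTR scan finds planted sites with most-specific-wins overlaps", {
  ms <- compile_seed_patterns("UAGCUUAUCAGACUGAUGUUGA")
  hit <- scan_utr("GGGATAAGCTAGGG", ms)
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$site_type, "8mer")
  expect_equal(hit$start, 4L)
  expect_equal(hit$end, 11L)
  # no-match sequence
  expect_equal(nrow(scan_utr("CCCCCCCCCCCC", ms)), 0L)
  # a bare 7mer-m8 (no trailing A) is reported as 7mer-m8, not 8mer
  hit2 <- scan_utr("GGATAAGCTGG", ms)
  expect_identical(hit2$site_type, "7mer-m8")
  expect_error(scan_utr("ACGTN", ms), "ACGT")
})

test_that("UTR scan equals the naive every-offset oracle on random seqs", {
  ms <- compile_seed_patterns(MIR125B_5P)
  set.seed(51)
  n_with_sites <- 0
  for (rep in 1:400) {
    s <- random_seq(300)
    if (rep %% 7 == 0) {  # force some hits
      p <- sample(280, 1)
      substr(s, p, p + 7) <- ms$patterns[["8mer"]]
    }
    got <- scan_utr(s, ms)
    want <- naive_scan_utr(s, ms)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      n_with_sites <- n_with_sites + 1
      expect_equal(got[, c("site_type", "start", "end")], want)
    }
  }
  expect_gt(n_with_sites, 30)
})

test_that("inverse-correlation filter keeps anti-correlated genes", {
  set.seed(52)
  mir <- rnorm(50)
  m <- rbind(pos = mir, neg = -mir, noise = rnorm(50))
  colnames(m) <- sprintf("s%02d", 1:50)
  hits <- inverse_targets(mir, m, 0.5)
  expect_identical(hits, "neg")
  expect_error(inverse_targets(mir[1:10], m), "does not match")
  # planted rho = -0.5 recovered at threshold 0.3 in most replicates
  ok <- 0
  for (rep in 1:40) {
    z <- rnorm(200)
    g <- -0.5 * z + sqrt(1 - 0.25) * rnorm(200)
    gm <- rbind(target = g)
    colnames(gm) <- sprintf("s%03d", 1:200)
    ok <- ok + ("target" %in% inverse_targets(z, gm, 0.3))
  }
  expect_gte(ok / 40, 0.95)
})

test_that("three-evidence integration reports all Venn regions", {
  ev <- integrate_evidence(letters[1:10], letters[1:10], letters[1:10])
  expect_length(ev$final, 10)
  ev2 <- integrate_evidence(c("a", "b"), c("c"), c("a", "c"))
  expect_length(ev2$final, 0)
  # random sets vs brute-force membership enumeration
  set.seed(53)
  u <- sprintf("t%03d", 1:60)
  s1 <- sample(u, 25); s2 <- sample(u, 25); s3 <- sample(u, 25)
  ev3 <- integrate_evidence(s1, s2, s3)
  expect_setequal(ev3$final, intersect(intersect(s1, s2), s3))
  pats <- vapply(sort(unique(c(s1, s2, s3))), function(g)
    paste(as.integer(c(g %in% s1, g %in% s2, g %in% s3)), collapse = ""),
    "")
  brute <- table(pats)
  expect_equal(ev3$region_counts[names(brute)], c(brute))
  expect_equal(sum(ev3$region_counts), length(unique(c(s1, s2, s3))))
})

test_that("promoter half-site scan reports upstream coordinate pairs", {
  # motif occupying upstream positions -10..-15 on the forward strand
  n <- 40
  s <- paste(rep("C", n), collapse = "")
  substr(s, n - 15 + 1, n - 10 + 1) <- "AGAACA"
  hit <- scan_promoter_halfsites(s)
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$strand, "+")
  expect_identical(hit$label, "-10/-15")
  # TGTTCT is a reverse-strand occurrence
  s2 <- paste0(paste(rep("C", 10), collapse = ""), "TGTTCT",
               paste(rep("C", 4), collapse = ""))
  hit2 <- scan_promoter_halfsites(s2)
  expect_identical(hit2$strand, "-")
  expect_identical(hit2$label, "-5/-10")
  # neither motif nor its reverse complement
  expect_equal(nrow(scan_promoter_halfsites("CCCCCCCC")), 0L)
  expect_warning(scan_promoter_halfsites(random_seq(2100)), "span")
})

test_that("promoter scan equals a naive oracle on random sequences", {
  set.seed(54)
  for (rep in 1:600) {
    n <- sample(50:200, 1)
    s <- random_seq(n)
    got <- scan_promoter_halfsites(s)
    fwd <- naive_find(s, "AGAACA")
    rev <- naive_find(s, "TGTTCT")
    want_i <- sort(c(fwd, rev))
    expect_equal(nrow(got), length(want_i))
    if (length(want_i)) {
      expect_equal(got$to, -(n - want_i + 1))
      expect_equal(got$from, got$to + 5)
      expect_identical(got$strand, ifelse(want_i %in% fwd, "+", "-"))
    }
  }
})
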