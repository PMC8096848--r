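test_that("dichotomization rules cut at the stated quantiles", {
  d <- dichotomize(1:10, "median")
  expect_equal(d$cutoff, 5.5)
  expect_equal(sum(d$labels == "high"), 5)
  expect_equal(sum(d$labels == "low"), 5)
  d2 <- dichotomize(1:8, "upper_quartile")
  expect_equal(sum(d2$labels == "high"), 2)
  # ties go low: a value equal to the cutoff is not "high"
  d3 <- dichotomize(c(1, 2, 2, 2, 3, 4, 5, 6, 7), "median")
  expect_identical(as.character(d3$labels[5]), "low")  # value 3 == median
  expect_error(dichotomize(rep(2, 5), "median"), "equal")
  d4 <- dichotomize(1:9, "lower_tertile")
  expect_equal(d4$cutoff, quantile(1:9, 1 / 3, names = FALSE))
})

test_that("Kaplan-Meier estimate matches the hand product-limit", {
  rec <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_estimate(rec)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  rec2 <- data.frame(time = c(2, 5, 9), event = c(0, 0, 0))
  expect_true(all(km_estimate(rec2)$surv == 1))
  # censoring before the first event shrinks the risk set
  rec3 <- data.frame(time = c(1, 2, 3), event = c(0, 1, 1))
  km3 <- km_estimate(rec3)
  ev <- km3[km3$n_event > 0, ]
  expect_equal(ev$n_risk[1], 2)
  expect_equal(ev$surv, c(1 / 2, 0))
  expect_error(km_estimate(data.frame(time = c(0, 1), event = c(1, 1))),
               "> 0")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(61)
  tt <- round(rexp(40, 0.1), 2) + 0.01
  km <- km_estimate(data.frame(time = tt, event = 1))
  for (i in seq_len(nrow(km)))
    expect_equal(km$surv[i], mean(tt > km$time[i]))
})

test_that("log-rank matches a hand tableau and is symmetric", {
  # two-group toy, 6 subjects, hand observed-minus-expected computation
  rec <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                    event = c(1, 1, 1, 1, 0, 1))
  grp <- c("A", "B", "A", "B", "A", "B")
  # hand tableau over pooled event times (1,2,3,4,6):
  # t=1: risk 6 (A3,B3), event in A -> E_A = 3/6, V = (3*3*5)/(36*5)
  oe <- 0; v <- 0
  at_risk <- data.frame(t = rec$time, e = rec$event, g = grp)
  for (t in c(1, 2, 3, 4, 6)) {
    rs <- at_risk[at_risk$t >= t, ]
    nA <- sum(rs$g == "A"); nn <- nrow(rs)
    d <- sum(at_risk$t == t & at_risk$e == 1)
    oA <- sum(at_risk$t == t & at_risk$e == 1 & at_risk$g == "A")
    oe <- oe + oA - d * nA / nn
    if (nn > 1) v <- v + d * (nA / nn) * (1 - nA / nn) * (nn - d) / (nn - 1)
  }
  hand_chisq <- oe^2 / v
  lr <- logrank_test(rec, grp)
  expect_equal(lr$chisq, hand_chisq, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(hand_chisq, 1, lower.tail = FALSE))
  # symmetry in group labels
  lr2 <- logrank_test(rec, ifelse(grp == "A", "B", "A"))
  expect_equal(lr2$chisq, lr$chisq)
  # identical copies of the same data in both groups: statistic 0
  rec_dup <- rbind(rec, rec)
  lr0 <- logrank_test(rec_dup, rep(c("A", "B"), each = 6))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_error(logrank_test(data.frame(time = 1:2, event = c(0, 0)),
                            c("A", "B")), "no events")
})

test_that("Cox fit recovers a planted hazard ratio and flags separation", {
  set.seed(62)
  n <- 800
  x <- rbinom(n, 1, 0.5)
  rec <- generate_survival(data.frame(sample_id = seq_len(n)),
                           x, betas = log(1.5), baseline_rate = 0.05,
                           censor_rate = 0.2, seed = 63)
  rec$x <- x
  fit <- cox_fit(rec, "x")
  expect_true(fit$converged)
  expect_lte(abs(fit$table$beta - log(1.5)), 0.2)
  expect_equal(fit$table$hr, exp(fit$table$beta))
  expect_equal(fit$table$lower,
               exp(fit$table$beta - 1.96 * fit$table$se))
  # perfect separation: all events in the high-covariate group come first
  sep <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                    event = c(1, 1, 1, 1, 1, 1),
                    z = c(1, 1, 1, 0, 0, 0))
  fit_sep <- cox_fit(sep, "z")
  expect_false(fit_sep$converged)
})

test_that("LASSO-Cox reduces to the unpenalized fit at lambda 0 and to the
           empty model at large lambda", {
  set.seed(64)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  lp <- 0.8 * X[, 1] - 0.6 * X[, 3]
  tt <- rexp(n, rate = 0.05 * exp(lp))
  rec <- data.frame(time = tt, event = 1)
  fit <- lasso_cox(rec, X, lambda = c(5, 1, 0.1, 0.01, 0), n_folds = 5,
                   seed = 65)
  cf0 <- as.matrix(coef(fit$fit$glmnet.fit, s = 0, exact = FALSE))[, 1]
  ref <- cox_fit(cbind(rec, as.data.frame(X)), colnames(X))
  expect_equal(unname(cf0), ref$table$beta, tolerance = 1e-4)
  # large lambda: all coefficients exactly zero
  cf_big <- as.matrix(coef(fit$fit$glmnet.fit, s = 5))[, 1]
  expect_true(all(cf_big == 0))
  # path: nonzero count non-increasing in lambda
  path <- fit$path[order(fit$path$lambda), ]
  expect_true(all(diff(path$nonzero) <= 0))
  expect_error(lasso_cox(data.frame(time = rexp(20) + 1,
                                    event = rep(c(1, 0), 10)),
                         matrix(rnorm(40), 20), n_folds = 20),
               "fewer events")
})

test_that("combined AR/miR stratification builds four groups and a merge", {
  set.seed(66)
  ar <- rnorm(40); mir <- rnorm(40)
  st <- combo_stratify(ar, mir)
  expect_equal(sum(table(st$four_group)), 40)
  both_high <- ar > st$ar_cutoff & mir > st$mir_cutoff
  expect_equal(as.character(st$four_group) == "both_high", both_high)
  expect_equal(sum(st$merged == "both_high"), sum(both_high))
  expect_identical(levels(st$merged), c("other", "both_high"))
})
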