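# Quantile dichotomization, Kaplan-Meier curves, log-rank tests, Cox
# proportional-hazards models and LASSO-Cox feature selection. The model
# fitting itself goes through the survival and glmnet packages; this module
# standardizes the cutpoint rules, tie policies and reporting used by the
# pipeline.

#' Quantile dichotomization of a marker
#'
#' Splits a continuous marker at a quantile cutpoint. The rules mirror
#' common biomarker practice: `median`, `upper_quartile` (0.75),
#' `upper_tertile` (2/3) and `lower_tertile` (1/3). "High" means strictly
#' above the cutoff; values tied with the cutoff are labeled low.
#'
#' @param values Numeric vector.
#' @param rule One of `"median"`, `"upper_quartile"`, `"upper_tertile"`,
#'   `"lower_tertile"`.
#' @return List with `labels` (factor `low`/`high`), `cutoff`, `rule`.
#' @examples
#' dichotomize(1:10, "median")
#' @export
dichotomize <- function(values, rule = c("median", "upper_quartile",
                                         "upper_tertile", "lower_tertile")) {
  rule <- match.arg(rule)
  if (any(!is.finite(values))) abort("'values' must be finite")
  n_distinct <- length(unique(values))
  if (n_distinct < 2L) abort("all values are equal; cannot dichotomize")
  min_needed <- switch(rule, median = 2L, upper_quartile = 4L,
                       upper_tertile = 3L, lower_tertile = 3L)
  if (n_distinct < min_needed)
    abort("rule '%s' needs >= %d distinct values", rule, min_needed)
  cutoff <- switch(rule,
                   median = stats::median(values),
                   upper_quartile = stats::quantile(values, 0.75, names = FALSE),
                   upper_tertile = stats::quantile(values, 2 / 3, names = FALSE),
                   lower_tertile = stats::quantile(values, 1 / 3, names = FALSE))
  labels <- factor(ifelse(values > cutoff, "high", "low"),
                   levels = c("low", "high"))
  list(labels = labels, cutoff = cutoff, rule = rule)
}

as_surv_df <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("time", "event") %in% names(records)))
    abort("records must contain 'time' and 'event' columns")
  if (any(records$time <= 0)) abort("survival times must be > 0")
  if (!all(records$event %in% c(0, 1))) abort("event must be 0/1")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records data.frame with `time` and `event` columns.
#' @return A `km_curve` data.frame: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (one row per distinct observed time; censoring-only times keep
#'   `n_event = 0`).
#' @export
km_estimate <- function(records) {
  records <- as_surv_df(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' @param records data.frame with `time` and `event`.
#' @param group Two-level grouping vector aligned with rows.
#' @return List with `chisq`, `df` (1), `p`.
#' @export
logrank_test <- function(records, group) {
  records <- as_surv_df(records)
  group <- as.character(group)
  if (length(group) != nrow(records)) abort("'group' length mismatch")
  if (length(unique(group)) != 2L) abort("log-rank needs exactly two groups")
  if (sum(records$event) == 0) abort("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(records, g = group))
  list(chisq = sd$chisq, df = 1L,
       p = stats::pchisq(sd$chisq, 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson fit with the Efron correction for tied
#' event times. Monotone-likelihood problems (perfect separation) are
#' flagged via `converged = FALSE` rather than silently reported.
#'
#' @param records data.frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return A `cox_fit`: `table` (term, beta, se, hr, lower/upper 95 percent
#'   Wald CI, z, p), `loglik`, `converged`, `iter`, `n`, `n_event`.
#' @export
cox_fit <- function(records, covariates) {
  records <- as_surv_df(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) abort("covariate '%s' not found", miss[1L])
  if (sum(records$event) == 0) abort("no events observed")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|out of iterations",
                conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(term = names(beta), beta = unname(beta),
                    se = unname(se), hr = exp(unname(beta)),
                    lower = exp(unname(beta) - 1.96 * unname(se)),
                    upper = exp(unname(beta) + 1.96 * unname(se)),
                    z = unname(beta / se),
                    p = 2 * stats::pnorm(-abs(unname(beta / se))),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[2L],
                 converged = converged, iter = fit$iter,
                 n = fit$n, n_event = fit$nevent),
            class = "cox_fit")
}

#' @method print cox_fit
#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d, converged = %s\n",
              x$n, x$n_event, x$converged))
  tab <- x$table
  tab$hr_ci <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$lower, tab$upper)
  print(tab[, c("term", "beta", "se", "hr_ci", "p")], row.names = FALSE)
  invisible(x)
}

#' LASSO-Cox feature selection with cross-validated lambda
#'
#' L1-penalized Cox partial-likelihood path (glmnet) with k-fold
#' cross-validation on the partial-likelihood deviance. The selected
#' features are the nonzero coefficients at the CV-optimal lambda
#' (`"min"` by default; `"1se"` for the one-standard-error rule).
#'
#' @param records data.frame with `time` and `event`.
#' @param features Numeric matrix, samples x features (column names are
#'   feature ids). Standardization is handled internally by the path
#'   algorithm.
#' @param lambda Optional decreasing lambda path (default: glmnet's).
#' @param n_folds CV folds (default 10).
#' @param seed Seed for fold assignment.
#' @param rule `"min"` or `"1se"`.
#' @return A `lasso_cox_fit`: `selected` (feature ids), `lambda_opt`,
#'   `coef_opt` (named vector at the optimum), `path` (lambda, nonzero
#'   count), `cv` (lambda, mean deviance, sd), and the underlying `cv.glmnet`
#'   object in `fit`.
#' @export
lasso_cox <- function(records, features, lambda = NULL, n_folds = 10L,
                      seed = 1L, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  records <- as_surv_df(records)
  if (!is.matrix(features) || nrow(features) != nrow(records))
    abort("'features' must be a samples x features matrix aligned with records")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (sum(records$event) < n_folds)
    abort("fewer events (%d) than folds (%d)", sum(records$event), n_folds)
  y <- survival::Surv(records$time, records$event)
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(n_folds), nrow(records)))
  cv <- glmnet::cv.glmnet(features, y, family = "cox", lambda = lambda,
                          foldid = foldid, standardize = TRUE,
                          thresh = 1e-12)
  lambda_opt <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.matrix(stats::coef(cv$glmnet.fit, s = lambda_opt))[, 1L]
  structure(list(selected = names(cf)[cf != 0],
                 lambda_opt = lambda_opt,
                 coef_opt = cf,
                 path = data.frame(lambda = cv$glmnet.fit$lambda,
                                   nonzero = cv$glmnet.fit$df),
                 cv = data.frame(lambda = cv$lambda, cvm = cv$cvm,
                                 cvsd = cv$cvsd),
                 fit = cv),
            class = "lasso_cox_fit")
}

#' @method print lasso_cox_fit
#' @export
print.lasso_cox_fit <- function(x, ...) {
  cat(sprintf("lasso_cox_fit: lambda_opt = %.4g, %d feature(s) selected: %s\n",
              x$lambda_opt, length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Four-group and merged stratification on two markers
#'
#' Dichotomizes two markers (by default the first at its median, the second
#' at its upper quartile) and crosses the labels into four groups; the
#' merged binary contrasts the both-high group against the other three
#' pooled.
#'
#' @param ar_values,mir_values Aligned numeric marker vectors.
#' @param ar_rule,mir_rule Dichotomization rules (see [dichotomize()]).
#' @return List with `four_group` (factor: `both_low`, `ar_high_mir_low`,
#'   `ar_low_mir_high`, `both_high`), `merged` (factor: `other`,
#'   `both_high`), and the two cutoffs.
#' @export
combo_stratify <- function(ar_values, mir_values, ar_rule = "median",
                           mir_rule = "upper_quartile") {
  if (length(ar_values) != length(mir_values))
    abort("marker vectors must be aligned")
  ar <- dichotomize(ar_values, ar_rule)
  mir <- dichotomize(mir_values, mir_rule)
  lab <- ifelse(ar$labels == "high",
                ifelse(mir$labels == "high", "both_high", "ar_high_mir_low"),
                ifelse(mir$labels == "high", "ar_low_mir_high", "both_low"))
  four <- factor(lab, levels = c("both_low", "ar_high_mir_low",
                                 "ar_low_mir_high", "both_high"))
  merged <- factor(ifelse(four == "both_high", "both_high", "other"),
                   levels = c("other", "both_high"))
  list(four_group = four, merged = merged,
       ar_cutoff = ar$cutoff, mir_cutoff = mir$cutoff)
}
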