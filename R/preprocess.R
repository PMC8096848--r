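# Normalization, scaling, train/validation splitting and the 2^-ddCt helper.

#' Counts-per-million with log2 transform
#'
#' Scales each sample column of a counts matrix to one million, then applies
#' `log2(cpm + pseudocount)`. This is the standard library-size normalization
#' applied to RNA-seq counts before feeding the sex classifier.
#'
#' @param counts An [expression_matrix()] with `scale = "counts"`.
#' @param pseudocount Positive value added before the log (default 1).
#' @return An `expr_matrix` with `scale = "log2"`. The pseudocount used is
#'   recorded in attribute `"pseudocount"`.
#' @export
cpm_log_normalize <- function(counts, pseudocount = 1) {
  if (!inherits(counts, "expr_matrix")) abort("'counts' must be an expr_matrix")
  if (counts$scale != "counts")
    abort("cpm_log_normalize expects a counts matrix, got scale '%s'",
          counts$scale)
  if (!is_number(pseudocount) || pseudocount <= 0)
    abort("'pseudocount' must be a positive number")
  libsize <- colSums(counts$values)
  bad <- which(libsize <= 0)
  if (length(bad))
    abort("sample '%s' has zero total counts", counts$sample_ids[bad[1L]])
  cpm <- sweep(counts$values, 2L, libsize, "/") * 1e6
  out <- expression_matrix(log2(cpm + pseudocount), scale = "log2")
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Per-gene z-scaling across samples
#'
#' Centers every gene row to mean 0 and scales to standard deviation 1 across
#' samples, the feature standardization applied before network training.
#' Zero-variance genes cannot be scaled and are dropped (and recorded) rather
#' than imputed.
#'
#' @param matrix An `expr_matrix` (any scale) or plain numeric matrix with
#'   dimnames, genes in rows.
#' @return A `scaled_matrix`: list with `values` (retained genes x samples),
#'   `gene_ids`, `sample_ids`, `means`, `sds` (per retained gene) and
#'   `dropped_genes`.
#' @export
zscale_genes <- function(matrix) {
  v <- as_expr_values(matrix)
  if (ncol(v) < 2L) abort("z-scaling requires at least 2 samples")
  m <- rowMeans(v)
  s <- row_sds(v)
  keep <- s > 1e-12
  dropped <- rownames(v)[!keep]
  v <- (v[keep, , drop = FALSE] - m[keep]) / s[keep]
  structure(list(values = v,
                 gene_ids = rownames(v),
                 sample_ids = colnames(v),
                 means = m[keep], sds = s[keep],
                 dropped_genes = dropped),
            class = "scaled_matrix")
}

#' Apply a fitted scaling to new samples
#'
#' Uses the means/sds stored in a `scaled_matrix` (fitted, e.g., on the
#' training split) to standardize another matrix over the same genes. Genes
#' dropped at fit time are dropped here too, so validation data never leaks
#' into the scaling parameters.
#'
#' @param scaling A `scaled_matrix` from [zscale_genes()].
#' @param matrix Matrix or `expr_matrix` containing at least the retained
#'   genes as rows.
#' @return A `scaled_matrix` over the new samples.
#' @export
zscale_apply <- function(scaling, matrix) {
  stopifnot(inherits(scaling, "scaled_matrix"))
  v <- as_expr_values(matrix)
  miss <- setdiff(scaling$gene_ids, rownames(v))
  if (length(miss)) abort("gene '%s' absent from new matrix", miss[1L])
  v <- (v[scaling$gene_ids, , drop = FALSE] - scaling$means) / scaling$sds
  structure(list(values = v, gene_ids = rownames(v),
                 sample_ids = colnames(v),
                 means = scaling$means, sds = scaling$sds,
                 dropped_genes = scaling$dropped_genes),
            class = "scaled_matrix")
}

#' @method print scaled_matrix
#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("scaled_matrix: %d genes x %d samples (%d dropped)\n",
              nrow(x$values), ncol(x$values), length(x$dropped_genes)))
  invisible(x)
}

#' Train/validation split
#'
#' Randomly holds out `round(fraction * n)` samples as a validation set
#' (default 10 percent). By default the split is stratified by sex so that
#' both classes keep their proportions within one sample; plain random
#' splitting is available via `stratify_by = NULL`.
#'
#' @param sample_ids Character vector of sample ids.
#' @param fraction Validation fraction in (0, 1); default 0.10.
#' @param seed Integer seed making the split reproducible.
#' @param stratify_by Optional factor-like vector aligned with `sample_ids`
#'   (typically sex); `NULL` for unstratified splitting.
#' @return A `split_plan`: list with `train_ids`, `validation_ids`,
#'   `fraction`, `seed`.
#' @export
split_train_validation <- function(sample_ids, fraction = 0.10, seed = 1,
                                   stratify_by = NULL) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (!is_number(fraction) || fraction <= 0 || fraction >= 1)
    abort("'fraction' must lie strictly between 0 and 1")
  n_val <- round(fraction * n)
  if (n_val < 1L || n_val >= n)
    abort("validation fraction %.2f leaves no usable split for n = %d",
          fraction, n)
  set.seed(as.integer(seed))
  if (is.null(stratify_by)) {
    val <- sample(sample_ids, n_val)
  } else {
    if (length(stratify_by) != n) abort("'stratify_by' length mismatch")
    strata <- split(sample_ids, as.character(stratify_by))
    # largest-remainder allocation of n_val across strata
    quota <- vapply(strata, length, 1L) * fraction
    base <- floor(quota)
    rem <- n_val - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    val <- unlist(Map(function(ids, k) if (k > 0) sample(ids, k) else character(),
                      strata, base), use.names = FALSE)
  }
  structure(list(train_ids = setdiff(sample_ids, val),
                 validation_ids = val,
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Relative quantification by the 2^-ddCt method
#'
#' Computes the fold change of a target transcript in a sample relative to a
#' calibrator, each normalized to a reference transcript:
#' `2^-[(Ct_target_sample - Ct_ref_sample) - (Ct_target_cal - Ct_ref_cal)]`.
#'
#' @param ct_target_sample,ct_ref_sample Cycle thresholds in the sample.
#' @param ct_target_calibrator,ct_ref_calibrator Cycle thresholds in the
#'   calibrator.
#' @return Positive fold change(s); vectorized over inputs.
#' @examples
#' ddct_fold_change(25, 20, 26, 20)  # ddCt = -1 -> 2
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  args <- cbind(ct_target_sample, ct_ref_sample,
                ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(args))) abort("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
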