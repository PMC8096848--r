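# Two-group differential expression (Welch t per gene) with the significance
# filter used for screening, plus the Pearson correlation test used for the
# hormone co-expression analyses.

#' Two-group differential expression
#'
#' Per-gene Welch two-sample t-test on a log2-scale matrix. The log2 fold
#' change is the difference of group means (group2 minus group1), and
#' p-values are Benjamini-Hochberg adjusted over all genes.
#'
#' @param matrix `expr_matrix` with `scale = "log2"`.
#' @param labels Two-level factor/character vector aligned with samples;
#'   the first level (or first unique value) is group1.
#' @return A `de_table` data.frame: `gene_id`, `logFC`, `t`, `df`, `pval`,
#'   `padj`, ordered as in the input matrix.
#' @export
group_de <- function(matrix, labels) {
  v <- as_expr_values(matrix)
  if (inherits(matrix, "expr_matrix") && matrix$scale != "log2")
    abort("group_de expects a log2-scale matrix")
  labels <- as.character(labels)
  if (length(labels) != ncol(v)) abort("'labels' length mismatch")
  lev <- unique(labels)
  if (length(lev) != 2L) abort("'labels' must have exactly two groups")
  i1 <- labels == lev[1L]; i2 <- labels == lev[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) abort("each group needs >= 2 samples")
  m1 <- rowMeans(v[, i1, drop = FALSE])
  m2 <- rowMeans(v[, i2, drop = FALSE])
  v1 <- row_sds(v[, i1, drop = FALSE])^2
  v2 <- row_sds(v[, i2, drop = FALSE])^2
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  pval <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(gene_id = rownames(v), logFC = m2 - m1, t = tstat,
                    df = df, pval = pval,
                    padj = stats::p.adjust(pval, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Filter differentially expressed genes
#'
#' Keeps genes with `pval < p_thresh` and fold change beyond `lfc_thresh`
#' (both strict inequalities). By default the fold-change threshold is read
#' on the log2 scale, i.e. `|log2FC| > lfc_thresh`; `scale = "linear"` gives
#' the literal linear-ratio reading `2^logFC > lfc_thresh`.
#'
#' @param table A `de_table` from [group_de()].
#' @param p_thresh P-value threshold (default 0.05).
#' @param lfc_thresh Fold-change threshold (default 0.5).
#' @param scale `"log2"` (default) or `"linear"`.
#' @return Character vector of retained gene ids.
#' @export
deg_filter <- function(table, p_thresh = 0.05, lfc_thresh = 0.5,
                       scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(table), all(c("gene_id", "logFC", "pval") %in%
                                        names(table)))
  if (p_thresh <= 0 || lfc_thresh < 0) abort("thresholds must be positive")
  keep <- table$pval < p_thresh &
    if (scale == "log2") abs(table$logFC) > lfc_thresh
    else 2^table$logFC > lfc_thresh
  table$gene_id[keep]
}

#' Pearson correlation test
#'
#' Correlation coefficient with the two-sided t-approximation p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @return List with `r`, `p`, `n`.
#' @examples
#' pearson_r(1:10, (1:10)^2)
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("'x' and 'y' must have equal length")
  if (length(x) < 3L) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
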