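#' Expression matrix container
#'
#' Light container for a gene-by-sample numeric matrix carrying a scale tag.
#' All pipeline stages consume and produce this class. `scale = "counts"`
#' marks raw non-negative counts (e.g. RNA-seq); `scale = "log2"` marks
#' log2 intensities or log2-CPM values.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must have
#'   unique row and column names and no missing values.
#' @param scale Either `"log2"` or `"counts"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `sample_ids` and `scale`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expression_matrix(m, "log2")
#' @export
expression_matrix <- function(values, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    abort("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("'values' must have gene row names and sample column names")
  if (anyNA(values)) abort("expression matrix contains missing values")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) abort("duplicate gene id: %s", dup[1L])
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) abort("duplicate sample id: %s", dup[1L])
  if (scale == "counts" && any(values < 0))
    abort("counts matrix contains negative values")
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 scale = scale),
            class = "expr_matrix")
}

#' @method print expr_matrix
#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (scale = %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

as_expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values
  else if (is.matrix(x)) x
  else abort("expected an expr_matrix or a numeric matrix")
}

#' Sample table constructor
#'
#' Validates the per-sample metadata used throughout the pipeline: sample id,
#' sex, cohort id and (optionally) right-censored survival in months.
#'
#' @param sample_id Character vector of unique sample ids.
#' @param sex Character or factor with values `"male"` / `"female"`.
#' @param cohort_id Cohort label, recycled if scalar.
#' @param time Optional positive survival times (months).
#' @param event Optional 0/1 event indicators; must accompany `time`.
#' @return A `data.frame` of class `sample_table`.
#' @export
sample_table <- function(sample_id, sex, cohort_id = "cohort1",
                         time = NULL, event = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    abort("duplicate sample id: %s", sample_id[duplicated(sample_id)][1L])
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    abort("sex must be 'male' or 'female'")
  if (length(sex) != length(sample_id)) abort("sex length mismatch")
  if (xor(is.null(time), is.null(event)))
    abort("'time' and 'event' must be supplied together")
  out <- data.frame(sample_id = sample_id, sex = sex,
                    cohort_id = rep_len(as.character(cohort_id),
                                        length(sample_id)),
                    stringsAsFactors = FALSE)
  if (!is.null(time)) {
    if (any(!is.finite(time)) || any(time <= 0))
      abort("survival times must be finite and > 0")
    if (!all(event %in% c(0, 1))) abort("event must be 0/1")
    out$time <- as.numeric(time)
    out$event <- as.integer(event)
  }
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Gene annotation constructor
#'
#' @param gene_id Unique gene identifiers.
#' @param chromosome One of `1..22`, `"X"`, `"Y"` per gene.
#' @param gene_class `"mRNA"`, `"miRNA"` or `"lncRNA"`.
#' @param tss Integer transcription start site position.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chromosome, gene_class, tss, strand) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    abort("duplicate gene id: %s", gene_id[duplicated(gene_id)][1L])
  chromosome <- as.character(chromosome)
  valid_chr <- c(as.character(1:22), "X", "Y")
  if (!all(chromosome %in% valid_chr))
    abort("chromosome must be one of 1..22, X, Y")
  if (!all(gene_class %in% c("mRNA", "miRNA", "lncRNA")))
    abort("gene_class must be mRNA, miRNA or lncRNA")
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  out <- data.frame(gene_id = gene_id, chromosome = chromosome,
                    gene_class = as.character(gene_class),
                    tss = as.integer(tss), strand = as.character(strand),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}
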