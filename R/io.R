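# Readers and writers for the plain-text formats the pipeline exchanges:
# expression TSV (genes as rows, header = sample ids), sample/annotation
# TSV, GMT gene-set collections, FASTA sequences and RNK-style ranked lists.

#' Read an expression TSV
#'
#' Expects gene ids in the first column and one column per sample.
#'
#' @param path File path.
#' @param scale Scale tag to attach (`"log2"` or `"counts"`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("expression TSV needs gene ids plus >= 1 sample")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) abort("duplicate gene id in %s: %s", path, dup[1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric expression values in %s", path)
  rownames(m) <- ids
  expression_matrix(m, scale)
}

#' Write an expression TSV
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(gene_id = expr$gene_ids, expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table TSV
#'
#' Required columns: `sample_id`, `sex`; optional `cohort_id`, `time`,
#' `event` plus arbitrary covariate columns (preserved).
#'
#' @param path File path.
#' @return A [sample_table()] with any extra columns carried along.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "sex"), names(df))
  if (length(need)) abort("missing column '%s' in %s", need[1L], path)
  st <- sample_table(df$sample_id, df$sex,
                     cohort_id = if ("cohort_id" %in% names(df))
                       df$cohort_id else "cohort1",
                     time = df$time, event = df$event)
  extra <- setdiff(names(df), names(st))
  for (cn in extra) st[[cn]] <- df[[cn]]
  st
}

#' Write a sample table TSV
#' @param samples A data.frame.
#' @param path Output path.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation TSV
#' @param path File path with columns gene_id, chromosome, gene_class, tss,
#'   strand.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character"))
  need <- setdiff(c("gene_id", "chromosome", "gene_class", "tss", "strand"),
                  names(df))
  if (length(need)) abort("missing column '%s' in %s", need[1L], path)
  gene_annotation(df$gene_id, df$chromosome, df$gene_class, df$tss,
                  df$strand)
}

#' Write a gene annotation TSV
#' @param annotation A `gene_annotation`.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      abort("malformed GMT line %d in %s (need name, description, genes)",
            i, path)
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "", USE.NAMES = FALSE)
  if (anyDuplicated(names(sets)))
    abort("duplicate set name in %s: %s", path,
          names(sets)[duplicated(names(sets))][1L])
  sets
}

#' Write a GMT gene-set collection
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @export
write_gmt <- function(collection, path, description = "na") {
  stopifnot(is.list(collection), !is.null(names(collection)))
  description <- rep_len(description, length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], description[i], collection[[i]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Lowercase bases are accepted and uppercased.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  if (anyDuplicated(names(out)))
    abort("duplicate sequence id in %s: %s", path,
          names(out)[duplicated(names(out))][1L])
  out
}

#' Write sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_sequences <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read an RNK-style ranked list
#'
#' Two tab-separated columns (gene id, score), no header.
#'
#' @param path File path.
#' @return A [gene_ranking()].
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2L) abort("RNK file must have two columns: %s", path)
  gene_ranking(df[[1L]], df[[2L]])
}

#' Write an RNK-style ranked list
#' @param ranking A `gene_ranking`.
#' @param path Output path.
#' @export
write_rnk <- function(ranking, path) {
  stopifnot(inherits(ranking, "gene_ranking"))
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
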