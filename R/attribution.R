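# Integrated-gradient attribution, per-gene scores, top-k sets and the
# cross-cohort consensus.

#' Wrap an arbitrary differentiable scorer for attribution
#'
#' Attribution functions accept either a trained network or any scorer
#' exposing a forward pass and its input gradient, e.g. a linear model whose
#' integrated gradients have a closed form.
#'
#' @param forward Function taking a samples x features matrix, returning one
#'   score per row.
#' @param gradient Function taking the same matrix, returning the
#'   samples x features gradient of the score.
#' @return An `ig_scorer`.
#' @examples
#' w <- c(1, -2, 0.5)
#' sc <- ig_scorer(function(X) drop(X %*% w) + 3,
#'                 function(X) matrix(w, nrow(X), 3, byrow = TRUE))
#' integrated_gradients(sc, c(1, 1, 1), m = 1)
#' @export
ig_scorer <- function(forward, gradient) {
  stopifnot(is.function(forward), is.function(gradient))
  structure(list(forward = forward, gradient = gradient),
            class = "ig_scorer")
}

score_forward <- function(model, X) {
  if (inherits(model, "ig_scorer")) model$forward(X)
  else net_forward(as_sexnet_model(model), X)
}

score_gradient <- function(model, X) {
  if (inherits(model, "ig_scorer")) model$gradient(X)
  else input_gradients(as_sexnet_model(model), X)$gradient
}

#' Integrated gradients for one sample
#'
#' Path-integral attribution of the classifier's male probability: for gene
#' i, `(x_i - x'_i)` times the m-step midpoint-rule approximation of the
#' integral over alpha in \[0, 1\] of the input gradient evaluated at
#' `x' + alpha * (x - x')`. Attributions satisfy completeness: they sum to
#' approximately `F(x) - F(x')`, with the residual shrinking as `m` grows.
#'
#' @param model `sexnet_model` or `sexnet_trained`.
#' @param x Numeric gene vector (standardized scale).
#' @param baseline Reference gene vector; default all zeros, i.e. the
#'   population mean profile in z-scaled space.
#' @param m Number of Riemann steps (default 128).
#' @return Numeric attribution vector (named like `x`); attribute
#'   `"completeness_error"` records `|sum(attr) - (F(x) - F(baseline))|`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, m = 128L) {
  if (!inherits(model, "ig_scorer")) model <- as_sexnet_model(model)
  if (!is_count(m)) abort("'m' must be a positive integer")
  x <- as.numeric(x)
  if (is.null(baseline)) baseline <- numeric(length(x))
  if (length(baseline) != length(x))
    abort("baseline length %d does not match input length %d",
          length(baseline), length(x))
  if (inherits(model, "sexnet_model") && length(x) != model$n_genes)
    abort("input has %d genes, model expects %d", length(x), model$n_genes)
  alphas <- (seq_len(m) - 0.5) / m
  diff <- x - baseline
  path <- matrix(baseline, m, length(x), byrow = TRUE) + outer(alphas, diff)
  g <- score_gradient(model, path)
  attr_vec <- diff * colMeans(g)
  f1 <- score_forward(model, matrix(x, 1L))
  f0 <- score_forward(model, matrix(baseline, 1L))
  attr(attr_vec, "completeness_error") <- abs(sum(attr_vec) - (f1 - f0))
  attr_vec
}

#' Integrated gradients for every sample of a matrix
#'
#' Applies [integrated_gradients()] to each sample column, batching all path
#' points of several samples into single forward/backward passes.
#'
#' @param model `sexnet_model` or `sexnet_trained`.
#' @param X `scaled_matrix` or gene-by-sample matrix.
#' @param baseline Baseline gene vector (default zeros).
#' @param m Riemann steps per sample (default 128).
#' @param chunk Samples per batched pass (default 8).
#' @return An `attribution_matrix`: list with `values` (samples x genes),
#'   `baseline`, `steps`, and per-sample `completeness_error`.
#' @export
attribution_matrix <- function(model, X, baseline = NULL, m = 128L,
                               chunk = 8L) {
  if (!inherits(model, "ig_scorer")) model <- as_sexnet_model(model)
  Xt <- scaled_to_xt(X)  # samples x genes
  if (is.null(baseline)) baseline <- numeric(ncol(Xt))
  if (length(baseline) != ncol(Xt)) abort("baseline length mismatch")
  if (!is_count(m)) abort("'m' must be a positive integer")
  n <- nrow(Xt)
  alphas <- (seq_len(m) - 0.5) / m
  vals <- matrix(0, n, ncol(Xt), dimnames = dimnames(Xt))
  f0 <- score_forward(model, matrix(baseline, 1L))
  comp <- numeric(n)
  for (s0 in seq(1L, n, by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, n)
    diffs <- sweep(Xt[idx, , drop = FALSE], 2L, baseline)
    # rows: sample-major blocks of m path points
    path <- do.call(rbind, lapply(seq_along(idx), function(j)
      matrix(baseline, m, ncol(Xt), byrow = TRUE) +
        outer(alphas, diffs[j, ])))
    g <- score_gradient(model, path)
    for (j in seq_along(idx)) {
      avg <- colMeans(g[(j - 1L) * m + seq_len(m), , drop = FALSE])
      vals[idx[j], ] <- diffs[j, ] * avg
    }
    f1 <- score_forward(model, Xt[idx, , drop = FALSE])
    comp[idx] <- abs(rowSums(vals[idx, , drop = FALSE]) - (f1 - f0))
  }
  structure(list(values = vals, baseline = baseline, steps = as.integer(m),
                 completeness_error = comp),
            class = "attribution_matrix")
}

#' @method print attribution_matrix
#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf(
    "attribution_matrix: %d samples x %d genes (m = %d, max completeness err %.2e)\n",
    nrow(x$values), ncol(x$values), x$steps, max(x$completeness_error)))
  invisible(x)
}

#' Group-averaged per-gene attribution scores
#'
#' The attribution score of a gene is its mean integrated-gradient value over
#' the samples of one sex group (male by default, matching the convention
#' that positive scores push the prediction toward male). Genes are returned
#' in descending score order with ties broken by gene id.
#'
#' @param attr An `attribution_matrix` (or plain samples x genes matrix).
#' @param sexes Character vector of `"male"`/`"female"` aligned with samples.
#' @param group Which group to average over: `"male"` (default), `"female"`,
#'   or `"difference"` (male mean minus female mean).
#' @return A `gene_ranking`: data.frame with columns `gene_id`, `score`,
#'   ordered by decreasing score.
#' @export
attribution_scores <- function(attr, sexes,
                               group = c("male", "female", "difference")) {
  group <- match.arg(group)
  v <- if (inherits(attr, "attribution_matrix")) attr$values else attr
  sexes <- as.character(sexes)
  if (length(sexes) != nrow(v)) abort("'sexes' length mismatch")
  grp_mean <- function(g) {
    if (!any(sexes == g)) abort("group '%s' is empty", g)
    colMeans(v[sexes == g, , drop = FALSE])
  }
  score <- switch(group,
                  male = grp_mean("male"),
                  female = grp_mean("female"),
                  difference = grp_mean("male") - grp_mean("female"))
  gene_ranking(names(score), score)
}

#' Construct a ranked gene list
#'
#' @param gene_id Character gene ids.
#' @param score Numeric scores.
#' @return `gene_ranking` data.frame sorted by decreasing score, ties broken
#'   lexicographically by gene id.
#' @export
gene_ranking <- function(gene_id, score) {
  gene_id <- as.character(gene_id)
  if (length(gene_id) != length(score)) abort("id/score length mismatch")
  if (anyDuplicated(gene_id))
    abort("duplicate gene id: %s", gene_id[duplicated(gene_id)][1L])
  o <- order(-score, gene_id)
  structure(data.frame(gene_id = gene_id[o], score = as.numeric(score)[o],
                       stringsAsFactors = FALSE),
            class = c("gene_ranking", "data.frame"))
}

#' Top-k genes of a ranking
#'
#' @param ranking A `gene_ranking`.
#' @param k How many genes (default 100, the per-cohort set size fed into the
#'   cross-cohort consensus).
#' @return Character vector of the k highest-scoring gene ids; boundary ties
#'   resolve to the lexicographically smallest ids (deterministic).
#' @export
top_k <- function(ranking, k = 100L) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (!is_count(k) || k > nrow(ranking))
    abort("'k' must be in 1..%d", nrow(ranking))
  ranking$gene_id[seq_len(k)]
}

#' Cross-set consensus (Venn decomposition)
#'
#' Given per-cohort gene sets, reports for every gene of the union which sets
#' contain it, the number of genes at each overlap degree, the count in every
#' membership region, and the full intersection.
#'
#' @param sets Named (or unnamed) list of two or more character vectors.
#' @return List with `membership` (logical gene x set data.frame),
#'   `degree_counts` (genes present in exactly d sets, d = 1..n),
#'   `region_counts` (named by binary membership pattern), and
#'   `intersection` (genes in all sets).
#' @export
consensus_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    abort("'sets' must be a list of >= 2 gene sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, 1L,
                                             dimnames = list(NULL, names(sets)))
  rownames(memb) <- universe
  degree <- rowSums(memb)
  degree_counts <- vapply(seq_along(sets), function(d) sum(degree == d), 1L)
  names(degree_counts) <- paste0("degree_", seq_along(sets))
  pattern <- apply(memb, 1L, function(r) paste(as.integer(r), collapse = ""))
  region_counts <- table(pattern)
  list(membership = as.data.frame(memb),
       degree_counts = degree_counts,
       region_counts = c(region_counts),
       intersection = universe[degree == length(sets)])
}

#' Genes present in at least `min_sets` of the input sets
#'
#' Convenience accessor over [consensus_sets()], e.g. the genes shared by at
#' least 4 of 5 per-cohort top-100 lists.
#'
#' @param sets List of character vectors.
#' @param min_sets Minimum overlap degree.
#' @return Character vector of gene ids.
#' @export
consensus_genes <- function(sets, min_sets = length(sets)) {
  cs <- consensus_sets(sets)
  rownames(cs$membership)[rowSums(cs$membership) >= min_sets]
}
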