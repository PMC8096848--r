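# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (every-offset string scans, brute-force running sums,
# explicit hand tableaux) so they stay independent of the implementation
# paths they check.

# small gene x sample matrix with dimnames
toy_matrix <- function(n_genes = 10, n_samples = 6, seed = 1, mean = 6) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = mean), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# a small trained classifier on separable data, cached per session
toy_trained_net <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(42)
    d <- 20; n <- 120
    X <- matrix(rnorm(n * d), d, n,
                dimnames = list(sprintf("g%02d", 1:d),
                                sprintf("s%03d", 1:n)))
    sex <- ifelse(X[1, ] + X[2, ] - X[3, ] + rnorm(n, sd = 0.4) > 0,
                  "male", "female")
    cfg <- net_config(total_layers = 4, hidden_width = 8, epochs = 40,
                      batch_size = 16, seed = 5)
    sc <- zscale_genes(X)
    tr <- train_classifier(build_model(d, cfg),
                           sc$values[, 1:90], sex[1:90],
                           sc$values[, 91:120], sex[91:120])
    cache <<- list(trained = tr, X = sc$values, sex = sex)
    cache
  }
})

# every-offset naive substring scan for one fixed pattern
naive_find <- function(seq, pattern) {
  L <- nchar(pattern)
  n <- nchar(seq)
  if (n < L) return(integer())
  which(vapply(seq_len(n - L + 1L),
               function(i) substr(seq, i, i + L - 1L) == pattern,
               logical(1)))
}

# naive seed-site scan: every offset for every pattern, then the same
# most-specific-wins overlap rule applied by an independent code path
naive_scan_utr <- function(seq, seed) {
  types <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  cand <- do.call(rbind, lapply(types, function(ty) {
    st <- naive_find(seq, seed$patterns[[ty]])
    if (!length(st)) return(NULL)
    data.frame(site_type = ty, start = st,
               end = st + nchar(seed$patterns[[ty]]) - 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) return(cand)
  cand <- cand[order(match(cand$site_type, types), cand$start), ]
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    clash <- FALSE
    for (j in which(keep)) {
      if (cand$start[i] <= cand$end[j] && cand$end[i] >= cand$start[j]) {
        clash <- TRUE; break
      }
    }
    keep[i] <- !clash
  }
  out <- cand[keep, ]
  out <- out[order(out$start, match(out$site_type, types)), ]
  rownames(out) <- NULL
  out
}

rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                        collapse = "")

# brute-force enrichment running sum, straight from the definition
brute_es <- function(ids_ranked, scores_ranked, gene_set, p = 1) {
  hit <- ids_ranked %in% gene_set
  w <- abs(scores_ranked[hit])^p
  if (sum(w) == 0) w <- rep(1, sum(hit))
  running <- 0
  best <- 0
  wi <- 0
  for (i in seq_along(ids_ranked)) {
    if (hit[i]) {
      wi <- wi + 1
      running <- running + w[wi] / sum(w)
    } else {
      running <- running - 1 / (length(ids_ranked) - sum(hit))
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
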