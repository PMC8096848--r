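# Synthetic multi-cohort generator. Emulates the statistical structure the
# analysis assumes: male-biased cohorts; Y-linked genes expressed only in
# males; an XIST-like female-specific stratum; X-inactivation-escape genes
# elevated in females; a hormone co-expression module (AR-like gene,
# miRNA-like gene, two host lncRNAs); proportional-hazards survival; and
# seeded UTR/promoter sequences with planted motif sites.

#' Cohort simulation configuration
#'
#' Defaults describe one simulated gastric-cancer-like cohort: 300 samples,
#' 2000 genes, a 2:1 male:female ratio (the male-biased incidence of the
#' disease), and 30 planted sex-informative genes (10 Y-linked, 10
#' XIST-like, 10 XCI-escape with a one log2-unit female shift) over a
#' Gaussian log2-intensity background with unit noise.
#'
#' @param n_samples Samples per cohort.
#' @param n_genes Total genes.
#' @param male_fraction Fraction of male samples in \[0, 1\].
#' @param n_y_linked,n_xist_like,n_xci_escape Planted gene counts.
#' @param sex_effect_size Female shift of XCI-escape genes, log2 units.
#' @param rho_ar_mir Population correlation of the AR-like and miRNA-like
#'   genes (default 0.5, the planted hormone-module coupling).
#' @param rho_host_mir Correlation of each host lncRNA with the miRNA-like
#'   gene (default 0.6).
#' @param noise_sd Per-sample Gaussian noise, log2 units.
#' @param floor_value Expression value of absent genes (Y-linked in females,
#'   XIST-like in males); defaults to 1, the simulated noise floor, rather
#'   than exact zero so downstream scaling stays well-defined.
#' @param scale `"log2"` (Gaussian intensities, default) or `"counts"`
#'   (negative-binomial counts with the log2 surface as log-mean, feeding
#'   [cpm_log_normalize()]).
#' @param seed Master seed; per-cohort child seeds derive from it via
#'   [child_seeds()].
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 300L, n_genes = 2000L,
                          male_fraction = 2 / 3,
                          n_y_linked = 10L, n_xist_like = 10L,
                          n_xci_escape = 10L,
                          sex_effect_size = 1.0,
                          rho_ar_mir = 0.5, rho_host_mir = 0.6,
                          noise_sd = 1.0, floor_value = 1.0,
                          scale = c("log2", "counts"), seed = 1L) {
  scale <- match.arg(scale)
  if (!is_count(n_samples)) abort("'n_samples' must be a positive integer")
  if (!is_count(n_genes)) abort("'n_genes' must be a positive integer")
  if (!is_number(male_fraction) || male_fraction < 0 || male_fraction > 1)
    abort("'male_fraction' must lie in [0, 1]")
  for (nm in c("n_y_linked", "n_xist_like", "n_xci_escape")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v))
      abort("'%s' must be a nonnegative integer", nm)
  }
  n_planted <- n_y_linked + n_xist_like + n_xci_escape + 4L  # + hormone module
  if (n_planted > n_genes)
    abort("planted gene counts (%d) exceed n_genes (%d)", n_planted, n_genes)
  if (!is_number(noise_sd) || noise_sd <= 0) abort("'noise_sd' must be > 0")
  if (!is_number(floor_value) || floor_value < 0)
    abort("'floor_value' must be >= 0")
  for (nm in c("rho_ar_mir", "rho_host_mir")) {
    v <- get(nm)
    if (!is_number(v) || abs(v) > 1) abort("'%s' must lie in [-1, 1]", nm)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 male_fraction = male_fraction,
                 n_y_linked = as.integer(n_y_linked),
                 n_xist_like = as.integer(n_xist_like),
                 n_xci_escape = as.integer(n_xci_escape),
                 sex_effect_size = sex_effect_size,
                 rho_ar_mir = rho_ar_mir, rho_host_mir = rho_host_mir,
                 noise_sd = noise_sd, floor_value = floor_value,
                 scale = scale, seed = as.integer(seed)),
            class = "cohort_config")
}

planted_gene_ids <- function(config) {
  list(y_linked = sprintf("Ygene%02d", seq_len(config$n_y_linked)),
       xist_like = sprintf("XISTlike%02d", seq_len(config$n_xist_like)),
       xci_escape = sprintf("XCIesc%02d", seq_len(config$n_xci_escape)),
       ar = "ARlike", mir = "MIRlike",
       hosts = c("HOSTlnc1", "HOSTlnc2"))
}

#' Generate synthetic cohorts
#'
#' Produces `n_cohorts` expression matrices sharing the same gene universe
#' and planted gene identities but with independent per-cohort noise and
#' sample labels. Planted structure per cohort: `round(male_fraction *
#' n_samples)` males; Y-linked genes at `floor_value` in every female;
#' XIST-like genes at `floor_value` in every male; XCI-escape genes shifted
#' up by `sex_effect_size` in females; and the hormone module (AR-like,
#' miRNA-like, two host lncRNAs) planted via [plant_hormone_module()].
#'
#' @param config A [cohort_config()].
#' @param n_cohorts Number of cohorts (default 5).
#' @param seed Master seed (defaults to `config$seed`).
#' @return List of cohorts, each a list with `expr` ([expression_matrix()]),
#'   `samples` ([sample_table()]), `annotation` ([gene_annotation()]).
#'   Attribute `"planted"` carries the planted gene ids.
#' @export
generate_cohorts <- function(config = cohort_config(), n_cohorts = 5L,
                             seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is_count(n_cohorts)) abort("'n_cohorts' must be >= 1")
  planted <- planted_gene_ids(config)
  n_bg <- config$n_genes - config$n_y_linked - config$n_xist_like -
    config$n_xci_escape - 4L
  gene_ids <- c(planted$y_linked, planted$xist_like, planted$xci_escape,
                planted$ar, planted$mir, planted$hosts,
                sprintf("gene%05d", seq_len(n_bg)))

  # gene-level properties are drawn once from the master seed so that all
  # cohorts share them
  set.seed(as.integer(seed))
  base_mean <- stats::runif(config$n_genes, 4, 10)
  names(base_mean) <- gene_ids
  base_mean[planted$y_linked] <- stats::runif(config$n_y_linked, 6, 9)
  base_mean[planted$xist_like] <- stats::runif(config$n_xist_like, 6, 9)
  chrom <- sample(as.character(1:22), config$n_genes, replace = TRUE)
  names(chrom) <- gene_ids
  chrom[planted$y_linked] <- "Y"
  chrom[c(planted$xist_like, planted$xci_escape, planted$ar)] <- "X"
  chrom[c(planted$mir, planted$hosts[1L])] <- "11"
  chrom[planted$hosts[2L]] <- "21"
  gclass <- rep("mRNA", config$n_genes)
  names(gclass) <- gene_ids
  gclass[c(planted$xist_like, planted$hosts)] <- "lncRNA"
  gclass[planted$mir] <- "miRNA"
  annotation <- gene_annotation(
    gene_id = gene_ids, chromosome = chrom, gene_class = gclass,
    tss = sample.int(1e8, config$n_genes),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE))

  seeds <- child_seeds(seed, n_cohorts)
  cohorts <- lapply(seq_len(n_cohorts), function(ci) {
    cs <- seeds[ci]
    set.seed(cs)
    n <- config$n_samples
    n_male <- round(config$male_fraction * n)
    sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))
    cohort_id <- sprintf("cohort%d", ci)
    sample_ids <- sprintf("%s_s%03d", cohort_id, seq_len(n))
    vals <- base_mean +
      matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
             config$n_genes, n)
    dimnames(vals) <- list(gene_ids, sample_ids)
    female <- sex == "female"
    if (config$n_y_linked)
      vals[planted$y_linked, female] <- config$floor_value
    if (config$n_xist_like)
      vals[planted$xist_like, !female] <- config$floor_value
    if (config$n_xci_escape)
      vals[planted$xci_escape, female] <-
        vals[planted$xci_escape, female] + config$sex_effect_size
    expr <- expression_matrix(vals, scale = "log2")
    expr <- plant_hormone_module(expr, ar_gene = planted$ar,
                                 mir_gene = planted$mir,
                                 host_genes = planted$hosts,
                                 rho = config$rho_ar_mir,
                                 rho_host = config$rho_host_mir,
                                 seed = cs + 1L)
    if (config$scale == "counts") {
      set.seed(cs + 2L)
      mu <- 2^expr$values
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 10),
                    nrow(mu), ncol(mu), dimnames = dimnames(mu))
      expr <- expression_matrix(cnt, scale = "counts")
    }
    list(expr = expr,
         samples = sample_table(sample_ids, sex, cohort_id),
         annotation = annotation)
  })
  attr(cohorts, "planted") <- planted
  attr(cohorts, "config") <- config
  cohorts
}

#' Plant a correlated hormone co-expression module
#'
#' Overwrites the rows of an AR-like gene, a miRNA-like gene and host lncRNA
#' genes with draws from a Gaussian model in which the AR and miRNA rows
#' have population correlation `rho` and each host row correlates with the
#' miRNA row at `rho_host` (emulating a host-gene/embedded-miRNA pair).
#' Rows are mapped onto the log2-intensity scale (mean 6, sd 1).
#'
#' @param matrix An [expression_matrix()].
#' @param ar_gene,mir_gene Gene ids present in the matrix.
#' @param host_genes Character vector of host lncRNA gene ids (may be empty).
#' @param rho AR-miRNA population correlation in \[-1, 1\].
#' @param rho_host Host-miRNA correlation (default 0.6).
#' @param seed Integer seed.
#' @return The matrix with the module rows replaced.
#' @export
plant_hormone_module <- function(matrix, ar_gene, mir_gene,
                                 host_genes = character(), rho = 0.5,
                                 rho_host = 0.6, seed = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  genes <- c(ar_gene, mir_gene, host_genes)
  miss <- setdiff(genes, matrix$gene_ids)
  if (length(miss)) abort("unknown gene id: %s", miss[1L])
  if (!is_number(rho) || abs(rho) > 1) abort("'rho' must lie in [-1, 1]")
  if (!is_number(rho_host) || abs(rho_host) > 1)
    abort("'rho_host' must lie in [-1, 1]")
  n <- ncol(matrix$values)
  set.seed(as.integer(seed))
  z_ar <- stats::rnorm(n)
  z_mir <- rho * z_ar + sqrt(1 - rho^2) * stats::rnorm(n)
  v <- matrix$values
  v[ar_gene, ] <- 6 + z_ar
  v[mir_gene, ] <- 6 + z_mir
  for (h in host_genes) {
    zh <- rho_host * z_mir + sqrt(1 - rho_host^2) * stats::rnorm(n)
    v[h, ] <- 6 + zh
  }
  out <- expression_matrix(v, scale = matrix$scale)
  out
}

#' Simulate proportional-hazards survival
#'
#' Event times are exponential with hazard `baseline_rate * exp(beta . x)`;
#' censoring is independent exponential with its rate calibrated by
#' bisection so that the realized censoring fraction hits `censor_rate`
#' within two percentage points (exactly zero censoring when
#' `censor_rate = 0`).
#'
#' @param table A [sample_table()] (or data.frame with `sample_id`).
#' @param covariate_values Numeric matrix samples x covariates (or a single
#'   vector), aligned with `table` rows.
#' @param betas Log-hazard-ratio vector, one per covariate column.
#' @param baseline_rate Baseline hazard in events/month (default 0.02).
#' @param censor_rate Target fraction censored in \[0, 1) (default 0.3).
#' @param seed Integer seed.
#' @return The input table with `time` (months) and `event` columns
#'   replaced.
#' @export
generate_survival <- function(table, covariate_values, betas,
                              baseline_rate = 0.02, censor_rate = 0.3,
                              seed = 1L) {
  stopifnot(is.data.frame(table))
  x <- if (is.matrix(covariate_values)) covariate_values
       else matrix(covariate_values, ncol = 1L)
  if (nrow(x) != nrow(table))
    abort("covariate rows (%d) must align with samples (%d)",
          nrow(x), nrow(table))
  if (length(betas) != ncol(x)) abort("'betas' length must match covariates")
  if (!is_number(baseline_rate) || baseline_rate <= 0)
    abort("'baseline_rate' must be > 0")
  if (!is_number(censor_rate) || censor_rate < 0 || censor_rate >= 1)
    abort("'censor_rate' must lie in [0, 1)")
  set.seed(as.integer(seed))
  hazard <- baseline_rate * exp(drop(x %*% betas))
  t_event <- stats::rexp(nrow(x), rate = hazard)
  if (censor_rate == 0) {
    table$time <- t_event
    table$event <- 1L
    return(table)
  }
  # bisection on the censoring rate against the realized censored fraction;
  # the uniform draws are fixed so the search is deterministic and monotone
  u <- stats::runif(nrow(x))
  frac_cens <- function(rate) mean(-log(u) / rate < t_event)
  lo <- 1e-8; hi <- 1e4 * baseline_rate
  while (frac_cens(hi) < censor_rate) hi <- hi * 10
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (frac_cens(mid) < censor_rate) lo <- mid else hi <- mid
    if (abs(frac_cens(mid) - censor_rate) <= 0.02) { lo <- hi <- mid; break }
  }
  t_cens <- -log(u) / hi
  table$time <- pmin(t_event, t_cens)
  table$event <- as.integer(t_event <= t_cens)
  table
}

# random DNA of length n from the current RNG
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate synthetic 3'-UTR sequences with planted miRNA seed sites
#'
#' Target UTRs contain exactly the requested seed-match sites (verified by
#' rescanning; sequences are rejection-sampled until no spurious site of any
#' type remains); decoy UTRs contain no seed match of any type.
#'
#' @param target_genes Character vector of target gene ids.
#' @param decoy_genes Character vector of decoy gene ids.
#' @param mirna_sequence Mature miRNA (RNA alphabet); default
#'   [MIR125B_5P].
#' @param sites_per_target Named list: for each target gene, a named integer
#'   vector of site counts by type, e.g. `c("8mer" = 1, "7mer-m8" = 1)`.
#'   Targets absent from the list get one 8mer.
#' @param utr_length UTR length in nt (default 500).
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector), `plan`
#'   (data.frame `gene_id`, `site_type`, `start`, `end`) and `seed_patterns`
#'   (the compiled `mirna_seed`).
#' @export
generate_utrs <- function(target_genes, decoy_genes,
                          mirna_sequence = MIR125B_5P,
                          sites_per_target = NULL,
                          utr_length = 500L, seed = 1L) {
  seedp <- compile_seed_patterns(mirna_sequence)
  max_pat <- max(nchar(seedp$patterns))
  if (utr_length < max_pat)
    abort("utr_length %d shorter than the longest site pattern (%d)",
          utr_length, max_pat)
  target_genes <- as.character(target_genes)
  decoy_genes <- as.character(decoy_genes)
  set.seed(as.integer(seed))
  plan_rows <- list()
  seqs <- character()

  for (g in target_genes) {
    want <- if (!is.null(sites_per_target) && g %in% names(sites_per_target))
      sites_per_target[[g]] else c("8mer" = 1L)
    bad <- setdiff(names(want), SITE_TYPES)
    if (length(bad)) abort("unknown site type '%s'", bad[1L])
    types <- rep(names(want), times = want)
    need <- sum(nchar(seedp$patterns[types]))
    if (need > utr_length)
      abort("requested sites for '%s' do not fit in utr_length %d",
            g, utr_length)
    ok <- FALSE
    for (try in 1:1000) {
      s <- random_dna(utr_length)
      # place sites at non-overlapping random positions (1 nt guard gap)
      pos <- integer(0); ends <- integer(0)
      placed <- TRUE
      for (ty in types) {
        L <- nchar(seedp$patterns[[ty]])
        cand <- setdiff(seq_len(utr_length - L + 1L), unlist(
          lapply(seq_along(pos), function(i)
            (pos[i] - L):(ends[i] + 1L))))
        if (!length(cand)) { placed <- FALSE; break }
        p <- if (length(cand) == 1L) cand else sample(cand, 1L)
        substr(s, p, p + L - 1L) <- seedp$patterns[[ty]]
        pos <- c(pos, p); ends <- c(ends, p + L - 1L)
      }
      if (!placed) next
      found <- scan_utr(s, seedp)
      wanted <- data.frame(site_type = types, start = pos,
                           stringsAsFactors = FALSE)
      wanted <- wanted[order(wanted$start), ]
      if (nrow(found) == nrow(wanted) &&
          all(found$start == wanted$start) &&
          all(found$site_type == wanted$site_type)) {
        ok <- TRUE
        seqs[g] <- s
        plan_rows[[g]] <- data.frame(
          gene_id = g, site_type = found$site_type,
          start = found$start, end = found$end, stringsAsFactors = FALSE)
        break
      }
    }
    if (!ok) abort("could not realize the site plan for '%s'", g)
  }

  for (g in decoy_genes) {
    ok <- FALSE
    for (try in 1:1000) {
      s <- random_dna(utr_length)
      if (nrow(scan_utr(s, seedp)) == 0L) { seqs[g] <- s; ok <- TRUE; break }
    }
    if (!ok) abort("could not generate decoy '%s'", g)
  }

  plan <- do.call(rbind, plan_rows)
  if (is.null(plan))
    plan <- data.frame(gene_id = character(), site_type = character(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
  rownames(plan) <- NULL
  list(sequences = seqs, plan = plan, seed_patterns = seedp)
}

#' Generate synthetic promoter sequences with planted ARE half-sites
#'
#' Upstream regions (ending at the base immediately 5' of the TSS) carrying
#' a requested number of motif half-sites on random strands, with no
#' spurious occurrences (rejection-sampled).
#'
#' @param genes Character vector of gene ids.
#' @param n_sites Integer vector (recycled) of planted sites per gene.
#' @param motif Half-site motif (default `"AGAACA"`).
#' @param span Promoter length in bases (default 2000).
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector) and `plan`
#'   (data.frame `gene_id`, `strand`, `from`, `to`).
#' @export
generate_promoters <- function(genes, n_sites = 1L, motif = "AGAACA",
                               span = 2000L, seed = 1L) {
  genes <- as.character(genes)
  n_sites <- rep_len(as.integer(n_sites), length(genes))
  set.seed(as.integer(seed))
  L <- nchar(motif)
  seqs <- character(); plans <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    for (try in 1:1000) {
      s <- random_dna(span)
      pos <- integer(0)
      placed <- TRUE
      for (k in seq_len(n_sites[gi])) {
        cand <- setdiff(seq_len(span - L + 1L),
                        unlist(lapply(pos, function(p) (p - L):(p + L))))
        if (!length(cand)) { placed <- FALSE; break }
        p <- if (length(cand) == 1L) cand else sample(cand, 1L)
        ins <- if (stats::runif(1) < 0.5) motif else dna_revcomp(motif)
        substr(s, p, p + L - 1L) <- ins
        pos <- c(pos, p)
      }
      if (!placed) next
      found <- scan_promoter_halfsites(s, motif, span)
      if (nrow(found) == n_sites[gi]) {
        seqs[g] <- s
        plans[[g]] <- cbind(gene_id = g, found[, c("strand", "from", "to")],
                            stringsAsFactors = FALSE)
        break
      }
    }
    if (!g %in% names(seqs)) abort("could not realize promoter for '%s'", g)
  }
  plan <- do.call(rbind, plans)
  rownames(plan) <- NULL
  list(sequences = seqs, plan = plan)
}
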