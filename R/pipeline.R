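# End-to-end orchestration: simulate (or load) cohorts, preprocess, train
# the sex classifier per cohort, attribute, build the cross-cohort
# consensus, run preranked GSEA, screen AR-associated differential
# expression, select survival markers by LASSO-Cox, stratify survival, and
# run the three-evidence miRNA target screen plus the promoter half-site
# scan. Every stage writes plain-text artifacts plus a manifest of MD5
# checksums so a run is reproducible bit-for-bit from its config and seed.

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions used throughout the package:
#' an 11-layer densely connected net trained for 200 epochs with a 10
#' percent validation split, top-100 attribution sets intersected across
#' cohorts, significance filter p < 0.05 with |log2FC| > 0.5, tenfold
#' cross-validated LASSO-Cox, and median/upper-quartile survival cutpoints.
#' Reduced problem sizes for a quick demonstration run are available via
#' [demo_config()].
#'
#' @param cohort A [cohort_config()].
#' @param n_cohorts Number of simulated cohorts.
#' @param net A [net_config()].
#' @param validation_fraction Held-out fraction per cohort.
#' @param ig_steps Integrated-gradient Riemann steps.
#' @param ig_chunk Samples per batched attribution pass.
#' @param attribution_group Group whose attributions are averaged.
#' @param top_k Per-cohort set size for the consensus.
#' @param min_sets Minimum overlap degree for the consensus gene list.
#' @param n_perm GSEA permutations.
#' @param gsea_weight GSEA hit-increment exponent.
#' @param de_p,de_lfc Differential-expression filter thresholds.
#' @param n_lasso_features How many top DE genes enter LASSO-Cox.
#' @param n_folds LASSO-Cox CV folds.
#' @param surv_betas Named log-hazard-ratios planted on the AR-like and
#'   miRNA-like markers when simulating survival.
#' @param baseline_rate,censor_rate Survival simulation settings.
#' @param ar_rule,mir_rule Dichotomization rules for the stratification.
#' @param mirna Mature miRNA driving the target screen.
#' @param r_threshold Inverse-correlation threshold.
#' @param n_targets,n_decoys,utr_length Target-screen simulation sizes.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), n_cohorts = 5L,
                            net = net_config(),
                            validation_fraction = 0.10,
                            ig_steps = 128L, ig_chunk = 8L,
                            attribution_group = "male",
                            top_k = 100L, min_sets = n_cohorts - 1L,
                            n_perm = 1000L, gsea_weight = 1,
                            de_p = 0.05, de_lfc = 0.5,
                            n_lasso_features = 40L, n_folds = 10L,
                            surv_betas = c(ar = log(1.45),
                                           mir = log(1.45)),
                            baseline_rate = 0.02, censor_rate = 0.3,
                            ar_rule = "median",
                            mir_rule = "upper_quartile",
                            mirna = MIR125B_5P, r_threshold = 0.3,
                            n_targets = 8L, n_decoys = 12L,
                            utr_length = 400L,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Reduced-size demonstration configuration
#'
#' Small cohorts and a narrow network so the full pipeline completes in
#' seconds; every stage still runs.
#'
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    cohort = cohort_config(n_samples = 80L, n_genes = 300L,
                           n_y_linked = 5L, n_xist_like = 5L,
                           n_xci_escape = 5L),
    n_cohorts = 2L,
    net = net_config(total_layers = 4L, hidden_width = 8L, epochs = 25L,
                     batch_size = 16L),
    ig_steps = 16L, top_k = 30L, min_sets = 2L, n_perm = 200L,
    n_lasso_features = 20L, n_folds = 5L,
    n_targets = 4L, n_decoys = 6L, utr_length = 300L,
    seed = seed)
}

#' Load a pipeline configuration from YAML (or JSON)
#'
#' Keys mirror the [pipeline_config()] arguments; `cohort` and `net` are
#' nested maps passed to [cohort_config()] / [net_config()]. Unknown keys
#' are an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$cohort)) args$cohort <- do.call(cohort_config, raw$cohort)
  if (!is.null(raw$net)) args$net <- do.call(net_config, raw$net)
  bad <- setdiff(names(args), names(formals(pipeline_config)))
  if (length(bad)) abort("unknown config key '%s'", bad[1L])
  do.call(pipeline_config, args)
}

stage_msg <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, train, attribute, consensus, GSEA,
#' differential expression, LASSO-Cox, survival stratification and the
#' target/promoter screens, writing per-stage TSV/JSON artifacts into
#' `output_dir` together with `manifest.json` (config echo, seeds, MD5
#' checksum per artifact) and a human-readable `summary.txt`.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if missing).
#' @param verbose Emit one message per stage.
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config = demo_config(), output_dir = tempfile("run"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(config$seed, 10L)
  artifacts <- character()
  emit <- function(name, writer) {
    path <- file.path(output_dir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
    path
  }

  ## -- simulate ------------------------------------------------------------
  stage_msg(verbose, "stage simulate: %d cohorts", config$n_cohorts)
  cohorts <- generate_cohorts(config$cohort, config$n_cohorts,
                              seed = seeds[1L])
  planted <- attr(cohorts, "planted")
  for (i in seq_along(cohorts)) {
    emit(sprintf("cohort%d_expression.tsv", i),
         function(p) write_expression(cohorts[[i]]$expr, p))
    emit(sprintf("cohort%d_samples.tsv", i),
         function(p) write_samples(cohorts[[i]]$samples, p))
  }
  emit("gene_annotation.tsv",
       function(p) write_annotation(cohorts[[1L]]$annotation, p))

  ## -- preprocess / train / attribute per cohort ---------------------------
  rankings <- list()
  topsets <- list()
  traces <- list()
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    expr <- co$expr
    if (expr$scale == "counts") expr <- cpm_log_normalize(expr)
    sc <- zscale_genes(expr)
    split <- split_train_validation(co$samples$sample_id,
                                    fraction = config$validation_fraction,
                                    seed = seeds[2L] + i,
                                    stratify_by = co$samples$sex)
    sexes <- stats::setNames(co$samples$sex, co$samples$sample_id)
    net <- config$net
    net$seed <- as.integer((seeds[3L] + i) %% 2147483647)
    model <- build_model(nrow(sc$values), net)
    stage_msg(verbose, "stage train: cohort %d (%d genes)", i,
              nrow(sc$values))
    trained <- train_classifier(
      model,
      sc$values[, split$train_ids, drop = FALSE], sexes[split$train_ids],
      sc$values[, split$validation_ids, drop = FALSE],
      sexes[split$validation_ids], config = net)
    traces[[i]] <- trained$validation_trace
    stage_msg(verbose, "stage attribute: cohort %d (best epoch %d)", i,
              trained$best_epoch)
    am <- attribution_matrix(trained, sc$values, m = config$ig_steps,
                             chunk = config$ig_chunk)
    rk <- attribution_scores(am, sexes[sc$sample_ids],
                             group = config$attribution_group)
    rankings[[i]] <- rk
    topsets[[i]] <- top_k(rk, config$top_k)
    emit(sprintf("cohort%d_ranking.rnk", i),
         function(p) write_rnk(rk, p))
  }
  names(topsets) <- sprintf("cohort%d", seq_along(topsets))

  ## -- consensus ------------------------------------------------------------
  cs <- consensus_sets(topsets)
  consensus <- consensus_genes(topsets, config$min_sets)
  emit("consensus_membership.tsv", function(p)
    utils::write.table(cbind(gene_id = rownames(cs$membership),
                             cs$membership),
                       p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("consensus_genes.txt", function(p) writeLines(consensus, p))

  ## -- GSEA on cohort-1 attribution scores ----------------------------------
  planted_sex <- c(planted$y_linked, planted$xist_like, planted$xci_escape)
  set.seed(seeds[4L])
  universe <- cohorts[[1L]]$expr$gene_ids
  collection <- list(
    y_linked = planted$y_linked,
    xist_like = planted$xist_like,
    xci_escape = planted$xci_escape,
    planted_sex_genes = planted_sex,
    random_setA = sample(universe, min(25L, length(universe))),
    random_setB = sample(universe, min(25L, length(universe))))
  collection <- collection[vapply(collection, length, 1L) > 0]
  emit("genesets.gmt", function(p) write_gmt(collection, p))
  gsea <- gsea_preranked(rankings[[1L]], collection,
                         n_perm = config$n_perm, seed = seeds[5L],
                         weight = config$gsea_weight)
  emit("gsea_results.tsv", function(p)
    utils::write.table(gsea, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  ## -- AR-associated differential expression (cohort 1) ---------------------
  co1 <- cohorts[[1L]]
  expr1 <- if (co1$expr$scale == "counts") cpm_log_normalize(co1$expr)
           else co1$expr
  ar_split <- dichotomize(expr1$values[planted$ar, ], config$ar_rule)
  de <- group_de(expr1, ar_split$labels)
  degs <- deg_filter(de, config$de_p, config$de_lfc)
  emit("de_table.tsv", function(p)
    utils::write.table(de, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("deg_list.txt", function(p) writeLines(degs, p))

  ## -- survival: simulate, LASSO-Cox selection, stratification --------------
  stage_msg(verbose, "stage survival")
  ar_vals <- expr1$values[planted$ar, ]
  mir_vals <- expr1$values[planted$mir, ]
  covars <- cbind(ar = as.numeric(scale(ar_vals)),
                  mir = as.numeric(scale(mir_vals)))
  surv_tab <- generate_survival(co1$samples, covars,
                                betas = config$surv_betas[c("ar", "mir")],
                                baseline_rate = config$baseline_rate,
                                censor_rate = config$censor_rate,
                                seed = seeds[6L])
  # candidate features: the planted markers plus the top AR-associated DE
  # genes, up to n_lasso_features
  cand <- de[order(de$pval), ]
  cand_genes <- utils::head(
    union(c(planted$ar, planted$mir), cand$gene_id),
    config$n_lasso_features)
  feat <- t(expr1$values[cand_genes, , drop = FALSE])
  lasso <- lasso_cox(surv_tab, feat, n_folds = config$n_folds,
                     seed = seeds[7L])
  cox_uni <- cox_fit(cbind(surv_tab, ar = covars[, "ar"]), "ar")
  cox_multi <- cox_fit(cbind(surv_tab, ar = covars[, "ar"],
                             mir = covars[, "mir"]), c("ar", "mir"))
  strat <- combo_stratify(ar_vals, mir_vals, config$ar_rule,
                          config$mir_rule)
  lr_merged <- logrank_test(surv_tab, strat$merged)
  km_high <- km_estimate(surv_tab[strat$merged == "both_high", ])
  km_other <- km_estimate(surv_tab[strat$merged == "other", ])
  emit("survival_table.tsv", function(p) write_samples(surv_tab, p))
  emit("cox_fits.json", function(p)
    jsonlite::write_json(list(univariate = cox_uni$table,
                              multivariate = cox_multi$table,
                              converged = cox_multi$converged), p,
                         auto_unbox = TRUE, digits = 10))
  emit("lasso_selected.json", function(p)
    jsonlite::write_json(list(selected = lasso$selected,
                              lambda_opt = lasso$lambda_opt), p,
                         auto_unbox = TRUE, digits = 10))
  emit("stratification.tsv", function(p)
    utils::write.table(
      data.frame(sample_id = surv_tab$sample_id,
                 four_group = strat$four_group, merged = strat$merged),
      p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## -- target screen ---------------------------------------------------------
  stage_msg(verbose, "stage targets")
  target_ids <- sprintf("TARGET%02d", seq_len(config$n_targets))
  decoy_ids <- sprintf("DECOY%02d", seq_len(config$n_decoys))
  utrs <- generate_utrs(target_ids, decoy_ids, config$mirna,
                        utr_length = config$utr_length, seed = seeds[8L])
  emit("utrs.fasta", function(p) write_sequences(utrs$sequences, p))
  seedp <- compile_seed_patterns(config$mirna)
  sites <- scan_utr_set(utrs$sequences, seedp)
  predicted <- unique(sites$gene_id)
  # patient evidence: targets planted inversely correlated with the miRNA
  pat <- plant_inverse_targets(
    expand_with_genes(expr1, c(target_ids, decoy_ids), seed = seeds[9L]),
    target_ids, planted$mir, rho = -0.5, seed = seeds[9L])
  patient_inverse <- inverse_targets(pat$values[planted$mir, ], pat,
                                     r_threshold = config$r_threshold)
  # transfection evidence: mimic-vs-control experiment with targets knocked
  # down by one log2 unit
  trans <- simulate_transfection(c(target_ids, decoy_ids),
                                 down_genes = target_ids,
                                 seed = seeds[10L])
  de_trans <- group_de(trans$expr, trans$group)
  trans_down <- de_trans$gene_id[de_trans$pval < config$de_p &
                                   de_trans$logFC < 0]
  evidence <- integrate_evidence(predicted, trans_down, patient_inverse)
  emit("target_sites.tsv", function(p)
    utils::write.table(sites, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("target_evidence.json", function(p)
    jsonlite::write_json(list(predicted = evidence$predicted,
                              transfection_down = evidence$transfection_down,
                              patient_inverse = evidence$patient_inverse,
                              final = evidence$final,
                              region_counts =
                                as.list(evidence$region_counts)),
                         p, auto_unbox = TRUE))

  ## -- promoter half-site scan ----------------------------------------------
  promoters <- generate_promoters(c("MIR_prom1", "MIR_prom2"),
                                  n_sites = c(1L, 3L), seed = seeds[10L] + 1L)
  are <- do.call(rbind, lapply(names(promoters$sequences), function(g)
    cbind(gene_id = g,
          scan_promoter_halfsites(promoters$sequences[[g]]),
          stringsAsFactors = FALSE)))
  emit("promoters.fasta", function(p) write_sequences(promoters$sequences, p))
  emit("are_sites.tsv", function(p)
    utils::write.table(are, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## -- manifest & summary ----------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("sexnet")),
    seed = config$seed,
    stage_seeds = seeds,
    config_hash = unname(tools::md5sum(
      emit("config_echo.json", function(p)
        jsonlite::write_json(config_as_list(config), p, auto_unbox = TRUE,
                             digits = 10)))),
    artifacts = stats::setNames(as.list(unname(tools::md5sum(artifacts))),
                                basename(artifacts)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  summary_lines <- c(
    sprintf("cohorts: %d x %d samples, %d genes", config$n_cohorts,
            config$cohort$n_samples, config$cohort$n_genes),
    sprintf("consensus (>= %d/%d cohorts): %d genes", config$min_sets,
            config$n_cohorts, length(consensus)),
    sprintf("planted sex genes recovered in consensus: %d / %d",
            length(intersect(consensus, planted_sex)), length(planted_sex)),
    sprintf("DE genes past filter: %d", length(degs)),
    sprintf("LASSO-Cox selected: %s", paste(lasso$selected, collapse = ", ")),
    sprintf("merged-stratification log-rank p: %.4g", lr_merged$p),
    sprintf("final miRNA targets: %d", length(evidence$final)),
    sprintf("ARE half-sites found: %d", nrow(are)))
  writeLines(summary_lines, file.path(output_dir, "summary.txt"))

  invisible(list(cohorts = cohorts, rankings = rankings, topsets = topsets,
                 consensus = consensus, gsea = gsea, de = de, degs = degs,
                 surv = surv_tab, lasso = lasso, cox_uni = cox_uni,
                 cox_multi = cox_multi, strat = strat,
                 logrank_merged = lr_merged, km = list(high = km_high,
                                                       other = km_other),
                 evidence = evidence, are = are, traces = traces,
                 manifest = manifest, output_dir = output_dir))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$cohort <- unclass(out$cohort)
  out$net <- unclass(out$net)
  out
}

# Append fresh noise rows for extra gene ids to an expression matrix (used
# to host the planted miRNA targets in the patient-evidence stage).
expand_with_genes <- function(expr, new_genes, seed = 1L) {
  stopifnot(inherits(expr, "expr_matrix"))
  new_genes <- setdiff(new_genes, expr$gene_ids)
  if (!length(new_genes)) return(expr)
  set.seed(as.integer(seed))
  add <- matrix(stats::rnorm(length(new_genes) * ncol(expr$values),
                             mean = 6), length(new_genes),
                ncol(expr$values),
                dimnames = list(new_genes, expr$sample_ids))
  expression_matrix(rbind(expr$values, add), expr$scale)
}

#' Plant genes inversely correlated with the miRNA-like gene
#'
#' Overwrites the given gene rows so that each has population correlation
#' `rho` (negative for repression targets) with the miRNA-like row,
#' emulating target down-regulation in patient data.
#'
#' @param matrix An [expression_matrix()] containing `mir_gene` and `genes`.
#' @param genes Gene ids to overwrite.
#' @param mir_gene The miRNA-like gene id.
#' @param rho Population correlation (default -0.5).
#' @param seed Integer seed.
#' @return The modified matrix.
#' @export
plant_inverse_targets <- function(matrix, genes, mir_gene, rho = -0.5,
                                  seed = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  miss <- setdiff(c(genes, mir_gene), matrix$gene_ids)
  if (length(miss)) abort("unknown gene id: %s", miss[1L])
  if (!is_number(rho) || abs(rho) > 1) abort("'rho' must lie in [-1, 1]")
  set.seed(as.integer(seed))
  v <- matrix$values
  zm <- as.numeric(scale(v[mir_gene, ]))
  for (g in genes)
    v[g, ] <- 6 + rho * zm + sqrt(1 - rho^2) * stats::rnorm(ncol(v))
  expression_matrix(v, matrix$scale)
}

# Tiny mimic-vs-control transfection experiment: down_genes are shifted down
# by one log2 unit in the mimic group.
simulate_transfection <- function(genes, down_genes, n_per_group = 6L,
                                  effect = 1.0, noise_sd = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  n <- 2L * n_per_group
  v <- matrix(stats::rnorm(length(genes) * n, mean = 6, sd = noise_sd),
              length(genes), n,
              dimnames = list(genes,
                              sprintf("t_s%02d", seq_len(n))))
  group <- rep(c("control", "mimic"), each = n_per_group)
  v[down_genes, group == "mimic"] <- v[down_genes, group == "mimic"] - effect
  list(expr = expression_matrix(v, "log2"), group = group)
}
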