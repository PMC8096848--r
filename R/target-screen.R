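# miRNA seed-pattern compilation, 3'-UTR site scanning, inverse-correlation
# filtering, three-evidence target integration, and ARE half-site scanning
# of promoter sequences.

#' Mature miR-125b-5p sequence
#'
#' Shipped as a convenience default for the target screen. External
#' knowledge: this is the miRBase mature sequence for hsa-miR-125b-5p
#' (MIMAT0000423), not a value derived inside this package.
#' @export
MIR125B_5P <- "UCCCUGAGACCCUAACUUGUGA"

# Reverse complement of an RNA fragment, written in DNA alphabet.
rna_revcomp_dna <- function(s) {
  comp <- chartr("ACGU", "TGCA", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

dna_revcomp <- function(s) {
  comp <- chartr("ACGT", "TGCA", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Site types from most to least specific; overlap resolution follows this
# order.
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Compile canonical seed-match site patterns for a miRNA
#'
#' The seed is miRNA positions 2-8 (5' to 3'). Site patterns are the DNA
#' reverse complements found in target 3'-UTRs: `7mer-m8` pairs seed
#' positions 2-8; `8mer` is the 7mer-m8 followed by an adenine opposite
#' position 1; `6mer` pairs positions 2-7; `7mer-A1` is the 6mer followed by
#' the position-1 adenine.
#'
#' @param mirna_seq Mature miRNA sequence, RNA alphabet (ACGU), length >= 8.
#' @return A `mirna_seed`: list with `mature`, `seed` (positions 2-8) and
#'   `patterns` (named DNA strings for the four site types).
#' @examples
#' compile_seed_patterns("UAGCUUAUCAGACUGAUGUUGA")$patterns
#' @export
compile_seed_patterns <- function(mirna_seq) {
  mirna_seq <- toupper(as.character(mirna_seq))
  if (nchar(mirna_seq) < 8L) abort("miRNA sequence must be >= 8 nt")
  if (grepl("[^ACGU]", mirna_seq))
    abort("miRNA sequence must use the RNA alphabet ACGU")
  seed28 <- substr(mirna_seq, 2L, 8L)
  seed27 <- substr(mirna_seq, 2L, 7L)
  m8 <- rna_revcomp_dna(seed28)
  six <- rna_revcomp_dna(seed27)
  patterns <- c("8mer" = paste0(m8, "A"),
                "7mer-m8" = m8,
                "7mer-A1" = paste0(six, "A"),
                "6mer" = six)
  structure(list(mature = mirna_seq, seed = seed28, patterns = patterns),
            class = "mirna_seed")
}

# All (possibly overlapping) start positions of a fixed pattern; uses
# Biostrings so overlapping self-matches are reported.
match_positions <- function(seq, pattern) {
  Biostrings::start(Biostrings::matchPattern(pattern,
                                             Biostrings::DNAString(seq)))
}

#' Scan a 3'-UTR for miRNA seed-match sites
#'
#' Reports every occurrence of the four canonical site types; where
#' occurrences overlap, only the most specific type is kept
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer; earlier-starting sites win within a
#' type). Positions are 1-based inclusive.
#'
#' @param utr_seq DNA string (ACGT, case-insensitive).
#' @param seed A `mirna_seed` from [compile_seed_patterns()].
#' @param site_types Which site types to report (default all four).
#' @return data.frame with `site_type`, `start`, `end`, `match`; zero rows
#'   if no site occurs.
#' @export
scan_utr <- function(utr_seq, seed, site_types = SITE_TYPES) {
  stopifnot(inherits(seed, "mirna_seed"))
  utr_seq <- toupper(as.character(utr_seq))
  if (grepl("[^ACGT]", utr_seq)) abort("UTR sequence must use ACGT")
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  cand <- do.call(rbind, lapply(SITE_TYPES, function(ty) {
    pat <- seed$patterns[[ty]]
    if (nchar(utr_seq) < nchar(pat)) return(NULL)
    st <- match_positions(utr_seq, pat)
    if (!length(st)) return(NULL)
    data.frame(site_type = ty, start = st, end = st + nchar(pat) - 1L,
               match = pat, stringsAsFactors = FALSE)
  }))
  empty <- data.frame(site_type = character(), start = integer(),
                      end = integer(), match = character(),
                      stringsAsFactors = FALSE)
  if (is.null(cand)) return(empty)
  # greedy overlap resolution in specificity order, then position
  cand <- cand[order(match(cand$site_type, SITE_TYPES), cand$start), ]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    overlaps <- kept & cand$start <= cand$end[i] & cand$end >= cand$start[i]
    if (!any(overlaps)) kept[i] <- TRUE
  }
  out <- cand[kept & cand$site_type %in% site_types, , drop = FALSE]
  out <- out[order(out$start, match(out$site_type, SITE_TYPES)), ]
  rownames(out) <- NULL
  out
}

#' Scan a set of UTRs
#'
#' @param utrs Named character vector (or `DNAStringSet`) of UTR sequences.
#' @param seed A `mirna_seed`.
#' @param site_types Site types to report.
#' @return data.frame with `gene_id` plus the [scan_utr()] columns.
#' @export
scan_utr_set <- function(utrs, seed, site_types = SITE_TYPES) {
  if (inherits(utrs, "DNAStringSet")) utrs <- as.character(utrs)
  if (is.null(names(utrs))) abort("'utrs' must be named by gene id")
  res <- lapply(names(utrs), function(g) {
    df <- scan_utr(utrs[[g]], seed, site_types)
    if (nrow(df)) cbind(gene_id = g, df, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(), site_type = character(),
                      start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genes inversely correlated with a miRNA
#'
#' @param mir_expr Numeric vector of miRNA expression across samples.
#' @param gene_matrix `expr_matrix` (or gene x sample matrix) over the same
#'   samples, in the same order.
#' @param r_threshold Positive threshold in (0, 1); genes with Pearson
#'   r < -r_threshold are returned.
#' @return Character vector of gene ids.
#' @export
inverse_targets <- function(mir_expr, gene_matrix, r_threshold = 0.3) {
  v <- as_expr_values(gene_matrix)
  if (length(mir_expr) != ncol(v))
    abort("miRNA vector length %d does not match %d samples",
          length(mir_expr), ncol(v))
  if (!is.null(names(mir_expr)) && !is.null(colnames(v)) &&
      !identical(names(mir_expr), colnames(v)))
    abort("sample ids of 'mir_expr' and 'gene_matrix' disagree")
  if (!is_number(r_threshold) || r_threshold <= 0 || r_threshold >= 1)
    abort("'r_threshold' must lie in (0, 1)")
  r <- suppressWarnings(as.numeric(stats::cor(t(v), mir_expr)))
  rownames(v)[!is.na(r) & r < -r_threshold]
}

#' Three-evidence target integration
#'
#' Intersects the predicted-site genes, the genes down-regulated after miRNA
#' mimic transfection, and the genes inversely correlated with the miRNA in
#' patient samples; the triple intersection is the final target list.
#'
#' @param predicted,transfection_down,patient_inverse Character gene sets.
#' @return An `evidence_sets`: the three sets, `final` (triple
#'   intersection), and `region_counts` over all membership patterns of the
#'   union.
#' @export
integrate_evidence <- function(predicted, transfection_down,
                               patient_inverse) {
  sets <- list(predicted = unique(as.character(predicted)),
               transfection_down = unique(as.character(transfection_down)),
               patient_inverse = unique(as.character(patient_inverse)))
  cs <- consensus_sets(sets)
  structure(c(sets,
              list(final = cs$intersection,
                   region_counts = cs$region_counts,
                   membership = cs$membership)),
            class = "evidence_sets")
}

#' @method print evidence_sets
#' @export
print.evidence_sets <- function(x, ...) {
  cat(sprintf(
    "evidence_sets: predicted %d, transfection_down %d, patient_inverse %d -> final %d\n",
    length(x$predicted), length(x$transfection_down),
    length(x$patient_inverse), length(x$final)))
  invisible(x)
}

#' Scan a promoter for ARE half-sites
#'
#' Searches the region upstream of a transcription start site for the
#' androgen-response-element half-site motif (default `AGAACA`) on both
#' strands; a reverse-strand occurrence is a forward occurrence of the
#' motif's reverse complement (`TGTTCT`). The input sequence is the upstream
#' region ending at the base immediately 5' of the TSS; sequences longer
#' than `span` are truncated (with a warning) to the `span` bases nearest
#' the TSS. Coordinates are upstream offsets: -1 is the base immediately
#' before the TSS, and each site is reported as the pair -a/-b with |a| <
#' |b| spanning the motif.
#'
#' @param promoter_seq DNA string (ACGT, case-insensitive).
#' @param motif Half-site motif (default `"AGAACA"`).
#' @param span Maximum upstream span in bases (default 2000).
#' @return data.frame with `strand` (`+`/`-`), `from` (offset nearest the
#'   TSS, -a), `to` (offset furthest, -b), `label` (`"-a/-b"`), `match`;
#'   rows in left-to-right (most upstream first) order.
#' @export
scan_promoter_halfsites <- function(promoter_seq, motif = "AGAACA",
                                    span = 2000L) {
  promoter_seq <- toupper(as.character(promoter_seq))
  if (grepl("[^ACGT]", promoter_seq)) abort("promoter sequence must use ACGT")
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) abort("motif must use ACGT")
  n <- nchar(promoter_seq)
  if (n > span) {
    warning(sprintf("promoter longer than span (%d > %d); keeping the %d bases nearest the TSS",
                    n, span, span), call. = FALSE)
    promoter_seq <- substr(promoter_seq, n - span + 1L, n)
    n <- as.integer(span)
  }
  L <- nchar(motif)
  fwd <- match_positions(promoter_seq, motif)
  rev <- match_positions(promoter_seq, dna_revcomp(motif))
  hits <- data.frame(strand = c(rep("+", length(fwd)),
                                rep("-", length(rev))),
                     i = c(fwd, rev), stringsAsFactors = FALSE)
  hits <- hits[order(hits$i, hits$strand), , drop = FALSE]
  from <- -(n - (hits$i + L - 1L) + 1L)  # offset of the 3'-most base, -a
  to <- -(n - hits$i + 1L)
  out <- data.frame(strand = hits$strand, from = from, to = to,
                    label = sprintf("%d/%d", from, to),
                    match = substr(rep(promoter_seq, nrow(hits)),
                                   hits$i, hits$i + L - 1L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
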