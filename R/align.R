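## Pairwise alignment engine: optimal global (Needleman-Wunsch) and local
## (Smith-Waterman) alignment with affine gaps, percent identity under
## selectable denominators, and a Karlin-Altschul e-value approximation.

.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Scoring schemes for pairwise alignment
#'
#' Protein default: BLOSUM62 with gap open 11 / extend 1 (blastp defaults).
#' Nucleotide default: match +2 / mismatch -3, gap open 5 / extend 2
#' (blastn defaults). A gap of length L costs open + extend * L.
#' `lambda` and `K` are the Karlin-Altschul parameters used for e-values;
#' the protein defaults are the standard gapped BLOSUM62-11-1 constants.
#'
#' @param matrix substitution matrix with residue dimnames; default BLOSUM62.
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @param lambda,K Karlin-Altschul constants.
#' @param match,mismatch nucleotide match/mismatch scores.
#' @return list of class `scoring_scheme`.
#' @export
aa_scoring <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                       lambda = 0.267, K = 0.041) {
  structure(list(type = "aa",
                 matrix = if (is.null(matrix)) .blosum62() else matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @rdname aa_scoring
#' @export
nt_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                       gap_extend = 2, lambda = 0.625, K = 0.41) {
  structure(list(type = "nt", match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Read an NCBI-format substitution matrix file
#'
#' Plain-text square matrix with '#' comments, a header row of residue
#' letters and one labelled row per residue.
#'
#' @param path matrix file.
#' @return numeric matrix with residue dimnames, usable in [aa_scoring()].
#' @export
read_score_matrix <- function(path) {
  lines <- grep("^\\s*#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cols))))
  dimnames(m) <- list(vapply(rows, `[[`, "", 1), cols)
  m
}

.seq_of <- function(x) {
  if (inherits(x, "data.frame")) {
    stopifnot(nrow(x) == 1)
    x$seq
  } else as.character(x)
}

.id_of <- function(x, default) {
  if (inherits(x, "data.frame")) x$id else default
}

# rare residues absent from BLOSUM62 are scored as X
.sanitize_aa <- function(s) chartr("JUO", "XXX", toupper(s))
.sanitize_nt <- function(s) {
  s <- chartr("U", "T", toupper(s))
  gsub("[RYSWKMBDHV]", "N", s)
}

.align_raw <- function(sa, sb, scoring, local) {
  if (scoring$type == "aa") {
    if (grepl(paste0("[^", .ALPHA_AA, "]"), sa) ||
        grepl(paste0("[^", .ALPHA_AA, "]"), sb))
      stop("sequence is not protein under an amino-acid scoring scheme")
    align_pair_cpp(.sanitize_aa(sa), .sanitize_aa(sb), scoring$matrix,
                   scoring$gap_open, scoring$gap_extend, local)
  } else {
    if (grepl(paste0("[^", .ALPHA_NT, "]"), sa) ||
        grepl(paste0("[^", .ALPHA_NT, "]"), sb))
      stop("sequence is not nucleotide under a nucleotide scoring scheme")
    align_pair_nt_cpp(.sanitize_nt(sa), .sanitize_nt(sb), scoring$match,
                      scoring$mismatch, scoring$gap_open, scoring$gap_extend,
                      local)
  }
}

#' Percent identity under an explicit denominator policy
#'
#' `"shorter"` divides matches by the length of the shorter sequence (the
#' CD-HIT convention, used for clustering and LinA typing); `"alignment"`
#' divides by alignment length including gap columns (the BLAST convention,
#' used for local screening hits). Values are kept at full precision;
#' report formatting rounds to 1 decimal place.
#'
#' @param matches number of identical aligned residues.
#' @param denominator_policy `"shorter"` or `"alignment"`.
#' @param len_a,len_b sequence lengths (for `"shorter"`).
#' @param aln_len alignment length (for `"alignment"`).
#' @return identity percentage in `[0, 100]`.
#' @export
percent_identity <- function(matches,
                             denominator_policy = c("shorter", "alignment"),
                             len_a = NULL, len_b = NULL, aln_len = NULL) {
  denominator_policy <- match.arg(denominator_policy)
  den <- if (denominator_policy == "shorter") min(len_a, len_b) else aln_len
  if (is.null(den) || length(den) == 0 || is.na(den))
    stop("missing denominator for policy ", denominator_policy)
  if (den == 0) stop("zero denominator in percent identity")
  if (matches > den && denominator_policy == "alignment")
    stop("matches exceed alignment length")
  100 * matches / den
}

#' Karlin-Altschul e-value
#'
#' E = K * m * n * exp(-lambda * S). An approximation adequate for
#' thresholding (the screening stages only gate on e-value); not a
#' substitute for composition-adjusted BLAST statistics.
#'
#' @param score alignment raw score S.
#' @param m query length (residues).
#' @param n database size (total residues searched).
#' @param lambda,K Karlin-Altschul constants.
#' @return expected number of chance hits at or above `score`.
#' @export
karlin_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

.aln_result <- function(raw, qid, sid, mode, len_a, len_b, id_policy,
                        evalue = NA_real_) {
  identity <- if (raw$aln_len == 0) 0 else
    percent_identity(raw$matches, id_policy, len_a = len_a, len_b = len_b,
                     aln_len = raw$aln_len)
  qcov <- if (mode == "global") 100 else
    if (raw$aln_len == 0) 0 else 100 * (raw$a_end - raw$a_start + 1) / len_a
  scov <- if (mode == "global") 100 else
    if (raw$aln_len == 0) 0 else 100 * (raw$b_end - raw$b_start + 1) / len_b
  structure(list(query_id = qid, subject_id = sid, mode = mode,
                 matches = raw$matches, aln_len = raw$aln_len,
                 identity_pct = identity, score = raw$score,
                 query_cov = qcov, subject_cov = scov, evalue = evalue,
                 aligned_query = raw$aligned_a,
                 aligned_subject = raw$aligned_b,
                 query_range = c(raw$a_start, raw$a_end),
                 subject_range = c(raw$b_start, raw$b_end)),
            class = "alignment_result")
}

#' Optimal global pairwise alignment
#'
#' End-to-end Needleman-Wunsch with affine gaps (Gotoh). Equal-scoring
#' tracebacks are broken deterministically (diagonal, then up, then left).
#'
#' @param a,b sequences: plain strings or single-row [seq_records()].
#' @param scoring an [aa_scoring()] or [nt_scoring()] scheme.
#' @param id_policy identity denominator, see [percent_identity()];
#'   global alignments default to the shorter-sequence convention.
#' @return `alignment_result` with score, matches, identity, coverage.
#' @export
align_global <- function(a, b, scoring = aa_scoring(),
                         id_policy = "shorter") {
  sa <- .seq_of(a); sb <- .seq_of(b)
  raw <- .align_raw(sa, sb, scoring, local = FALSE)
  .aln_result(raw, .id_of(a, "query"), .id_of(b, "subject"), "global",
              nchar(sa), nchar(sb), id_policy)
}

#' Optimal local pairwise alignment with an e-value estimate
#'
#' Smith-Waterman with affine gaps; the e-value is computed from the raw
#' score, the query length and `db_size` via [karlin_evalue()].
#'
#' @inheritParams align_global
#' @param db_size search-space size in residues; defaults to the subject
#'   length (single-sequence search).
#' @param id_policy local hits default to the alignment-length convention.
#' @return `alignment_result` including `evalue`.
#' @export
align_local <- function(a, b, scoring = aa_scoring(), db_size = NULL,
                        id_policy = "alignment") {
  sa <- .seq_of(a); sb <- .seq_of(b)
  raw <- .align_raw(sa, sb, scoring, local = TRUE)
  if (is.null(db_size)) db_size <- nchar(sb)
  ev <- karlin_evalue(raw$score, nchar(sa), db_size, scoring$lambda,
                      scoring$K)
  .aln_result(raw, .id_of(a, "query"), .id_of(b, "subject"), "local",
              nchar(sa), nchar(sb), id_policy, evalue = ev)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment %s vs %s: score %.1f, identity %.1f%% (%d/%d)",
              x$mode, x$query_id, x$subject_id, x$score, x$identity_pct,
              x$matches, x$aln_len))
  if (!is.na(x$evalue)) cat(sprintf(", e-value %.2g", x$evalue))
  cat("\n")
  invisible(x)
}
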