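## Whole-genome average nucleotide identity (ANIb style: chop the query
## into ~1020-bp fragments, align each to the subject, average identities
## of fragments passing the 30% identity / 70% coverage gates) and
## whole-proteome average amino acid identity over reciprocal best hits.

#' Chop a genome into consecutive fragments
#'
#' Non-overlapping windows per replicon; the terminal remainder is kept
#' only when it is at least half the fragment length.
#'
#' @param asm a [genome_assembly()].
#' @param fragment_len window size in bp (>= 100; default 1020, the
#'   Goris/Richter ANIb convention).
#' @return a [seq_records()] set; ids are `replicon:start-end` (1-based).
#' @export
fragment_genome <- function(asm, fragment_len = 1020) {
  stopifnot(inherits(asm, "genome_assembly"), fragment_len >= 100)
  ids <- character(0); seqs <- character(0)
  for (rid in names(asm$replicons)) {
    s <- asm$replicons[[rid]]
    L <- nchar(s)
    starts <- seq(1, L, by = fragment_len)
    for (st in starts) {
      en <- min(st + fragment_len - 1, L)
      if (en - st + 1 < fragment_len && en - st + 1 < fragment_len / 2) next
      ids <- c(ids, sprintf("%s:%d-%d", rid, st, en))
      seqs <- c(seqs, substr(s, st, en))
    }
  }
  seq_records(ids, seqs, genome_id = asm$genome_id)
}

#' Fragment-based average nucleotide identity (ANIb style)
#'
#' The query genome is fragmented ([fragment_genome()]); each fragment is
#' mapped onto the subject with exact-word seeds (both strands) and then
#' locally aligned to its best-voted subject window. A fragment is used
#' iff its best alignment has identity >= `min_identity` over >=
#' `min_coverage` of its length; the reported ANI is the mean identity of
#' used fragments. Directionality is query -> subject; average the two
#' directions for a symmetric report.
#'
#' @param query,subject [genome_assembly()] objects (nucleotide).
#' @param fragment_len fragment size (default 1020 bp).
#' @param min_identity,min_coverage fragment acceptance gates (defaults
#'   30 and 70, the Goris/Richter convention).
#' @param seed_k exact-word seed length for candidate window location.
#' @param scoring nucleotide scoring ([nt_scoring()]).
#' @return object of class `ani_result`: `ani_pct` (NA when no fragment
#'   is usable, never 0), `n_fragments_total`, `n_fragments_used`,
#'   `aligned_fraction`, per-fragment table in `$fragments`.
#' @export
anib <- function(query, subject, fragment_len = 1020, min_identity = 30,
                 min_coverage = 70, seed_k = 15, scoring = nt_scoring()) {
  stopifnot(inherits(query, "genome_assembly"),
            inherits(subject, "genome_assembly"))
  frags <- fragment_genome(query, fragment_len)
  subj <- paste(chartr("U", "T", toupper(subject$replicons)),
                collapse = strrep("N", seed_k))
  map <- anib_map_cpp(frags$seq, subj, seed_k, 150L, scoring$match,
                      scoring$mismatch, scoring$gap_open,
                      scoring$gap_extend)
  used <- !is.na(map$identity) & map$identity >= min_identity &
    map$frag_cov >= min_coverage
  ani <- if (any(used)) mean(map$identity[used]) else NA_real_
  total_bp <- sum(nchar(frags$seq))
  aligned_bp <- sum(nchar(frags$seq)[used] * map$frag_cov[used] / 100)
  structure(list(query_genome = query$genome_id,
                 subject_genome = subject$genome_id,
                 ani_pct = ani, n_fragments_total = nrow(map),
                 n_fragments_used = sum(used),
                 aligned_fraction = aligned_bp / total_bp,
                 fragments = cbind(data.frame(fragment = frags$id,
                                              stringsAsFactors = FALSE),
                                   map, used = used)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s -> %s: %s%% over %d/%d fragments (aligned fraction %.2f)\n",
              x$query_genome, x$subject_genome,
              if (is.na(x$ani_pct)) "NA" else sprintf("%.1f", x$ani_pct),
              x$n_fragments_used, x$n_fragments_total, x$aligned_fraction))
  invisible(x)
}

#' Pairwise ANI matrices for a set of genomes
#'
#' @param assemblies list of [genome_assembly()] objects.
#' @param ... passed to [anib()].
#' @return list with one-way `ani` matrix (rows = query), symmetrized
#'   `ani_mean`, and `aligned_fraction`.
#' @export
ani_matrix <- function(assemblies, ...) {
  ids <- vapply(assemblies, `[[`, "", "genome_id")
  n <- length(ids)
  A <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  AF <- A
  diag(A) <- 100
  diag(AF) <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- anib(assemblies[[i]], assemblies[[j]], ...)
    A[i, j] <- r$ani_pct
    AF[i, j] <- r$aligned_fraction
  }
  list(ani = A, ani_mean = (A + t(A)) / 2, aligned_fraction = AF)
}

# best eligible hit of each query in a score table; ties broken by subject
# id (radix order) for determinism
.best_hits <- function(tab, from, to) {
  tab <- tab[tab$eligible, , drop = FALSE]
  if (nrow(tab) == 0) return(setNames(character(0), character(0)))
  o <- order(tab[[from]], -tab$score, tab[[to]], method = "radix")
  tab <- tab[o, , drop = FALSE]
  keep <- !duplicated(tab[[from]])
  setNames(tab[[to]][keep], tab[[from]][keep])
}

#' Average amino acid identity via reciprocal best hits
#'
#' All query-by-subject local alignments are computed once per unordered
#' pair; a hit is eligible when e-value <= `evalue_max`, identity >=
#' `identity_min` and the alignment covers >= `coverage_min` of the
#' shorter protein (CompareM-style defaults). AAI is the mean identity
#' (alignment-length denominator) over reciprocal best-hit pairs and is
#' symmetric by construction.
#'
#' @param protA,protB non-empty [seq_records()] proteomes.
#' @param evalue_max,identity_min,coverage_min eligibility gates.
#' @param scoring protein scoring scheme.
#' @return object of class `aai_result`: `aai_pct` (NA when no RBH pair,
#'   never 0), `n_rbh_pairs`, the `pairs` table.
#' @export
aai <- function(protA, protB, evalue_max = 1e-3, identity_min = 30,
                coverage_min = 70, scoring = aa_scoring()) {
  if (nrow(protA) == 0 || nrow(protB) == 0) stop("empty proteome")
  dbA <- sum(nchar(protA$seq)); dbB <- sum(nchar(protB$seq))
  rows <- vector("list", nrow(protA) * nrow(protB))
  r <- 0L
  for (i in seq_len(nrow(protA))) for (j in seq_len(nrow(protB))) {
    raw <- .align_raw(protA$seq[i], protB$seq[j], scoring, local = TRUE)
    r <- r + 1L
    la <- nchar(protA$seq[i]); lb <- nchar(protB$seq[j])
    ident <- if (raw$aln_len == 0) 0 else 100 * raw$matches / raw$aln_len
    cov_short <- if (raw$aln_len == 0) 0 else
      100 * min(raw$a_end - raw$a_start + 1, raw$b_end - raw$b_start + 1) /
        min(la, lb)
    ev_ab <- karlin_evalue(raw$score, la, dbB, scoring$lambda, scoring$K)
    ev_ba <- karlin_evalue(raw$score, lb, dbA, scoring$lambda, scoring$K)
    rows[[r]] <- data.frame(a = protA$id[i], b = protB$id[j],
                            score = raw$score, identity = ident,
                            cov_short = cov_short, evalue_ab = ev_ab,
                            evalue_ba = ev_ba, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$eligible <- tab$identity >= identity_min &
    tab$cov_short >= coverage_min & tab$evalue_ab <= evalue_max
  bestAB <- .best_hits(tab, "a", "b")
  tab$eligible <- tab$identity >= identity_min &
    tab$cov_short >= coverage_min & tab$evalue_ba <= evalue_max
  bestBA <- .best_hits(tab, "b", "a")
  rbh_a <- names(bestAB)[!is.na(bestBA[bestAB]) &
                           bestBA[bestAB] == names(bestAB)]
  pairs <- data.frame(a = rbh_a, b = unname(bestAB[rbh_a]),
                      stringsAsFactors = FALSE)
  key <- paste(tab$a, tab$b, sep = "\r")
  pairs$identity <- tab$identity[match(paste(pairs$a, pairs$b, sep = "\r"),
                                       key)]
  structure(list(genome_a = protA$genome_id[1], genome_b = protB$genome_id[1],
                 aai_pct = if (nrow(pairs)) mean(pairs$identity) else NA_real_,
                 n_rbh_pairs = nrow(pairs), pairs = pairs),
            class = "aai_result")
}

#' @export
print.aai_result <- function(x, ...) {
  cat(sprintf("AAI %s vs %s: %s%% over %d reciprocal best hits\n",
              x$genome_a, x$genome_b,
              if (is.na(x$aai_pct)) "NA" else sprintf("%.1f", x$aai_pct),
              x$n_rbh_pairs))
  invisible(x)
}
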