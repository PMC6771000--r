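## Homology screen of proteomes against a labelled degradation-pathway
## reference database, copy-number accounting, and LinA dehydrochlorinase
## isoform typing with diagnostic residues.

#' Read a labelled pathway reference database
#'
#' FASTA whose headers carry a `route=` key in the description, e.g.
#' `>catA route=catechol_12_dioxygenation catechol 1,2-dioxygenase`.
#' Entries without the key get route `"unlabelled"`.
#'
#' @param path reference FASTA (amino acid).
#' @return [seq_records()] with an extra `route` column.
#' @export
read_refdb <- function(path) {
  db <- read_fasta(path, "aa")
  mm <- regexpr("route=[^[:space:]]+", db$desc)
  route <- rep("unlabelled", nrow(db))
  route[mm > 0] <- sub("^route=", "", regmatches(db$desc, mm))
  db$route <- route
  db
}

#' Homology screen against a pathway database
#'
#' Every query protein is locally aligned against every reference; hits
#' are kept only when they pass both gates strictly as printed filters do:
#' e-value < `evalue_max` and identity > `identity_min` (boundary values
#' excluded). The e-value search space is the whole reference database.
#'
#' @param proteome [seq_records()] with `genome_id` filled in.
#' @param refdb a [read_refdb()] database (needs a `route` column).
#' @param evalue_max,identity_min strict thresholds (defaults 1e-5 / 50).
#' @param id_policy identity denominator for hits; `"alignment"` (BLAST
#'   convention) by default.
#' @param scoring protein scoring scheme.
#' @param prefilter skip clearly unrelated pairs via shared words.
#' @return data frame of class `screen_hits`: query_id, genome_id, ref_id,
#'   route, identity_pct, query_cov, evalue, score — passing hits only.
#' @export
screen_pathways <- function(proteome, refdb, evalue_max = 1e-5,
                            identity_min = 50, id_policy = "alignment",
                            scoring = aa_scoring(), prefilter = TRUE) {
  if (is.null(refdb) || nrow(refdb) == 0) stop("empty reference database")
  if (is.null(refdb$route)) refdb$route <- "unlabelled"
  db_size <- sum(nchar(refdb$seq))
  rows <- list()
  for (i in seq_len(nrow(proteome))) {
    q <- proteome$seq[i]
    for (j in seq_len(nrow(refdb))) {
      if (prefilter && shared_kmer_positions_cpp(q, refdb$seq[j], 4) < 2)
        next
      raw <- .align_raw(q, refdb$seq[j], scoring, local = TRUE)
      if (raw$aln_len == 0) next
      ident <- percent_identity(raw$matches, id_policy, len_a = nchar(q),
                                len_b = nchar(refdb$seq[j]),
                                aln_len = raw$aln_len)
      ev <- karlin_evalue(raw$score, nchar(q), db_size, scoring$lambda,
                          scoring$K)
      if (ev < evalue_max && ident > identity_min)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = proteome$id[i], genome_id = proteome$genome_id[i],
          ref_id = refdb$id[j], route = refdb$route[j],
          identity_pct = ident,
          query_cov = 100 * (raw$a_end - raw$a_start + 1) / nchar(q),
          evalue = ev, score = raw$score, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), genome_id = character(0),
               ref_id = character(0), route = character(0),
               identity_pct = numeric(0), query_cov = numeric(0),
               evalue = numeric(0), score = numeric(0),
               stringsAsFactors = FALSE)
  class(out) <- c("screen_hits", "data.frame")
  out
}

#' Copy-number summary of screen hits
#'
#' Counts distinct query proteins per (genome, reference) pair — multiple
#' hits of one genome's proteins to the same reference are copy number,
#' not filtered to best-only — and reports the fraction of pairs hit
#' once, twice, thrice and four-or-more times.
#'
#' @param hits a [screen_pathways()] result.
#' @return list: `counts` (genome, ref_id, n_queries) and `fractions`
#'   (named `1`, `2`, `3`, `>=4`, summing to 1 over pairs with >= 1 hit).
#' @export
copy_number_summary <- function(hits) {
  if (nrow(hits) == 0)
    return(list(counts = data.frame(genome = character(0),
                                    ref_id = character(0),
                                    n_queries = integer(0)),
                fractions = setNames(rep(NA_real_, 4),
                                     c("1", "2", "3", ">=4"))))
  key <- unique(hits[, c("genome_id", "query_id", "ref_id")])
  agg <- stats::aggregate(list(n_queries = key$query_id),
                          by = list(genome = key$genome_id,
                                    ref_id = key$ref_id), FUN = length)
  n <- agg$n_queries
  fr <- c(`1` = mean(n == 1), `2` = mean(n == 2), `3` = mean(n == 3),
          `>=4` = mean(n >= 4))
  list(counts = agg[order(agg$genome, agg$ref_id), ], fractions = fr)
}

# query residues at reference-frame positions, projected through a global
# alignment: insertions in the query never shift reported positions
.project_residues <- function(aln_query, aln_ref, positions) {
  qa <- strsplit(aln_query, "")[[1]]
  ra <- strsplit(aln_ref, "")[[1]]
  ref_pos <- cumsum(ra != "-")
  out <- setNames(rep(NA_character_, length(positions)),
                  as.character(positions))
  for (p in positions) {
    col <- which(ref_pos == p & ra != "-")
    if (length(col) == 1) out[as.character(p)] <- qa[col]
  }
  out
}

#' LinA isoform typing
#'
#' Globally aligns a candidate dehydrochlorinase against a set of named
#' LinA reference variants; identity uses the shorter-sequence denominator
#' (reported to 1 decimal place). Diagnostic residues are read off the
#' query at reference-frame positions (1-based on the 154-residue LinA
#' frame) through the alignment to the best-matching reference:
#' catalytic_ok requires D25, H73 and R129; the enantioselectivity call is
#' `minus_preferring` when K20, L96 and A131 are all present,
#' `indeterminate` when any of those positions cannot be read, and
#' `plus_preferring` otherwise.
#'
#' @param query a single protein record or string.
#' @param references named character vector (or `seq_set`) of LinA
#'   variants; at least one should be the 154-residue frame.
#' @param min_identity identity floor: a query below it against every
#'   reference is reported as `best_variant = "none"` with residues unset
#'   (default 60).
#' @param positions diagnostic positions to read.
#' @param scoring protein scoring scheme.
#' @return object of class `lina_report`: `query_id`, `identities`
#'   (percent per variant), `best_variant`, `residues`, `catalytic_ok`,
#'   `enantiomer_call`.
#' @export
type_lina <- function(query, references,
                      min_identity = 60,
                      positions = c(20, 23, 25, 35, 73, 96, 129, 131),
                      scoring = aa_scoring()) {
  if (inherits(references, "data.frame"))
    references <- setNames(references$seq, references$id)
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("references must be named by variant")
  qseq <- .seq_of(query)
  qid <- .id_of(query, "query")
  alns <- lapply(references, function(rs)
    .align_raw(qseq, rs, scoring, local = FALSE))
  ident <- vapply(seq_along(alns), function(i)
    100 * alns[[i]]$matches / min(nchar(qseq), nchar(references[[i]])),
    0)
  names(ident) <- names(references)
  best <- names(ident)[which.max(ident)]   # first max: reference order
  if (max(ident) < min_identity) {
    return(structure(list(query_id = qid, identities = ident,
                          best_variant = "none",
                          residues = setNames(character(0), character(0)),
                          catalytic_ok = NA, enantiomer_call = "indeterminate"),
                     class = "lina_report"))
  }
  ba <- alns[[best]]
  res <- .project_residues(ba$aligned_a, ba$aligned_b, positions)
  ok <- function(p, a) !is.na(res[as.character(p)]) &&
    res[as.character(p)] == a
  catalytic <- ok(25, "D") && ok(73, "H") && ok(129, "R")
  enant_pos <- c("20", "96", "131")
  enant <- if (any(is.na(res[enant_pos])) ||
               any(res[enant_pos] == "-")) "indeterminate"
  else if (ok(20, "K") && ok(96, "L") && ok(131, "A")) "minus_preferring"
  else "plus_preferring"
  structure(list(query_id = qid, identities = ident, best_variant = best,
                 residues = res, catalytic_ok = catalytic,
                 enantiomer_call = enant),
            class = "lina_report")
}

#' @export
print.lina_report <- function(x, ...) {
  cat(sprintf("LinA typing of %s\n", x$query_id))
  for (v in names(x$identities))
    cat(sprintf("  identity to %-12s %5.1f%%%s\n", v, x$identities[v],
                if (identical(v, x$best_variant)) "  <- best" else ""))
  if (identical(x$best_variant, "none")) {
    cat("  no reference matched at the identity floor; residues unset\n")
  } else {
    cat("  residues:",
        paste(sprintf("%s%s", x$residues, names(x$residues)),
              collapse = " "), "\n")
    cat(sprintf("  catalytic triad (D25/H73/R129): %s\n",
                if (isTRUE(x$catalytic_ok)) "intact" else "NOT intact"))
    cat(sprintf("  enantiomer preference call: %s\n", x$enantiomer_call))
  }
  invisible(x)
}
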