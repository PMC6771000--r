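## Greedy incremental protein clustering (CD-HIT semantics): records are
## sorted longest-first and each joins the first existing cluster whose
## representative it matches at identity >= c (shorter-sequence
## denominator) and length ratio len(short)/len(long) >= s; otherwise it
## founds a new cluster. Representatives are cluster founders, hence always
## a longest member.

#' Clustering parameters
#'
#' @param c identity threshold in (0, 1]; default 0.8.
#' @param s length-difference cutoff in (0, 1], interpreted as
#'   len(shorter)/len(longer) >= s; default 0.9.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(c = 0.8, s = 0.9) {
  stopifnot(c > 0, c <= 1, s > 0, s <= 1)
  structure(list(c = c, s = s), class = "cluster_params")
}

# Conservative word filter: a pair at identity >= c shares a large fraction
# of its shorter sequence's k-mers; clearly unrelated pairs share almost
# none. The 10% cut-off leaves a wide margin below the ~40% expected at
# c = 0.8 (property-tested); it is a heuristic, not a proof, so it can be
# switched off.
.prefilter_pass <- function(seq_a, seq_b, k = 4, frac = 0.1) {
  ls <- min(nchar(seq_a), nchar(seq_b))
  if (ls < 2 * k) return(TRUE)
  need <- max(1, ceiling(frac * (ls - k + 1)))
  shared_kmer_positions_cpp(seq_a, seq_b, k) >= need
}

#' Greedy incremental clustering of protein records
#'
#' @param records a [seq_records()] set of amino-acid sequences with
#'   `genome_id` filled in.
#' @param params a [cluster_params()]; defaults c = 0.8, s = 0.9.
#' @param scoring protein [aa_scoring()] used for the member-representative
#'   global alignments.
#' @param best if `FALSE` (default, CD-HIT semantics) a record joins the
#'   first eligible cluster in founding order; if `TRUE`, the eligible
#'   cluster with the highest identity.
#' @param prefilter apply the shared-word prefilter before aligning.
#' @return object of class `cluster_set`: list with `clusters` (each has
#'   `cluster_id`, `representative`, `members`, `genomes_present`),
#'   `params`, `n_input`, and `membership` (id -> cluster_id map).
#' @export
greedy_cluster <- function(records, params = cluster_params(),
                           scoring = aa_scoring(), best = FALSE,
                           prefilter = TRUE) {
  if (is.null(records) || nrow(records) == 0) stop("no records to cluster")
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  .check_alphabet(records, "aa")
  ord <- order(-nchar(records$seq), records$id, method = "radix")
  rec <- records[ord, , drop = FALSE]
  n <- nrow(rec)
  lens <- nchar(rec$seq)
  rep_idx <- integer(0)       # indices (into rec) of representatives
  assign <- integer(n)        # cluster index per record
  for (i in seq_len(n)) {
    chosen <- 0L
    best_id <- -Inf
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      if (lens[i] / lens[r] < params$s) next
      if (prefilter && params$c >= 0.7 &&
          !.prefilter_pass(rec$seq[i], rec$seq[r])) next
      raw <- .align_raw(rec$seq[i], rec$seq[r], scoring, local = FALSE)
      ident <- raw$matches / min(lens[i], lens[r])
      if (ident >= params$c) {
        if (!best) { chosen <- ci; break }
        if (ident > best_id) { best_id <- ident; chosen <- ci }
      }
    }
    if (chosen == 0L) {
      rep_idx <- c(rep_idx, i)
      chosen <- length(rep_idx)
    }
    assign[i] <- chosen
  }
  clusters <- lapply(seq_along(rep_idx), function(ci) {
    m <- which(assign == ci)
    list(cluster_id = ci - 1L,
         representative = rec$id[rep_idx[ci]],
         members = rec$id[m],
         genomes_present = sort(unique(rec$genome_id[m])))
  })
  membership <- setNames(rep(vapply(clusters, `[[`, 0L, "cluster_id"),
                             vapply(clusters, function(x) length(x$members),
                                    0L)),
                         unlist(lapply(clusters, `[[`, "members")))
  structure(list(clusters = clusters, params = params, n_input = n,
                 membership = membership,
                 genome_of = setNames(records$genome_id, records$id)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 0L)
  cat(sprintf("cluster_set: %d records in %d clusters (c=%.2f, s=%.2f); ",
              x$n_input, length(x$clusters), x$params$c, x$params$s))
  cat(sprintf("largest %d, singletons %d\n", max(sizes), sum(sizes == 1L)))
  invisible(x)
}

#' Cluster-by-genome presence matrix
#'
#' @param cs a [greedy_cluster()] result.
#' @param genome_ids column order; must cover every member genome.
#' @return binary matrix, rows = cluster ids, columns = genomes; entry 1
#'   iff the cluster has at least one member from the genome.
#' @export
cluster_presence_matrix <- function(cs, genome_ids = NULL) {
  all_g <- sort(unique(unlist(lapply(cs$clusters, `[[`, "genomes_present"))))
  if (is.null(genome_ids)) genome_ids <- all_g
  unknown <- setdiff(all_g, genome_ids)
  if (length(unknown))
    stop("clusters contain genomes absent from genome_ids: ",
         paste(unknown, collapse = ", "))
  m <- matrix(0L, nrow = length(cs$clusters), ncol = length(genome_ids),
              dimnames = list(vapply(cs$clusters, `[[`, 0L, "cluster_id"),
                              genome_ids))
  for (i in seq_along(cs$clusters))
    m[i, cs$clusters[[i]]$genomes_present] <- 1L
  m
}

#' Cluster membership as a table
#'
#' @param cs a `cluster_set`.
#' @return data frame (cluster_id, representative, member, genome).
#' @export
cluster_table <- function(cs) {
  do.call(rbind, lapply(cs$clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id, representative = cl$representative,
               member = cl$members,
               genome = unname(cs$genome_of[cl$members]),
               stringsAsFactors = FALSE)))
}

#' Write a CD-HIT-style .clstr file
#'
#' @param cs a `cluster_set`.
#' @param path output file.
#' @export
write_clstr <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cl in cs$clusters) {
    writeLines(sprintf(">Cluster %d", cl$cluster_id), con)
    mem <- c(cl$representative, setdiff(cl$members, cl$representative))
    for (i in seq_along(mem)) {
      tag <- if (mem[i] == cl$representative) "*" else "at"
      writeLines(sprintf("%d\t>%s... %s", i - 1L, mem[i], tag), con)
    }
  }
  invisible(path)
}
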