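## Core / accessory / unique partitioning of a cluster set, the homology
## false-positive filter for unique clusters, accumulation curves with
## median/IQR over genome orderings, a Heaps-law openness fit, and the
## unique-count vs tree-distance correlation.

#' Partition clusters into core, accessory and unique
#'
#' Core = present in every genome; unique = present in exactly one (only
#' meaningful with more than one genome: a single-genome collection is all
#' core); accessory = the rest. The three classes are disjoint and cover
#' every cluster.
#'
#' @param cs a [greedy_cluster()] result.
#' @param genome_ids genomes analysed; defaults to those observed.
#' @return object of class `pangenome_partition`: `core`, `accessory`
#'   (integer cluster ids), `unique_by_genome` (named list of cluster ids),
#'   `n_genomes`, `presence` (named presence counts).
#' @export
partition_pangenome <- function(cs, genome_ids = NULL) {
  if (is.null(cs$clusters) || length(cs$clusters) == 0)
    stop("empty cluster set")
  pm <- cluster_presence_matrix(cs, genome_ids)
  genome_ids <- colnames(pm)
  G <- ncol(pm)
  counts <- rowSums(pm)
  ids <- as.integer(rownames(pm))
  core <- ids[counts == G]
  uniq <- if (G > 1) ids[counts == 1] else integer(0)
  accessory <- setdiff(ids, c(core, uniq))
  unique_by_genome <- setNames(vector("list", G), genome_ids)
  for (g in genome_ids)
    unique_by_genome[[g]] <- ids[counts == 1 & pm[, g] == 1 & G > 1]
  structure(list(core = sort(core), accessory = sort(accessory),
                 unique_by_genome = unique_by_genome, n_genomes = G,
                 genome_ids = genome_ids, presence = setNames(counts, ids)),
            class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  nu <- vapply(x$unique_by_genome, length, 0L)
  cat(sprintf(
    "pangenome over %d genomes: %d core, %d accessory, %d unique clusters",
    x$n_genomes, length(x$core), length(x$accessory), sum(nu)))
  if (x$n_genomes > 1)
    cat(sprintf(" (%d-%d per genome)\n", min(nu), max(nu))) else cat("\n")
  invisible(x)
}

#' Homology false-positive filter for unique clusters
#'
#' A cluster called unique by the partition may still have a diverged
#' homolog in another genome that the clustering threshold missed. Each
#' unique cluster's representative is locally aligned against every
#' protein of every other genome; a hit with e-value <= `evalue_max` and
#' identity >= `identity_min` reclassifies the cluster to accessory
#' (never deleted, so the partition stays exhaustive). Removals are logged
#' in the `reclassified` attribute with the offending hit.
#'
#' @param p a [partition_pangenome()] result.
#' @param cs the underlying `cluster_set`.
#' @param proteomes the full [seq_records()] set used for clustering.
#' @param evalue_max,identity_min filter thresholds (inclusive); defaults
#'   e-value 1e-5 and identity 50 (the screening thresholds, reused here
#'   as the closest documented choice).
#' @param id_policy identity denominator for the filter hits
#'   (alignment-length by default, the BLAST convention).
#' @param scoring protein scoring scheme.
#' @param prefilter skip clearly unrelated pairs via shared words.
#' @return updated `pangenome_partition` with attribute `reclassified`.
#' @export
filter_unique <- function(p, cs, proteomes, evalue_max = 1e-5,
                          identity_min = 50, id_policy = "alignment",
                          scoring = aa_scoring(), prefilter = TRUE) {
  stopifnot(evalue_max > 0, identity_min > 0)
  seqs <- setNames(proteomes$seq, proteomes$id)
  genome_of <- setNames(proteomes$genome_id, proteomes$id)
  reps <- setNames(vapply(cs$clusters, `[[`, "", "representative"),
                   vapply(cs$clusters, `[[`, 0L, "cluster_id"))
  log <- list()
  moved <- integer(0)
  for (g in names(p$unique_by_genome)) {
    others <- names(genome_of)[genome_of != g]
    if (length(others) == 0) next
    db_size <- sum(nchar(seqs[others]))
    for (cid in p$unique_by_genome[[g]]) {
      rep_id <- reps[[as.character(cid)]]
      rep_seq <- seqs[[rep_id]]
      for (sid in others) {
        if (prefilter &&
            shared_kmer_positions_cpp(rep_seq, seqs[[sid]], 4) < 2) next
        raw <- .align_raw(rep_seq, seqs[[sid]], scoring, local = TRUE)
        if (raw$aln_len == 0) next
        ident <- percent_identity(raw$matches, id_policy,
                                  len_a = nchar(rep_seq),
                                  len_b = nchar(seqs[[sid]]),
                                  aln_len = raw$aln_len)
        ev <- karlin_evalue(raw$score, nchar(rep_seq), db_size,
                            scoring$lambda, scoring$K)
        if (ev <= evalue_max && ident >= identity_min) {
          moved <- c(moved, cid)
          log[[length(log) + 1L]] <- data.frame(
            cluster_id = cid, representative = rep_id, genome = g,
            hit_id = sid, hit_genome = unname(genome_of[sid]),
            identity_pct = ident, evalue = ev, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  for (g in names(p$unique_by_genome))
    p$unique_by_genome[[g]] <- setdiff(p$unique_by_genome[[g]], moved)
  p$accessory <- sort(c(p$accessory, moved))
  attr(p, "reclassified") <-
    if (length(log)) do.call(rbind, log) else
      data.frame(cluster_id = integer(0), representative = character(0),
                 genome = character(0), hit_id = character(0),
                 hit_genome = character(0), identity_pct = numeric(0),
                 evalue = numeric(0), stringsAsFactors = FALSE)
  p
}

# all permutations of 1..n (n <= 9), deterministic order
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Pangenome and core-genome accumulation curves
#'
#' For each of `R` genome orderings, the pangenome size (clusters seen so
#' far) and core size (clusters present in every genome so far) are
#' recorded after each added genome; per-step medians and IQRs (type-7
#' quantiles) are taken across orderings. Orderings are random
#' permutations under `seed`; when `R` >= G! (and G <= 9) all G!
#' orderings are enumerated instead, making the result exact.
#'
#' @param cs a `cluster_set`.
#' @param R number of orderings (>= 1).
#' @param seed integer seed; mandatory for reproducibility.
#' @param genome_ids genomes to accumulate over; default observed.
#' @return object of class `accumulation_curve`: data frame (k,
#'   pan_median, pan_iqr, core_median, core_iqr) with attributes `R`
#'   (orderings actually used), `seed`, `exhaustive`, and the per-ordering
#'   `pan` / `core` matrices.
#' @export
accumulation <- function(cs, R = 100, seed, genome_ids = NULL) {
  if (R < 1) stop("R must be >= 1")
  if (missing(seed)) stop("seed is required")
  pm <- cluster_presence_matrix(cs, genome_ids) > 0
  G <- ncol(pm)
  exhaustive <- G <= 9 && R >= factorial(G)
  if (exhaustive) {
    perms <- .all_perms(G)
  } else {
    set.seed(seed)
    perms <- t(vapply(seq_len(R), function(i) sample.int(G), integer(G)))
  }
  nr <- nrow(perms)
  pan <- matrix(0L, nr, G)
  core <- matrix(0L, nr, G)
  for (r in seq_len(nr)) {
    seen <- rep(FALSE, nrow(pm))
    inall <- rep(TRUE, nrow(pm))
    for (k in seq_len(G)) {
      col <- pm[, perms[r, k]]
      seen <- seen | col
      inall <- inall & col
      pan[r, k] <- sum(seen)
      core[r, k] <- sum(inall)
    }
  }
  iqr7 <- function(x) unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
  out <- data.frame(
    k = seq_len(G),
    pan_median = apply(pan, 2, median),
    pan_iqr = apply(pan, 2, iqr7),
    core_median = apply(core, 2, median),
    core_iqr = apply(core, 2, iqr7))
  structure(out, R = nr, seed = if (exhaustive) NA_integer_ else seed,
            exhaustive = exhaustive, pan = pan, core = core,
            class = c("accumulation_curve", "data.frame"))
}

#' Heaps-law openness fit
#'
#' Fits the new-cluster discovery rate n(k) = kappa * k^(-alpha) (Tettelin
#' form) to the median number of new clusters contributed by the k-th
#' genome, by least squares on the log-log scale. alpha < 1 means the
#' pangenome keeps growing without bound: verdict "open"; alpha >= 1 (or a
#' curve that stops growing entirely) means "closed". gamma = 1 - alpha.
#'
#' @param curve an [accumulation()] result over at least 3 genomes.
#' @return object of class `heaps_fit`: `kappa`, `alpha`, `gamma`,
#'   `verdict`, `rss` (residual sum of squares on the original scale).
#' @export
heaps_fit <- function(curve) {
  G <- nrow(curve)
  if (G < 3) stop("need at least 3 genomes for a Heaps fit")
  if (any(diff(curve$pan_median) < 0))
    stop("pan curve is not non-decreasing; invalid accumulation curve")
  newk <- diff(curve$pan_median)          # new clusters at k = 2..G
  k <- seq(2, G)
  pos <- newk > 0
  if (sum(pos) < 2) {
    return(structure(list(kappa = NA_real_, alpha = Inf, gamma = -Inf,
                          verdict = "closed", rss = 0),
                     class = "heaps_fit"))
  }
  fit <- lm(log(newk[pos]) ~ log(k[pos]))
  alpha <- -unname(coef(fit)[2])
  kappa <- exp(unname(coef(fit)[1]))
  pred <- kappa * k^(-alpha)
  rss <- sum((newk - pred)^2)
  structure(list(kappa = kappa, alpha = alpha, gamma = 1 - alpha,
                 verdict = if (alpha < 1) "open" else "closed", rss = rss),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf(
    "Heaps fit: n(k) = %.3g * k^(-%.3g); gamma = %.3g -> pangenome %s\n",
    x$kappa, x$alpha, x$gamma, x$verdict))
  invisible(x)
}

#' Unique-cluster counts versus distance to the closest relative
#'
#' Spearman rank correlation (average ranks for ties, two-sided p-value)
#' between the number of unique clusters of each genome and its nearest
#' patristic distance on the tree.
#'
#' @param p a `pangenome_partition` (after [filter_unique()] if desired).
#' @param tree a `phylo` tree whose leaves include every genome.
#' @return list: `rho`, `pvalue`, `n`, and the per-genome `table`.
#' @export
unique_vs_distance <- function(p, tree) {
  genomes <- p$genome_ids
  if (length(genomes) < 4) stop("insufficient for correlation: < 4 genomes")
  missing_leaves <- setdiff(genomes, tree$tip.label)
  if (length(missing_leaves))
    stop("genomes absent from tree: ", paste(missing_leaves, collapse = ", "))
  counts <- vapply(genomes, function(g) length(p$unique_by_genome[[g]]), 0L)
  dists <- vapply(genomes, function(g) nearest_patristic_distance(tree, g),
                  0)
  ct <- suppressWarnings(cor.test(counts, dists, method = "spearman",
                                  alternative = "two.sided"))
  list(rho = unname(ct$estimate), pvalue = ct$p.value, n = length(genomes),
       table = data.frame(genome = genomes, n_unique = counts,
                          nearest_distance = dists, row.names = NULL,
                          stringsAsFactors = FALSE))
}
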