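## Sequence and tree input/output, basic genome statistics.

# residues accepted per alphabet (IUPAC, ambiguity codes included)
.ALPHA_AA <- "ACDEFGHIKLMNPQRSTVWYBJZXUO*"
.ALPHA_NT <- "ACGTURYSWKMBDHVN"

#' Construct a set of sequence records
#'
#' The basic container used throughout the package: a data frame with one
#' row per sequence and columns `id`, `desc`, `seq`, `genome_id`.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of residue strings (uppercased on input).
#' @param desc free-text descriptions.
#' @param genome_id source genome of each record.
#' @return data frame of class `seq_set`.
#' @export
seq_records <- function(id, seq, desc = "", genome_id = NA_character_) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  if (anyDuplicated(id))
    stop("duplicate id: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(seq))) stop("empty sequence for id: ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  out <- data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
                    seq = seq,
                    genome_id = rep_len(as.character(genome_id), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

.check_alphabet <- function(records, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  allowed <- if (alphabet == "aa") .ALPHA_AA else .ALPHA_NT
  pat <- paste0("[^", allowed, "]")
  for (i in seq_len(nrow(records))) {
    bad <- regexpr(pat, records$seq[i])
    if (bad > 0)
      stop(sprintf("record '%s': residue '%s' at position %d outside %s alphabet",
                   records$id[i], substr(records$seq[i], bad, bad), bad,
                   alphabet))
  }
  invisible(records)
}

#' Read a FASTA file into a record set
#'
#' The record id is the first whitespace-delimited token of the header;
#' the remainder becomes the description. Sequence lines are concatenated
#' and uppercased. Genome membership is supplied by the caller (one
#' proteome file per genome), never parsed from header text.
#'
#' @param path FASTA file (plain text, folded or single-line).
#' @param alphabet `"aa"` or `"nt"`; residues outside the IUPAC alphabet
#'   (ambiguity codes allowed) raise an error naming the position.
#' @param genome_id genome to attach to every record.
#' @return a [seq_records()] data frame, input order preserved.
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt"),
                       genome_id = NA_character_) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("FASTA parse error in ", path, ": ",
                                         conditionMessage(e)))
  if (length(x) == 0) stop("no records in ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rec <- seq_records(ids, as.character(x), desc, genome_id)
  .check_alphabet(rec, alphabet)
}

#' Write a record set to FASTA
#'
#' @param records a [seq_records()] data frame.
#' @param path output file.
#' @param width line width for folding (default 70).
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i]))
      paste(records$id[i], records$desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read one proteome FASTA per genome
#'
#' @param paths named character vector, names are genome ids; or unnamed,
#'   in which case the file base name (without extension) is the genome id.
#' @return single `seq_set` with `genome_id` filled in.
#' @export
read_proteomes <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  recs <- lapply(names(paths), function(g)
    read_fasta(paths[[g]], "aa", genome_id = g))
  out <- do.call(rbind, recs)
  if (anyDuplicated(out$id))
    stop("duplicate id across proteomes: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Construct a genome assembly
#'
#' @param genome_id genome name.
#' @param replicons named character vector of nucleotide sequences
#'   (chromosome/plasmid scaffolds) or a `seq_set`.
#' @param source free-text provenance.
#' @return object of class `genome_assembly`.
#' @export
genome_assembly <- function(genome_id, replicons, source = "") {
  if (inherits(replicons, "seq_set")) {
    reps <- setNames(replicons$seq, replicons$id)
  } else {
    reps <- toupper(as.character(replicons))
    names(reps) <- names(replicons)
  }
  if (length(reps) < 1) stop("assembly needs at least one replicon")
  if (is.null(names(reps)) || any(!nzchar(names(reps))))
    names(reps) <- paste0(genome_id, "_r", seq_along(reps))
  if (anyDuplicated(names(reps))) stop("replicon ids must be unique")
  structure(list(genome_id = genome_id, replicons = reps, source = source),
            class = "genome_assembly")
}

#' Basic genome statistics
#'
#' Total length, per-replicon lengths, GC content over unambiguous A/C/G/T
#' only (ambiguity codes such as N count towards total length but enter
#' neither the GC numerator nor denominator), and, when a feature table is
#' given, the percentage of the genome covered by the union of feature
#' intervals (overlaps counted once).
#'
#' @param asm a [genome_assembly()].
#' @param features optional data frame with columns `replicon_id`, `start`,
#'   `end` (1-based inclusive, GFF convention).
#' @return list of class `genome_stats`: `total_bp`, `gc_percent`,
#'   `coding_percent` (NA without features), `n_replicons`,
#'   `replicon_lengths`.
#' @export
genome_stats <- function(asm, features = NULL) {
  stopifnot(inherits(asm, "genome_assembly"))
  lens <- nchar(asm$replicons)
  dna <- Biostrings::DNAStringSet(chartr("U", "T", asm$replicons))
  freq <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T"))
  acgt <- sum(freq)
  gc <- if (acgt > 0) 100 * sum(freq[, c("C", "G")]) / acgt else NA_real_
  coding <- NA_real_
  if (!is.null(features) && nrow(features) > 0) {
    covered <- 0L
    for (rid in unique(features$replicon_id)) {
      if (!rid %in% names(asm$replicons))
        stop("feature table names unknown replicon: ", rid)
      f <- features[features$replicon_id == rid, , drop = FALSE]
      bad <- f$start < 1 | f$end > lens[[rid]] | f$start > f$end
      if (any(bad))
        stop(sprintf("feature interval out of bounds on %s: [%d,%d]",
                     rid, f$start[which(bad)[1]], f$end[which(bad)[1]]))
      covered <- covered +
        sum(IRanges::width(IRanges::reduce(IRanges::IRanges(f$start, f$end))))
    }
    coding <- 100 * covered / sum(lens)
  }
  structure(list(total_bp = sum(lens), gc_percent = gc,
                 coding_percent = coding, n_replicons = length(lens),
                 replicon_lengths = lens),
            class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf("genome: %s bp over %d replicon(s); GC %.1f%%",
              format(x$total_bp, big.mark = ","), x$n_replicons,
              x$gc_percent))
  if (!is.na(x$coding_percent))
    cat(sprintf("; %.1f%% coding", x$coding_percent))
  cat("\n")
  invisible(x)
}

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with two additions: unbalanced parentheses are
#' reported with the character offset of the first imbalance, and missing
#' branch lengths default to 0 with a warning (the patristic-distance
#' contract is unchanged).
#'
#' @param path file containing a Newick string, or the string itself when
#'   `text = TRUE`.
#' @param text interpret `path` as the Newick string directly.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, text = FALSE) {
  s <- if (text) path else paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("Newick parse error: unbalanced ')' at character ", i)
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of input (",
         nchar(s), " characters)")
  tr <- tryCatch(ape::read.tree(text = s),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree in input")
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tr
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of leaves.
#'
#' @param tree a `phylo` object.
#' @return symmetric matrix, zero diagonal, leaf labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  stats::cophenetic(tree)
}

#' Distance to the closest relative on the tree
#'
#' @param tree a `phylo` object with at least two leaves.
#' @param leaf leaf (genome) label.
#' @return minimum patristic distance from `leaf` to any other leaf.
#' @export
nearest_patristic_distance <- function(tree, leaf) {
  if (length(tree$tip.label) < 2) stop("no relatives: tree has a single leaf")
  if (!leaf %in% tree$tip.label) stop("unknown leaf: ", leaf)
  d <- patristic_matrix(tree)
  min(d[leaf, setdiff(colnames(d), leaf)])
}

#' Read a feature table
#'
#' TSV with columns replicon_id, start, end, strand, feature_id; lines
#' starting with "#" are ignored. Coordinates are 1-based inclusive.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_feature_table <- function(path) {
  f <- read.delim(path, comment.char = "#", header = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(f) < 3) stop("feature table needs replicon_id, start, end")
  names(f)[1:3] <- c("replicon_id", "start", "end")
  if (ncol(f) >= 4) names(f)[4] <- "strand"
  if (ncol(f) >= 5) names(f)[5] <- "feature_id"
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  f
}
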