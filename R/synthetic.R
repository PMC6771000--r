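## Synthetic-data generator: pangenomes with known core/accessory/unique
## structure, diverged nucleotide genome pairs for ANI calibration, and
## LinA-like variant sets at controlled pairwise identities. Substitutions
## are uniform over alternative residues so expected identities stay
## analytically exact; no indels, rate heterogeneity or HGT are modelled.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.NT4 <- c("A", "C", "G", "T")

#' Random protein or nucleotide sequence
#'
#' @param len length in residues.
#' @param alphabet `"aa"` or `"nt"`.
#' @param gc GC fraction for nucleotide sequences.
#' @return a single sequence string. Seed the RNG with [set.seed()] (the
#'   higher-level generators do this for you).
#' @export
random_sequence <- function(len, alphabet = c("aa", "nt"), gc = 0.5) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "aa") {
    paste(sample(.AA20, len, replace = TRUE), collapse = "")
  } else {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(.NT4, len, replace = TRUE, prob = p), collapse = "")
  }
}

#' Mutate a sequence by random substitution
#'
#' Rate mode (`d`): each position is substituted independently with
#' probability `d` to a uniformly chosen *different* residue, so the
#' expected identity to the input is exactly 100 * (1 - d). Count-exact
#' mode (`k`, optionally `positions`): exactly `k` positions are
#' substituted — handy for analytic fixtures such as a 154-residue pair
#' at exactly 152/154 = 98.7% identity.
#'
#' @param seq sequence string (or single-row record).
#' @param d per-site substitution probability in `[0, 1)`.
#' @param seed optional integer seed (local to this call).
#' @param k exact number of substitutions (overrides `d`).
#' @param positions positions to substitute in count-exact mode; sampled
#'   when omitted.
#' @param alphabet `"aa"` or `"nt"`.
#' @return mutated sequence string.
#' @export
mutate_sequence <- function(seq, d = 0, seed = NULL, k = NULL,
                            positions = NULL, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  s <- strsplit(.seq_of(seq), "")[[1]]
  residues <- if (alphabet == "aa") .AA20 else .NT4
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (!is.null(k)) {
    if (is.null(positions)) positions <- sample(length(s), k)
    stopifnot(length(positions) == k, all(positions <= length(s)))
    idx <- positions
  } else {
    stopifnot(d >= 0, d < 1)
    idx <- which(runif(length(s)) < d)
  }
  if (length(idx)) {
    # uniform over the |alphabet|-1 alternative residues, vectorized
    cur <- match(s[idx], residues)
    step <- sample.int(length(residues) - 1L, length(idx), replace = TRUE)
    s[idx] <- residues[(cur - 1L + step) %% length(residues) + 1L]
  }
  paste(s, collapse = "")
}

# quick dissimilarity guard for new family ancestors: cheap shared-word
# screen first, full alignment only for suspicious pairs
.too_similar <- function(new_seq, pool, max_identity = 0.4,
                         scoring = aa_scoring()) {
  for (s in pool) {
    ls <- min(nchar(new_seq), nchar(s))
    hits <- shared_kmer_positions_cpp(new_seq, s, 4)
    if (hits < 0.05 * (ls - 3)) next
    raw <- .align_raw(new_seq, s, scoring, local = FALSE)
    if (raw$matches / ls >= max_identity) return(TRUE)
  }
  FALSE
}

.new_family_ancestor <- function(pool, len_range, max_retry = 100) {
  for (t in seq_len(max_retry)) {
    len <- sample(seq(len_range[1], len_range[2]), 1)
    cand <- random_sequence(len, "aa")
    if (!.too_similar(cand, pool)) return(cand)
  }
  stop("could not draw a sufficiently dissimilar family ancestor after ",
       max_retry, " tries; sequence space exhausted for this spec")
}

# reverse-translate a protein, choosing synonymous codons whose wobble
# base hits the target GC fraction
.CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("CTT", "CTC", "CTA", "CTG"), M = "ATG",
  N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"), R = c("CGT", "CGC", "CGA", "CGG"),
  S = c("TCT", "TCC", "TCA", "TCG"), T = c("ACT", "ACC", "ACA", "ACG"),
  V = c("GTT", "GTC", "GTA", "GTG"), W = "TGG", Y = c("TAT", "TAC"))

.reverse_translate <- function(protein, gc = 0.5) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- .CODONS[[a]]
    if (length(opts) == 1) return(opts)
    w <- substr(opts, 3, 3) %in% c("G", "C")
    pick_gc <- runif(1) < gc
    pool <- opts[w == pick_gc]
    if (!length(pool)) pool <- opts
    sample(pool, 1)
  }, "")
  paste(codons, collapse = "")
}

#' Simulate a pangenome with known ground truth
#'
#' Families get independent random ancestors kept pairwise below 40%
#' identity by rejection sampling. Core families appear in every genome,
#' accessory families in each genome independently with probability
#' `accessory_p`, unique families privately in one genome; every copy is
#' the ancestor mutated at `divergence`. The emitted truth classes are
#' derived from the *realized* presence pattern (an accessory family that
#' happens to land in all genomes is truthfully core). Companion
#' nucleotide genomes reverse-translate each genome's proteins (wobble
#' positions steered to `gc`) joined by random spacers, and a
#' star-with-noise tree over the genomes is returned.
#'
#' @param n_genomes number of genomes G.
#' @param n_core core family count.
#' @param n_accessory accessory family count.
#' @param accessory_p per-genome presence probability of an accessory
#'   family.
#' @param n_unique_per_genome unique families per genome (scalar or
#'   length-G vector).
#' @param divergence per-site substitution rate from the family ancestor.
#' @param protein_len length range, default 200-400 residues.
#' @param gc GC target of companion nucleotide genomes.
#' @param make_nt also build nucleotide genomes (default TRUE).
#' @param seed mandatory integer seed; output is fully deterministic.
#' @return list: `proteomes` ([seq_records()]), `genomes` (list of
#'   [genome_assembly()] or NULL), `truth` (gene_id, genome_id, family_id,
#'   class), `families` (family_id, class, presence_count), `tree`
#'   (`phylo`), `genome_ids`.
#' @export
simulate_pangenome <- function(n_genomes, n_core, n_accessory = 0,
                               accessory_p = 0.5, n_unique_per_genome = 0,
                               divergence = 0.05,
                               protein_len = c(200, 400), gc = 0.55,
                               make_nt = TRUE, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_genomes >= 1, n_core >= 0, n_accessory >= 0,
            divergence >= 0, divergence < 1)
  set.seed(seed)
  n_unique_per_genome <- rep_len(n_unique_per_genome, n_genomes)
  genome_ids <- sprintf("g%02d", seq_len(n_genomes))
  ancestors <- character(0)
  fam_tab <- list()
  add_family <- function(fid, pattern) {
    anc <- .new_family_ancestor(ancestors, protein_len)
    ancestors <<- c(ancestors, anc)
    fam_tab[[length(fam_tab) + 1L]] <<-
      list(family_id = fid, ancestor = anc, pattern = pattern)
  }
  for (i in seq_len(n_core))
    add_family(sprintf("core%04d", i), rep(TRUE, n_genomes))
  for (i in seq_len(n_accessory)) {
    pat <- runif(n_genomes) < accessory_p
    if (!any(pat)) pat[sample(n_genomes, 1)] <- TRUE
    add_family(sprintf("acc%04d", i), pat)
  }
  for (g in seq_len(n_genomes)) {
    for (i in seq_len(n_unique_per_genome[g])) {
      pat <- rep(FALSE, n_genomes)
      pat[g] <- TRUE
      add_family(sprintf("uniq_%s_%03d", genome_ids[g], i), pat)
    }
  }
  ids <- character(0); seqs <- character(0); gids <- character(0)
  fids <- character(0)
  for (fam in fam_tab) {
    for (g in which(fam$pattern)) {
      gene <- sprintf("%s|%s", genome_ids[g], fam$family_id)
      ids <- c(ids, gene)
      seqs <- c(seqs, mutate_sequence(fam$ancestor, d = divergence,
                                      alphabet = "aa"))
      gids <- c(gids, genome_ids[g])
      fids <- c(fids, fam$family_id)
    }
  }
  proteomes <- seq_records(ids, seqs, genome_id = gids)
  presence <- vapply(fam_tab, function(f) sum(f$pattern), 0L)
  cls <- ifelse(presence == n_genomes, "core",
                ifelse(presence == 1 & n_genomes > 1, "unique", "accessory"))
  families <- data.frame(
    family_id = vapply(fam_tab, `[[`, "", "family_id"),
    class = cls, presence_count = presence, stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, genome_id = gids, family_id = fids,
                      class = families$class[match(fids,
                                                   families$family_id)],
                      stringsAsFactors = FALSE)
  genomes <- NULL
  if (make_nt) {
    genomes <- lapply(seq_len(n_genomes), function(g) {
      prot <- proteomes$seq[proteomes$genome_id == genome_ids[g]]
      parts <- character(2 * length(prot))
      for (i in seq_along(prot)) {
        parts[2 * i - 1] <- .reverse_translate(prot[i], gc)
        parts[2 * i] <- random_sequence(sample(50:150, 1), "nt", gc)
      }
      genome_assembly(genome_ids[g],
                      setNames(paste(parts, collapse = ""),
                               paste0(genome_ids[g], "_chr")),
                      source = "synthetic")
    })
    names(genomes) <- genome_ids
  }
  bl <- 0.5 + runif(n_genomes, 0, 0.2)
  tree <- read_newick(paste0("(", paste(sprintf("%s:%.4f", genome_ids, bl),
                                        collapse = ","), ");"), text = TRUE)
  list(proteomes = proteomes, genomes = genomes, truth = truth,
       families = families, tree = tree, genome_ids = genome_ids)
}

#' Simulate a diverged nucleotide genome pair
#'
#' Genome B is genome A substituted per site at rate `d` (uniform over the
#' three alternative bases), so expected ANI is about 100 * (1 - d).
#'
#' @param length_bp genome length (>= 10x the ANI fragment length).
#' @param d per-site divergence in `[0, 1)`.
#' @param gc GC fraction of genome A.
#' @param seed mandatory integer seed.
#' @return list of two [genome_assembly()] objects `A` and `B`.
#' @export
simulate_genome_pair <- function(length_bp, d, gc = 0.5, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  a <- random_sequence(length_bp, "nt", gc)
  b <- mutate_sequence(a, d = d, alphabet = "nt")
  list(A = genome_assembly("A", c(A_chr = a), source = "synthetic"),
       B = genome_assembly("B", c(B_chr = b), source = "synthetic"))
}

#' Simulate a LinA-like variant set
#'
#' Builds a synthetic 154-residue reference frame and named variants at
#' exact substitution counts from it (count-exact mutation), so pairwise
#' identities to the frame are exactly (154 - k) / 154. These are
#' synthetic stand-ins with the real variants' divergence structure, not
#' the deposited sequences.
#'
#' @param counts named integer vector: substitutions per variant, e.g.
#'   `c("type-1" = 2, "LinA1" = 15)`.
#' @param frame_len frame length (default 154).
#' @param seed mandatory integer seed.
#' @return [seq_records()]: first record `frame`, then one per variant.
#' @export
simulate_lina_variants <- function(counts = c("type-1" = 2, "LinA1" = 15,
                                              "LinA3" = 10, "type-3" = 21),
                                   frame_len = 154, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  frame <- random_sequence(frame_len, "aa")
  vars <- vapply(counts, function(k)
    mutate_sequence(frame, k = k, alphabet = "aa"), "")
  seq_records(c("frame", names(counts)), c(frame, vars),
              desc = "synthetic LinA-like variant")
}
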