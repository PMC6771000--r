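# Independent oracles and small fixture builders shared across tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_prot <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")
rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive affine-gap DP, scores only; gap of length L costs
# open + extend * L. Written independently of the package's traceback
# implementation.
dp_oracle_score <- function(a, b, mat, go, ge, local = FALSE) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (local) {
    M[, 1] <- 0; M[1, ] <- 0
  } else {
    X[1 + (1:n), 1] <- -(go + ge * (1:n))
    Y[1, 1 + (1:m)] <- -(go + ge * (1:m))
  }
  best <- 0
  for (i in 1 + (1:n)) {
    for (j in 1 + (1:m)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      if (local) M[i, j] <- max(0, M[i, j])
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      if (local) best <- max(best, M[i, j])
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force patristic distances straight from the edge list
brute_patristic <- function(tree) {
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length)
  tips <- as.character(seq_along(tree$tip.label))
  d <- d[tips, tips]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# enumeration oracle for accumulation medians: every ordering of the
# genome columns, plain set unions/intersections
enumerate_accumulation <- function(presence) {
  G <- ncol(presence)
  perms <- list()
  gen <- function(prefix, rest) {
    if (!length(rest)) {
      perms[[length(perms) + 1L]] <<- prefix
      return(invisible())
    }
    for (r in rest) gen(c(prefix, r), setdiff(rest, r))
  }
  gen(integer(0), seq_len(G))
  pan <- matrix(0L, length(perms), G)
  core <- matrix(0L, length(perms), G)
  for (p in seq_along(perms)) {
    for (k in seq_len(G)) {
      cols <- presence[, perms[[p]][seq_len(k)], drop = FALSE]
      pan[p, k] <- sum(rowSums(cols) > 0)
      core[p, k] <- sum(rowSums(cols) == k)
    }
  }
  list(pan_median = apply(pan, 2, median),
       core_median = apply(core, 2, median))
}

# small three-genome record set with hand-known cluster structure
toy_records <- function() {
  set.seed(404)
  fam1 <- rand_prot(150)
  fam2 <- rand_prot(220)
  seq_records(
    id = c("a1", "b1", "c1", "a2", "b2", "c3"),
    seq = c(fam1,
            mutate_sequence(fam1, k = 8, seed = 1),   # 94.7% to fam1
            mutate_sequence(fam1, k = 10, seed = 2),  # 93.3% to fam1
            fam2,
            mutate_sequence(fam2, k = 11, seed = 3),  # 95.0% to fam2
            rand_prot(180)),
    genome_id = c("gA", "gB", "gC", "gA", "gB", "gC"))
}

write_proteome_dir <- function(proteomes, dir = tempfile("proteomes")) {
  dir.create(dir)
  for (g in unique(proteomes$genome_id)) {
    sub <- proteomes[proteomes$genome_id == g, , drop = FALSE]
    write_fasta(sub, file.path(dir, paste0(g, ".faa")))
  }
  dir
}
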