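test_that("mutate_sequence: identity arithmetic and determinism", {
  set.seed(91)
  s <- rand_prot(154)
  expect_identical(mutate_sequence(s, d = 0), s)
  # count-exact mode: exactly 2 substitutions -> 152/154 = 98.7
  m <- mutate_sequence(s, k = 2, positions = c(23, 35), seed = 1)
  diffs <- which(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(diffs, c(23, 35))
  expect_equal(sprintf("%.1f", 100 * (154 - 2) / 154), "98.7")
  # seeded mutation is reproducible and does not disturb the global RNG
  set.seed(5); before <- runif(1)
  a1 <- mutate_sequence(s, d = 0.1, seed = 99)
  a2 <- mutate_sequence(s, d = 0.1, seed = 99)
  expect_identical(a1, a2)
})

test_that("mutation rate hits its binomial expectation", {
  set.seed(92)
  s <- rand_prot(1000)
  obs <- vapply(1:500, function(i) {
    m <- mutate_sequence(s, d = 0.2)
    mean(strsplit(s, "")[[1]] == strsplit(m, "")[[1]])
  }, 0)
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - 0.8), 3 * se + 1e-12)
})

test_that("simulate_pangenome truth table is self-consistent", {
  sim <- simulate_pangenome(n_genomes = 5, n_core = 7, n_accessory = 5,
                            accessory_p = 0.5, n_unique_per_genome = 2,
                            divergence = 0.05, make_nt = FALSE, seed = 93)
  # class derived from realized presence
  for (f in sim$families$family_id) {
    pres <- sum(sim$truth$family_id == f)
    cls <- sim$families$class[sim$families$family_id == f]
    if (pres == 5) expect_equal(cls, "core")
    else if (pres == 1) expect_equal(cls, "unique")
    else expect_equal(cls, "accessory")
  }
  expect_equal(sum(sim$families$presence_count), nrow(sim$proteomes))
  # core families occur once per genome
  expect_equal(sum(sim$families$class == "core") * 5 +
                 sum(sim$families$presence_count[
                   sim$families$class != "core"]),
               nrow(sim$truth))
})

test_that("generator output is byte-identical under a fixed seed", {
  s1 <- simulate_pangenome(n_genomes = 3, n_core = 5,
                           n_unique_per_genome = 1, divergence = 0.05,
                           make_nt = TRUE, seed = 94)
  s2 <- simulate_pangenome(n_genomes = 3, n_core = 5,
                           n_unique_per_genome = 1, divergence = 0.05,
                           make_nt = TRUE, seed = 94)
  expect_identical(s1$proteomes, s2$proteomes)
  expect_identical(lapply(s1$genomes, `[[`, "replicons"),
                   lapply(s2$genomes, `[[`, "replicons"))
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(s1$proteomes, f1); write_fasta(s2$proteomes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate generator cases", {
  # divergence 0: every family is a set of identical members
  sim <- simulate_pangenome(n_genomes = 3, n_core = 4, divergence = 0,
                            make_nt = FALSE, seed = 95)
  cs <- greedy_cluster(sim$proteomes)
  expect_length(cs$clusters, 4)
  for (cl in cs$clusters) {
    seqs <- sim$proteomes$seq[match(cl$members, sim$proteomes$id)]
    expect_length(unique(seqs), 1)
  }
  # single genome: everything is core
  sim1 <- simulate_pangenome(n_genomes = 1, n_core = 3,
                             n_unique_per_genome = 2, divergence = 0.05,
                             make_nt = FALSE, seed = 96)
  expect_true(all(sim1$families$class == "core"))
  p <- partition_pangenome(greedy_cluster(sim1$proteomes))
  expect_length(p$core, 5)
})

test_that("companion nucleotide genomes encode the proteins at target GC", {
  sim <- simulate_pangenome(n_genomes = 2, n_core = 6, divergence = 0.03,
                            gc = 0.62, make_nt = TRUE, seed = 97)
  g <- sim$genomes[["g01"]]
  st <- genome_stats(g)
  expect_equal(st$total_bp, nchar(g$replicons[[1]]))
  # wobble-position steering pulls GC towards the target; generous band
  expect_gt(st$gc_percent, 48)
  # translating the first embedded ORF back gives the first protein
  prot <- sim$proteomes$seq[sim$proteomes$genome_id == "g01"][1]
  nt <- substr(g$replicons[[1]], 1, 3 * nchar(prot))
  back <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  expect_identical(back, prot)
})

test_that("genome pair divergence is honored", {
  pr <- simulate_genome_pair(3e4, 0.1, gc = 0.5, seed = 98)
  a <- strsplit(pr$A$replicons[[1]], "")[[1]]
  b <- strsplit(pr$B$replicons[[1]], "")[[1]]
  obs <- mean(a != b)
  expect_equal(obs, 0.1, tolerance = 0.07)
  expect_identical(nchar(pr$A$replicons[[1]]), nchar(pr$B$replicons[[1]]))
})

test_that("LinA variant set has the requested exact distances", {
  v <- simulate_lina_variants(counts = c(x = 2, y = 15), seed = 99)
  frame <- v$seq[v$id == "frame"]
  for (nm in c(x = 2, y = 15)) NULL
  d_x <- sum(strsplit(frame, "")[[1]] !=
               strsplit(v$seq[v$id == "x"], "")[[1]])
  d_y <- sum(strsplit(frame, "")[[1]] !=
               strsplit(v$seq[v$id == "y"], "")[[1]])
  expect_equal(d_x, 2)
  expect_equal(d_y, 15)
})

test_that("end-to-end truth recovery including the unique filter", {
  # divergence 0.05 keeps every member safely above the 0.8 identity
  # threshold to its representative (pairwise ~90%); recovery is exact
  sim <- simulate_pangenome(n_genomes = 5, n_core = 10, n_accessory = 8,
                            accessory_p = 0.5, n_unique_per_genome = 3,
                            divergence = 0.05, make_nt = FALSE, seed = 100)
  cs <- greedy_cluster(sim$proteomes)
  p <- filter_unique(partition_pangenome(cs), cs, sim$proteomes)
  expect_length(p$core, sum(sim$families$class == "core"))
  expect_length(p$accessory, sum(sim$families$class == "accessory"))
  truth_uniq <- table(sim$truth$genome_id[sim$truth$class == "unique"])
  for (g in names(truth_uniq))
    expect_length(p$unique_by_genome[[g]], truth_uniq[[g]])
})
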