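test_that("partition classes: core, unique, disjoint and exhaustive", {
  cs <- greedy_cluster(toy_records())
  p <- partition_pangenome(cs)
  # fam1 spans gA/gB/gC -> core; fam2 spans gA/gB -> accessory; c3 unique
  expect_length(p$core, 1)
  expect_length(p$accessory, 1)
  expect_equal(sum(lengths(p$unique_by_genome)), 1)
  expect_equal(names(which(lengths(p$unique_by_genome) == 1)), "gC")
  all_ids <- c(p$core, p$accessory, unlist(p$unique_by_genome))
  expect_setequal(all_ids, as.integer(names(p$presence)))
  expect_equal(anyDuplicated(all_ids), 0)
  expect_error(partition_pangenome(structure(list(clusters = list()),
                                             class = "cluster_set")),
               "empty")
})

test_that("single-genome collection partitions as all core", {
  set.seed(51)
  rec <- seq_records(paste0("p", 1:4), vapply(rep(100, 4), rand_prot, ""),
                     genome_id = "only")
  p <- partition_pangenome(greedy_cluster(rec))
  expect_length(p$core, 4)
  expect_equal(sum(lengths(p$unique_by_genome)), 0)
})

test_that("filter_unique reclassifies planted homologs, keeps true uniques", {
  set.seed(52)
  core <- rand_prot(200)
  uniq_real <- rand_prot(210)
  uniq_false <- rand_prot(190)
  # the false unique has a diverged (~70%) homolog in another genome:
  # below the 80% clustering threshold but far above the 50% filter
  homolog <- mutate_sequence(uniq_false, k = 57, seed = 3)
  rec <- seq_records(
    c("c_a", "c_b", "fp", "fp_hom", "real_u"),
    c(core, mutate_sequence(core, k = 6, seed = 4), uniq_false, homolog,
      uniq_real),
    genome_id = c("gA", "gB", "gA", "gB", "gB"))
  cs <- greedy_cluster(rec)
  p <- partition_pangenome(cs)
  expect_equal(sum(lengths(p$unique_by_genome)), 3)  # fp, fp_hom, real_u
  p2 <- filter_unique(p, cs, rec)
  # fp and fp_hom both reclassified (each finds the other), real_u kept
  expect_equal(sum(lengths(p2$unique_by_genome)), 1)
  log <- attr(p2, "reclassified")
  expect_setequal(log$representative, c("fp", "fp_hom"))
  expect_true(all(log$evalue <= 1e-5))
  expect_true(all(log$identity_pct >= 50))
  # partition still disjoint and exhaustive, unique never increases
  all_ids <- c(p2$core, p2$accessory, unlist(p2$unique_by_genome))
  expect_setequal(all_ids, as.integer(names(p2$presence)))
  expect_equal(anyDuplicated(all_ids), 0)
})

test_that("filter_unique flips exactly at the identity threshold", {
  set.seed(53)
  base <- rand_prot(200)
  rec0 <- seq_records(c("u", "partner"),
                      c(base, rand_prot(200)),
                      genome_id = c("gA", "gB"))
  cs <- greedy_cluster(rec0)
  p <- partition_pangenome(cs)
  # sweep planted homolog identity; threshold on the alignment-length
  # identity achieved by the hit itself (read from the filter log)
  for (k in c(30, 60, 90, 120)) {
    hom <- mutate_sequence(base, k = k, seed = k)
    rec <- seq_records(c("u", "hom"), c(base, hom),
                       genome_id = c("gA", "gB"))
    cs2 <- greedy_cluster(rec)
    p2 <- partition_pangenome(cs2)
    if (sum(lengths(p2$unique_by_genome)) == 0) next # clustered together
    ident <- align_local(base, hom)$identity_pct
    f <- filter_unique(p2, cs2, rec, evalue_max = 1e-5, identity_min = 50)
    reclassified <- nrow(attr(f, "reclassified")) > 0
    expect_equal(reclassified, ident >= 50,
                 label = sprintf("k=%d ident=%.1f", k, ident))
  }
})

test_that("accumulation: edge cases and exhaustive enumeration oracle", {
  set.seed(54)
  # G = 1
  rec <- seq_records(paste0("p", 1:3), vapply(rep(90, 3), rand_prot, ""),
                     genome_id = "g1")
  cs1 <- greedy_cluster(rec)
  c1 <- accumulation(cs1, R = 5, seed = 1)
  expect_equal(c1$pan_median, 3)
  expect_equal(c1$core_median, 3)
  expect_equal(c1$pan_iqr, 0)
  # identical genome content -> flat curves
  s <- vapply(rep(110, 3), rand_prot, "")
  rec2 <- seq_records(c(outer(1:3, 1:3, function(i, g)
    sprintf("q%d_g%d", i, g))), rep(s, 3),
    genome_id = rep(paste0("g", 1:3), each = 3))
  cs2 <- greedy_cluster(rec2)
  c2 <- accumulation(cs2, R = 10, seed = 2)
  expect_true(all(c2$pan_median == 3))
  expect_true(all(c2$core_median == 3))
  # exhaustive enumeration against the independent oracle, G = 4
  sim <- simulate_pangenome(n_genomes = 4, n_core = 5, n_accessory = 6,
                            n_unique_per_genome = 2, divergence = 0.04,
                            make_nt = FALSE, seed = 55)
  cs <- greedy_cluster(sim$proteomes)
  curve <- accumulation(cs, R = factorial(4), seed = 3)
  expect_true(attr(curve, "exhaustive"))
  ora <- enumerate_accumulation(cluster_presence_matrix(cs))
  expect_equal(curve$pan_median, ora$pan_median)
  expect_equal(curve$core_median, ora$core_median)
  # monotone within every single ordering, not just medians
  pan <- attr(curve, "pan"); core <- attr(curve, "core")
  expect_true(all(apply(pan, 1, function(x) all(diff(x) >= 0))))
  expect_true(all(apply(core, 1, function(x) all(diff(x) <= 0))))
  # fixed seed reproducibility for the sampled path
  a <- accumulation(cs, R = 7, seed = 99)
  b <- accumulation(cs, R = 7, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(accumulation(cs, R = 0, seed = 1), "R must be")
})

test_that("heaps_fit: exact recovery, open and closed verdicts", {
  G <- 10
  kappa <- 120; alpha <- 0.6
  pan <- cumsum(c(300, kappa * (2:G)^(-alpha)))
  curve <- data.frame(k = 1:G, pan_median = pan, pan_iqr = 0,
                      core_median = rep(250, G), core_iqr = 0)
  fit <- heaps_fit(curve)
  expect_equal(fit$kappa, kappa, tolerance = 1e-6)
  expect_equal(fit$alpha, alpha, tolerance = 1e-6)
  expect_equal(fit$gamma, 1 - alpha, tolerance = 1e-6)
  expect_equal(fit$verdict, "open")
  expect_lt(fit$rss, 1e-10)
  # constant novelty: alpha = 0 -> open
  curve2 <- data.frame(k = 1:G, pan_median = 300 + 15 * (0:(G - 1)),
                       pan_iqr = 0, core_median = 250, core_iqr = 0)
  expect_equal(heaps_fit(curve2)$verdict, "open")
  # saturation: nothing new after k = 2 -> closed
  curve3 <- data.frame(k = 1:G, pan_median = c(300, rep(320, G - 1)),
                       pan_iqr = 0, core_median = 250, core_iqr = 0)
  expect_equal(heaps_fit(curve3)$verdict, "closed")
  # steep decay, alpha > 1 -> closed
  pan4 <- cumsum(c(300, 100 * (2:G)^(-1.8)))
  curve4 <- data.frame(k = 1:G, pan_median = pan4, pan_iqr = 0,
                       core_median = 250, core_iqr = 0)
  expect_equal(heaps_fit(curve4)$verdict, "closed")
  expect_error(heaps_fit(curve[1:2, ]), "at least 3")
  bad <- curve; bad$pan_median[4] <- bad$pan_median[3] - 5
  expect_error(heaps_fit(bad), "non-decreasing")
})

test_that("unique_vs_distance: monotone, anti-monotone, tie handling", {
  make_part <- function(counts) {
    ub <- lapply(seq_along(counts), function(i) seq_len(counts[i]) * 1000L + i)
    names(ub) <- names(counts)
    structure(list(core = integer(0), accessory = integer(0),
                   unique_by_genome = ub, n_genomes = length(counts),
                   genome_ids = names(counts),
                   presence = setNames(integer(0), character(0))),
              class = "pangenome_partition")
  }
  leaves <- sprintf("g%d", 1:6)
  bl <- c(1, 2, 3, 4, 5, 6)
  tree <- read_newick(paste0("(", paste(sprintf("%s:%d", leaves, bl),
                                        collapse = ","), ");"), text = TRUE)
  nd <- vapply(leaves, function(l) nearest_patristic_distance(tree, l), 0)
  counts <- setNames(rank(nd) * 3L, leaves)           # perfectly monotone
  r <- unique_vs_distance(make_part(counts), tree)
  expect_equal(r$rho, 1)
  # anti-monotone with the same tie structure as the distances
  anti <- setNames(as.integer(2 * (length(nd) + 1 - rank(nd))), leaves)
  r2 <- unique_vs_distance(make_part(anti), tree)
  expect_equal(r2$rho, -1)
  # ties: compare to a direct average-rank computation
  counts3 <- setNames(c(2L, 2L, 5L, 5L, 9L, 1L), leaves)
  r3 <- unique_vs_distance(make_part(counts3), tree)
  rho_manual <- cor(rank(counts3), rank(nd))
  expect_equal(r3$rho, rho_manual, tolerance = 1e-12)
  expect_true(r3$pvalue >= 0 && r3$pvalue <= 1)
  expect_error(unique_vs_distance(make_part(counts[1:3]),
                                  read_newick("(g1:1,(g2:1,g3:1):1);",
                                              text = TRUE)),
               "insufficient")
})
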