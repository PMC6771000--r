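refdb_fixture <- function() {
  read_refdb(system.file("extdata", "toy_pathway_db.faa",
                         package = "panlin"))
}

test_that("refdb fixture parses with route labels", {
  db <- refdb_fixture()
  expect_gt(nrow(db), 5)
  expect_true(all(nzchar(db$route)))
  expect_true("catechol_12_dioxygenation" %in% db$route)
})

test_that("screen finds exact copies and rejects distant homologs", {
  db <- refdb_fixture()
  set.seed(81)
  ref <- db[1, ]
  prot <- seq_records(c("hit1", "junk"),
                      c(ref$seq, rand_prot(250)), genome_id = "gA")
  hits <- screen_pathways(prot, db)
  expect_true("hit1" %in% hits$query_id)
  h <- hits[hits$query_id == "hit1" & hits$ref_id == ref$id, ]
  expect_equal(h$identity_pct, 100)
  expect_equal(h$route, ref$route)
  expect_false("junk" %in% hits$query_id)
  # homolog mutated to ~45% identity: below the >50% gate
  far <- mutate_sequence(ref$seq, k = ceiling(0.55 * nchar(ref$seq)),
                         seed = 5)
  hits2 <- screen_pathways(seq_records("far", far, genome_id = "gA"), db)
  expect_false("far" %in% hits2$query_id[hits2$ref_id == ref$id])
  expect_error(screen_pathways(prot, db[0, ]), "empty reference")
})

test_that("screen thresholds are strict: boundary values are excluded", {
  db <- refdb_fixture()
  set.seed(82)
  ref <- db[2, ]
  q <- mutate_sequence(ref$seq, k = floor(0.3 * nchar(ref$seq)), seed = 7)
  prot <- seq_records("q", q, genome_id = "gA")
  base <- screen_pathways(prot, db)
  h <- base[base$ref_id == ref$id, ]
  expect_equal(nrow(h), 1)
  # identity boundary: a gate set exactly at the achieved identity drops
  # the hit (strict >), infinitesimally below keeps it
  at <- screen_pathways(prot, db, identity_min = h$identity_pct)
  expect_false(ref$id %in% at$ref_id)
  below <- screen_pathways(prot, db,
                           identity_min = h$identity_pct - 1e-9)
  expect_true(ref$id %in% below$ref_id)
  # e-value boundary: gate exactly at the achieved e-value drops (strict <)
  at_e <- screen_pathways(prot, db, evalue_max = h$evalue)
  expect_false(ref$id %in% at_e$ref_id)
  above_e <- screen_pathways(prot, db, evalue_max = h$evalue * (1 + 1e-9))
  expect_true(ref$id %in% above_e$ref_id)
})

test_that("screen hit set is invariant under proteome order", {
  db <- refdb_fixture()
  set.seed(83)
  prot <- seq_records(c("p1", "p2", "p3"),
                      c(db$seq[1], mutate_sequence(db$seq[3], k = 20),
                        rand_prot(200)), genome_id = "gA")
  h1 <- screen_pathways(prot, db)
  prot2 <- prot[c(3, 1, 2), , drop = FALSE]
  class(prot2) <- class(prot)
  h2 <- screen_pathways(prot2, db)
  key <- function(h) {
    k <- paste(h$query_id, h$ref_id)
    h[order(k), c("query_id", "ref_id", "identity_pct", "evalue")]
  }
  expect_equal(key(h1), key(h2), ignore_attr = TRUE)
})

test_that("copy-number summary fractions", {
  db <- refdb_fixture()
  mk <- function(qids, refidx, genome = "gA") {
    seq_records(qids, db$seq[refidx], genome_id = genome)
  }
  # each ref hit once -> all singletons
  h1 <- screen_pathways(mk(c("q1", "q2"), c(1, 2)), db)
  s1 <- copy_number_summary(h1)
  expect_equal(unname(s1$fractions["1"]), 1)
  # one ref hit twice, one once -> 0.5 / 0.5
  h2 <- screen_pathways(mk(c("q1", "q2", "q3"), c(1, 1, 2)), db)
  s2 <- copy_number_summary(h2)
  expect_equal(unname(s2$fractions["1"]), 0.5)
  expect_equal(unname(s2$fractions["2"]), 0.5)
  # planted duplications match generator truth: 2 singles, 1 triple
  h3 <- screen_pathways(mk(c("a", "b", "c1", "c2", "c3"),
                           c(1, 2, 3, 3, 3)), db)
  s3 <- copy_number_summary(h3)
  expect_equal(unname(s3$fractions["1"]), 2 / 3)
  expect_equal(unname(s3$fractions["3"]), 1 / 3)
  expect_equal(sum(s3$fractions), 1)
})

test_that("type_lina: self, diagnostic substitutions, catalytic loss", {
  v <- simulate_lina_variants(seed = 84)
  refs <- setNames(v$seq[v$id != "frame"], v$id[v$id != "frame"])
  # a reference typed against the set is 100% to itself
  r0 <- type_lina(seq_records("self", refs[["type-1"]]), refs)
  expect_equal(unname(r0$identities["type-1"]), 100)
  expect_equal(r0$best_variant, "type-1")
  # substitutions only at 23 (A) and 35 (I -> V): identity 98.7, residues
  t1 <- refs[["type-1"]]
  t1 <- paste0(substr(t1, 1, 22), "A", substr(t1, 24, 34), "I",
               substr(t1, 36, 154))
  q <- paste0(substr(t1, 1, 22), "G", substr(t1, 24, 34), "V",
              substr(t1, 36, 154))
  refs2 <- refs; refs2[["type-1"]] <- t1
  rep <- type_lina(seq_records("WS5A3p_like", q), refs2)
  expect_equal(rep$best_variant, "type-1")
  expect_equal(sprintf("%.1f", rep$identities[["type-1"]]), "98.7")
  expect_equal(unname(rep$residues["23"]), "G")
  expect_equal(unname(rep$residues["35"]), "V")
  # catalytic rule: D25N breaks catalytic_ok
  base <- refs[["type-1"]]
  d25 <- paste0(substr(base, 1, 19), "K",            # K20
                substr(base, 21, 24), "D",           # D25
                substr(base, 26, 72), "H",           # H73
                substr(base, 74, 95), "L",           # L96
                substr(base, 97, 128), "R",          # R129
                substr(base, 130, 130), "A",         # A131
                substr(base, 132, 154))
  ok <- type_lina(seq_records("ok", d25), refs)
  expect_true(ok$catalytic_ok)
  expect_equal(ok$enantiomer_call, "minus_preferring")
  broken <- paste0(substr(d25, 1, 24), "N", substr(d25, 26, 154))
  r2 <- type_lina(seq_records("broken", broken), refs)
  expect_false(r2$catalytic_ok)
  # unrelated query: best_variant "none", residues unset
  set.seed(85)
  r3 <- type_lina(seq_records("rand", rand_prot(154)), refs)
  expect_equal(r3$best_variant, "none")
  expect_length(r3$residues, 0)
  expect_equal(r3$enantiomer_call, "indeterminate")
})

test_that("residue read-off survives query insertions (alignment projected)", {
  v <- simulate_lina_variants(seed = 86)
  refs <- setNames(v$seq[v$id != "frame"], v$id[v$id != "frame"])
  base <- refs[["type-1"]]
  # insert 5 residues after position 50: positions > 50 must still be
  # read at reference coordinates
  ins <- paste0(substr(base, 1, 50), "GGGGG", substr(base, 51, 154))
  r <- type_lina(seq_records("ins", ins), refs)
  expect_equal(r$best_variant, "type-1")
  for (p in c("20", "73", "96", "129", "131"))
    expect_equal(unname(r$residues[p]),
                 substr(base, as.integer(p), as.integer(p)))
})
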