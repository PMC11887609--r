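test_that("exact deduplication keeps first copies and is idempotent", {
  s <- seq_set(c("x1", "x2", "x3"), c("ACGTACGTAC", "ACGTACGTAC", "GGGGCCCCAA"))
  d <- dedup_exact(s)
  expect_identical(d$id, c("x1", "x3"))
  expect_length(dedup_exact(seq_set(character(), character())), 0)

  # 10 random sequences with 2 planted duplicates: 8 kept, checked against
  # brute-force pairwise comparison
  base <- vapply(1:8, function(i) random_dna(60, seed = i), "")
  seqs <- c(base, base[c(2, 5)])
  ss <- seq_set(sprintf("s%d", 1:10), seqs)
  expected_dups <- sum(vapply(seq_along(seqs), function(i)
    any(vapply(seq_len(i - 1), function(j) seqs[i] == seqs[j], TRUE)), TRUE))
  d <- dedup_exact(ss)
  expect_length(d, 10 - expected_dups)
  expect_length(d, 8)
  expect_identical(dedup_exact(d)$seq, d$seq)
})

test_that("the exclusion screen removes similar records and only those", {
  excl <- seq_set("rRNA1", random_dna(300, seed = 21))
  hidden <- paste0(random_dna(50, seed = 22),
                   substr(excl$seq, 1, 200),
                   random_dna(50, seed = 23))
  far <- random_dna(280, seed = 24)
  db <- reference_db(seq_set(c("copy", "embedded", "unrelated"),
                             c(excl$seq, hidden, far)))
  scr <- screen_exclusion(db, excl, min_identity = 0.8, min_cov = 0.5)
  expect_identical(scr$records$id, "unrelated")
  expect_setequal(attr(scr, "exclusion_report")$id, c("copy", "embedded"))
  # embedded case: 200/300 coverage at 100 percent identity
  expect_gte(attr(scr, "exclusion_report")$best_hit_identity[2], 0.99)

  # never removes a record whose best exhaustive-alignment identity is
  # below threshold
  kept <- scr$records$id
  for (id in kept) {
    st <- amoacap:::align_stats_bothstrands(
      db$records$seq[db$records$id == id], excl$seq)
    expect_true(st$identity < 0.8 || st$shorter_cov < 0.5)
  }
})

test_that("recruitment power counts alignable database members", {
  g <- test_genes(2)
  q <- g$seq[1]
  recs <- seq_set(sprintf("r%d", 1:7),
                  c(rep(q, 5), g$seq[2], random_dna(600, seed = 31)))
  db <- reference_db(recs)
  expect_identical(recruitment_power(db, q, min_identity = 0.99), 5L)
  # no shared 12-mers: zero
  db0 <- reference_db(seq_set("far", random_dna(600, seed = 32)))
  expect_identical(recruitment_power(db0, q, min_identity = 0.5), 0L)

  # diverged relatives above/below the identity cut-off, verified by
  # brute-force alignment
  rel <- vapply(1:3, function(i) diverge_cds(q, 0.02, seed = 100 + i), "")
  db2 <- reference_db(seq_set(sprintf("rel%d", 1:3), rel))
  ids <- vapply(rel, function(r)
    amoacap:::align_stats_bothstrands(r, q)$identity, 0)
  expect_true(all(ids >= 0.95))
  expect_identical(recruitment_power(db2, q, min_identity = 0.95), 3L)
})

test_that("curation wrapper records stage counts", {
  g <- test_genes(2)
  recs <- seq_set(c("a", "b", "c"), c(g$seq[1], g$seq[1], g$seq[2]))
  db <- curate_refdb(recs, labels = data.frame(
    id = c("a", "b", "c"), gene_family = "amoA-AOA", clade = "cl1"))
  expect_equal(db$n_input, 3)
  expect_equal(db$n_after_dedup, 2)
  expect_equal(db$n_after_exclusion, 2)
  expect_identical(db$records$meta$gene_family, rep("amoA-AOA", 2))
})
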