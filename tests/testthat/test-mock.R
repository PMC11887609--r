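test_that("gene families are frame-consistent, divergent and reproducible", {
  g <- generate_gene_family(seed = 3)
  expect_identical(nchar(g$seq), c(654L, 702L, 738L, 768L, 792L, 846L))
  expect_true(all(substr(g$seq, 1, 3) == "ATG"))
  last3 <- substr(g$seq, nchar(g$seq) - 2, nchar(g$seq))
  expect_true(all(last3 %in% c("TAA", "TAG", "TGA")))
  # no internal in-frame stops
  for (s in g$seq) {
    cods <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 1, 3))
    expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
  }
  # pairwise identities below the OTU threshold margin (exhaustive global
  # alignment over all pairs)
  pairs <- utils::combn(length(g), 2)
  ids <- apply(pairs, 2, function(p) global_identity(g$seq[p[1]], g$seq[p[2]]))
  expect_true(all(ids <= 0.85))
  # determinism and single-gene case
  expect_identical(generate_gene_family(seed = 3)$seq, g$seq)
  expect_length(generate_gene_family(n_genes = 1, lengths = 654, seed = 5), 1)
  expect_error(generate_gene_family(lengths = 300), "\\[400, 1000\\]")
})

test_that("mock construction follows the molar dilution design", {
  g <- test_genes(3)
  m0 <- build_mock(g, seed = 2)
  expect_length(m0$constructs, 3)
  expect_true(all(m0$ratio == m0$ratio[1]))
  expect_equal(sum(m0$ratio), 2)
  m1 <- build_mock(g, dilution_ratio = 1000, seed = 2)
  expect_length(m1$constructs, 4)
  expect_equal(m1$ratio[4], 1000)
  expect_equal(m1$constructs[[4]]$insert_len, 0)
  expect_equal(m1$constructs[[4]]$total_len, 2786)
  m2 <- build_mock(g, dilution_ratio = 100000, seed = 2)
  expect_equal(m2$ratio[4], 100000)
  expect_error(build_mock(g, dilution_ratio = -1), "non-negative")
  # insert occupies [vector_len, total_len) of the construct
  con <- m0$constructs[[1]]
  expect_identical(substr(con$seq, con$insert_start + 1, con$total_len),
                   g$seq[1])
  expect_equal(con$total_len, 2739 + nchar(g$seq[1]))
})

test_that("copies per ng follows the mass balance closed form", {
  g6 <- generate_gene_family(seed = 4)
  diluted <- build_mock(g6, dilution_ratio = 1000, seed = 4)
  v <- copies_per_ng(diluted)
  m_bp <- 650 / 6.022e23 * 1e9
  by_hand <- 2 / ((sum(2 / 6 * (nchar(g6$seq) + 2739)) + 1000 * 2786) * m_bp)
  expect_equal(v, by_hand)
  expect_equal(round(log10(v)), 6)   # approximately 1e6 copies/ng

  single <- community_spec(list(plasmid_construct(
    "c1", generate_vector(2739, 1), paste0("ATG", strrep("AAA", 248), "TAA"))), 1)
  expect_equal(copies_per_ng(single), 1 / (3489 * m_bp), tolerance = 1e-12)
  expect_equal(copies_per_ng(single) / 1e8, 2.655, tolerance = 0.005)
  expect_equal(copies_per_ng(single, gene_predicate = function(con) 0), 0)
  # 1/x scaling in the diluent ratio
  sweep <- vapply(c(1e3, 1e4, 1e5), function(x)
    copies_per_ng(build_mock(g6, dilution_ratio = x, seed = 4)), 0)
  expect_equal(sweep[1] / sweep[2], 10, tolerance = 0.01)
  expect_equal(sweep[2] / sweep[3], 10, tolerance = 0.01)
})

test_that("insert and contained fractions match their closed forms", {
  vec <- generate_vector(2739, 7)
  g750 <- paste0("ATG", strrep("ACC", 248), "TAA")
  single <- community_spec(list(plasmid_construct("c", vec, g750)), 1)
  expect_equal(expected_insert_fraction(single), 750 / 3489)
  expect_equal(round(100 * expected_insert_fraction(single)), 21)
  # g = V gives one half
  gv <- community_spec(list(plasmid_construct(
    "c", vec, paste0("ATG", strrep("ACC", (2739 - 6) / 3), "TAA")))
    , 1)
  expect_equal(expected_insert_fraction(gv), 0.5, tolerance = 1e-3)
  # contained fraction: (750 - 199) / 3489 at 200 nt fragments
  expect_equal(expected_contained_fraction(single, 200), 551 / 3489)
  expect_equal(expected_contained_fraction(single, 1),
               expected_insert_fraction(single))
  # default six-gene mock reproduces the non-capture mapped-ratio expectation
  mock <- build_mock(generate_gene_family(seed = 7), seed = 7)
  expect_equal(expected_insert_fraction(mock), 4500 / 20934)
  expect_equal(expected_contained_fraction(mock, 200), 3306 / 20934)
  expect_equal(round(100 * expected_contained_fraction(mock, 200), 1), 15.8)
  # containment never exceeds the base fraction; equality only at L = 1
  for (L in c(1, 50, 200, 400)) {
    expect_lte(expected_contained_fraction(mock, L),
               expected_insert_fraction(mock))
  }
  expect_lt(expected_contained_fraction(mock, 2),
            expected_insert_fraction(mock))
})

test_that("Monte-Carlo fragmentation converges to the contained closed form", {
  mock <- build_mock(generate_gene_family(seed = 8), seed = 8)
  n <- 2e5
  fr <- fragment_community(mock, n, frag_len_mean = 200, frag_len_sd = 0,
                           seed = 8, sequences = FALSE)
  p <- expected_contained_fraction(mock, 200)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(fr$contained) - p), 3 * se)
})

test_that("diverged homologues preserve frame and hit the divergence target", {
  g <- test_genes(1)
  d <- diverge_cds(g$seq[1], 0.08, seed = 5)
  expect_identical(nchar(d), nchar(g$seq[1]))
  expect_identical(substr(d, 1, 3), "ATG")
  cods <- substring(d, seq(1, nchar(d) - 3, 3), seq(3, nchar(d) - 1, 3))
  expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
  pid <- 1 - amoacap:::hamming(d, g$seq[1]) / nchar(d)
  expect_gt(pid, 0.88); expect_lt(pid, 0.96)
})
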