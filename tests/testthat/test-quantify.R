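test_that("seed-and-extend mapping assigns reads to their source OTU", {
  g <- test_genes(2, seed = 82)
  otus <- data.frame(otu_id = c("OTU_1", "OTU_2"), representative = g$seq,
                     stringsAsFactors = FALSE)
  read <- substr(g$seq[1], 101, 300)
  asn <- map_reads(read, otus)
  expect_identical(asn$otu, "OTU_1")
  # reverse-strand reads map too
  expect_identical(map_reads(revcomp(read), otus)$otu, "OTU_1")
  # one substitution inside the first seed is tolerated (multi-seed rescue)
  mut <- read
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read, 10, 10))[1]
  expect_identical(map_reads(mut, otus)$otu, "OTU_1")
  # a read from elsewhere stays unassigned
  expect_true(is.na(map_reads(random_dna(200, 83), otus)$otu))
  # equal-best ties across OTUs are discarded
  dup <- data.frame(otu_id = c("OTU_1", "OTU_2"),
                    representative = c(g$seq[1], g$seq[1]),
                    stringsAsFactors = FALSE)
  expect_true(is.na(map_reads(read, dup)$otu))
  # a read overhanging the representative end fails the aligned-fraction rule
  over <- paste0(random_dna(40, 84), substr(g$seq[1], 1, 160))
  expect_true(is.na(map_reads(over, otus,
                              mapping_params(min_aligned_fraction = 0.9))$otu))
})

test_that("pair mapping enforces the same-OTU rule", {
  g <- test_genes(2, seed = 85)
  otus <- data.frame(otu_id = c("OTU_1", "OTU_2"), representative = g$seq,
                     stringsAsFactors = FALSE)
  p <- make_pairs(c(substr(g$seq[1], 1, 150), substr(g$seq[1], 1, 150)),
                  c(revcomp(substr(g$seq[1], 201, 350)),
                    revcomp(substr(g$seq[2], 201, 350))))
  asn <- map_read_pairs(p, otus)
  expect_identical(asn$otu, c("OTU_1", NA_character_))
})

test_that("truth-aware mapping accuracy is near-perfect for contained reads", {
  g <- generate_gene_family(seed = 86)
  mock <- build_mock(g, seed = 86)
  fr <- fragment_community(mock, 4000, seed = 86)
  fr <- fr[fr$contained, ]
  rp <- sequence_paired(fr, read_len = 300, error_rate = 0, seed = 86)
  otus <- data.frame(otu_id = g$id, representative = g$seq,
                     stringsAsFactors = FALSE)
  asn <- map_reads(rp$fwd, otus)
  ok <- !is.na(asn$otu) & asn$otu == rp$truth$gene_id
  expect_gte(mean(ok), 0.99)
})

test_that("RPKMS follows its formula and scale invariances", {
  t1 <- rpkms(100, 800, 1e6)
  expect_equal(as.numeric(t1$rpkms), 125)
  expect_equal(as.numeric(rpkms(0, 800, 1e6)$rpkms), 0)
  # doubling counts and totals together leaves RPKMS unchanged
  cnt <- matrix(c(10, 40, 0, 25), nrow = 2)
  a <- rpkms(cnt, c(700, 850), c(1000, 2000))
  b <- rpkms(2 * cnt, c(700, 850), 2 * c(1000, 2000))
  expect_equal(a$rpkms, b$rpkms)
  expect_error(rpkms(10, 0, 100), "positive")
  expect_error(rpkms(matrix(200, 1, 1), 700, 100), "exceed")
})

test_that("mapped ratio and enrichment factor behave at the boundaries", {
  asn <- data.frame(read_id = c("a", "b", "c"),
                    otu = c("OTU_1", NA, "OTU_2"), score = 1)
  expect_equal(mapped_ratio(asn, 3), 2 / 3)
  expect_equal(mapped_ratio(asn[0, ], 10), 0)
  expect_equal(mapped_ratio(3, 3), 1)
  expect_equal(enrichment_factor(0.5, 0.5), 1)
  expect_lt(enrichment_factor(0.1, 0.5), 1)
  # the dilution-series arithmetic: 63.1 percent capture over the analytic
  # non-capture expectation gives roughly the 990-fold enrichment floor
  expect_equal(enrichment_factor(0.631, 0.000637), 990.6, tolerance = 0.001)
  z <- enrichment_factor(0.5, 0)
  expect_true(is.infinite(z))
  expect_true(attr(z, "undefined"))
})

test_that("analytic rarefaction matches the hypergeometric expectation", {
  # two OTUs at 50/50: one expected OTU in a draw of 1
  cnt <- c(50, 50)
  r <- rarefaction(cnt, sizes = c(1, 100))
  expect_equal(r$expected_otus[r$size == 1], 1)
  expect_equal(r$expected_otus[r$size == 100], 2)   # full draw: exact richness
  # samples under the mapping floor are excluded
  expect_equal(nrow(rarefaction(c(49, 50), min_mapped = 100)), 0)
  expect_equal(nrow(rarefaction(c(50, 50), min_mapped = 100)), 20)
  # independent oracle: vegan's rarefy implements the same expectation
  counts <- c(120, 60, 30, 15, 5, 1)
  sizes <- c(10, 50, 150)
  ours <- rarefaction(counts, sizes = sizes, min_mapped = 100)
  veg <- as.numeric(vegan::rarefy(counts, sizes))
  expect_equal(ours$expected_otus, veg, tolerance = 1e-8)
})
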