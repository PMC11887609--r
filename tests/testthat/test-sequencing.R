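test_that("PCR multiplicities follow the Bernoulli doubling process", {
  f <- data.frame(source_id = "s", gene_id = NA, start = 0L, length = 60L,
                  strand = "+",
                  seq = vapply(1:200, function(i) random_dna(60, i), ""),
                  on_target = TRUE, contained = TRUE, is_chimera = FALSE,
                  multiplicity = 1, stringsAsFactors = FALSE)
  expect_identical(simulate_pcr(f, pcr_model(cycles = 0), 1)$multiplicity,
                   f$multiplicity)
  det <- simulate_pcr(f, pcr_model(cycles = 3, efficiency = 1,
                                   chimera_rate = 0), 1)
  expect_true(all(det$multiplicity == 8))
  amp <- simulate_pcr(f, pcr_model(cycles = 5, efficiency = 0.9,
                                   chimera_rate = 0), 2)
  m <- amp$multiplicity
  se <- stats::sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - 1.9^5), 3 * se)
})

test_that("PCR chimeras join two templates at a shared k-mer", {
  shared <- random_dna(12, 91)
  a <- paste0(random_dna(80, 92), shared, random_dna(80, 93))
  b <- paste0(random_dna(80, 94), shared, random_dna(80, 95))
  f <- data.frame(source_id = c("a", "b"), gene_id = NA, start = 0L,
                  length = nchar(c(a, b)), strand = "+", seq = c(a, b),
                  on_target = TRUE, contained = TRUE, is_chimera = FALSE,
                  multiplicity = 1, stringsAsFactors = FALSE)
  out <- simulate_pcr(f, pcr_model(cycles = 10, chimera_rate = 0.2), 3)
  chim <- out[out$is_chimera, ]
  expect_gt(nrow(chim), 0)
  for (cs in chim$seq) {
    expect_true(grepl(shared, cs, fixed = TRUE))
    expect_false(cs %in% c(a, b))
    # prefix from one parent, suffix from the other
    expect_true((startsWith(a, substr(cs, 1, 20)) &&
                   endsWith(b, substr(cs, nchar(cs) - 19, nchar(cs)))) ||
                  (startsWith(b, substr(cs, 1, 20)) &&
                     endsWith(a, substr(cs, nchar(cs) - 19, nchar(cs)))))
  }
})

test_that("paired-end sequencing reads both fragment ends faithfully", {
  frag <- random_dna(200, 96)
  f <- data.frame(source_id = "s", gene_id = "g", start = 0L, length = 200L,
                  strand = "+", seq = frag, on_target = TRUE,
                  contained = TRUE, is_chimera = FALSE, multiplicity = 1,
                  stringsAsFactors = FALSE)
  rp <- sequence_paired(f, read_len = 300, error_rate = 0, seed = 1)
  expect_equal(nchar(rp$fwd$seq), 200)
  expect_equal(nchar(rp$rev$seq), 200)
  expect_identical(rp$fwd$seq, frag)
  expect_identical(revcomp(rp$rev$seq), frag)
  # long fragments give non-overlapping 300 nt mates that tile the ends
  f2 <- f; f2$seq <- random_dna(700, 97); f2$length <- 700L
  rp2 <- sequence_paired(f2, read_len = 300, error_rate = 0, seed = 1)
  expect_identical(rp2$fwd$seq, substr(f2$seq, 1, 300))
  expect_identical(rp2$rev$seq, revcomp(substr(f2$seq, 401, 700)))
  # substitution errors are binomial at the requested rate
  f3 <- do.call(rbind, replicate(2500, f, simplify = FALSE))
  rp3 <- sequence_paired(f3, read_len = 300, error_rate = 1e-3, seed = 2)
  n_err <- sum(vapply(seq_along(rp3$fwd$seq), function(i)
    amoacap:::hamming(rp3$fwd$seq[i], frag), 0L))
  n_bases <- 2500 * 200
  expect_lt(abs(n_err - n_bases * 1e-3), 3 * sqrt(n_bases * 1e-3))
  # qualities encode the error rate
  expect_identical(substr(rp3$fwd$qual[1], 1, 1), intToUtf8(30 + 33))
})

test_that("N-linker concatenation stitches mates for the chimera screen", {
  p <- make_pairs("ACGTACGTAC", "GGGGGTTTTT")
  cc <- nlinker_concat(p, linker_len = 50)
  expect_equal(nchar(cc$seq), 10 + 50 + 10)
  expect_identical(substr(cc$seq, 11, 60), strrep("N", 50))
  expect_identical(substr(cc$seq, 1, 10), "ACGTACGTAC")
  expect_identical(substr(cc$seq, 61, 70), revcomp("GGGGGTTTTT"))
})

test_that("degenerate primer matching honours IUPAC codes", {
  pr <- francis_primers()
  g <- test_genes(1, seed = 31)
  tpl_c <- implant_primer_sites(g$seq[1], pr, 0, 0, product_len = 635, seed = 1)
  prod <- amoacap:::find_product(tpl_c, pr)
  expect_equal(nchar(prod$seq), 635)
  expect_equal(prod$mismatches, 0)
  # S in the forward primer matches C and G templates equally
  site_c <- sub("^S", "C", pr$fwd)
  site_g <- sub("^S", "G", pr$fwd)
  for (site in c(site_c, site_g)) {
    tpl <- paste0(random_dna(30, 5), site, random_dna(30, 6))
    hit <- amoacap:::best_primer_site(pr$fwd, tpl, 3)
    expect_equal(hit$mismatches, 0)
  }
})

test_that("amplicon simulation reproduces primer bias", {
  pr <- francis_primers()
  g <- generate_gene_family(seed = 33)
  tpl <- g$seq
  tpl[1] <- implant_primer_sites(tpl[1], pr, 0, 0, seed = 41)
  tpl[2] <- implant_primer_sites(tpl[2], pr, 2, 0, seed = 42)
  tpl[3] <- implant_primer_sites(tpl[3], pr, 1, 2, seed = 43)
  templates <- seq_set(c("aoa_perfect", "aoa_mm2", "aoa_mm3",
                         "aob1", "aob2", "aob3"), tpl)
  reads <- simulate_amplicon(templates, pr, pcr_model(cycles = 35),
                             long_read = TRUE, n_reads = 2000,
                             error_rate = 0, seed = 44)
  tab <- attr(reads, "products")
  expect_equal(tab$mismatches[1:3], c(0L, 2L, 3L))
  expect_true(all(is.na(tab$product_len[4:6])))   # AOB: no primer sites
  share <- table(reads$meta$template) / length(reads)
  expect_gte(share[["aoa_perfect"]], 0.95)
  expect_false(any(c("aob1", "aob2", "aob3") %in% reads$meta$template))
  # adding mismatches never increases a template's expected product share
  expect_true(all(diff(tab$weight[1:3]) <= 0))
  # a zero-mismatch product is the 635 nt region
  expect_equal(tab$product_len[1], 635L)
})
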