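test_that("fragmentation is mass-weighted, truth-tagged and reproducible", {
  g <- test_genes(2)
  mock <- build_mock(g, seed = 12)
  f1 <- fragment_community(mock, 2000, seed = 12)
  f2 <- fragment_community(mock, 2000, seed = 12)
  expect_identical(f1$seq, f2$seq)
  expect_false(identical(
    f1$start, fragment_community(mock, 2000, seed = 13)$start))
  # sequences equal the circular substring of their source
  con <- mock$constructs[[1]]
  sel <- which(f1$source_id == con$construct_id)[1:20]
  for (i in sel) {
    s <- amoacap:::circ_substr(con$seq, f1$start[i], f1$length[i])
    if (f1$strand[i] == "-") s <- revcomp(s)
    expect_identical(f1$seq[i], s)
  }
  # truth: on_target iff the fragment overlaps the insert
  ins <- con$insert_start
  G <- con$total_len
  for (i in sel) {
    covered <- (f1$start[i] + seq_len(f1$length[i]) - 1) %% G
    expect_identical(f1$on_target[i], any(covered >= ins))
    expect_identical(f1$contained[i], all(covered >= ins) &&
                       f1$start[i] + f1$length[i] <= G)
  }
  # a construct with no insert yields only off-target fragments
  empty <- community_spec(list(plasmid_construct("e", generate_vector(2786, 1))), 1)
  fe <- fragment_community(empty, 500, seed = 1)
  expect_false(any(fe$on_target))
  expect_error(fragment_community(empty, 10, frag_len_mean = 3000),
               "shortest construct")
})

test_that("size selection keeps fragments at or above the threshold", {
  f <- data.frame(source_id = "s", gene_id = NA, start = 0L,
                  length = c(140L, 150L, 160L), strand = "+",
                  seq = c(random_dna(140, 1), random_dna(150, 2),
                          random_dna(160, 3)),
                  on_target = FALSE, contained = FALSE, is_chimera = FALSE,
                  multiplicity = 1, stringsAsFactors = FALSE)
  expect_identical(size_select(f, 150)$length, c(150L, 160L))
  expect_identical(size_select(f, 100)$length, f$length)
  # removal fraction matches the normal tail (lengths are rounded draws)
  mock <- build_mock(test_genes(2), seed = 14)
  fr <- fragment_community(mock, 2e4, frag_len_mean = 200, frag_len_sd = 30,
                           seed = 14, sequences = FALSE)
  p <- stats::pnorm(149.5, 200, 30)
  removed <- 1 - nrow(size_select(fr, 150)) / nrow(fr)
  expect_lt(abs(removed - p), 3 * sqrt(p * (1 - p) / 2e4))
})

test_that("capture retains probe-matching fragments and only those", {
  g <- test_genes(2)
  mock <- build_mock(g, seed = 15)
  probes <- design_probes(seq_set(g$id, g$seq), 100, 50)$probes
  fr <- size_select(fragment_community(mock, 4000, seed = 15), 150)
  strict <- capture_model(nonspecific_rate = 0, rounds = 1)
  kept <- simulate_capture(fr, probes, strict, seed = 15)
  # specificity: every retained fragment truly overlaps the insert
  expect_true(all(kept$on_target))
  # fragments wholly inside a tiled insert are always retained
  inside <- fr[fr$contained, ]
  kept_in <- simulate_capture(inside, probes, strict, seed = 15)
  expect_equal(nrow(kept_in), nrow(inside))
  # rounds = 0 is a pass-through
  expect_identical(simulate_capture(fr, probes,
                                    capture_model(rounds = 0), 1), fr)
  # empty probe set with zero nonspecific rate drops everything
  none <- probes[0, ]
  expect_equal(nrow(simulate_capture(fr, none, strict, 1)), 0)
  # a fragment with zero probe overlap is dropped
  far <- fr[!fr$on_target, ][1:50, ]
  expect_equal(nrow(simulate_capture(far, probes, strict, 1)), 0)
})

test_that("capture enriches the on-target fraction as expected", {
  g <- generate_gene_family(seed = 16)
  mock <- build_mock(g, seed = 16)
  probes <- design_probes(seq_set(g$id, g$seq), 100, 50)$probes
  fr <- fragment_community(mock, 6000, frag_len_mean = 200, frag_len_sd = 0,
                           seed = 16)
  # pre-capture on-target fraction: sum(g + L - 1) / sum(G)
  pre_expect <- sum(nchar(g$seq) + 199) / sum(nchar(g$seq) + 2739)
  pre <- mean(fr$on_target)
  expect_lt(abs(pre - pre_expect), 3 * sqrt(pre_expect * (1 - pre_expect) / 6000))
  kept <- simulate_capture(fr, probes, capture_model(nonspecific_rate = 1e-4),
                           seed = 16)
  expect_gt(mean(kept$on_target), 0.99)
  # monotonicity: a second round never lowers the on-target fraction,
  # and a higher nonspecific rate never raises it
  kept2 <- simulate_capture(fr, probes,
                            capture_model(nonspecific_rate = 1e-4, rounds = 2),
                            seed = 16)
  expect_gte(mean(kept2$on_target), mean(kept$on_target))
  loose <- simulate_capture(fr, probes,
                            capture_model(nonspecific_rate = 0.05), seed = 16)
  expect_lte(mean(loose$on_target), mean(kept$on_target))
})

test_that("mismatch-tolerant capture keeps diverged targets", {
  g <- test_genes(1)
  # probes tiled from a 5 percent diverged relative still capture fragments
  rel <- diverge_cds(g$seq[1], 0.05, seed = 17)
  probes <- design_probes(seq_set("rel", rel), 100, 50)$probes
  mock <- build_mock(g[1], seed = 17)
  fr <- size_select(fragment_community(mock, 1500, seed = 17), 150)
  kept <- simulate_capture(fr, probes, capture_model(nonspecific_rate = 0),
                           seed = 17)
  expect_gt(nrow(kept), 0)
  expect_true(all(kept$on_target))
  contained <- sum(fr$contained)
  expect_gt(nrow(kept), 0.8 * contained)
})
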