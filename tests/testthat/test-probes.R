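test_that("tiling places probes on the stride grid with a right-anchored tail", {
  db <- seq_set(c("g100", "g300", "g99"),
                c(random_dna(100, 41), random_dna(300, 42), random_dna(99, 43)))
  ps <- tile_probes(db, probe_len = 100, stride = 50)
  expect_identical(ps$offset[ps$source_id == "g100"], 0L)
  expect_identical(ps$offset[ps$source_id == "g300"],
                   c(0L, 50L, 100L, 150L, 200L))
  expect_false("g99" %in% ps$source_id)
  expect_true(all(nchar(ps$seq) == 100))
  # off-grid record length: the final probe is anchored at the 3' end
  ps2 <- tile_probes(seq_set("g230", random_dna(230, 44)), 100, 50)
  expect_identical(ps2$offset, c(0L, 50L, 100L, 130L))
})

test_that("probe dedup collapses shared blocks and is idempotent", {
  shared <- random_dna(100, 45)
  db <- seq_set(c("a", "b"), c(paste0(shared, random_dna(100, 46)),
                               paste0(shared, random_dna(100, 47))))
  ps <- tile_probes(db, 100, 100)
  expect_equal(sum(ps$seq == shared), 2)
  dd <- dedup_probes(ps)
  expect_equal(sum(dd$seq == shared), 1)
  expect_identical(dd$source_id[dd$seq == shared], "a")
  expect_identical(dedup_probes(dd)$seq, dd$seq)
  # all-unique probes unchanged
  ps3 <- tile_probes(seq_set("x", random_dna(300, 48)), 100, 50)
  expect_identical(dedup_probes(ps3)$seq, ps3$seq)
})

test_that("coverage is the union of probe footprints over database bases", {
  rec <- seq_set("r", random_dna(200, 49))
  one <- tile_probes(rec, 100, 300)   # single probe at offset 0 ... plus tail
  # hand-build probe sets for the interval arithmetic cases
  mk <- function(offs) {
    structure(data.frame(probe_id = sprintf("r:%d", offs), source_id = "r",
                         offset = offs,
                         seq = substring(rec$seq, offs + 1, offs + 100),
                         stringsAsFactors = FALSE),
              probe_len = 100L, stride = 50L,
              class = c("probe_set", "data.frame"))
  }
  expect_equal(probe_coverage(mk(0L), rec), 0.5)
  expect_equal(probe_coverage(mk(c(0L, 50L)), rec), 0.75)
  expect_equal(probe_coverage(mk(c(0L, 100L)), rec), 1.0)
  # monotone in added probes
  expect_gte(probe_coverage(mk(c(0L, 50L)), rec), probe_coverage(mk(0L), rec))
  # full tiling covers everything when all records reach probe length
  db <- seq_set(c("a", "b"), c(random_dna(350, 50), random_dna(120, 51)))
  full <- tile_probes(db, 100, 50)
  expect_equal(probe_coverage(full, db), 1.0)
  d <- design_probes(db, 100, 50)
  expect_equal(d$coverage, 1.0)
  expect_equal(d$coverage_raw, 1.0)
  expect_identical(d$report$n_probes >= 1L, c(TRUE, TRUE))
})
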