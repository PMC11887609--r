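test_that("the ecotype map is exactly the three-clade correspondence", {
  m <- ecotype_map()
  expect_length(m, 3)
  expect_identical(unname(m), c("WCA", "WCB", "NMC"))
  expect_identical(unname(m[paste0("NP-", "ε", "-2")]), "WCA")
  expect_identical(unname(m[paste0("NP-", "α", "-2.2.2.1")]), "WCB")
  expect_identical(unname(m[paste0("NP-", "γ", "-2.1")]), "NMC")
})

test_that("taxonomy transfer uses best hits, ties and the identity floor", {
  g <- test_genes(2, seed = 87)
  labels <- data.frame(id = c("gene1", "gene2"),
                       gene_family = c("amoA-AOA", "amoA-AOA"),
                       clade = c(names(ecotype_map())[3], "NP-δ"),
                       stringsAsFactors = FALSE)
  db <- curate_refdb(seq_set(g$id, g$seq), labels)
  otus <- data.frame(otu_id = c("OTU_1", "OTU_2"),
                     representative = c(g$seq[1], random_dna(600, 88)),
                     stringsAsFactors = FALSE)
  tax <- assign_ecotype(assign_taxonomy(otus, db))
  expect_identical(tax$best_ref[1], "gene1")
  expect_equal(tax$identity[1], 100)
  expect_identical(tax$clade[1], names(ecotype_map())[3])
  expect_identical(tax$ecotype[1], "NMC")
  # clade outside the map: ecotype none
  otus2 <- data.frame(otu_id = "OTU_3", representative = g$seq[2],
                      stringsAsFactors = FALSE)
  tax2 <- assign_ecotype(assign_taxonomy(otus2, db))
  expect_identical(tax2$ecotype, "none")
  # an unrelated sequence falls below the floor
  expect_identical(tax$gene_family[2], "unclassified-CuMMO")
  expect_true(is.na(tax$ecotype[2]))

  # equidistant tie between two clades keeps only the shared family rank
  dup_labels <- data.frame(id = c("r1", "r2"),
                           gene_family = c("amoA-AOA", "amoA-AOA"),
                           clade = c("cladeX", "cladeY"),
                           stringsAsFactors = FALSE)
  db2 <- reference_db(seq_set(c("r1", "r2"), c(g$seq[1], g$seq[1])),
                      dup_labels)
  tie <- assign_taxonomy(data.frame(otu_id = "O", representative = g$seq[1],
                                    stringsAsFactors = FALSE), db2)
  expect_identical(tie$gene_family, "amoA-AOA")
  expect_true(is.na(tie$clade))
})

test_that("neighbour joining recovers additive four-taxon topologies", {
  # (A,B) vs (C,D): A/B nearly identical, C/D nearly identical, pairs far
  g <- test_genes(2, seed = 89)
  a <- g$seq[1]
  b <- diverge_cds(a, 0.02, seed = 90)
  c_ <- g$seq[2]
  d <- diverge_cds(c_, 0.02, seed = 91)
  nwk <- build_tree(c(A = a, B = b, C = c_, D = d))
  tree <- attr(nwk, "phylo")
  expect_s3_class(tree, "phylo")
  # the AB|CD split is present in the unrooted tree
  ab <- ape::getMRCA(ape::root(tree, "C"), c("A", "B"))
  tips <- ape::extract.clade(ape::root(tree, "C"), ab)$tip.label
  expect_setequal(tips, c("A", "B"))
  # input order permutation leaves the unrooted topology unchanged
  nwk2 <- build_tree(c(D = d, B = b, C = c_, A = a))
  expect_equal(ape::dist.topo(tree, attr(nwk2, "phylo")), 0,
               ignore_attr = TRUE)
  # three identical sequences: a zero-length star
  s <- a
  nwk3 <- build_tree(c(x = s, y = s, z = s))
  expect_true(all(abs(attr(nwk3, "phylo")$edge.length) < 1e-12))
  expect_error(build_tree(c(x = s, y = s)), "at least 3")
  expect_true(is.character(nwk) && grepl(";$", nwk))
})
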