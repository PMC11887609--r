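# Synthetic mock communities: circular plasmid constructs carrying target-gene
# inserts, a molar dilution series against an empty vector, and the analytic
# expectations (insert base fraction, copies per ng, contained-fragment
# probability) that the sequencing simulation is checked against.

# mass of one base pair of dsDNA in nanograms (650 g/mol convention)
BP_MASS_NG <- 650 / 6.022e23 * 1e9

# stop codons in all three frames of both strands, with no G anywhere, so no
# start codon can occur inside; placed on both flanks of the cloning site so
# the maximal-ORF rule recovers insert CDSs exactly (real cloning vectors
# likewise carry stops/terminators around the multiple cloning site)
CLONING_SITE_FLANK <- strrep("TTAA", 5L)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# random in-frame coding block of n_codons codons, none of them stops
random_codons <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  repeat {
    cod <- paste0(sample(bases, n_codons, replace = TRUE),
                  sample(bases, n_codons, replace = TRUE),
                  sample(bases, n_codons, replace = TRUE))
    bad <- cod %in% STOP_CODONS
    if (!any(bad)) return(paste(cod, collapse = ""))
    cod[bad] <- vapply(which(bad), function(i) {
      repeat {
        x <- paste(sample(bases, 3, replace = TRUE), collapse = "")
        if (!(x %in% STOP_CODONS)) return(x)
      }
    }, "")
    return(paste(cod, collapse = ""))
  }
}

#' Generate a synthetic target-gene family
#'
#' Emits `n_genes` frame-consistent coding sequences (start codon ATG, final
#' stop codon, no internal in-frame stops) whose pairwise global identities
#' stay at or below `pairwise_identity_max`, so each gene founds its own OTU
#' under the default 97 percent clustering threshold. Default lengths span
#' the 651-846 nt range typical of amoA genes, with mean 750.
#'
#' @param n_genes number of genes.
#' @param lengths nt lengths (multiples of 3, within 400-1000 so genes
#'   survive the pipeline's CDS length filter); recycled to `n_genes`.
#' @param pairwise_identity_max maximum allowed pairwise global identity.
#' @param seed integer seed; identical seeds give identical genes.
#' @param max_tries resampling budget before giving up on the identity target.
#' @return A `seq_set` of genes named `gene1..geneN`.
#' @export
generate_gene_family <- function(n_genes = 6L,
                                 lengths = c(654L, 702L, 738L, 768L, 792L, 846L),
                                 pairwise_identity_max = 0.85,
                                 seed = 1L, max_tries = 20L) {
  lengths <- rep_len(as.integer(lengths), n_genes)
  if (any(lengths %% 3 != 0)) stop("gene lengths must be multiples of 3")
  if (any(lengths < 400 | lengths > 1000)) {
    stop("gene lengths must lie in [400, 1000] nt to survive the CDS length filter")
  }
  with_seed(derive_seed(seed, "gene_family"), {
    genes <- character(n_genes)
    for (i in seq_len(n_genes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- paste0("ATG", random_codons(lengths[i] / 3L - 2L),
                       sample(STOP_CODONS, 1))
        ids <- if (i > 1) {
          vapply(genes[seq_len(i - 1)], global_identity, 0, b = cand,
                 USE.NAMES = FALSE)
        } else numeric()
        if (all(ids <= pairwise_identity_max)) {
          genes[i] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not reach the pairwise identity target after ",
                    max_tries, " tries")
    }
    seq_set(paste0("gene", seq_len(n_genes)), genes)
  })
}

#' Mutate a coding sequence while preserving its reading frame
#'
#' Random substitutions at the requested per-base divergence; the start and
#' stop codons are left untouched and substitutions that would create an
#' in-frame stop are resampled, so the mutant remains a clean ORF (as a
#' diverged homologue of the input gene).
#'
#' @param nt an in-frame CDS nucleotide string.
#' @param divergence expected per-base substitution fraction.
#' @param seed integer seed.
#' @return The mutated nucleotide string.
#' @export
diverge_cds <- function(nt, divergence, seed = 1L) {
  with_seed(derive_seed(seed, "diverge_cds"), {
    n <- nchar(nt)
    chars <- strsplit(nt, "")[[1]]
    bases <- c("A", "C", "G", "T")
    sites <- which(stats::runif(n) < divergence)
    sites <- sites[sites > 3 & sites <= n - 3]  # keep start/stop codons
    for (p in sites) {
      old <- chars[p]
      cod_i <- (p - 1) %/% 3
      for (try in 1:10) {
        chars[p] <- sample(setdiff(bases, old), 1)
        cod <- paste(chars[(cod_i * 3 + 1):(cod_i * 3 + 3)], collapse = "")
        if (!(cod %in% STOP_CODONS)) break
        chars[p] <- old
      }
    }
    paste(chars, collapse = "")
  })
}

#' Build a synthetic labelled reference collection around a gene family
#'
#' Emulates a curated database: each input gene plus `n_relatives` diverged
#' homologues, all labelled with the gene's family and clade. Uneven
#' `n_relatives` reproduce the uneven recruitment power of real databases.
#'
#' @param genes a `seq_set` of genes.
#' @param gene_family character vector of family labels per gene.
#' @param clade character vector of clade labels per gene.
#' @param n_relatives integer (recycled) count of diverged homologues per gene.
#' @param divergence per-base divergence of the homologues.
#' @param seed integer seed.
#' @return A list with `records` (`seq_set`) and `labels` (data frame) ready
#'   for [curate_refdb()].
#' @export
make_reference_collection <- function(genes,
                                      gene_family = rep("amoA-AOA", length(genes)),
                                      clade = paste0("clade", seq_along(genes)),
                                      n_relatives = 3L, divergence = 0.05,
                                      seed = 1L) {
  n_relatives <- rep_len(as.integer(n_relatives), length(genes))
  ids <- character(); seqs <- character()
  fam <- character(); cl <- character()
  for (i in seq_along(genes)) {
    ids <- c(ids, genes$id[i]); seqs <- c(seqs, genes$seq[i])
    fam <- c(fam, gene_family[i]); cl <- c(cl, clade[i])
    for (r in seq_len(n_relatives[i])) {
      ids <- c(ids, sprintf("%s_rel%d", genes$id[i], r))
      seqs <- c(seqs, diverge_cds(genes$seq[i], divergence,
                                  seed = derive_seed(seed, paste0(i, "_", r))))
      fam <- c(fam, gene_family[i]); cl <- c(cl, clade[i])
    }
  }
  list(records = seq_set(ids, seqs),
       labels = data.frame(id = ids, gene_family = fam, clade = cl,
                           source = "synthetic", stringsAsFactors = FALSE))
}

#' Generate a circular cloning-vector backbone
#'
#' Random sequence with stop-codon blocks (no start codons) flanking the
#' cloning site at both ends, so inserted CDSs are recovered exactly by the
#' ORF scan.
#'
#' @param len vector length in nt.
#' @param seed integer seed.
#' @return A nucleotide string of length `len`.
#' @export
generate_vector <- function(len, seed = 1L) {
  flank <- CLONING_SITE_FLANK
  if (len < 2 * nchar(flank) + 1) stop("vector too short")
  with_seed(derive_seed(seed, "vector"), {
    mid <- paste(sample(c("A", "C", "G", "T"), len - 2 * nchar(flank),
                        replace = TRUE), collapse = "")
    paste0(flank, mid, flank)
  })
}

#' A circular plasmid construct
#'
#' The insert occupies 0-based coordinates `[vector_len, total_len)` of the
#' construct sequence before circular wrap.
#'
#' @param construct_id identifier.
#' @param vector_seq backbone nucleotide string.
#' @param insert_seq optional insert nucleotide string (NULL for an empty
#'   diluent vector).
#' @param gene_id identifier of the inserted gene (NA when empty).
#' @return An object of class `plasmid_construct`.
#' @export
plasmid_construct <- function(construct_id, vector_seq, insert_seq = NULL,
                              gene_id = NA_character_) {
  vl <- nchar(vector_seq)
  il <- if (is.null(insert_seq)) 0L else nchar(insert_seq)
  structure(list(construct_id = construct_id,
                 seq = paste0(vector_seq, if (is.null(insert_seq)) "" else insert_seq),
                 vector_len = vl, insert_len = il,
                 insert_start = if (il > 0) vl else NA_integer_,
                 total_len = vl + il,
                 gene_id = gene_id, circular = TRUE),
            class = "plasmid_construct")
}

#' Build a mock community from a gene family
#'
#' Each gene is cloned into a shared circular vector backbone; the insert-
#' bearing constructs share 2 molar parts equally (so a `dilution_ratio` of
#' 1000 reproduces the 2:1000 mixture), and a positive `dilution_ratio` adds
#' an empty diluent vector at that many parts. `dilution_ratio = 0` gives the
#' undiluted mock.
#'
#' @param genes a `seq_set` of insert genes.
#' @param vector_len backbone length (default 2739 nt).
#' @param diluent_len empty diluent vector length (default 2786 nt).
#' @param dilution_ratio diluent molar parts per 2 parts of insert constructs.
#' @param seed integer seed for the backbone sequences.
#' @return An object of class `community_spec`: constructs plus molar ratios.
#' @export
build_mock <- function(genes, vector_len = 2739L, diluent_len = 2786L,
                       dilution_ratio = 0, seed = 1L) {
  if (length(genes) == 0) stop("genes must be non-empty")
  if (dilution_ratio < 0) stop("dilution_ratio must be non-negative")
  backbone <- generate_vector(vector_len, seed = derive_seed(seed, "backbone"))
  constructs <- lapply(seq_along(genes), function(i) {
    plasmid_construct(sprintf("construct_%s", genes$id[i]), backbone,
                      genes$seq[i], gene_id = genes$id[i])
  })
  ratio <- rep(2 / length(genes), length(genes))
  if (dilution_ratio > 0) {
    dil <- generate_vector(diluent_len, seed = derive_seed(seed, "diluent"))
    constructs <- c(constructs, list(plasmid_construct("diluent", dil)))
    ratio <- c(ratio, dilution_ratio)
  }
  community_spec(constructs, ratio)
}

#' Assemble a community specification
#'
#' @param constructs list of `plasmid_construct`s.
#' @param ratio positive molar ratios (not necessarily normalised).
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(constructs, ratio) {
  if (length(constructs) == 0) stop("at least one member required")
  if (length(ratio) != length(constructs) || any(ratio <= 0)) {
    stop("one positive molar ratio per construct required")
  }
  structure(list(constructs = constructs, ratio = as.numeric(ratio)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  df <- community_table(x)
  cat("community_spec with", nrow(df), "constructs\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate a community specification
#' @param spec a `community_spec`.
#' @return Data frame of construct ids, lengths (nt), gene ids and ratios.
#' @export
community_table <- function(spec) {
  data.frame(
    construct_id = vapply(spec$constructs, `[[`, "", "construct_id"),
    total_len = vapply(spec$constructs, `[[`, 0L, "total_len"),
    insert_len = vapply(spec$constructs, `[[`, 0L, "insert_len"),
    gene_id = vapply(spec$constructs, `[[`, "", "gene_id"),
    ratio = spec$ratio, stringsAsFactors = FALSE)
}

#' Target-gene copies per nanogram of community DNA
#'
#' Mass balance at the 650 g/mol-per-bp dsDNA convention:
#' `sum(ratio_i * gene_count_i) / sum(ratio_i * total_len_i * m_bp)` with
#' `m_bp = 650 / 6.022e23` grams, expressed per ng.
#'
#' @param spec a `community_spec`.
#' @param gene_predicate function taking a `plasmid_construct` and returning
#'   its target-gene copy count; default counts one per insert-bearing
#'   construct.
#' @param bp_mass_ng mass of one base pair in ng.
#' @return Copies per ng (a real number).
#' @export
copies_per_ng <- function(spec, gene_predicate = NULL,
                          bp_mass_ng = BP_MASS_NG) {
  if (is.null(gene_predicate)) {
    gene_predicate <- function(con) as.integer(con$insert_len > 0)
  }
  counts <- vapply(spec$constructs, gene_predicate, 0)
  lens <- vapply(spec$constructs, `[[`, 0L, "total_len")
  mass <- sum(spec$ratio * lens) * bp_mass_ng
  if (mass <= 0) stop("community has zero total mass")
  sum(spec$ratio * counts) / mass
}

#' Expected fraction of community bases belonging to inserts
#'
#' `sum(ratio_i * insert_len_i) / sum(ratio_i * total_len_i)`.
#'
#' @param spec a `community_spec`.
#' @return A fraction in `[0, 1]`.
#' @export
expected_insert_fraction <- function(spec) {
  ins <- vapply(spec$constructs, `[[`, 0L, "insert_len")
  tot <- vapply(spec$constructs, `[[`, 0L, "total_len")
  sum(spec$ratio * ins) / sum(spec$ratio * tot)
}

#' Probability that a uniformly placed fragment lies wholly inside an insert
#'
#' Closed form for circular constructs:
#' `sum(ratio_i * max(insert_len_i - frag_len + 1, 0)) /
#'  sum(ratio_i * total_len_i)`. At `frag_len = 1` it reduces to the insert
#' base fraction; it explains why the mapped-read ratio of a shotgun sample
#' falls short of the insert base fraction (edge-straddling fragments fail to
#' map).
#'
#' @param spec a `community_spec`.
#' @param frag_len fragment length in nt (>= 1).
#' @return A fraction in `[0, 1]`.
#' @export
expected_contained_fraction <- function(spec, frag_len) {
  stopifnot(frag_len >= 1)
  ins <- vapply(spec$constructs, `[[`, 0L, "insert_len")
  tot <- vapply(spec$constructs, `[[`, 0L, "total_len")
  sum(spec$ratio * pmax(ins - frag_len + 1, 0)) / sum(spec$ratio * tot)
}

#' Write the constructs of a community as FASTA
#'
#' Headers carry the circular flag and 0-based half-open insert coordinates
#' (coordinates wrap modulo construct length).
#'
#' @param spec a `community_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community_fasta <- function(spec, path) {
  ids <- vapply(spec$constructs, function(con) {
    sprintf("%s circular=true insert=%s:%s-%s", con$construct_id,
            ifelse(is.na(con$gene_id), "none", con$gene_id),
            ifelse(con$insert_len > 0, con$insert_start, ""),
            ifelse(con$insert_len > 0, con$total_len, ""))
  }, "")
  write_fasta(seq_set(ids, vapply(spec$constructs, `[[`, "", "seq")), path)
}
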