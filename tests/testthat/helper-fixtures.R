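# Shared fixtures: small gene families and hand-built records used across
# the unit tests. Everything is generated in code; no binary fixtures.

test_genes <- function(n = 3L, seed = 11L) {
  generate_gene_family(n_genes = n, lengths = c(654L, 702L, 738L)[seq_len(n)],
                       seed = seed)
}

random_dna <- function(n, seed = 1L) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}

# read pairs wrapper around explicit mate sequences/qualities
make_pairs <- function(fwd, rev, fq = NULL, rq = NULL, sample = "t") {
  if (is.null(fq)) fq <- vapply(nchar(fwd), function(n)
    phred_encode(rep(35L, n)), "")
  if (is.null(rq)) rq <- vapply(nchar(rev), function(n)
    phred_encode(rep(35L, n)), "")
  ids <- sprintf("%s_read%03d", sample, seq_along(fwd))
  structure(list(fwd = seq_set(paste0(ids, "/1"), fwd, qual = fq),
                 rev = seq_set(paste0(ids, "/2"), rev, qual = rq),
                 truth = data.frame(read_id = ids, stringsAsFactors = FALSE),
                 sample = sample), class = "read_pairs")
}

# error-free reads tiled over a template at the given step
tile_reads <- function(template, read_len = 100L, step = 5L) {
  L <- nchar(template)
  starts <- unique(c(seq(1L, L - read_len + 1L, by = step), L - read_len + 1L))
  substring(template, starts, starts + read_len - 1L)
}

# brute-force single-linkage clustering at the given identity/coverage:
# connected components of the pairwise match graph (independent of the
# greedy centroid path)
bruteforce_clusters <- function(seqs, identity = 0.97, coverage = 0.5) {
  n <- length(seqs)
  adj <- diag(TRUE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- amoacap:::align_stats(seqs[i], seqs[j], type = "local")
      adj[i, j] <- adj[j, i] <-
        st$identity >= identity && st$shorter_cov >= coverage
    }
  }
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 0)
    if (identical(new, comp)) break
    comp <- new
  }
  comp
}
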