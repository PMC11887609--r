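#' PCR model parameters
#'
#' Per-cycle Bernoulli doubling: a molecule duplicates with probability
#' `efficiency` each cycle, so a perfect-match template reaches an expected
#' `(1 + efficiency)^cycles` copies. Primer mismatches depress the effective
#' per-cycle gain multiplicatively (`mismatch_penalty` per mismatch) in the
#' amplicon path. Chimeras arise from template switching during duplication.
#'
#' @param cycles number of PCR cycles.
#' @param efficiency per-cycle duplication probability (default 0.9).
#' @param mismatch_penalty multiplicative efficiency penalty per primer
#'   mismatch (default 0.5).
#' @param chimera_rate probability that a duplication joins two templates at
#'   a shared k-mer (default 1e-4).
#' @param chimera_k exact shared k-mer length for chimeric joins.
#' @return A list of class `pcr_model`.
#' @export
pcr_model <- function(cycles = 20L, efficiency = 0.9, mismatch_penalty = 0.5,
                      chimera_rate = 1e-4, chimera_k = 12L) {
  stopifnot(cycles >= 0, efficiency >= 0, efficiency <= 1)
  structure(list(cycles = as.integer(cycles), efficiency = efficiency,
                 mismatch_penalty = mismatch_penalty,
                 chimera_rate = chimera_rate, chimera_k = as.integer(chimera_k)),
            class = "pcr_model")
}

#' Simulate LM-PCR amplification of a fragment library
#'
#' Each template's copy number follows the per-cycle Bernoulli doubling
#' branching process (multiplied into the `multiplicity` column). Chimeric
#' molecules are materialised per template lineage with probability
#' `1 - (1 - chimera_rate)^cycles` (the first-order per-duplication rate):
#' each joins the prefix of its template with the suffix of another template
#' at an exact shared `chimera_k`-mer, mimicking template switching, and is
#' appended with its own amplification-weighted multiplicity.
#'
#' @param fragments a `fragment_set` with sequences.
#' @param model a `pcr_model`.
#' @param seed integer seed.
#' @return The amplified `fragment_set` (original rows with updated
#'   `multiplicity`, plus chimeric rows flagged `is_chimera`).
#' @export
simulate_pcr <- function(fragments, model = pcr_model(), seed = 1L) {
  n <- nrow(fragments)
  if (n == 0 || model$cycles == 0) return(fragments)
  with_seed(derive_seed(seed, "pcr"), {
    m <- fragments$multiplicity
    for (cyc in seq_len(model$cycles)) {
      m <- m + stats::rbinom(n, size = m, prob = model$efficiency)
    }
    fragments$multiplicity <- m
    p_chim <- 1 - (1 - model$chimera_rate) ^ model$cycles
    n_chim <- stats::rbinom(1, n, p_chim)
    if (n_chim > 0 && n >= 2) {
      rows <- list()
      a_idx <- sample.int(n, n_chim, replace = TRUE)
      for (j in seq_len(n_chim)) {
        a <- a_idx[j]
        chim <- NULL
        for (try in 1:5) {
          b <- sample.int(n, 1)
          if (b == a) next
          chim <- join_at_shared_kmer(fragments$seq[a], fragments$seq[b],
                                      model$chimera_k)
          if (!is.null(chim)) break
        }
        if (is.null(chim)) next
        # born part-way through cycling, so amplified for a random remainder
        born <- sample.int(model$cycles, 1)
        mult <- 1
        for (cyc in seq_len(model$cycles - born)) {
          mult <- mult + stats::rbinom(1, mult, model$efficiency)
        }
        row <- fragments[a, , drop = FALSE]
        row$seq <- chim
        row$length <- nchar(chim)
        row$is_chimera <- TRUE
        row$gene_id <- NA_character_
        row$multiplicity <- mult
        rows[[length(rows) + 1]] <- row
      }
      if (length(rows) > 0) {
        fragments <- rbind(fragments, do.call(rbind, rows))
        rownames(fragments) <- NULL
      }
    }
    fragments
  })
}

# join a prefix of `a` with a suffix of `b` at an exact shared k-mer;
# NULL when the two share no k-mer
join_at_shared_kmer <- function(a, b, k) {
  ka <- kmers_of(a, k)
  kb <- kmers_of(b, k)
  shared <- intersect(ka, kb)
  if (length(shared) == 0) return(NULL)
  km <- shared[sample.int(length(shared), 1)]
  pa <- regexpr(km, a, fixed = TRUE)
  pb <- regexpr(km, b, fixed = TRUE)
  chim <- paste0(substr(a, 1, pa + k - 1), substr(b, pb + k, nchar(b)))
  if (chim == a || chim == b) return(NULL)
  chim
}
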