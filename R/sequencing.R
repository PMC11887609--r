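#' Simulate paired-end sequencing of a fragment library
#'
#' Forward and reverse reads are taken from the two fragment ends; fragments
#' shorter than `read_len` yield mates truncated to the fragment length (the
#' adapter would be read through and trimmed), so 200 bp fragments produce
#' fully overlapping pairs. Substitution errors are uniform at `error_rate`
#' and qualities are the matching constant Phred score.
#'
#' @param fragments a `fragment_set` with sequences (multiplicity-aware).
#' @param read_len read length in nt (default 300, MiSeq 2x300).
#' @param error_rate per-base substitution probability.
#' @param n_pairs when given, sample this many molecules with probability
#'   proportional to `multiplicity` (with replacement); when NULL, one pair
#'   per fragment row.
#' @param sample_name sample label recorded in read ids and truth.
#' @param seed integer seed.
#' @return A `read_pairs` object: `fwd` and `rev` `seq_set`s plus a `truth`
#'   data frame (source construct, gene, on-target and containment flags).
#' @export
sequence_paired <- function(fragments, read_len = 300L, error_rate = 1e-3,
                            n_pairs = NULL, sample_name = "sample",
                            seed = 1L) {
  with_seed(derive_seed(seed, "sequence"), {
    idx <- seq_len(nrow(fragments))
    if (!is.null(n_pairs)) {
      if (nrow(fragments) == 0) stop("no fragments to sequence")
      idx <- sample.int(nrow(fragments), n_pairs, replace = TRUE,
                        prob = fragments$multiplicity)
    }
    frag <- fragments$seq[idx]
    flen <- fragments$length[idx]
    w <- pmin(flen, read_len)
    fwd <- substr(frag, 1L, w)
    rev <- revcomp(substr(frag, flen - w + 1L, flen))
    fwd <- inject_errors(fwd, error_rate)
    rev <- inject_errors(rev, error_rate)
    q <- if (error_rate > 0) min(41L, round(-10 * log10(error_rate))) else 40L
    qual <- if (length(w) > 0) {
      substring(strrep(intToUtf8(q + 33L), max(w)), 1L, w)
    } else character()
    ids <- sprintf("%s_read%06d", sample_name, seq_along(idx))
    truth <- data.frame(read_id = ids,
                        source_id = fragments$source_id[idx],
                        gene_id = fragments$gene_id[idx],
                        on_target = fragments$on_target[idx],
                        contained = fragments$contained[idx],
                        is_chimera = fragments$is_chimera[idx],
                        frag_len = flen, stringsAsFactors = FALSE)
    structure(list(fwd = seq_set(paste0(ids, "/1"), fwd, qual = qual),
                   rev = seq_set(paste0(ids, "/2"), rev, qual = qual),
                   truth = truth, sample = sample_name),
              class = "read_pairs")
  })
}

#' @export
print.read_pairs <- function(x, ...) {
  cat("read_pairs: sample ", x$sample, ", ", length(x$fwd), " pairs\n", sep = "")
  invisible(x)
}

# uniform substitution errors; only reads that drew at least one error are
# touched, so the common case stays vectorised
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    L <- nchar(seqs[i])
    for (p in sample.int(L, min(n_err[i], L))) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- bases[bases != old][sample.int(3L, 1L)]
    }
  }
  seqs
}

#' Concatenate paired reads with an N linker
#'
#' `fwd + N*linker_len + reverse_complement(rev)`; the concatenamers are the
#' chimera-screen input for short-read amplicon data whose pairs do not span
#' the full product.
#'
#' @param pairs a `read_pairs` object.
#' @param linker_len number of N bases between the mates (default 50).
#' @return A `seq_set` of concatenamers (one per pair, no qualities).
#' @export
nlinker_concat <- function(pairs, linker_len = 50L) {
  linker <- strrep("N", linker_len)
  seq_set(pairs$truth$read_id,
          paste0(pairs$fwd$seq, linker, revcomp(pairs$rev$seq)))
}
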