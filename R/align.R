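# Alignment helpers shared by the curation, clustering and classification
# stages. All identity figures are fractions in [0,1] unless a function is
# documented as returning percent.

# score parameters follow common nucleotide/protein local-alignment practice
.nt_sub <- function() Biostrings::nucleotideSubstitutionMatrix(
  match = 2, mismatch = -3, baseOnly = FALSE)

align_stats <- function(query, subject, type = "local", protein = FALSE) {
  if (protein) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(subject),
      type = type, substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(subject),
      type = type, substitutionMatrix = .nt_sub(),
      gapOpening = 5, gapExtension = 2)
  }
  p <- as.character(Biostrings::alignedPattern(aln))
  alen <- nchar(p)
  nm <- Biostrings::nmatch(aln)
  qw <- Biostrings::width(Biostrings::pattern(aln))
  sw <- Biostrings::width(Biostrings::subject(aln))
  list(identity = if (alen > 0) nm / alen else 0,
       aln_len = alen,
       query_cov = qw / nchar(query),
       subject_cov = sw / nchar(subject),
       shorter_cov = if (nchar(query) <= nchar(subject)) qw / nchar(query)
                     else sw / nchar(subject),
       n_match = nm)
}

# best local alignment of `query` against each strand of `subject`
align_stats_bothstrands <- function(query, subject, protein = FALSE) {
  a <- align_stats(query, subject, type = "local", protein = protein)
  if (protein) return(a)
  b <- align_stats(query, revcomp(subject), type = "local", protein = FALSE)
  if (b$n_match > a$n_match) b else a
}

#' Global pairwise nucleotide identity
#'
#' Identity is matches divided by global alignment length (gaps included).
#'
#' @param a,b nucleotide strings.
#' @return A fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  align_stats(a, b, type = "global")$identity
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# all k-mers of a string at the given step (1-based starts)
kmers_of <- function(seq, k, step = 1L) {
  n <- nchar(seq)
  if (n < k) return(character())
  starts <- seq.int(1L, n - k + 1L, by = step)
  substring(seq, starts, starts + k - 1L)
}

# TRUE for each query sequence sharing at least one exact k-mer with any
# subject sequence (either strand of the subject set when both_strands)
shares_kmer <- function(queries, subjects, k = 12L, both_strands = TRUE) {
  subj <- subjects
  if (both_strands) subj <- c(subj, revcomp(subjects))
  tab <- unique(unlist(lapply(subj, kmers_of, k = k), use.names = FALSE))
  if (length(tab) == 0) return(rep(FALSE, length(queries)))
  vapply(queries, function(q) {
    any(kmers_of(q, k) %in% tab)
  }, TRUE, USE.NAMES = FALSE)
}
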