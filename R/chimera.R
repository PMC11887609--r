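#' Two-parent chimera detection
#'
#' Queries are screened in ascending-abundance order against the set of
#' strictly more abundant sequences (potential parents). A query is flagged
#' chimeric when some crossover position splits it so that the left segment's
#' identity to one parent and the right segment's identity to another each
#' exceed the query's best whole-length identity to any single parent by at
#' least `delta` percentage points. Both segments must exceed the whole-
#' length optimum, which only genuinely bipartite sequences can do, so pure
#' sequences are safe at any divergence.
#'
#' @param seqs character vector (or `seq_set`) of sequences.
#' @param abundance numeric read support per sequence.
#' In addition, both segments must reconstruct the query at
#' `min_parent_identity` or better: amplification chimeras copy their
#' parents up to polymerase error, so a genuine two-parent model is
#' near-perfect, while distant relatives cannot reach the bar and are never
#' flagged on segment-level fluctuations alone.
#'
#' @param delta required identity excess in percentage points (default 1.5).
#' @param min_segment minimum segment length in nt considered for a
#'   crossover (default 30).
#' @param min_parent_identity minimum absolute identity of each segment to
#'   its parent (fraction, default 0.9).
#' @return A list with `kept` (indices of retained sequences), `flagged`
#'   (indices removed) and a `report` data frame (query, best parents,
#'   segment identities).
#' @export
remove_chimeras <- function(seqs, abundance, delta = 1.5, min_segment = 30L,
                            min_parent_identity = 0.9) {
  if (inherits(seqs, "seq_set")) seqs <- seqs$seq
  n <- length(seqs)
  if (n == 0) return(list(kept = integer(), flagged = integer(),
                          report = NULL))
  flagged <- logical(n)
  rep_rows <- list()
  ord <- order(abundance, seq_len(n))  # ascending; parents must be strictly richer
  for (qi in ord) {
    parents <- which(abundance > abundance[qi] & !flagged)
    if (length(parents) < 2) next
    L <- nchar(seqs[qi])
    if (L < 2L * min_segment) next
    # per-parent cumulative match profile on query coordinates
    profs <- lapply(parents, function(p) match_profile(seqs[qi], seqs[p]))
    cums <- vapply(profs, cumsum, numeric(L))
    tot <- cums[L, ]
    best_single <- max(tot / L)
    xs <- min_segment:(L - min_segment)
    left <- cums[xs, , drop = FALSE] / xs            # identity of [1, x]
    right <- (matrix(tot, nrow = length(xs), ncol = length(parents),
                     byrow = TRUE) - cums[xs, , drop = FALSE]) / (L - xs)
    thr <- max(best_single + delta / 100, min_parent_identity)
    lb <- apply(left, 1, max)
    rb <- apply(right, 1, max)
    hit <- which(lb >= thr & rb >= thr)
    if (length(hit) > 0) {
      x <- xs[hit[which.max(pmin(lb[hit], rb[hit]))]]
      pa <- parents[which.max(left[x - min_segment + 1L, ])]
      pb <- parents[which.max(right[x - min_segment + 1L, ])]
      if (pa != pb) {
        flagged[qi] <- TRUE
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          query = qi, crossover = x, parent_left = pa, parent_right = pb,
          best_single = 100 * best_single,
          left_identity = 100 * left[x - min_segment + 1L, which.max(left[x - min_segment + 1L, ])],
          right_identity = 100 * right[x - min_segment + 1L, which.max(right[x - min_segment + 1L, ])])
      }
    }
  }
  list(kept = which(!flagged), flagged = which(flagged),
       report = if (length(rep_rows) > 0) do.call(rbind, rep_rows))
}

# per-position match indicator of `query` against `parent` on query
# coordinates, from a global alignment (unaligned query positions count 0)
match_profile <- function(query, parent) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(parent),
    type = "global", substitutionMatrix = .nt_sub(),
    gapOpening = 5, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- cumsum(p != "-")
  prof <- numeric(nchar(query))
  hit <- p != "-" & p == s
  prof[qpos[hit]] <- 1
  prof
}
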