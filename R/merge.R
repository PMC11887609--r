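#' Merge overlapping read pairs
#'
#' For each pair the forward read and the reverse complement of the reverse
#' read are scanned for a suffix-prefix (or full-containment) overlap of at
#' least `min_overlap` nt with a mismatch density at most
#' `max_mismatch_rate`; the smallest shift (largest overlap) that qualifies
#' wins. Overlap consensus takes the base with the higher quality (forward
#' mate on ties). Unmergeable pairs are passed through unmerged, flagged.
#'
#' @param pairs a `read_pairs` object.
#' @param min_overlap minimum overlap in nt (default 10).
#' @param max_mismatch_rate maximum fraction of mismatching overlap
#'   positions (default 0.25).
#' @return A list with `merged` (a `seq_set` with qualities and a `truth`
#'   attribute), `unmerged` (a `read_pairs` of the flagged pairs) and
#'   `stats` (in/merged/unmerged counts).
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_rate = 0.25) {
  n <- length(pairs$fwd)
  a_seq <- pairs$fwd$seq
  b_seq <- revcomp(pairs$rev$seq)
  a_q <- pairs$fwd$qual
  b_q <- vapply(pairs$rev$qual, function(q) {
    if (nchar(q) == 0) "" else intToUtf8(rev(utf8ToInt(q)))
  }, "", USE.NAMES = FALSE)
  merged_seq <- character(n)
  merged_qual <- character(n)
  ok <- logical(n)
  # fast path: identical mates (error-free fully overlapping pairs)
  same <- a_seq == b_seq & nchar(a_seq) >= min_overlap
  merged_seq[same] <- a_seq[same]
  merged_qual[same] <- a_q[same]
  ok[same] <- TRUE
  for (i in which(!same)) {
    m <- merge_one(a_seq[i], b_seq[i], a_q[i], b_q[i],
                   min_overlap, max_mismatch_rate)
    if (!is.null(m)) {
      merged_seq[i] <- m$seq
      merged_qual[i] <- m$qual
      ok[i] <- TRUE
    }
  }
  keep <- which(ok)
  merged <- seq_set(pairs$truth$read_id[keep] %||% pairs$fwd$id[keep],
                    merged_seq[keep], qual = merged_qual[keep])
  attr(merged, "truth") <- if (!is.null(pairs$truth))
    pairs$truth[keep, , drop = FALSE]
  unm <- which(!ok)
  unmerged <- structure(list(fwd = pairs$fwd[unm], rev = pairs$rev[unm],
                             truth = if (!is.null(pairs$truth))
                               pairs$truth[unm, , drop = FALSE],
                             sample = pairs$sample), class = "read_pairs")
  list(merged = merged, unmerged = unmerged,
       stats = c(n_input = n, n_merged = length(keep),
                 n_unmerged = length(unm)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# scan shifts of b along a (b starts at a position shift+1); smallest shift
# first, so the largest overlap is preferred; also tries b extending left of
# a (negative shifts) when no forward shift qualifies
merge_one <- function(a, b, qa, qb, min_overlap, max_rate) {
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  qva <- utf8ToInt(qa); qvb <- utf8ToInt(qb)
  la <- length(va); lb <- length(vb)
  for (shift in 0:(la - min_overlap)) {
    ov <- min(la - shift, lb)
    if (ov < min_overlap) break
    ia <- (shift + 1):(shift + ov)
    ib <- 1:ov
    mism <- va[ia] != vb[ib]
    if (sum(mism) / ov <= max_rate) {
      cons_a <- qva[ia] >= qvb[ib]
      mid <- ifelse(cons_a, va[ia], vb[ib])
      midq <- pmax(qva[ia], qvb[ib])
      tail_s <- if (shift + ov < la) {       # b contained in a
        va[(shift + ov + 1):la]
      } else if (ov < lb) {                   # b extends past a
        vb[(ov + 1):lb]
      } else integer()
      tail_q <- if (shift + ov < la) {
        qva[(shift + ov + 1):la]
      } else if (ov < lb) {
        qvb[(ov + 1):lb]
      } else integer()
      seq <- intToUtf8(c(va[seq_len(shift)], mid, tail_s))
      qual <- intToUtf8(c(qva[seq_len(shift)], midq, tail_q))
      return(list(seq = seq, qual = qual))
    }
  }
  NULL
}
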