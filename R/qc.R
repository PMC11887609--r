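# Read quality control: end trimming at the Phred threshold, length and
# low-complexity filtering for short paired reads; length window and terminal
# trimming for long amplicon (HiFi-style) reads.

# DUST-style low-complexity score on the whole read: with w = L-2 triplets
# and c_t the count of triplet t, score = 100 * sum(c_t*(c_t-1)/2) /
# (w*(w-1)/2). A homopolymer scores 100; random sequence scores ~3.
dust_score <- function(seq) dust_scores(seq)

# vectorised over many reads: triplet counting on the concatenation with
# read-boundary triplets masked out
dust_scores <- function(seqs) {
  n <- length(seqs)
  if (n == 0) return(numeric())
  L <- nchar(seqs)
  out <- numeric(n)
  ok <- L >= 5
  if (!any(ok)) return(out)
  sub <- seqs[ok]
  Ls <- L[ok]
  code <- integer(128)
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  v <- code[utf8ToInt(paste(sub, collapse = ""))]
  total <- length(v)
  trip <- v[seq_len(total - 2L)] * 16L +
    v[seq.int(2L, total - 1L)] * 4L + v[seq.int(3L, total)]
  ends <- cumsum(Ls)
  starts <- ends - Ls + 1L
  w <- Ls - 2L
  # positions whose triplet stays within one read
  keep_idx <- sequence(w) + rep(starts - 1L, w)
  read_of <- rep(seq_along(sub), w)
  key <- (read_of - 1L) * 64L + trip[keep_idx] + 1L
  cnt <- tabulate(key, length(sub) * 64L)
  cm <- matrix(cnt, nrow = 64L)
  sums <- colSums(cm * (cm - 1) / 2)
  out[ok] <- 100 * sums / (w * (w - 1) / 2)
  out
}

# trim both ends up to the first/last base with quality >= min_qual;
# returns c(from, to) (1-based, from > to means the read vanishes)
qual_trim_bounds <- function(qual, min_qual) {
  q <- phred_decode(qual)
  ok <- which(q >= min_qual)
  if (length(ok) == 0) return(c(1L, 0L))
  c(ok[1], ok[length(ok)])
}

#' Quality-control short paired-end reads
#'
#' Both ends of each mate are trimmed at the Phred threshold, then reads
#' shorter than `min_len` or with a DUST-style complexity score above
#' `dust_threshold` are discarded. Pairs are kept synchronised: when either
#' mate fails, the orphan mate is dropped too.
#'
#' @param pairs a `read_pairs` object.
#' @param min_qual Phred threshold for end trimming (default 20).
#' @param min_len minimum post-trim read length (default 100).
#' @param dust_threshold maximum DUST score (default 7).
#' @return The filtered `read_pairs`, with an `n_input` attribute.
#' @export
qc_short_reads <- function(pairs, min_qual = 20L, min_len = 100L,
                           dust_threshold = 7) {
  n <- length(pairs$fwd)
  trim_one <- function(set) {
    low <- intToUtf8(seq(33L, min_qual + 32L), multiple = TRUE)
    need <- substr(set$qual, 1L, 1L) %in% low |
      substr(set$qual, nchar(set$qual), nchar(set$qual)) %in% low
    seqs <- set$seq; quals <- set$qual
    for (i in which(need)) {
      b <- qual_trim_bounds(quals[i], min_qual)
      seqs[i] <- substr(seqs[i], b[1], b[2])
      quals[i] <- substr(quals[i], b[1], b[2])
    }
    list(seq = seqs, qual = quals)
  }
  f <- trim_one(pairs$fwd)
  r <- trim_one(pairs$rev)
  pass <- nchar(f$seq) >= min_len & nchar(r$seq) >= min_len
  chk <- which(pass)
  if (length(chk) > 0) {
    pass[chk] <- dust_scores(f$seq[chk]) <= dust_threshold &
      dust_scores(r$seq[chk]) <= dust_threshold
  }
  keep <- which(pass)
  out <- structure(list(
    fwd = seq_set(pairs$fwd$id[keep], f$seq[keep], qual = f$qual[keep]),
    rev = seq_set(pairs$rev$id[keep], r$seq[keep], qual = r$qual[keep]),
    truth = if (!is.null(pairs$truth)) pairs$truth[keep, , drop = FALSE],
    sample = pairs$sample), class = "read_pairs")
  attr(out, "n_input") <- n
  out
}

#' Quality-control long amplicon (HiFi-style) reads
#'
#' The length window is applied first, then `end_trim` bases are cut from
#' both terminals (primer removal), mirroring the long-read amplicon
#' protocol's order of operations.
#'
#' @param reads a `seq_set` of long reads.
#' @param len_range inclusive nt length window (default 400-1000).
#' @param end_trim bases trimmed from each terminal after the window
#'   (default 20).
#' @return The filtered and trimmed `seq_set`, with an `n_input` attribute.
#' @export
qc_hifi <- function(reads, len_range = c(400L, 1000L), end_trim = 20L) {
  n <- length(reads)
  L <- nchar(reads$seq)
  keep <- which(L >= len_range[1] & L <= len_range[2])
  out <- reads[keep]
  L <- nchar(out$seq)
  out$seq <- substr(out$seq, end_trim + 1L, L - end_trim)
  if (!is.null(out$qual)) {
    out$qual <- substr(out$qual, end_trim + 1L, L - end_trim)
  }
  attr(out, "n_input") <- n
  out
}
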