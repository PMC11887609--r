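#' Greedy overlap-consensus assembly
#'
#' Deterministic desk-scale assembler: seeds with the most abundant unused
#' read and extends in both directions one base at a time by an
#' abundance-weighted majority vote over all reads joined through exact
#' `min_overlap`-mer terminal windows (joins tolerate a small mismatch
#' fraction so sequencing errors do not orphan reads). Reads are indexed on
#' both strands. After extension, reads wholly contained in the contig are
#' absorbed, and a pileup consensus over every consumed read polishes
#' residual seed errors. Contigs supported by fewer than `min_reads` reads
#' are dropped.
#'
#' @param reads a `seq_set` or character vector of (merged) reads.
#' @param abundance optional per-read weights (default 1 each; duplicate
#'   sequences are pooled).
#' @param min_overlap exact overlap window in nt (default 30).
#' @param min_reads minimum read support per emitted contig (default 2).
#' @param mismatch_tol tolerated mismatch fraction when verifying a read
#'   against the contig (default 0.05).
#' @param sample sample label stamped on the contigs.
#' @return A data frame of contigs: `id`, `seq`, `member_reads`, `sample`.
#' @export
assemble_reads <- function(reads, abundance = NULL, min_overlap = 30L,
                           min_reads = 2L, mismatch_tol = 0.05,
                           sample = "sample") {
  seqs <- if (inherits(reads, "seq_set")) reads$seq else as.character(reads)
  if (is.null(abundance)) abundance <- rep(1, length(seqs))
  keep <- nchar(seqs) >= min_overlap
  seqs <- seqs[keep]; abundance <- abundance[keep]
  empty <- data.frame(id = character(), seq = character(),
                      member_reads = numeric(), sample = character(),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0) return(empty)
  u <- unique(seqs)
  ab <- as.numeric(rowsum(abundance, factor(match(seqs, u),
                                            levels = seq_along(u)))[, 1])
  nu <- length(u)
  eseq <- c(u, revcomp(u))
  eread <- rep(seq_len(nu), 2L)
  elen <- nchar(eseq)
  k <- as.integer(min_overlap)
  pfx <- split(seq_along(eseq), substr(eseq, 1L, k))
  pfx_env <- list2env(pfx, hash = TRUE, size = max(29L, length(pfx)))
  used <- logical(nu)
  ne <- length(eseq)
  cons_ids <- integer(ne)     # entries consumed by the current contig
  n_cons <- 0L
  members <- 0
  contig <- ""
  Lc <- 0L

  # verify entry `id` against the contig at 0-based offset `off`; on
  # acceptance mark its read used and record it for the pileup polish,
  # returning TRUE when it extends past the current contig end
  try_add <- function(id, off) {
    rd <- eread[id]
    if (used[rd]) return(NA)
    aend <- min(Lc, off + elen[id])
    ov <- aend - off
    mm <- hamming(substr(contig, off + 1L, aend), substr(eseq[id], 1L, ov))
    if (mm > floor(mismatch_tol * ov)) return(NA)
    used[rd] <<- TRUE
    members <<- members + ab[rd]
    n_cons <<- n_cons + 1L
    cons_ids[n_cons] <<- id
    off + elen[id] > Lc
  }

  extend_right <- function() {
    act_id <- integer(); act_off <- integer()
    join_at <- function(pos) {           # window starting at `pos` (1-based)
      ids <- pfx_env[[substr(contig, pos, pos + k - 1L)]]
      for (id in ids) {
        ext <- try_add(id, pos - 1L)
        if (isTRUE(ext)) {
          act_id <<- c(act_id, id); act_off <<- c(act_off, pos - 1L)
        }
      }
    }
    for (pos in seq_len(max(0L, Lc - k + 1L))) join_at(pos)
    repeat {
      live <- act_off + elen[act_id] > Lc
      act_id <- act_id[live]; act_off <- act_off[live]
      if (length(act_id) == 0) break
      rel <- Lc + 1L - act_off
      chars <- substr(eseq[act_id], rel, rel)
      base <- chars[1]
      if (any(chars != base)) {
        ch_u <- unique(chars)
        w <- vapply(ch_u, function(cc)
          sum(ab[eread[act_id[chars == cc]]]), 0)
        base <- ch_u[order(-w, ch_u)][1]
        okv <- chars == base
        act_id <- act_id[okv]; act_off <- act_off[okv]
      }
      contig <<- paste0(contig, base)
      Lc <<- Lc + 1L
      join_at(Lc - k + 1L)
    }
  }

  contigs <- list()
  for (s in order(-ab, -nchar(u), seq_len(nu))) {
    if (used[s]) next
    used[s] <- TRUE
    members <- ab[s]
    n_cons <- 1L
    cons_ids[1L] <- s
    contig <- u[s]
    Lc <- nchar(contig)
    extend_right()
    contig <- revcomp(contig)
    extend_right()
    contig <- revcomp(contig)
    # absorb unused reads wholly contained in the contig
    for (pos in seq_len(max(0L, Lc - k + 1L))) {
      ids <- pfx_env[[substr(contig, pos, pos + k - 1L)]]
      for (id in ids) {
        if (pos - 1L + elen[id] <= Lc) try_add(id, pos - 1L)
      }
    }
    ci <- cons_ids[seq_len(n_cons)]
    # the reverse-complement of entry e sits at e +/- nu, so the polish can
    # try both orientations without rebuilding sequences
    rc_ci <- ifelse(ci > nu, ci - nu, ci + nu)
    contig <- polish_contig(contig, eseq[ci], eseq[rc_ci], ab[eread[ci]])
    if (members >= min_reads) {
      contigs[[length(contigs) + 1]] <- list(seq = contig, members = members)
    }
  }
  if (length(contigs) == 0) return(empty)
  data.frame(id = sprintf("%s_contig%03d", sample, seq_along(contigs)),
             seq = vapply(contigs, `[[`, "", "seq"),
             member_reads = vapply(contigs, `[[`, 0, "members"),
             sample = sample, stringsAsFactors = FALSE)
}

# abundance-weighted pileup consensus over the consumed reads: each read is
# re-located on the final contig (either orientation) through a shared
# 20-mer; positions where an alternative base strictly outvotes the current
# one are corrected
polish_contig <- function(contig, cons_seqs, cons_rc, cons_w) {
  Lc <- nchar(contig)
  m <- matrix(0, nrow = 4L, ncol = Lc)
  lookup <- integer(128)
  lookup[c(65L, 67L, 71L, 84L)] <- 1:4
  for (i in seq_along(cons_seqs)) {
    rd <- cons_seqs[i]
    off <- locate_on(contig, rd)
    if (is.na(off)) {
      rd <- cons_rc[i]
      off <- locate_on(contig, rd)
      if (is.na(off)) next
    }
    v <- utf8ToInt(rd)
    bi <- lookup[v]
    pos <- off + seq_along(v)
    okp <- bi > 0 & pos >= 1 & pos <= Lc
    idx <- cbind(bi[okp], pos[okp])
    m[idx] <- m[idx] + cons_w[i]
  }
  cv <- utf8ToInt(contig)
  ci <- lookup[cv]
  best <- max.col(t(m), ties.method = "first")
  covered <- colSums(m) > 0
  change <- covered & ci > 0 &
    m[cbind(best, seq_len(Lc))] > m[cbind(pmax(ci, 1L), seq_len(Lc))]
  cv[change] <- c(65L, 67L, 71L, 84L)[best[change]]
  intToUtf8(cv)
}

# 0-based offset of the first close match (up to 10 percent mismatches) of
# `read` on `contig`, anchored at a shared 20-mer; NA when absent. Overlaps
# running past either contig end are clipped.
locate_on <- function(contig, read) {
  lr <- nchar(read)
  if (lr < 20L) return(NA_integer_)
  for (pp in unique(pmax(1L, c(1L, lr %/% 2L - 10L, lr - 19L)))) {
    pos <- regexpr(substr(read, pp, pp + 19L), contig, fixed = TRUE)
    if (pos < 0) next
    off <- as.integer(pos) - pp
    a <- max(1L, off + 1L)
    b <- min(nchar(contig), off + lr)
    if (b - a + 1L < 20L) next
    if (hamming(substr(contig, a, b),
                substr(read, a - off, b - off)) <= ceiling(0.1 * (b - a + 1L))) {
      return(off)
    }
  }
  NA_integer_
}
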