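# Read-to-OTU mapping and abundance estimation: seed-and-extend alignment
# with mismatch-tolerant seeding, RPKMS units, enrichment factors and the
# analytic (hypergeometric) rarefaction expectation.

#' Read mapping parameters
#'
#' The seed stage uses several non-overlapping exact seeds per read
#' (offsets 0, seed_len, 2*seed_len): a single substitution can break at
#' most one seed, giving the one-mismatch-in-seed tolerance of short-read
#' mappers. Candidates are verified ungapped on the seeded diagonal.
#'
#' @param seed_len exact seed length in nt (default 22).
#' @param n_seeds number of non-overlapping seeds tried per read.
#' @param min_aligned_fraction minimum fraction of the read that must lie on
#'   the reference (default 0.9).
#' @param min_identity minimum identity over the aligned part (default 0.9).
#' @return A list of class `mapping_params`.
#' @export
mapping_params <- function(seed_len = 22L, n_seeds = 3L,
                           min_aligned_fraction = 0.9, min_identity = 0.9) {
  structure(list(seed_len = as.integer(seed_len), n_seeds = as.integer(n_seeds),
                 min_aligned_fraction = min_aligned_fraction,
                 min_identity = min_identity), class = "mapping_params")
}

# position index of every seed_len-mer of both strands of the references
build_ref_index <- function(refs, seed_len) {
  seqs <- c(refs, revcomp(refs))
  n <- length(refs)
  key <- character(); rep_i <- integer(); pos_i <- integer()
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    if (L < seed_len) next
    starts <- seq_len(L - seed_len + 1L)
    key <- c(key, substring(seqs[i], starts, starts + seed_len - 1L))
    rep_i <- c(rep_i, rep.int(i, length(starts)))
    pos_i <- c(pos_i, starts)
  }
  idx <- split(seq_along(key), key)
  list(env = list2env(idx, hash = TRUE, size = max(29L, length(idx))),
       rep = rep_i, pos = pos_i, seqs = seqs, n_fwd = n,
       lens = nchar(seqs))
}

#' Map reads to OTU representatives
#'
#' Seed-and-extend on both strands; the best-scoring OTU wins, and reads
#' whose best score is tied between different OTUs are left unassigned
#' (bias-free abundance). Use [map_read_pairs()] for unmerged pairs.
#'
#' @param reads a `seq_set` or character vector of reads.
#' @param otus OTU table from [cluster_otus()] (or a character vector of
#'   reference sequences).
#' @param params a `mapping_params`.
#' @return A data frame with `read_id`, `otu` (NA when unassigned) and
#'   `score` (matching bases of the best alignment).
#' @export
map_reads <- function(reads, otus, params = mapping_params()) {
  ids <- if (inherits(reads, "seq_set")) reads$id else
    sprintf("read%d", seq_along(reads))
  seqs <- if (inherits(reads, "seq_set")) reads$seq else as.character(reads)
  refs <- if (is.data.frame(otus)) otus$representative else as.character(otus)
  otu_ids <- if (is.data.frame(otus)) otus$otu_id else
    sprintf("OTU_%d", seq_along(refs))
  if (length(refs) == 0) stop("no OTU representatives to map against")
  idx <- build_ref_index(refs, params$seed_len)
  otu <- rep(NA_character_, length(seqs))
  score <- rep(NA_real_, length(seqs))
  for (i in seq_along(seqs)) {
    hit <- map_one(seqs[i], idx, params)
    if (!is.null(hit)) {
      otu[i] <- otu_ids[hit$otu]
      score[i] <- hit$score
    }
  }
  data.frame(read_id = ids, otu = otu, score = score,
             stringsAsFactors = FALSE)
}

# best ungapped placement of one read; NULL when unmapped or ambiguous
map_one <- function(read, idx, params) {
  L <- nchar(read)
  sl <- params$seed_len
  if (L < sl) return(NULL)
  offs <- seq.int(1L, by = sl, length.out = params$n_seeds)
  offs <- offs[offs + sl - 1L <= L]
  cand_rep <- integer(); cand_diag <- integer()
  for (o in offs) {
    ids <- idx$env[[substr(read, o, o + sl - 1L)]]
    for (e in ids) {
      cand_rep <- c(cand_rep, idx$rep[e])
      cand_diag <- c(cand_diag, idx$pos[e] - o)   # ref = read + diag
    }
  }
  if (length(cand_rep) == 0) return(NULL)
  dup <- duplicated(paste(cand_rep, cand_diag))
  cand_rep <- cand_rep[!dup]; cand_diag <- cand_diag[!dup]
  best_sc <- -1; best_otu <- 0L; tie <- FALSE
  for (j in seq_along(cand_rep)) {
    ri <- cand_rep[j]
    rl <- idx$lens[ri]
    a <- max(1L, 1L + cand_diag[j])           # ref window
    b <- min(rl, L + cand_diag[j])
    ov <- b - a + 1L
    if (ov < params$min_aligned_fraction * L) next
    mm <- hamming(substr(idx$seqs[ri], a, b),
                  substr(read, a - cand_diag[j], b - cand_diag[j]))
    if (1 - mm / ov < params$min_identity) next
    sc <- ov - mm
    fwd_otu <- if (ri > idx$n_fwd) ri - idx$n_fwd else ri
    if (sc > best_sc) {
      best_sc <- sc; best_otu <- fwd_otu; tie <- FALSE
    } else if (sc == best_sc && fwd_otu != best_otu) {
      tie <- TRUE
    }
  }
  if (best_sc < 0 || tie) return(NULL)
  list(otu = best_otu, score = best_sc)
}

#' Map unmerged read pairs under the same-OTU rule
#'
#' Both mates are mapped independently; a pair is assigned only when both
#' mates hit the same OTU.
#'
#' @param pairs a `read_pairs` object.
#' @param otus OTU table (see [map_reads()]).
#' @param params a `mapping_params`.
#' @return A data frame with `read_id`, `otu`, `score` (summed mates).
#' @export
map_read_pairs <- function(pairs, otus, params = mapping_params()) {
  f <- map_reads(pairs$fwd, otus, params)
  r <- map_reads(pairs$rev, otus, params)
  same <- !is.na(f$otu) & !is.na(r$otu) & f$otu == r$otu
  data.frame(read_id = sub("/1$", "", f$read_id),
             otu = ifelse(same, f$otu, NA_character_),
             score = ifelse(same, f$score + r$score, NA_real_),
             stringsAsFactors = FALSE)
}

#' RPKMS: reads per kilobase of gene per million reads sequenced
#'
#' `RPKMS = mapped_reads / (length_kb * total_reads_millions)`; the
#' denominator is the sample's quality-controlled read count, not its mapped
#' count, so values are comparable across enrichment levels.
#'
#' @param counts matrix of mapped read counts (samples x OTUs), or a vector
#'   for a single sample.
#' @param lengths OTU representative lengths in nt.
#' @param totals per-sample QC read totals.
#' @return An `otu_table`: list with `counts`, `rpkms`, `lengths`, `totals`.
#' @export
rpkms <- function(counts, lengths, totals) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (any(lengths <= 0)) stop("OTU lengths must be positive")
  if (any(totals <= 0)) stop("per-sample totals must be positive")
  if (ncol(counts) != length(lengths)) {
    stop("one length per OTU column required")
  }
  if (nrow(counts) != length(totals)) {
    stop("one total per sample row required")
  }
  if (any(rowSums(counts) > totals)) {
    stop("mapped counts exceed sample totals")
  }
  r <- counts / (matrix(lengths / 1000, nrow(counts), ncol(counts),
                        byrow = TRUE) *
                   matrix(totals / 1e6, nrow(counts), ncol(counts)))
  structure(list(counts = counts, rpkms = r, lengths = lengths,
                 totals = totals), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("RPKMS:\n")
  print(round(x$rpkms, 2))
  invisible(x)
}

#' Fraction of reads assigned to OTUs
#'
#' @param assignments assignment data frame from [map_reads()] (or a count
#'   of assigned reads).
#' @param total_reads total QC read count.
#' @return A fraction in `[0, 1]`.
#' @export
mapped_ratio <- function(assignments, total_reads) {
  n <- if (is.data.frame(assignments)) sum(!is.na(assignments$otu))
  else assignments
  if (total_reads == 0) return(0)
  n / total_reads
}

#' Enrichment factor of a capture arm over the non-capture arm
#'
#' @param ratio_capture mapped ratio of the capture sample.
#' @param ratio_noncapture mapped ratio of the matched non-capture sample.
#' @return The quotient; `Inf` with an `undefined` attribute when the
#'   non-capture ratio is zero.
#' @export
enrichment_factor <- function(ratio_capture, ratio_noncapture) {
  if (ratio_noncapture == 0) {
    return(structure(Inf, undefined = TRUE))
  }
  ratio_capture / ratio_noncapture
}

#' Analytic rarefaction curves
#'
#' Expected distinct-OTU counts at each subsample size via the
#' hypergeometric expectation `E[S_m] = sum_i (1 - C(N - n_i, m) / C(N, m))`
#' (no resampling noise). Samples with fewer than `min_mapped` mapped reads
#' are excluded.
#'
#' @param counts matrix of mapped counts (samples x OTUs) with sample row
#'   names, or a vector for one sample.
#' @param sizes subsample sizes; default 20 steps up to each sample's total.
#' @param min_mapped minimum mapped reads for a sample to be included
#'   (default 100).
#' @return A data frame with `sample`, `size`, `expected_otus`.
#' @export
rarefaction <- function(counts, sizes = NULL, min_mapped = 100L) {
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1, dimnames = list("sample1", NULL))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("sample%d", seq_len(nrow(counts)))
  }
  out <- list()
  for (s in seq_len(nrow(counts))) {
    n <- counts[s, ]
    n <- n[n > 0]
    N <- sum(n)
    if (N < min_mapped) next
    sz <- if (is.null(sizes)) unique(round(seq(1, N, length.out = 20))) else
      sizes[sizes <= N]
    es <- vapply(sz, function(m) rarefy_expected(n, m), 0)
    out[[length(out) + 1]] <- data.frame(sample = rownames(counts)[s],
                                         size = sz, expected_otus = es,
                                         stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(sample = character(), size = numeric(),
                      expected_otus = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# E[distinct OTUs] in a draw of m reads without replacement
rarefy_expected <- function(n, m) {
  N <- sum(n)
  sum(1 - exp(lchoose(N - n, m) - lchoose(N, m)))
}
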