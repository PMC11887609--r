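# Fragmentation and hybridisation-capture simulation. Fragments carry ground
# truth (source construct, overlap/containment of the insert) so downstream
# accuracy can be audited against the generating community.

#' Fragment a community by simulated sonication
#'
#' Constructs are sampled with probability proportional to `ratio * total_len`
#' (mass-weighted), start positions are uniform on each circle, and lengths
#' follow a normal distribution around `frag_len_mean` truncated to
#' `[1, total_len - 1]`. Truth fields record whether a fragment overlaps an
#' insert by at least one base (`on_target`) and whether it lies wholly
#' inside the insert (`contained`).
#'
#' @param spec a `community_spec`.
#' @param n_fragments number of fragments to draw.
#' @param frag_len_mean mean fragment length in nt (default 200, the
#'   sonication target).
#' @param frag_len_sd standard deviation of fragment length (default 30).
#' @param seed integer seed; identical seeds give identical fragments.
#' @param sequences when FALSE, skip sequence extraction (coordinates and
#'   truth only; used for large Monte-Carlo runs).
#' @return A `fragment_set` data frame with columns `source_id`, `gene_id`,
#'   `start` (0-based circular), `length`, `strand`, `seq`, `on_target`,
#'   `contained`, `is_chimera`, `multiplicity`.
#' @export
fragment_community <- function(spec, n_fragments, frag_len_mean = 200,
                               frag_len_sd = 30, seed = 1L,
                               sequences = TRUE) {
  stopifnot(n_fragments >= 1)
  tot <- vapply(spec$constructs, `[[`, 0L, "total_len")
  if (frag_len_mean >= min(tot)) {
    stop("fragment length must be below the shortest construct length")
  }
  with_seed(derive_seed(seed, "fragment"), {
    w <- spec$ratio * tot
    ci <- sample.int(length(tot), n_fragments, replace = TRUE, prob = w)
    G <- tot[ci]
    len <- round(stats::rnorm(n_fragments, frag_len_mean, frag_len_sd))
    bad <- which(len < 1 | len >= G)
    while (length(bad) > 0) {
      len[bad] <- round(stats::rnorm(length(bad), frag_len_mean, frag_len_sd))
      bad <- bad[len[bad] < 1 | len[bad] >= G[bad]]
    }
    start <- floor(stats::runif(n_fragments) * G)
    strand <- sample(c("+", "-"), n_fragments, replace = TRUE)
    vs <- vapply(spec$constructs, function(con)
      if (con$insert_len > 0) con$insert_start else NA_integer_, 0L)[ci]
    # circular overlap of [start, start+len) with the insert [vs, G); the
    # wrapped tail [0, start+len-G) only reaches the insert if it extends
    # past vs (len < G, so each position is covered at most once)
    no_wrap <- start + len <= G
    ov <- ifelse(no_wrap,
                 pmax(0, pmin(start + len, G) - pmax(start, vs)),
                 pmax(0, G - pmax(start, vs)) +
                   pmax(0, (start + len - G) - vs))
    on_target <- !is.na(vs) & ov > 0
    contained <- !is.na(vs) & no_wrap & start >= vs & (start + len) <= G
    seqs <- NA_character_
    if (sequences) {
      seqs <- character(n_fragments)
      maxlen <- max(len)
      for (k in unique(ci)) {
        con <- spec$constructs[[k]]
        ext <- paste0(con$seq, substr(con$seq, 1, maxlen))
        sel <- which(ci == k)
        seqs[sel] <- substring(ext, start[sel] + 1L, start[sel] + len[sel])
      }
      rc <- strand == "-"
      if (any(rc)) seqs[rc] <- revcomp(seqs[rc])
    }
    structure(data.frame(
      source_id = vapply(spec$constructs, `[[`, "", "construct_id")[ci],
      gene_id = vapply(spec$constructs, `[[`, "", "gene_id")[ci],
      start = as.integer(start), length = as.integer(len), strand = strand,
      seq = seqs, on_target = on_target, contained = contained,
      is_chimera = FALSE, multiplicity = 1,
      stringsAsFactors = FALSE), class = c("fragment_set", "data.frame"))
  })
}

#' Size-select fragments
#'
#' Retains fragments of at least `min_len` nt (the bead-based removal of
#' short library molecules; threshold is inclusive).
#'
#' @param fragments a `fragment_set`.
#' @param min_len minimum retained length (default 150).
#' @return The filtered `fragment_set`.
#' @export
size_select <- function(fragments, min_len = 150L) {
  out <- fragments[fragments$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hybridisation-capture model parameters
#'
#' Capture is modelled as alignment overlap and identity rather than
#' thermodynamics: a fragment is retained by a round when its best ungapped
#' probe alignment (either strand) covers at least `min_overlap` nt at
#' `min_identity` or better; otherwise it survives the round with probability
#' `nonspecific_rate` (bead carry-over). `rounds = 0` is the pass-through
#' non-capture arm.
#'
#' @param min_overlap minimum probe-fragment overlap in nt (default 100, one
#'   probe length).
#' @param min_identity minimum identity over the overlap (default 0.80,
#'   hybridisation tolerates mismatches).
#' @param nonspecific_rate per-fragment per-round carry-over probability.
#' @param rounds number of capture rounds (0, 1 or 2).
#' @param seed_len exact seed length used to locate candidate probes.
#' @return A list of class `capture_model`.
#' @export
capture_model <- function(min_overlap = 100L, min_identity = 0.80,
                          nonspecific_rate = 1e-4, rounds = 1L,
                          seed_len = 12L) {
  stopifnot(rounds %in% 0:2)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity,
                 nonspecific_rate = nonspecific_rate,
                 rounds = as.integer(rounds),
                 seed_len = as.integer(seed_len)),
            class = "capture_model")
}

# which fragments have a qualifying ungapped probe alignment (either strand):
# exact seed_len-mer seeding against the probe set, then Hamming extension on
# the seeded diagonal
capture_hit <- function(frag_seqs, probeset, min_overlap = 100L,
                        min_identity = 0.80, seed_len = 12L) {
  n <- length(frag_seqs)
  if (n == 0 || nrow(probeset) == 0) return(logical(n))
  probes <- c(probeset$seq, revcomp(probeset$seq))
  plen <- nchar(probes)
  seed_tab <- list()
  seed_probe <- integer(); seed_pos <- integer(); seed_str <- character()
  for (p in seq_along(probes)) {
    starts <- seq.int(1L, plen[p] - seed_len + 1L, by = seed_len)
    seed_probe <- c(seed_probe, rep.int(p, length(starts)))
    seed_pos <- c(seed_pos, starts)
    seed_str <- c(seed_str, substring(probes[p], starts, starts + seed_len - 1L))
  }
  useed <- unique(seed_str)
  si <- match(seed_str, useed)
  by_seed <- split(seq_along(seed_str), si)
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(useed))
  hits_per_frag <- Biostrings::vwhichPDict(
    pdict, Biostrings::DNAStringSet(frag_seqs))
  out <- logical(n)
  cand_frags <- which(lengths(hits_per_frag) > 0)
  for (i in cand_frags) {
    entries <- unlist(by_seed[as.character(hits_per_frag[[i]])],
                      use.names = FALSE)
    probes_hit <- seed_probe[entries]
    frag <- frag_seqs[i]
    flen <- nchar(frag)
    for (e in entries[!duplicated(probes_hit)]) {
      p <- seed_probe[e]
      posf <- regexpr(seed_str[e], frag, fixed = TRUE)
      if (posf < 0) next
      diag <- as.integer(posf) - seed_pos[e]
      a <- max(1L, 1L + diag)
      b <- min(flen, plen[p] + diag)
      ov <- b - a + 1L
      if (ov < min_overlap) next
      mism <- hamming(substr(frag, a, b), substr(probes[p], a - diag, b - diag))
      if (1 - mism / ov >= min_identity) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

#' Simulate one or more rounds of hybridisation capture
#'
#' @param fragments a `fragment_set` with sequences.
#' @param probeset a `probe_set`.
#' @param model a `capture_model`.
#' @param seed integer seed (nonspecific carry-over draws).
#' @return The retained `fragment_set`.
#' @export
simulate_capture <- function(fragments, probeset, model = capture_model(),
                             seed = 1L) {
  if (model$rounds == 0) return(fragments)
  hit <- capture_hit(fragments$seq, probeset, model$min_overlap,
                     model$min_identity, model$seed_len)
  with_seed(derive_seed(seed, "capture"), {
    keep <- hit
    miss <- which(!hit)
    if (length(miss) > 0 && model$nonspecific_rate > 0) {
      keep[miss] <- stats::runif(length(miss)) <
        model$nonspecific_rate ^ model$rounds
    }
    out <- fragments[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
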