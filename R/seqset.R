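#' Vectorised sequence record container
#'
#' A `seq_set` holds parallel vectors of record ids, uppercase nucleotide or
#' amino-acid sequences, optional per-base Phred qualities (Phred+33 strings)
#' and an optional metadata data frame (sample, provenance tags and the like).
#' It is the interchange type used by every module: readers return it,
#' simulators emit it and the pipeline stages consume it.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of sequences; lowercase input is normalised to
#'   uppercase. Only IUPAC nucleotide/amino-acid codes (plus `*` and `-`) are
#'   accepted.
#' @param qual optional character vector of Phred+33 quality strings, one per
#'   record, each the same length as its sequence.
#' @param meta optional data frame with one row per record.
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(id, seq, qual = NULL, meta = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("id and seq must have the same length")
  }
  bad <- grep("[^ACGTUNRYSWKMBDHVEFILPQXZ*.-]", seq)
  if (length(bad) > 0) {
    stop("record ", id[bad[1]], " contains characters outside the IUPAC alphabet")
  }
  if (!is.null(qual)) {
    qual <- as.character(qual)
    if (length(qual) != length(seq)) {
      stop("qual must have one entry per record")
    }
    mism <- which(nchar(qual) != nchar(seq))
    if (length(mism) > 0) {
      stop("record ", id[mism[1]], ": quality length does not match sequence length")
    }
  }
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != length(id)) stop("meta must have one row per record")
  }
  structure(list(id = id, seq = seq, qual = qual, meta = meta),
            class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$id)

#' @export
`[.seq_set` <- function(x, i) {
  seq_set(x$id[i], x$seq[i],
          qual = if (!is.null(x$qual)) x$qual[i] else NULL,
          meta = if (!is.null(x$meta)) x$meta[i, , drop = FALSE] else NULL)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", length(x), "records\n")
  n <- min(length(x), 6L)
  if (n > 0) {
    w <- nchar(x$seq[seq_len(n)])
    prev <- ifelse(w > 40, paste0(substr(x$seq[seq_len(n)], 1, 37), "..."),
                   x$seq[seq_len(n)])
    cat(sprintf("  %-20s %5d nt  %s\n", x$id[seq_len(n)], w, prev), sep = "")
    if (length(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Concatenate sequence sets
#'
#' @param ... `seq_set` objects. Qualities are kept only if every set has
#'   them; metadata columns are unioned with NA fill.
#' @return A single `seq_set`.
#' @export
concat_seq_sets <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, length, 1L) > 0]
  if (length(sets) == 0) return(seq_set(character(), character()))
  id <- unlist(lapply(sets, `[[`, "id"), use.names = FALSE)
  seq <- unlist(lapply(sets, `[[`, "seq"), use.names = FALSE)
  qual <- NULL
  if (all(vapply(sets, function(s) !is.null(s$qual), TRUE))) {
    qual <- unlist(lapply(sets, `[[`, "qual"), use.names = FALSE)
  }
  metas <- lapply(sets, function(s) {
    if (is.null(s$meta)) data.frame(row.names = seq_along(s$id)) else s$meta
  })
  cols <- unique(unlist(lapply(metas, names)))
  meta <- NULL
  if (length(cols) > 0) {
    meta <- do.call(rbind, lapply(metas, function(m) {
      for (cl in setdiff(cols, names(m))) m[[cl]] <- NA
      m[, cols, drop = FALSE]
    }))
    rownames(meta) <- NULL
  }
  seq_set(id, seq, qual = qual, meta = meta)
}

# -- Phred+33 arithmetic ------------------------------------------------------

#' Decode a Phred+33 quality string to integer scores
#' @param qual a single quality string.
#' @return integer vector of Phred scores.
#' @export
phred_decode <- function(qual) {
  if (nchar(qual) == 0) return(integer())
  utf8ToInt(qual) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores integer vector of Phred scores (0-93).
#' @return a single quality string.
#' @export
phred_encode <- function(scores) {
  if (length(scores) == 0) return("")
  intToUtf8(pmin(pmax(as.integer(scores), 0L), 93L) + 33L)
}

# -- small sequence utilities -------------------------------------------------

#' Reverse complement of nucleotide strings
#' @param seq character vector of IUPAC nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  out <- character(length(seq))
  nz <- nchar(seq) > 0
  out[nz] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq[nz])))
  out
}

# substring on a circular sequence: 0-based start, wraps modulo length
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  start <- start %% n
  end <- start + len
  if (end <= n) {
    substr(seq, start + 1, end)
  } else {
    paste0(substr(seq, start + 1, n), substr(strrep(seq, ceiling(end / n)), n + 1, end))
  }
}
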