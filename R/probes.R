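#' Tile capture probes over a reference database
#'
#' For each record of length `L >= probe_len`, probes are placed at offsets
#' 0, stride, 2*stride, ... plus a final right-anchored probe ending at `L`,
#' so the 3' end is always covered. Records shorter than `probe_len` yield no
#' probes. Offsets are 0-based.
#'
#' @param db a `reference_db` or `seq_set`.
#' @param probe_len probe length in nt (default 100).
#' @param stride tiling stride in nt (default 50, i.e. 2x tiling).
#' @return A `probe_set`: data frame of probes (`probe_id`, `source_id`,
#'   `offset`, `seq`) with `probe_len` and `stride` attributes.
#' @export
tile_probes <- function(db, probe_len = 100L, stride = 50L) {
  stopifnot(probe_len >= 1, stride >= 1)
  recs <- if (inherits(db, "reference_db")) db$records else db
  rows <- lapply(seq_along(recs), function(i) {
    L <- nchar(recs$seq[i])
    if (L < probe_len) return(NULL)
    offs <- seq.int(0L, L - probe_len, by = stride)
    if (offs[length(offs)] != L - probe_len) offs <- c(offs, L - probe_len)
    data.frame(source_id = recs$id[i], offset = as.integer(offs),
               seq = substring(recs$seq[i], offs + 1L, offs + probe_len),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  probes <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(source_id = character(), offset = integer(),
               seq = character(), stringsAsFactors = FALSE)
  }
  probes <- cbind(probe_id = sprintf("%s:%d", probes$source_id, probes$offset),
                  probes)
  structure(probes, probe_len = as.integer(probe_len),
            stride = as.integer(stride), class = c("probe_set", "data.frame"))
}

#' Collapse probes with identical sequences
#'
#' Identical probe sequences are collapsed to one, keeping the first source,
#' so shared gene regions do not draw a disproportionate share of the probe
#' pool. Idempotent.
#'
#' @param probeset a `probe_set`.
#' @return The deduplicated `probe_set`.
#' @export
dedup_probes <- function(probeset) {
  keep <- !duplicated(probeset$seq)
  out <- as.data.frame(probeset)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, probe_len = attr(probeset, "probe_len"),
            stride = attr(probeset, "stride"),
            class = c("probe_set", "data.frame"))
}

#' Fraction of database nucleotides covered by probe footprints
#'
#' The union of probe intervals on each source record, divided by the total
#' nucleotide count of the database. Deduplicated probes still cover their
#' original footprints only on the source kept, so coverage is reported both
#' before and after dedup by the design report.
#'
#' @param probeset a `probe_set`.
#' @param db the `reference_db` (or `seq_set`) the probes were tiled from.
#' @return A fraction in `[0, 1]`.
#' @export
probe_coverage <- function(probeset, db) {
  recs <- if (inherits(db, "reference_db")) db$records else db
  total <- sum(nchar(recs$seq))
  if (total == 0) return(0)
  plen <- attr(probeset, "probe_len")
  covered <- 0
  for (id in unique(probeset$source_id)) {
    offs <- probeset$offset[probeset$source_id == id]
    ir <- IRanges::reduce(IRanges::IRanges(start = offs + 1L,
                                           width = plen))
    covered <- covered + sum(IRanges::width(ir))
  }
  covered / total
}

#' Design a probe set: tile, deduplicate and report coverage
#'
#' @inheritParams tile_probes
#' @return A list with the deduplicated `probe_set` and a per-record design
#'   report (`report`), plus coverage before (`coverage_raw`) and after
#'   (`coverage`) probe deduplication.
#' @export
design_probes <- function(db, probe_len = 100L, stride = 50L) {
  raw <- tile_probes(db, probe_len = probe_len, stride = stride)
  cov_raw <- probe_coverage(raw, db)
  ded <- dedup_probes(raw)
  cov <- probe_coverage(ded, db)
  recs <- if (inherits(db, "reference_db")) db$records else db
  report <- data.frame(
    id = recs$id,
    length_nt = nchar(recs$seq),
    n_probes = as.integer(table(factor(ded$source_id, levels = recs$id))))
  list(probes = ded, report = report, coverage = cov, coverage_raw = cov_raw)
}

#' Write a probe set as FASTA (id encodes source:offset)
#' @param probeset a `probe_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probeset, path) {
  write_fasta(seq_set(probeset$probe_id, probeset$seq), path)
}
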