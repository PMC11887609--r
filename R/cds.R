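#' Extract candidate protein-coding sequences from contigs
#'
#' Six-frame scan for maximal start-to-stop ORFs: within each frame, open
#' reading stretches between stop codons are emitted from their first start
#' codon (ATG/GTG/TTG, bacterial/archaeal starts) through the closing stop
#' codon. ORFs shorter than `min_aa` codons (stop excluded) are dropped.
#' Reverse-strand ORFs are reported in their coding orientation with the
#' strand annotated.
#'
#' @param contigs contig data frame from [assemble_reads()] (columns `id`,
#'   `seq`, `member_reads`, `sample`) or a `seq_set`.
#' @param min_aa minimum ORF length in amino acids (default 100).
#' @return A data frame of candidate CDS: `id`, `contig_id`, `sample`,
#'   `strand`, `start` (0-based on the contig's forward strand), `nt_seq`
#'   (stop codon included), `aa_seq`, `abundance` (contig read support).
#' @export
extract_cds <- function(contigs, min_aa = 100L) {
  if (inherits(contigs, "seq_set")) {
    contigs <- data.frame(id = contigs$id, seq = contigs$seq,
                          member_reads = 1, sample = NA_character_,
                          stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    fwd <- contigs$seq[i]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      for (frame in 0:2) {
        for (orf in frame_orfs(s, frame, min_aa)) {
          start_fwd <- if (strand == "+") orf$start else
            nchar(fwd) - (orf$start + nchar(orf$nt))
          rows[[length(rows) + 1]] <- data.frame(
            contig_id = contigs$id[i], sample = contigs$sample[i],
            strand = strand, start = start_fwd, nt_seq = orf$nt,
            abundance = contigs$member_reads[i], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id = character(), contig_id = character(),
                      sample = character(), strand = character(),
                      start = integer(), nt_seq = character(),
                      aa_seq = character(), abundance = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$id <- sprintf("%s_cds%02d", out$contig_id,
                    stats::ave(seq_len(nrow(out)), out$contig_id,
                               FUN = seq_along))
  out$aa_seq <- vapply(out$nt_seq, translate_cds, "", USE.NAMES = FALSE)
  rownames(out) <- NULL
  out[, c("id", "contig_id", "sample", "strand", "start", "nt_seq",
          "aa_seq", "abundance")]
}

START_CODONS <- c("ATG", "GTG", "TTG")

# maximal ORFs of one frame of one strand; start is 0-based on `s`
frame_orfs <- function(s, frame, min_aa) {
  n <- nchar(s)
  n_cod <- (n - frame) %/% 3
  if (n_cod < min_aa + 1L) return(list())
  starts <- frame + seq.int(0L, (n_cod - 1L) * 3L, by = 3L)
  cod <- substring(s, starts + 1L, starts + 3L)
  is_stop <- cod %in% STOP_CODONS
  is_start <- cod %in% START_CODONS
  orfs <- list()
  seg_begin <- 1L
  for (j in c(which(is_stop), if (!any(is_stop) || !is_stop[n_cod]) NA)) {
    if (is.na(j)) break  # trailing segment without a stop codon: skipped
    seg <- seg_begin:j
    st <- seg[is_start[seg]]
    if (length(st) > 0) {
      first <- st[1]
      aa_len <- j - first  # codons before the stop
      if (aa_len >= min_aa) {
        orfs[[length(orfs) + 1]] <- list(
          start = starts[first],
          nt = substr(s, starts[first] + 1L, starts[j] + 3L))
      }
    }
    seg_begin <- j + 1L
  }
  orfs
}
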