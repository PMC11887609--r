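#' Curated target-gene reference database
#'
#' Holds labelled CuMMO-family sequences (gene family, clade, source) plus the
#' curation counts (input, after exact deduplication, after the rRNA exclusion
#' screen). It is the substrate for probe tiling and the subject of the
#' pipeline's protein homology search.
#'
#' @param records a `seq_set` of nucleotide reference sequences.
#' @param labels optional data frame with columns `id`, `gene_family`
#'   (e.g. `amoA-AOA`, `amoA-AOB`, `pmoA`, `other-CuMMO`), `clade` and
#'   optionally `source`; matched to records by `id`. Unlabelled records get
#'   NA labels.
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(records, labels = NULL) {
  meta <- data.frame(gene_family = rep(NA_character_, length(records)),
                     clade = NA_character_, source = NA_character_,
                     stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    i <- match(records$id, labels$id)
    for (cl in intersect(c("gene_family", "clade", "source"), names(labels))) {
      meta[[cl]] <- labels[[cl]][i]
    }
  }
  records$meta <- meta
  structure(list(records = records,
                 n_input = length(records),
                 n_after_dedup = NA_integer_,
                 n_after_exclusion = NA_integer_),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("reference_db: ", length(x$records), " records",
      " (input ", x$n_input,
      if (!is.na(x$n_after_dedup)) paste0(", after dedup ", x$n_after_dedup),
      if (!is.na(x$n_after_exclusion))
        paste0(", after exclusion ", x$n_after_exclusion),
      ")\n", sep = "")
  fam <- table(x$records$meta$gene_family, useNA = "ifany")
  if (length(fam) > 0) print(fam)
  invisible(x)
}

#' Remove exact duplicate sequences, keeping the first occurrence
#'
#' Duplicate means exact full-string equality on the forward strand;
#' reverse-complement duplicates are handled downstream by strand-agnostic
#' search. Idempotent.
#'
#' @param db a `reference_db` or `seq_set`.
#' @return The same type with duplicates removed; a `reference_db` records
#'   the post-dedup count.
#' @export
dedup_exact <- function(db) {
  if (inherits(db, "seq_set")) {
    return(db[!duplicated(db$seq)])
  }
  keep <- !duplicated(db$records$seq)
  db$records <- db$records[keep]
  db$n_after_dedup <- sum(keep)
  db
}

#' Screen out records similar to an exclusion reference set
#'
#' Records with a local alignment (either strand) to any exclusion reference
#' at `min_identity` or better, covering at least `min_cov` of the shorter
#' sequence, are removed. A shared 12-mer prefilter skips records that cannot
#' reach the thresholds cheaply. Removals are reported with their best-hit
#' identity in the `exclusion_report` attribute.
#'
#' @param db a `reference_db`.
#' @param exclusion_refs a `seq_set` of exclusion sequences (e.g. 16S rRNA).
#' @param min_identity minimum local-alignment identity (fraction).
#' @param min_cov minimum coverage of the shorter sequence (fraction).
#' @return The screened `reference_db`.
#' @export
screen_exclusion <- function(db, exclusion_refs, min_identity = 0.80,
                             min_cov = 0.50) {
  stopifnot(inherits(db, "reference_db"))
  if (length(exclusion_refs) == 0) stop("exclusion_refs must be non-empty")
  recs <- db$records
  cand <- shares_kmer(recs$seq, exclusion_refs$seq, k = 12L)
  removed <- rep(FALSE, length(recs))
  best_id <- rep(NA_real_, length(recs))
  for (i in which(cand)) {
    for (j in seq_along(exclusion_refs)) {
      st <- align_stats_bothstrands(recs$seq[i], exclusion_refs$seq[j])
      if (is.na(best_id[i]) || st$identity > best_id[i]) best_id[i] <- st$identity
      if (st$identity >= min_identity && st$shorter_cov >= min_cov) {
        removed[i] <- TRUE
        break
      }
    }
  }
  report <- data.frame(id = recs$id[removed],
                       best_hit_identity = best_id[removed])
  db$records <- recs[!removed]
  db$n_after_exclusion <- sum(!removed)
  attr(db, "exclusion_report") <- report
  db
}

#' Count database records recruitable by a query gene
#'
#' The probe-bias diagnostic: how many database sequences align to the query
#' at `min_identity` or better over at least half of the shorter sequence.
#' Genes with few recruitable relatives are tiled by few probe variants and
#' are captured less efficiently.
#'
#' @param db a `reference_db`.
#' @param query_gene a nucleotide string.
#' @param min_identity minimum local-alignment identity (fraction).
#' @return Integer count.
#' @export
recruitment_power <- function(db, query_gene, min_identity) {
  stopifnot(inherits(db, "reference_db"))
  recs <- db$records
  if (length(recs) == 0) return(0L)
  cand <- shares_kmer(recs$seq, query_gene, k = 12L)
  n <- 0L
  for (i in which(cand)) {
    st <- align_stats_bothstrands(recs$seq[i], query_gene)
    if (st$identity >= min_identity && st$shorter_cov >= 0.5) n <- n + 1L
  }
  n
}

#' Full curation: exact dedup then exclusion screen
#'
#' @inheritParams screen_exclusion
#' @param records a `seq_set` of reference sequences.
#' @param labels optional label table (see [reference_db()]).
#' @param exclusion_refs optional `seq_set`; when NULL the screen is skipped.
#' @return A curated `reference_db`.
#' @export
curate_refdb <- function(records, labels = NULL, exclusion_refs = NULL,
                         min_identity = 0.80, min_cov = 0.50) {
  db <- dedup_exact(reference_db(records, labels))
  if (!is.null(exclusion_refs) && length(exclusion_refs) > 0) {
    db <- screen_exclusion(db, exclusion_refs, min_identity, min_cov)
  } else {
    db$n_after_exclusion <- length(db$records)
  }
  db
}

#' Write the curation report
#'
#' @param db a curated `reference_db`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(db, path) {
  df <- data.frame(stage = c("input", "after_dedup", "after_exclusion"),
                   n_records = c(db$n_input, db$n_after_dedup,
                                 db$n_after_exclusion))
  write_tsv_report(df, path, "reference database curation; n_records = count")
}

# protein translations of the reference records, used by the homology search;
# records are assumed to be in-frame CDS nucleotide sequences
refdb_proteins <- function(db) {
  vapply(db$records$seq, translate_cds, "", USE.NAMES = FALSE)
}

# translate an in-frame CDS, trimming any partial terminal codon and the
# trailing stop; internal stops are kept as '*' (they simply depress identity)
translate_cds <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, n)),
    if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}
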