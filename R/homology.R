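#' Protein-level homology filter against the CuMMO reference database
#'
#' Each candidate CDS translation is aligned locally (BLOSUM62) against the
#' reference protein set; the best-scoring hit is kept only when its identity
#' and both query and subject coverages meet the thresholds, after which the
#' nucleotide length window is applied. Identity/coverage thresholds stand in
#' for the e-value criterion of database search tools, whose value depends on
#' database size.
#'
#' @param cds_df candidate CDS data frame from [extract_cds()].
#' @param refdb a `reference_db` of in-frame nucleotide references.
#' @param min_identity minimum percent amino-acid identity (default 60).
#' @param min_query_cov,min_subject_cov minimum percent coverage of query and
#'   subject (default 50 each).
#' @param nt_len_range inclusive nucleotide length window (default 400-1000).
#' @return The filtered CDS data frame with hit columns `hit_ref`,
#'   `hit_identity` (percent), `hit_query_cov`, `hit_subject_cov` (percent).
#' @export
search_cummo <- function(cds_df, refdb, min_identity = 60,
                         min_query_cov = 50, min_subject_cov = 50,
                         nt_len_range = c(400L, 1000L)) {
  prots <- refdb_proteins(refdb)
  ref_ids <- refdb$records$id
  n <- nrow(cds_df)
  hit_ref <- rep(NA_character_, n)
  hit_id <- rep(NA_real_, n)
  hit_qc <- rep(NA_real_, n)
  hit_sc <- rep(NA_real_, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    q <- cds_df$aa_seq[i]
    if (nchar(q) == 0 || length(prots) == 0) next
    best <- NULL
    best_nm <- -1
    for (j in seq_along(prots)) {
      st <- align_stats(q, prots[j], type = "local", protein = TRUE)
      if (st$n_match > best_nm) {
        best_nm <- st$n_match
        best <- st
        hit_ref[i] <- ref_ids[j]
      }
    }
    hit_id[i] <- 100 * best$identity
    hit_qc[i] <- 100 * best$query_cov
    hit_sc[i] <- 100 * best$subject_cov
    keep[i] <- hit_id[i] >= min_identity && hit_qc[i] >= min_query_cov &&
      hit_sc[i] >= min_subject_cov
  }
  out <- cds_df
  out$hit_ref <- hit_ref
  out$hit_identity <- hit_id
  out$hit_query_cov <- hit_qc
  out$hit_subject_cov <- hit_sc
  L <- nchar(out$nt_seq)
  out <- out[keep & L >= nt_len_range[1] & L <= nt_len_range[2], ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
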