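#' Greedy centroid clustering into OTUs
#'
#' Sequences are processed by decreasing abundance (ties: length descending,
#' then id ascending). Each sequence joins the first existing centroid it
#' matches at `identity` or better over at least `coverage` of the shorter
#' sequence, otherwise it founds a new centroid. Clusters below
#' `min_members` sequences (singletons by default) are discarded; surviving
#' clusters are the OTUs, represented by their centroid.
#'
#' @param seqs character vector (or `seq_set`) of sequences; for CDS input
#'   pass `nt_seq`.
#' @param abundance numeric read support per sequence (default 1 each).
#' @param ids optional sequence identifiers (default positional).
#' @param identity minimum pairwise identity (fraction, default 0.97;
#'   inclusive).
#' @param coverage minimum aligned coverage of the shorter sequence
#'   (fraction, default 0.50).
#' @param discard_singletons drop single-member clusters (default TRUE).
#' @return A data frame of OTUs ordered by total abundance: `otu_id`,
#'   `representative` (centroid sequence), `length`, `member_count`,
#'   `abundance`, `members` (comma-joined ids).
#' @export
cluster_otus <- function(seqs, abundance = NULL, ids = NULL,
                         identity = 0.97, coverage = 0.50,
                         discard_singletons = TRUE) {
  if (inherits(seqs, "seq_set")) {
    if (is.null(ids)) ids <- seqs$id
    seqs <- seqs$seq
  }
  n <- length(seqs)
  if (is.null(abundance)) abundance <- rep(1, n)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_len(n))
  empty <- data.frame(otu_id = character(), representative = character(),
                      length = integer(), member_count = integer(),
                      abundance = numeric(), members = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  ord <- order(-abundance, -nchar(seqs), ids)
  cent_seq <- character()
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(cent_seq)) {
      if (seqs[i] == cent_seq[ci]) {        # exact duplicates skip alignment
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
      st <- align_stats(seqs[i], cent_seq[ci], type = "local")
      if (st$identity >= identity && st$shorter_cov >= coverage) {
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cent_seq <- c(cent_seq, seqs[i])
      members[[length(members) + 1]] <- i
    }
  }
  cnt <- lengths(members)
  keep <- if (discard_singletons) which(cnt >= 2L) else seq_along(cnt)
  if (length(keep) == 0) return(empty)
  totab <- vapply(members[keep], function(m) sum(abundance[m]), 0)
  o <- order(-totab, seq_along(keep))
  keep <- keep[o]
  data.frame(
    otu_id = sprintf("OTU_%d", seq_along(keep)),
    representative = cent_seq[keep],
    length = nchar(cent_seq[keep]),
    member_count = as.integer(cnt[keep]),
    abundance = totab[o],
    members = vapply(members[keep], function(m)
      paste(ids[m], collapse = ","), ""),
    stringsAsFactors = FALSE)
}
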