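# Taxonomy and ecotype assignment for OTUs, plus a working neighbour-joining
# phylogeny emitted as newick for external re-estimation.

#' The oceanic AOA ecotype map
#'
#' The three-way correspondence between Nitrosopumilales (NP) order clades
#' and the classic water-column ecotypes: NP-epsilon-2 is water column
#' cluster A (WCA), NP-alpha-2.2.2.1 is water column cluster B (WCB) and
#' NP-gamma-2.1 is the Nitrosopumilus maritimus-like cluster (NMC). All
#' other clades map to none.
#'
#' @return A named character vector of length three (clade -> ecotype).
#' @export
ecotype_map <- function() {
  m <- c("WCA", "WCB", "NMC")
  names(m) <- c(paste0("NP-", "\u03b5", "-2"),
                paste0("NP-", "\u03b1", "-2.2.2.1"),
                paste0("NP-", "\u03b3", "-2.1"))
  m
}

#' Assign taxonomy to OTUs by best-hit label transfer
#'
#' Each OTU representative is aligned (local, both strands) against the
#' labelled reference database; the best hit's gene family and clade are
#' transferred with the identity recorded. Ties across references keep only
#' the deepest label shared by all tied hits. Representatives below the
#' identity floor, or whose best alignment covers less than half of the
#' shorter sequence (a short local hit carries no taxonomic signal), are
#' reported as unclassified CuMMO.
#'
#' @param otus OTU data frame from [cluster_otus()] (or a `seq_set`).
#' @param refdb a labelled `reference_db`.
#' @param floor_identity percent identity below which an OTU is
#'   unclassified (default 75).
#' @return A data frame: `otu_id`, `best_ref`, `identity` (percent),
#'   `gene_family`, `clade`, `ecotype` (filled by [assign_ecotype()]).
#' @export
assign_taxonomy <- function(otus, refdb, floor_identity = 75) {
  seqs <- if (is.data.frame(otus)) otus$representative else otus$seq
  ids <- if (is.data.frame(otus)) otus$otu_id else otus$id
  meta <- refdb$records$meta
  out <- data.frame(otu_id = ids, best_ref = NA_character_,
                    identity = NA_real_, gene_family = NA_character_,
                    clade = NA_character_, ecotype = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(seqs)) {
    sts <- lapply(seq_along(refdb$records), function(j) {
      align_stats_bothstrands(seqs[i], refdb$records$seq[j])
    })
    nm <- vapply(sts, `[[`, 0, "n_match")
    ident <- vapply(sts, `[[`, 0, "identity")
    cov <- vapply(sts, `[[`, 0, "shorter_cov")
    best <- which(nm == max(nm))
    out$best_ref[i] <- refdb$records$id[best[1]]
    out$identity[i] <- 100 * max(ident[best])
    if (out$identity[i] < floor_identity || max(cov[best]) < 0.5) {
      out$gene_family[i] <- "unclassified-CuMMO"
      next
    }
    fams <- unique(meta$gene_family[best])
    clades <- unique(meta$clade[best])
    out$gene_family[i] <- if (length(fams) == 1) fams else "CuMMO"
    out$clade[i] <- if (length(clades) == 1) clades else NA_character_
  }
  out
}

#' Fill ecotype labels from clade assignments
#'
#' Only archaeal amoA OTUs (gene family `amoA-AOA`) receive an ecotype;
#' clades outside the map get `"none"`.
#'
#' @param assignments data frame from [assign_taxonomy()].
#' @param map clade-to-ecotype map (default [ecotype_map()]).
#' @return The assignments with the `ecotype` column filled.
#' @export
assign_ecotype <- function(assignments, map = ecotype_map()) {
  eco <- rep(NA_character_, nrow(assignments))
  is_aoa <- !is.na(assignments$gene_family) &
    assignments$gene_family == "amoA-AOA"
  eco[is_aoa] <- ifelse(assignments$clade[is_aoa] %in% names(map),
                        map[assignments$clade[is_aoa]], "none")
  assignments$ecotype <- eco
  assignments
}

#' Neighbour-joining tree of OTU representatives
#'
#' Pairwise global-alignment p-distances are Jukes-Cantor corrected and fed
#' to neighbour joining; the result is deterministic given the input order
#' and emitted as a newick string for external re-estimation with
#' model-based tools.
#'
#' @param otus OTU data frame, `seq_set` or named character vector of at
#'   least three sequences.
#' @return The newick string; the `phylo` attribute carries the [ape] tree.
#' @export
build_tree <- function(otus) {
  if (is.data.frame(otus)) {
    seqs <- otus$representative; ids <- otus$otu_id
  } else if (inherits(otus, "seq_set")) {
    seqs <- otus$seq; ids <- otus$id
  } else {
    seqs <- as.character(otus)
    ids <- names(otus) %||% sprintf("seq%d", seq_along(seqs))
  }
  n <- length(seqs)
  if (n < 3) stop("at least 3 sequences are required for a tree")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- 1 - global_identity(seqs[i], seqs[j])
      d[i, j] <- d[j, i] <- jc_distance(p)
    }
  }
  tree <- ape::nj(stats::as.dist(d))
  nwk <- ape::write.tree(tree)
  attr(nwk, "phylo") <- tree
  nwk
}

# Jukes-Cantor correction of a p-distance (capped below saturation)
jc_distance <- function(p) {
  p <- min(p, 0.7495)
  -0.75 * log(1 - 4 * p / 3)
}
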