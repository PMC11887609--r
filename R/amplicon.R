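#' A degenerate PCR primer pair
#'
#' @param fwd forward primer (5'-3', IUPAC codes allowed).
#' @param rev reverse primer (5'-3' on the opposite strand).
#' @param max_mismatch maximum tolerated mismatches per primer site.
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(fwd, rev, max_mismatch = 3L) {
  structure(list(fwd = toupper(fwd), rev = toupper(rev),
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' The archaeal amoA primer pair of Francis and colleagues
#'
#' Arch-amoAF (`STAATGGTCTGGCTTAGACG`) and Arch-amoAR
#' (`GCGGCCATCCATCTGTATGT`), amplifying a 635 bp region of archaeal amoA.
#' IUPAC degeneracy is honoured during matching (S pairs with C or G).
#'
#' @param max_mismatch maximum tolerated mismatches per primer site.
#' @return A `primer_pair`.
#' @export
francis_primers <- function(max_mismatch = 3L) {
  primer_pair("STAATGGTCTGGCTTAGACG", "GCGGCCATCCATCTGTATGT", max_mismatch)
}

# best (fewest-mismatch) binding site of a primer on the given strand of a
# template; returns NULL or list(start, end, mismatches) in template coords
best_primer_site <- function(primer, template, max_mismatch) {
  pat <- Biostrings::DNAString(primer)
  subj <- Biostrings::DNAString(template)
  m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                fixed = FALSE)
  if (length(m) == 0) return(NULL)
  mism <- Biostrings::neditStartingAt(pat, subj, starting.at = Biostrings::start(m),
                                      fixed = FALSE)
  i <- which.min(mism)
  list(start = Biostrings::start(m)[i], end = Biostrings::end(m)[i],
       mismatches = as.integer(mism[i]))
}

# locate an amplifiable product on a template: forward primer on the plus
# strand, reverse primer on the minus strand downstream of it
find_product <- function(template, primers) {
  f <- best_primer_site(primers$fwd, template, primers$max_mismatch)
  if (is.null(f)) return(NULL)
  r <- best_primer_site(primers$rev, revcomp(template), primers$max_mismatch)
  if (is.null(r)) return(NULL)
  # convert the minus-strand site to plus-strand coordinates
  n <- nchar(template)
  r_start <- n - r$end + 1L
  r_end <- n - r$start + 1L
  if (r_end <= f$start) return(NULL)
  list(start = f$start, end = r_end,
       seq = substr(template, f$start, r_end),
       mismatches = f$mismatches + r$mismatches)
}

#' Implant primer binding sites into a template
#'
#' Writes the forward primer site (degeneracies resolved) and the reverse
#' primer site into a template so that the amplified product spans
#' `product_len` nt; `mismatch_fwd`/`mismatch_rev` positions of each site are
#' then altered so the primers carry that many mismatches. Used to build
#' amplicon-bias fixtures with controlled primer affinity.
#'
#' @param template a nucleotide string (length >= `offset + product_len`).
#' @param primers a `primer_pair`.
#' @param mismatch_fwd,mismatch_rev mismatches to plant in each site.
#' @param product_len product length in nt including both primer sites.
#' @param offset 1-based start of the forward site (default 10).
#' @param seed integer seed (degeneracy resolution and mismatch placement).
#' @return The modified template string.
#' @export
implant_primer_sites <- function(template, primers, mismatch_fwd = 0L,
                                 mismatch_rev = 0L, product_len = 635L,
                                 offset = 10L, seed = 1L) {
  if (nchar(template) < offset + product_len - 1L) {
    stop("template too short for the requested product")
  }
  with_seed(derive_seed(seed, "implant"), {
    fwd_site <- resolve_degenerate(primers$fwd)
    rev_site <- revcomp(resolve_degenerate(primers$rev))
    fwd_site <- plant_mismatches(fwd_site, mismatch_fwd, primers$fwd)
    rev_site <- plant_mismatches(rev_site, mismatch_rev,
                                 revcomp(primers$rev))
    ch <- strsplit(template, "")[[1]]
    ch[offset:(offset + nchar(fwd_site) - 1L)] <- strsplit(fwd_site, "")[[1]]
    r_end <- offset + product_len - 1L
    r_start <- r_end - nchar(rev_site) + 1L
    ch[r_start:r_end] <- strsplit(rev_site, "")[[1]]
    paste(ch, collapse = "")
  })
}

# resolve IUPAC degeneracies to a concrete base (uniformly at random)
resolve_degenerate <- function(seq) {
  code <- Biostrings::IUPAC_CODE_MAP
  ch <- strsplit(seq, "")[[1]]
  amb <- which(!(ch %in% c("A", "C", "G", "T")))
  for (p in amb) {
    opts <- strsplit(code[[ch[p]]], "")[[1]]
    ch[p] <- opts[sample.int(length(opts), 1)]
  }
  paste(ch, collapse = "")
}

# alter `n` site positions so the given (possibly degenerate) primer carries
# exactly that many mismatches against the site
plant_mismatches <- function(site, n, primer) {
  if (n == 0) return(site)
  code <- Biostrings::IUPAC_CODE_MAP
  ch <- strsplit(site, "")[[1]]
  pch <- strsplit(primer, "")[[1]]
  pos <- sample.int(length(ch), n)
  for (p in pos) {
    allowed <- strsplit(code[[pch[p]]], "")[[1]]
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), allowed), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate two-step PCR amplicon sequencing
#'
#' For each template the best forward/reverse primer sites are located
#' (degenerate-aware, at most `max_mismatch` mismatches each); templates
#' without both sites yield no product. A template's amplification weight is
#' `(1 + efficiency * mismatch_penalty^(m_f + m_r))^cycles`, the branching-
#' process expectation under mismatch-depressed priming. Reads are drawn from
#' products proportionally to weight: `long_read = TRUE` emits one
#' near-perfect long read per drawn product (HiFi-style, >= 99 percent
#' accuracy), otherwise 2x300 pairs from the product ends.
#'
#' @param templates a `seq_set` of full-length template genes/cDNA.
#' @param primers a `primer_pair` (default the archaeal amoA pair).
#' @param model a `pcr_model` carrying cycles/efficiency/mismatch_penalty.
#' @param long_read emit long reads (TRUE) or 2x300 pairs (FALSE).
#' @param n_reads number of reads (or pairs) to draw.
#' @param error_rate per-base substitution rate of the reads (default 1e-3,
#'   within the HiFi >= 99 percent accuracy envelope).
#' @param sample_name sample label.
#' @param seed integer seed.
#' @return For long reads a `seq_set` with a `meta` data frame naming each
#'   read's template; otherwise a `read_pairs` object. The `products`
#'   attribute tabulates per-template product length, mismatches and weight.
#' @export
simulate_amplicon <- function(templates, primers = francis_primers(),
                              model = pcr_model(cycles = 35L),
                              long_read = TRUE, n_reads = 1000L,
                              error_rate = 1e-3, sample_name = "amplicon",
                              seed = 1L) {
  prods <- lapply(templates$seq, find_product, primers = primers)
  has <- !vapply(prods, is.null, TRUE)
  tab <- data.frame(
    template = templates$id,
    product_len = vapply(prods, function(p) if (is.null(p)) NA_integer_ else
      nchar(p$seq), 0L),
    mismatches = vapply(prods, function(p) if (is.null(p)) NA_integer_ else
      p$mismatches, 0L),
    weight = 0, stringsAsFactors = FALSE)
  tab$weight[has] <- vapply(prods[has], function(p) {
    (1 + model$efficiency * model$mismatch_penalty ^ p$mismatches) ^ model$cycles
  }, 0)
  if (!any(has) || sum(tab$weight) == 0) {
    empty <- seq_set(character(), character())
    empty$meta <- data.frame(template = character())
    attr(empty, "products") <- tab
    return(empty)
  }
  with_seed(derive_seed(seed, "amplicon"), {
    draw <- sample(which(has), n_reads, replace = TRUE,
                   prob = tab$weight[has] / sum(tab$weight[has]))
    seqs <- vapply(prods[draw], `[[`, "", "seq")
    if (long_read) {
      seqs <- inject_errors(seqs, error_rate)
      q <- if (error_rate > 0) min(41L, round(-10 * log10(error_rate))) else 40L
      out <- seq_set(sprintf("%s_ccs%06d", sample_name, seq_along(draw)), seqs,
                     qual = vapply(nchar(seqs), function(n)
                       phred_encode(rep(q, n)), ""),
                     meta = data.frame(template = templates$id[draw],
                                       stringsAsFactors = FALSE))
      attr(out, "products") <- tab
      out
    } else {
      frags <- data.frame(source_id = templates$id[draw],
                          gene_id = templates$id[draw],
                          start = 0L, length = nchar(seqs), strand = "+",
                          seq = seqs, on_target = TRUE, contained = TRUE,
                          is_chimera = FALSE, multiplicity = 1,
                          stringsAsFactors = FALSE)
      out <- sequence_paired(frags, read_len = 300L, error_rate = error_rate,
                             sample_name = sample_name,
                             seed = derive_seed(seed, "amplicon_pairs"))
      attr(out, "products") <- tab
      out
    }
  })
}
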