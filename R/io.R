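#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that normalises
#' sequences to uppercase and returns the package's `seq_set` container.
#' A light pre-scan reports structural problems with the offending line
#' number before handing the file to the parser.
#'
#' @param path path to a FASTA file.
#' @return A `seq_set` (no qualities).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) return(seq_set(character(), character()))
  if (!startsWith(lines[nonempty[1]], ">")) {
    stop("malformed FASTA at line ", nonempty[1], ": expected '>' header")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seq_set(ids, toupper(as.character(set)))
}

#' Write a FASTA file
#'
#' @param records a `seq_set`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (strict 4-line dialect, Phred+33)
#'
#' The reader enforces the strict 4-line record layout and reports the line
#' number of the first malformed record, including sequence/quality length
#' mismatches.
#'
#' @param path path to a FASTQ file.
#' @return A `seq_set` with qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) return(seq_set(character(), character(), qual = character()))
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ record starting at line ",
         4L * (length(lines) %/% 4L) + 1L)
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0) {
    stop("malformed FASTQ at line ", 4L * (bad[1] - 1L) + 1L,
         ": expected '@' header")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0) {
    stop("malformed FASTQ at line ", 4L * (bad[1] - 1L) + 3L,
         ": expected '+' separator")
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad) > 0) {
    stop("malformed FASTQ at line ", 4L * (bad[1] - 1L) + 2L,
         ": sequence and quality lengths differ")
  }
  seq_set(sub("^@", "", sub("\\s.*$", "", hdr)), seqs, qual = qual)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param records a `seq_set` with qualities; records lacking qualities get a
#'   constant Q40 string.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  qual <- records$qual
  if (is.null(qual)) qual <- vapply(nchar(records$seq), function(n)
    phred_encode(rep(40L, n)), "")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(records) > 0) {
    writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual), con)
  }
  invisible(path)
}

# -- deterministic RNG management --------------------------------------------

#' Derive a module-level seed from the global run seed
#'
#' One global seed drives a run; each module draws its own stream from a
#' deterministic hash of the global seed and a stream label, so modules are
#' reproducible independently of evaluation order.
#'
#' @param seed integer global seed.
#' @param stream character label of the consuming module/operation.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state, so simulations do not perturb
#' the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# -- run configuration --------------------------------------------------------

#' Default run configuration
#'
#' All tunable thresholds of every module, named and serialisable to YAML.
#' Values passed via `...` override the defaults (nested lists are merged).
#'
#' @param seed integer global seed.
#' @param ... named overrides, e.g. `probe = list(stride = 25)`.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    refdb = list(exclusion_min_identity = 0.80, exclusion_min_cov = 0.50),
    probe = list(probe_len = 100L, stride = 50L),
    mock = list(vector_len = 2739L, diluent_len = 2786L,
                gene_lengths = c(654L, 702L, 738L, 768L, 792L, 846L),
                pairwise_identity_max = 0.85,
                contaminant_fraction = 9e-4, contaminant_divergence = 0.08),
    capture = list(min_overlap = 100L, min_identity = 0.80,
                   nonspecific_rate = 1e-4, rounds = 1L, seed_len = 12L),
    pcr = list(efficiency = 0.9, mismatch_penalty = 0.5, chimera_rate = 1e-4,
               chimera_k = 12L,
               cycles = list(pre_capture_dna = 9L, pre_capture_cdna = 11L,
                             post_capture = 20L, amplicon_short = 40L,
                             amplicon_long = 35L)),
    sequencing = list(read_len = 300L, error_rate = 1e-3,
                      frag_len_mean = 200, frag_len_sd = 30,
                      size_select_min = 150L),
    qc = list(min_qual = 20L, min_len = 100L, dust_threshold = 7,
              hifi_end_trim = 20L, hifi_len_range = c(400L, 1000L)),
    merge = list(min_overlap = 10L, max_mismatch_rate = 0.25),
    assembly = list(min_overlap = 30L, min_reads = 2L),
    cds = list(min_aa = 100L),
    homology = list(min_identity = 60, min_query_cov = 50, min_subject_cov = 50,
                    nt_len_range = c(400L, 1000L)),
    chimera = list(delta = 1.5, min_segment = 30L,
                   min_parent_identity = 0.9),
    cluster = list(identity = 0.97, coverage = 0.50, discard_singletons = TRUE),
    mapping = list(seed_len = 22L, seed_mismatch = 1L,
                   min_aligned_fraction = 0.9),
    rarefaction = list(min_mapped = 100L),
    taxonomy = list(floor_identity = 75)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to a YAML file
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' Values absent from the file keep their defaults.
#'
#' @param path path to a YAML config.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = if (is.null(raw$seed)) 1L else raw$seed),
                        raw[setdiff(names(raw), "seed")]))
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config (seed ", x$seed, ")\n", sep = "")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Start a run log, echoing the fully resolved configuration
#'
#' @param path log file path.
#' @param config a `run_config`.
#' @return A function `log(...)` appending timestamped lines to the file.
#' @export
open_run_log <- function(path, config) {
  cat("# amoacap run log\n# seed: ", config$seed, "\n", sep = "", file = path)
  cat(paste0("# config: ", yaml::as.yaml(unclass(config))), file = path,
      append = TRUE)
  function(...) {
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", paste0(...), "\n",
        sep = "", file = path, append = TRUE)
  }
}

# All interchange tables are TSV with a commented header naming units.
write_tsv_report <- function(df, path, comment_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cl in comment_lines) cat("# ", cl, "\n", sep = "", file = con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
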