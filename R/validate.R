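# End-to-end validation on the synthetic mock community: build the default
# six-gene mock (plus an optional low-level contaminant), simulate capture
# and non-capture sequencing, run the OTU workflow and report the recovery
# metrics.

#' Combine two read-pair sets
#'
#' @param a,b `read_pairs` objects from the same sample.
#' @return A single `read_pairs`.
#' @export
combine_read_pairs <- function(a, b) {
  structure(list(fwd = concat_seq_sets(a$fwd, b$fwd),
                 rev = concat_seq_sets(a$rev, b$rev),
                 truth = rbind(a$truth, b$truth),
                 sample = a$sample), class = "read_pairs")
}

#' Simulate one sequencing sample from a community
#'
#' Fragmentation, size selection, optional hybridisation capture
#' (`rounds` 0/1/2), post-capture LM-PCR and paired-end sequencing, using
#' the parameter blocks of a [run_config()].
#'
#' @param spec a `community_spec`.
#' @param probeset a `probe_set` (ignored when `rounds = 0`).
#' @param n_pairs read pairs to emit.
#' @param rounds capture rounds (0 = non-capture).
#' @param pcr_cycles post-capture LM-PCR cycles (0 skips PCR).
#' @param n_fragments library complexity before capture (default
#'   `1.2 * n_pairs`).
#' @param sample_name sample label.
#' @param config a `run_config` (sequencing/capture/pcr blocks used).
#' @param seed integer seed.
#' @return A `read_pairs` object.
#' @export
simulate_sample <- function(spec, probeset = NULL, n_pairs = 1e4,
                            rounds = 1L, pcr_cycles = 20L,
                            n_fragments = NULL, sample_name = "sample",
                            config = run_config(), seed = 1L) {
  sq <- config$sequencing
  if (is.null(n_fragments)) n_fragments <- ceiling(1.2 * n_pairs)
  frags <- fragment_community(spec, n_fragments,
                              frag_len_mean = sq$frag_len_mean,
                              frag_len_sd = sq$frag_len_sd,
                              seed = derive_seed(seed, paste0("f_", sample_name)))
  frags <- size_select(frags, min_len = sq$size_select_min)
  if (rounds > 0) {
    cm <- capture_model(min_overlap = config$capture$min_overlap,
                        min_identity = config$capture$min_identity,
                        nonspecific_rate = config$capture$nonspecific_rate,
                        rounds = rounds, seed_len = config$capture$seed_len)
    frags <- simulate_capture(frags, probeset, cm,
                              seed = derive_seed(seed, paste0("c_", sample_name)))
    if (nrow(frags) == 0) stop("capture retained no fragments")
  }
  if (pcr_cycles > 0) {
    pm <- pcr_model(cycles = pcr_cycles, efficiency = config$pcr$efficiency,
                    mismatch_penalty = config$pcr$mismatch_penalty,
                    chimera_rate = config$pcr$chimera_rate,
                    chimera_k = config$pcr$chimera_k)
    frags <- simulate_pcr(frags, pm,
                          seed = derive_seed(seed, paste0("p_", sample_name)))
  }
  sequence_paired(frags, read_len = sq$read_len, error_rate = sq$error_rate,
                  n_pairs = n_pairs, sample_name = sample_name,
                  seed = derive_seed(seed, paste0("s_", sample_name)))
}

#' Run the OTU workflow on a set of sequenced samples
#'
#' Per sample: quality control, pair merging and greedy assembly; then the
#' pooled ("sample concatenating") stages: ORF extraction, CuMMO homology
#' filtering, chimera removal and greedy 97 percent clustering with
#' singleton discard. Per-sample mapped ratios are computed by mapping each
#' sample's QC-merged reads back to the OTUs.
#'
#' @param samples named list of `read_pairs`.
#' @param refdb a `reference_db` (homology subject and taxonomy source).
#' @param config a `run_config`.
#' @return A list: `otus`, `cds`, `per_sample` (data frame of QC, merge,
#'   mapping counts and ratios), `table` (an `otu_table`), `assignments`
#'   (per-sample per-read OTU), `stage_counts`.
#' @export
run_gene_pipeline <- function(samples, refdb, config = run_config()) {
  qc <- config$qc
  contigs <- list()
  merged_sets <- list()
  per_sample <- list()
  for (nm in names(samples)) {
    s <- qc_short_reads(samples[[nm]], min_qual = qc$min_qual,
                        min_len = qc$min_len,
                        dust_threshold = qc$dust_threshold)
    mg <- merge_pairs(s, min_overlap = config$merge$min_overlap,
                      max_mismatch_rate = config$merge$max_mismatch_rate)
    ctg <- assemble_reads(mg$merged,
                          min_overlap = config$assembly$min_overlap,
                          min_reads = config$assembly$min_reads,
                          sample = nm)
    contigs[[nm]] <- ctg
    merged_sets[[nm]] <- mg$merged
    per_sample[[nm]] <- data.frame(
      sample = nm, n_pairs_in = attr(s, "n_input"),
      n_pairs_qc = length(s$fwd), n_merged = length(mg$merged),
      n_contigs = nrow(ctg), stringsAsFactors = FALSE)
  }
  all_ctg <- do.call(rbind, contigs)
  rownames(all_ctg) <- NULL
  cds <- extract_cds(all_ctg, min_aa = config$cds$min_aa)
  hits <- search_cummo(cds, refdb,
                       min_identity = config$homology$min_identity,
                       min_query_cov = config$homology$min_query_cov,
                       min_subject_cov = config$homology$min_subject_cov,
                       nt_len_range = config$homology$nt_len_range)
  chim <- remove_chimeras(hits$nt_seq, hits$abundance,
                          delta = config$chimera$delta,
                          min_segment = config$chimera$min_segment,
                          min_parent_identity = config$chimera$min_parent_identity)
  clean <- hits[chim$kept, , drop = FALSE]
  otus <- cluster_otus(clean$nt_seq, abundance = clean$abundance,
                       ids = clean$id,
                       identity = config$cluster$identity,
                       coverage = config$cluster$coverage,
                       discard_singletons = config$cluster$discard_singletons)
  assignments <- list()
  counts <- NULL
  ps <- do.call(rbind, per_sample)
  ps$n_mapped <- 0L
  ps$mapped_ratio <- 0
  if (nrow(otus) > 0) {
    mp <- mapping_params(seed_len = config$mapping$seed_len,
                         min_aligned_fraction = config$mapping$min_aligned_fraction)
    counts <- matrix(0L, nrow = length(samples), ncol = nrow(otus),
                     dimnames = list(names(samples), otus$otu_id))
    for (i in seq_along(merged_sets)) {
      asn <- map_reads(merged_sets[[i]], otus, mp)
      assignments[[names(merged_sets)[i]]] <- asn
      tab <- table(factor(asn$otu, levels = otus$otu_id))
      counts[i, ] <- as.integer(tab)
      ps$n_mapped[i] <- sum(!is.na(asn$otu))
      ps$mapped_ratio[i] <- mapped_ratio(asn, length(merged_sets[[i]]))
    }
  }
  rownames(ps) <- NULL
  list(otus = otus, cds = hits, per_sample = ps,
       table = if (!is.null(counts) && all(ps$n_merged > 0))
         rpkms(counts, otus$length, pmax(ps$n_merged, 1L)),
       assignments = assignments,
       stage_counts = data.frame(
         stage = c("contigs", "orfs", "homology_pass", "chimera_pass", "otus"),
         n = c(nrow(all_ctg), nrow(cds), nrow(hits), length(chim$kept),
               nrow(otus))))
}

#' End-to-end mock-community validation
#'
#' Builds the default six-gene equimolar mock (three archaeal and three
#' bacterial amoA lineages on a shared 2739 nt vector), designs probes from
#' a synthetic labelled reference collection, simulates four capture samples
#' (one single-capture, three double-capture LM-PCR profiles) and one
#' non-capture sample, spikes a low-level contaminant gene into the capture
#' samples, and runs the full OTU workflow. The headline metrics are the
#' OTU count, the number of OTU representatives that match the inserted
#' gene CDSs exactly, and per-sample mapped ratios.
#'
#' @param seed integer global seed.
#' @param n_pairs read pairs per sample (default 5e4).
#' @param n_capture number of capture samples (default 4).
#' @param contaminant_fraction read fraction of the spiked contaminant in
#'   capture samples (default 9e-4); 0 disables the spike.
#' @param config a `run_config`.
#' @return A list: `genes`, `otus`, `metrics` (n_otus, n_complete_match,
#'   contaminant detection), `per_sample`, `pipeline` (full
#'   [run_gene_pipeline()] output), `taxonomy`.
#' @export
validate_mock <- function(seed = 1L, n_pairs = 5e4, n_capture = 4L,
                          contaminant_fraction = 9e-4,
                          config = run_config(seed)) {
  genes <- generate_gene_family(
    lengths = config$mock$gene_lengths,
    pairwise_identity_max = config$mock$pairwise_identity_max,
    seed = seed)
  fam <- c(rep("amoA-AOA", 3), rep("amoA-AOB", 3))
  clades <- c(names(ecotype_map()), "Nitrosomonas", "Nitrosococcus",
              "comammox-Nitrospira")
  refcol <- make_reference_collection(genes, gene_family = fam,
                                      clade = clades, n_relatives = 3L,
                                      divergence = 0.05, seed = seed)
  db <- curate_refdb(refcol$records, refcol$labels)
  probes <- design_probes(db, probe_len = config$probe$probe_len,
                          stride = config$probe$stride)$probes
  mock <- build_mock(genes, vector_len = config$mock$vector_len,
                     diluent_len = config$mock$diluent_len,
                     dilution_ratio = 0, seed = seed)
  # contaminant: a frame-preserving diverged homologue of gene1 on its own
  # backbone, spiked at read level into the capture samples
  cont <- NULL
  if (contaminant_fraction > 0) {
    cont_gene <- diverge_cds(genes$seq[1], config$mock$contaminant_divergence,
                             seed = derive_seed(seed, "contam"))
    cont_vec <- generate_vector(config$mock$vector_len,
                                seed = derive_seed(seed, "contam_vec"))
    cont <- community_spec(list(plasmid_construct("construct_contam",
                                                  cont_vec, cont_gene,
                                                  gene_id = "contaminant")), 1)
  }
  profiles <- data.frame(
    name = c("single_Mock-cycle20", "double_Mock-cycle5_20",
             "double_Mock-cycle7_14", "double_Mock-cycle7_20"),
    rounds = c(1L, 2L, 2L, 2L),
    cycles = c(20L, 25L, 21L, 27L), stringsAsFactors = FALSE)
  samples <- list()
  for (i in seq_len(n_capture)) {
    pr <- profiles[((i - 1L) %% nrow(profiles)) + 1L, ]
    n_spike <- if (!is.null(cont)) round(n_pairs * contaminant_fraction) else 0L
    rp <- simulate_sample(mock, probes, n_pairs = n_pairs - n_spike,
                          rounds = pr$rounds, pcr_cycles = pr$cycles,
                          sample_name = pr$name, config = config,
                          seed = derive_seed(seed, paste0("cap", i)))
    if (n_spike > 0) {
      cf <- fragment_community(cont, 4000,
                               frag_len_mean = config$sequencing$frag_len_mean,
                               frag_len_sd = config$sequencing$frag_len_sd,
                               seed = derive_seed(seed, paste0("spikef", i)))
      cf <- size_select(cf[cf$on_target, , drop = FALSE],
                        min_len = config$sequencing$size_select_min)
      sp <- sequence_paired(cf, read_len = config$sequencing$read_len,
                            error_rate = config$sequencing$error_rate,
                            n_pairs = n_spike,
                            sample_name = paste0(pr$name, "-spk"),
                            seed = derive_seed(seed, paste0("spike", i)))
      rp <- combine_read_pairs(rp, sp)
    }
    samples[[pr$name]] <- rp
  }
  samples[["non-capture_Mock"]] <- simulate_sample(
    mock, NULL, n_pairs = n_pairs, rounds = 0L, pcr_cycles = 0L,
    sample_name = "non-capture_Mock", config = config,
    seed = derive_seed(seed, "noncap"))
  pipe <- run_gene_pipeline(samples, db, config)
  complete <- pipe$otus$representative %in% genes$seq
  tax <- if (nrow(pipe$otus) > 0)
    assign_ecotype(assign_taxonomy(pipe$otus, db,
                                   floor_identity = config$taxonomy$floor_identity))
  list(genes = genes, otus = pipe$otus,
       metrics = list(n_otus = nrow(pipe$otus),
                      n_complete_match = sum(complete),
                      contaminant_recovered =
                        !is.null(cont) && any(!complete)),
       per_sample = pipe$per_sample, pipeline = pipe, taxonomy = tax,
       refdb = db, probes = probes, mock = mock)
}
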