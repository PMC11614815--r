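## End-to-end orchestration: simulate (or load) -> classify -> quantify ->
## clusters -> signatures, with a run directory of TSV/BED outputs, a
## machine-readable parameter manifest and a log of per-stage
## read-conservation checks. Outputs carry no timestamps, so a rerun with
## the same config and seed is byte-identical.

#' Run the small-RNA analysis pipeline
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Must contain either a `simulation` block (arguments for
#'   [sim_config()]) or an `inputs` block naming `genome` (FASTA),
#'   `alignments` (BED6+2, see [read_alignment_table()]) and `annotations`
#'   (TSV with header `scaffold,start,end,strand,feature_class,family,
#'   name,is_htt`); optional `inputs$rnaseq_counts` (TSV
#'   `feature,count,length_nt`) enables TE RPKM. Optional blocks: `sample`,
#'   `replicate`, `seed`, and `params` with `pirna_range`, `sirna_range`,
#'   `cluster` (see [cluster_params()]) and `signatures`
#'   (`max_overlap`, `max_distance`).
#' @param out_dir Run directory to create (must not pre-exist).
#' @return `out_dir`, invisibly. On stage failure a `FAILED` marker file is
#'   left in the directory and the error is re-thrown.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$simulation) && is.null(cfg$inputs))
    stop("config must contain a 'simulation' or an 'inputs' block")
  if (is.null(cfg$simulation)) {
    need <- c("genome", "alignments", "annotations")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss))
      stop("inputs block missing: ", paste(miss, collapse = ", "))
    gone <- !file.exists(unlist(cfg$inputs[need]))
    if (any(gone))
      stop("input file(s) not found: ",
           paste(unlist(cfg$inputs[need])[gone], collapse = ", "))
  }
  if (dir.exists(out_dir)) stop("output directory already exists: ", out_dir)
  dir.create(out_dir, recursive = TRUE)

  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  ok <- FALSE
  on.exit({
    writeLines(log_lines, file.path(out_dir, "log.txt"))
    if (!ok) file.create(file.path(out_dir, "FAILED"))
  })

  p <- cfg$params
  pirna_range <- as.integer(p$pirna_range %||% c(24L, 32L))
  sirna_range <- as.integer(p$sirna_range %||% c(18L, 23L))
  cp <- do.call(cluster_params, as.list(p$cluster %||% list()))
  max_overlap <- as.integer(p$signatures$max_overlap %||% 30L)
  max_distance <- as.integer(p$signatures$max_distance %||% 50L)
  sample_lab <- cfg$sample %||% "sample"
  replicate <- as.integer(cfg$replicate %||% 1L)

  ## --- stage: simulate or load ---
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
    sc <- do.call(sim_config, sim_args)
    sg <- simulate_genome(sc)
    lib <- simulate_library(sc, sg, sample = sample_lab,
                            replicate = replicate)
    genome <- sg$genome
    reads <- lib$reads
    annotations <- sg$annotations
    mapped_total <- lib$mapped_total
    write_fasta(genome, file.path(out_dir, "genome.fa"))
    write_alignment_table(reads, file.path(out_dir, "reads.bed"))
    data.table::fwrite(annotations, file.path(out_dir, "annotations.tsv"),
                       sep = "\t")
    data.table::fwrite(lib$manifest, file.path(out_dir, "truth_manifest.tsv"),
                       sep = "\t")
    note("simulate: ", mapped_total, " reads, ",
         nrow(reads), " mappings [seed=", sc$seed, "]")
  } else {
    genome <- read_fasta(cfg$inputs$genome)
    reads <- read_alignment_table(cfg$inputs$alignments)
    annotations <- data.table::fread(cfg$inputs$annotations, sep = "\t")
    mapped_total <- length(unique(reads$read_id))
    note("load: ", mapped_total, " reads, ", nrow(reads), " mappings")
  }
  scaffold_sizes <- setNames(nchar(genome), names(genome))

  tryCatch({
    ## --- stage: classify ---
    labels <- classify_reads(reads, annotations, pirna_range, sirna_range,
                             scaffold_sizes)
    cs <- class_summary(reads, annotations, pirna_range, sirna_range)
    data.table::fwrite(cs, file.path(out_dir, "class_summary.tsv"),
                       sep = "\t")
    mass <- sum(reads$weight)
    note(sprintf(
      "classify: total apportioned mass %.6f vs %d distinct reads (%s)",
      mass, mapped_total,
      if (abs(mass - mapped_total) < 1e-6) "conserved" else "MISMATCH"))
    data.table::fwrite(length_histogram(reads, mapped_total),
                       file.path(out_dir, "length_hist_all.tsv"), sep = "\t")
    data.table::fwrite(
      length_histogram(reads, mapped_total, te_only = TRUE,
                       annotations = annotations),
      file.path(out_dir, "length_hist_te.tsv"), sep = "\t")

    pirna <- reads[labels == "piRNA"]
    sirna <- reads[labels == "siRNA_candidate"]
    note("classify: ", nrow(pirna), " piRNA mappings, ",
         nrow(sirna), " siRNA-candidate mappings")

    ## --- stage: quantify ---
    sa <- sense_antisense_counts(pirna, annotations, mapped_total,
                                 unit = "RPM")
    data.table::fwrite(sa, file.path(out_dir, "sense_antisense_rpm.tsv"),
                       sep = "\t")
    sa_cnt <- sense_antisense_counts(pirna, annotations, unit = "count")
    te_mass <- apportioned_counts(pirna, annotations, by = "family")
    te_assigned <- sum(te_mass[group != "unassigned"]$count)
    note(sprintf(
      "quantify: sense+antisense mass %.6f vs TE-assigned %.6f (%s)",
      sum(sa_cnt$sense + sa_cnt$antisense), te_assigned,
      if (abs(sum(sa_cnt$sense + sa_cnt$antisense) - te_assigned) < 1e-6)
        "conserved" else "MISMATCH"))

    ## --- stage: clusters ---
    upirna <- pirna[mapping_count == 1L]
    clusters <- call_clusters(upirna, scaffold_sizes, cp,
                              mapped_total = mapped_total)
    write_bed(clusters, file.path(out_dir, "clusters.bed"))
    data.table::fwrite(clusters, file.path(out_dir, "clusters.tsv"),
                       sep = "\t")
    note("clusters: ", nrow(clusters), " called from ",
         nrow(upirna), " unique piRNA mappings")

    ## --- stage: signatures ---
    pp <- pingpong_histogram(pirna, max_overlap = max_overlap)
    write_signature_tsv(pp, file.path(out_dir, "pingpong.tsv"))
    ph <- phasing_signature(pirna, max_distance = max_distance)
    write_signature_tsv(ph, file.path(out_dir, "phasing.tsv"))
    bias <- if (nrow(pirna)) base_frequency_matrix(pirna) else NULL
    if (!is.null(bias)) {
      bm <- data.table::data.table(position = seq_len(nrow(bias$freqs)))
      for (b in colnames(bias$freqs)) bm[[b]] <- bias$freqs[, b]
      data.table::fwrite(bm, file.path(out_dir, "bias_matrix.tsv"),
                         sep = "\t")
    }
    pf <- paired_fraction(pirna, max_overlap = max_overlap)
    note(sprintf("signatures: z(10)=%.3f Z0=%.3f paired=%.4f",
                 pp$focal, ph$focal, pf))

    ## optional RNA-seq TE expression
    te_rpkm_total <- NA_real_
    if (!is.null(cfg$inputs$rnaseq_counts)) {
      rc <- data.table::fread(cfg$inputs$rnaseq_counts, sep = "\t")
      lib_size <- cfg$inputs$rnaseq_library_size %||% sum(rc$count)
      rc[, value := rpkm(count, length_nt, lib_size)]
      data.table::fwrite(rc[, .(feature, rpkm = value)],
                         file.path(out_dir, "te_rpkm.tsv"), sep = "\t")
      te_rpkm_total <- sum(rc$value)
    }

    ## per-sample summary for cross-sample joins
    top10 <- if (nrow(clusters)) {
      shares <- cumulative_share(clusters)
      shares[min(10L, length(shares))]
    } else NA_real_
    summary <- data.table::data.table(
      sample = sample_lab, replicate = replicate,
      mapped_total = mapped_total,
      pirna_rpm = rpm(sum(pirna$weight), mapped_total),
      sirna_rpm = rpm(sum(sirna$weight), mapped_total),
      n_clusters = nrow(clusters), top10_share = top10,
      pingpong_z10 = pp$focal, phasing_z0 = ph$focal,
      paired_fraction = pf,
      u1_fraction = if (is.null(bias)) NA_real_ else bias$u1_fraction,
      a10_fraction = if (is.null(bias)) NA_real_ else bias$a10_fraction,
      te_rpkm_total = te_rpkm_total)
    sfile <- file.path(out_dir, "summary.tsv")
    writeLines("#units=rpm:RPM;te_rpkm_total:RPKM", sfile)
    data.table::fwrite(summary, sfile, sep = "\t", append = TRUE,
                       col.names = TRUE)

    params_out <- list(sample = sample_lab, replicate = replicate,
                       seed = cfg$seed %||% cfg$simulation$seed %||% NA,
                       pirna_range = pirna_range,
                       sirna_range = sirna_range, cluster = cp,
                       signatures = list(max_overlap = max_overlap,
                                         max_distance = max_distance))
    jsonlite::write_json(params_out, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ok <- TRUE
  }, error = function(e) {
    note("FAILED: ", conditionMessage(e))
    stop(e)
  })
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Join per-sample summaries from completed runs
#'
#' @param run_dirs Character vector of two or more [run_pipeline()] output
#'   directories.
#' @param path Optional path to write the joined TSV.
#' @return `data.table`, one row per run, with the per-sample piRNA RPM,
#'   siRNA RPM, signature statistics and (when available) TE RPKM columns
#'   that support the piRNA-vs-TE anticorrelation readout.
#' @export
compare_samples <- function(run_dirs, path = NULL) {
  if (length(run_dirs) < 2L)
    stop("compare_samples needs at least two completed runs")
  rows <- lapply(run_dirs, function(d) {
    f <- file.path(d, "summary.tsv")
    if (!file.exists(f)) stop("no summary.tsv in ", d, " (incomplete run?)")
    units <- readLines(f, n = 1L)
    dt <- data.table::fread(f, skip = 1L, sep = "\t")
    attr(dt, "units") <- units
    dt
  })
  u <- vapply(rows, attr, character(1), "units")
  if (length(unique(u)) != 1L)
    stop("unit mismatch between runs: ", paste(unique(u), collapse = " vs "))
  out <- data.table::rbindlist(rows)
  if (!is.null(path)) data.table::fwrite(out, path, sep = "\t")
  out[]
}
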