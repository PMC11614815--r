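# construct aligned-read tables for tests
make_reads <- function(scaffold, start, end, strand, read_id = NULL,
                       mapping_count = 1L, sequence = NULL) {
  n <- max(length(scaffold), length(start), length(end), length(strand),
           length(read_id), length(sequence))
  dt <- data.table::data.table(
    scaffold = rep_len(scaffold, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    strand = rep_len(strand, n),
    read_id = if (is.null(read_id)) sprintf("t%04d", seq_len(n))
              else rep_len(read_id, n),
    mapping_count = as.integer(rep_len(mapping_count, n)))
  if (is.null(sequence)) {
    dt$sequence <- vapply(dt$end - dt$start, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  } else dt$sequence <- rep_len(sequence, n)
  dt$weight <- 1 / dt$mapping_count
  dt$length <- dt$end - dt$start
  dt
}

# minimal annotation table
make_ann <- function(scaffold, start, end, strand = "+",
                     feature_class = "TE", family = "Mariner",
                     name = NULL, is_htt = FALSE) {
  n <- max(length(scaffold), length(start), length(end), length(strand),
           length(feature_class), length(family))
  data.table::data.table(
    scaffold = rep_len(scaffold, n), start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)), strand = rep_len(strand, n),
    feature_class = rep_len(feature_class, n),
    family = rep_len(family, n),
    name = if (is.null(name)) sprintf("f%03d", seq_len(n))
           else rep_len(name, n),
    is_htt = rep_len(is_htt, n))
}

# a small, fast simulation configuration used across tests
small_sim_config <- function(seed, ...) {
  args <- list(
    seed = seed,
    genome = c(chr = 100000L),
    clusters = data.frame(scaffold = "chr", start = 20000L, end = 60000L,
                          strand = "+"),
    decoy_regions = data.frame(scaffold = "chr", start = 80000L,
                               end = 90000L, density = 2),
    htt_insertions = data.frame(family = "OC1",
                                scaffold = c("chr", "chr", "chr"),
                                start = c(30000L, 65000L, 70000L),
                                strand = "+"),
    n_reads = 2000L,
    dispersed_per_family = 1L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
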