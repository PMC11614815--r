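## Synthetic small-RNA library generator.
##
## Emulates the statistical structure of an insect small-RNA library:
## a toy genome with uni-strand piRNA clusters stuffed with TE fragments in
## both orientations, dispersed TE copies, low-copy horizontally
## transferred transposon (HTT) insertions, miRNA and contaminant loci;
## and a read library with a bimodal (~22 / ~28 nt) length mixture,
## ping-pong sense/antisense pairs at an exact 5'-5' overlap, phased
## head-to-tail read trails, 1U/10A base biases and multi-mapping reads.
## A ground-truth manifest labels every read for parameter-recovery tests.
##
## Base biases are realized by writing constraints into the genome before
## sequences are extracted, so read sequence == genome slice (reverse
## complemented on the - strand) holds for every uniquely mapped read.
## Constraints are applied first-wins per genomic base; ping-pong
## antisense mates receive no 5' constraint of their own because their
## first base is the complement of the sense mate's 10th (the two biases
## describe the same base pair), and multi-mapped reads carry the shared
## TE-consensus sequence unmodified.

RESIDENT_FAMILIES <- c("Mariner", "Ty3", "RTE-X", "Jockey", "Helitron")
HTT_FAMILIES <- c("SPIN", "hAT", "OC1", "ET")

#' Simulation configuration
#'
#' Defaults describe a scaled-down embryo-like library: two scaffolds
#' totalling 700 kb, three uni-strand clusters, a 22/28 nt length mixture
#' dominated by the 28 nt (piRNA) mode, 30% of 28 nt-mode cluster reads in
#' ping-pong pairs with an exact 10 nt 5'-5' overlap, 30% of the remainder
#' in phased trails, a 0.8 1U and 0.6 10A bias, 70% of TE-derived reads
#' antisense to their element, 15% multi-mappers, and a handful of HTT
#' insertions (OC1 the most numerous) of which some fall inside clusters.
#'
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output. Keep below 2^31 - 10.
#' @param genome Named list/vector of scaffold lengths (nt); each must be
#'   at least twice the cluster-caller window size.
#' @param clusters `data.frame` of planted clusters
#'   (`scaffold,start,end,strand`); must not overlap one another.
#' @param decoy_regions `data.frame` (`scaffold,start,end,density`) of
#'   sub-threshold regions, `density` in reads/kb.
#' @param n_reads Number of reads beyond the decoy reads.
#' @param length_modes List: `means` (two mode centres), `weights`
#'   (mixture weights), `jitter` (probabilities of -1/0/+1 nt around the
#'   centre).
#' @param pingpong_fraction Fraction of 28 nt-mode cluster reads emitted as
#'   sense/antisense pairs.
#' @param pingpong_overlap Exact 5'-5' overlap of the pairs (nt).
#' @param phasing_fraction Fraction of the remaining 28 nt-mode cluster
#'   reads emitted as head-to-tail trails.
#' @param u1_bias Probability that an eligible read's first base is U
#'   (else drawn uniformly from A/C/G, making the parameter identifiable
#'   from the position-1 U frequency).
#' @param a10_bias Probability that a ping-pong sense mate's 10th base is A
#'   (else uniform over C/G/U).
#' @param antisense_fraction Probability that an independent TE-derived
#'   read is antisense to its element.
#' @param multimap_fraction Fraction of independent TE-derived reads
#'   duplicated at 2-4 copies of the same family.
#' @param htt_insertions `data.frame` (`family,scaffold,start,strand`) of
#'   HTT copies, placed exactly as listed.
#' @param te_mix List controlling cluster TE fragments: `frag_per_kb`,
#'   `frag_len` (min,max), `minus_fraction`.
#' @param dispersed_per_family Full-length TE copies planted outside
#'   clusters per resident family (multi-mapping targets).
#' @param mirna_fraction,contaminant_fraction,background_fraction Fractions
#'   of `n_reads` drawn from miRNA loci, contaminant features (rRNA, snRNA,
#'   simple repeat, low complexity) and uniform genomic background.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(scaf1 = 400000L, scaf2 = 300000L),
                       clusters = NULL,
                       decoy_regions = NULL,
                       n_reads = 10000L,
                       length_modes = list(means = c(22L, 28L),
                                           weights = c(0.35, 0.65),
                                           jitter = c(0.2, 0.6, 0.2)),
                       pingpong_fraction = 0.3,
                       pingpong_overlap = 10L,
                       phasing_fraction = 0.3,
                       u1_bias = 0.8,
                       a10_bias = 0.6,
                       antisense_fraction = 0.7,
                       multimap_fraction = 0.15,
                       htt_insertions = NULL,
                       te_mix = list(frag_per_kb = 0.8,
                                     frag_len = c(300L, 800L),
                                     minus_fraction = 0.5),
                       dispersed_per_family = 4L,
                       mirna_fraction = 0.15,
                       contaminant_fraction = 0.05,
                       background_fraction = 0.05) {
  if (is.null(clusters))
    clusters <- data.table::data.table(
      scaffold = c("scaf1", "scaf1", "scaf2"),
      start = c(50000L, 200000L, 100000L),
      end = c(80000L, 220000L, 110000L),
      strand = c("+", "-", "+"))
  else clusters <- data.table::as.data.table(clusters)
  if (is.null(decoy_regions))
    decoy_regions <- data.table::data.table(
      scaffold = c("scaf1", "scaf2"),
      start = c(320000L, 200000L),
      end = c(330000L, 210000L),
      density = c(2, 2))
  else decoy_regions <- data.table::as.data.table(decoy_regions)
  if (is.null(htt_insertions))
    htt_insertions <- data.table::data.table(
      family = c(rep("OC1", 6), "SPIN", "SPIN", rep("hAT", 3), "ET"),
      scaffold = c("scaf1", "scaf1", "scaf1", "scaf2", "scaf2", "scaf1",
                   "scaf1", "scaf2", "scaf1", "scaf1", "scaf2", "scaf2"),
      start = c(55000L, 205000L, 150000L, 50000L, 150000L, 355000L,
                60000L, 160000L, 75000L, 250000L, 220000L, 250000L),
      strand = c("+", "-", "+", "+", "-", "+",
                 "+", "+", "-", "+", "+", "-"))
  else htt_insertions <- data.table::as.data.table(htt_insertions)

  genome <- unlist(genome)
  stopifnot(!is.null(names(genome)), all(genome >= 10000L))
  fr <- c(pingpong_fraction, phasing_fraction, u1_bias, a10_bias,
          antisense_fraction, multimap_fraction, mirna_fraction,
          contaminant_fraction, background_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1))
  # planted clusters must not overlap one another
  cl <- data.table::copy(clusters)[order(scaffold, start)]
  if (nrow(cl) > 1L) {
    same <- cl$scaffold[-1] == cl$scaffold[-nrow(cl)]
    if (any(same & cl$start[-1] < cl$end[-nrow(cl)]))
      stop("config error: overlapping planted clusters")
  }
  unk <- setdiff(c(clusters$scaffold, decoy_regions$scaffold,
                   htt_insertions$scaffold), names(genome))
  if (length(unk)) stop("config references unknown scaffold(s): ",
                        paste(unk, collapse = ", "))
  structure(list(
    seed = as.integer(seed), genome = genome, clusters = clusters,
    decoy_regions = decoy_regions, n_reads = as.integer(n_reads),
    length_modes = length_modes, pingpong_fraction = pingpong_fraction,
    pingpong_overlap = as.integer(pingpong_overlap),
    phasing_fraction = phasing_fraction, u1_bias = u1_bias,
    a10_bias = a10_bias, antisense_fraction = antisense_fraction,
    multimap_fraction = multimap_fraction, htt_insertions = htt_insertions,
    te_mix = te_mix, dispersed_per_family = as.integer(dispersed_per_family),
    mirna_fraction = mirna_fraction,
    contaminant_fraction = contaminant_fraction,
    background_fraction = background_fraction), class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

## place n non-overlapping intervals of the given lengths uniformly inside
## [lo, hi), avoiding `avoid` (data.table scaffold/start/end rows already on
## this scaffold); gives up on an interval after 50 tries
place_nonoverlapping <- function(n, lens, lo, hi, taken_s = integer(0),
                                 taken_e = integer(0)) {
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(n)) {
    L <- lens[i]
    if (hi - lo < L) next
    for (try in 1:50) {
      s <- lo + sample.int(hi - lo - L + 1L, 1L) - 1L
      e <- s + L
      if (!any(s < c(taken_e, out_e) & e > c(taken_s, out_s))) {
        out_s <- c(out_s, s); out_e <- c(out_e, e)
        break
      }
    }
  }
  list(start = out_s, end = out_e)
}

#' Simulate a toy genome with planted annotations
#'
#' Builds random scaffold sequences, stamps a per-family consensus sequence
#' into every TE copy (cluster fragments, dispersed copies and HTT
#' insertions, reverse complemented on `-` copies, so all copies of a
#' family are identical at shared consensus positions), and places miRNA
#' and contaminant loci outside the clusters.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (named character vector), `annotations`
#'   (feature `data.table`), `te_copies` (copies with consensus offsets),
#'   `consensus` (named character vector), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cons_len <- c(setNames(rep(1200L, length(RESIDENT_FAMILIES)),
                         RESIDENT_FAMILIES),
                setNames(rep(800L, length(HTT_FAMILIES)), HTT_FAMILIES))
  consensus <- vapply(cons_len, rand_dna, character(1))

  genome <- lapply(config$genome, function(n)
    sample(c("A", "C", "G", "T"), n, replace = TRUE))

  copies <- list()
  stamp <- function(scaffold, s, fam, str, cons_start, L) {
    seq_ <- substr(consensus[[fam]], cons_start + 1L, cons_start + L)
    if (str == "-") seq_ <- revcomp(seq_)
    genome[[scaffold]][(s + 1L):(s + L)] <<- strsplit(seq_, "")[[1]]
  }

  # cluster TE fragments
  cl <- config$clusters
  for (i in seq_len(nrow(cl))) {
    len_kb <- (cl$end[i] - cl$start[i]) / 1000
    nf <- max(4L, round(config$te_mix$frag_per_kb * len_kb))
    lens <- sample(config$te_mix$frag_len[1]:config$te_mix$frag_len[2], nf,
                   replace = TRUE)
    pl <- place_nonoverlapping(nf, lens, cl$start[i], cl$end[i])
    nfp <- length(pl$start)
    fams <- sample(RESIDENT_FAMILIES, nfp, replace = TRUE)
    strs <- ifelse(runif(nfp) < config$te_mix$minus_fraction, "-", "+")
    for (j in seq_len(nfp)) {
      L <- pl$end[j] - pl$start[j]
      cs <- sample.int(cons_len[[fams[j]]] - L + 1L, 1L) - 1L
      stamp(cl$scaffold[i], pl$start[j], fams[j], strs[j], cs, L)
      copies[[length(copies) + 1L]] <- data.table::data.table(
        scaffold = cl$scaffold[i], start = pl$start[j], end = pl$end[j],
        strand = strs[j], family = fams[j], cons_start = cs,
        is_htt = FALSE, in_cluster = TRUE)
    }
  }

  # dispersed full-length resident copies outside clusters/decoys
  for (sc in names(config$genome)) {
    avoid <- rbind(
      config$clusters[scaffold == sc, .(start, end)],
      config$decoy_regions[scaffold == sc, .(start, end)])
    n_disp <- config$dispersed_per_family * length(RESIDENT_FAMILIES)
    lens <- rep(1200L, n_disp)
    pl <- place_nonoverlapping(n_disp, lens, 0L, config$genome[[sc]],
                               avoid$start, avoid$end)
    fams <- rep(RESIDENT_FAMILIES, length.out = length(pl$start))
    strs <- sample(c("+", "-"), length(pl$start), replace = TRUE)
    for (j in seq_along(pl$start)) {
      stamp(sc, pl$start[j], fams[j], strs[j], 0L, 1200L)
      copies[[length(copies) + 1L]] <- data.table::data.table(
        scaffold = sc, start = pl$start[j], end = pl$end[j],
        strand = strs[j], family = fams[j], cons_start = 0L,
        is_htt = FALSE, in_cluster = FALSE)
    }
  }

  # HTT insertions exactly as listed
  htt <- config$htt_insertions
  for (i in seq_len(nrow(htt))) {
    L <- 800L
    if (htt$start[i] + L > config$genome[[htt$scaffold[i]]])
      stop("HTT insertion beyond scaffold end: row ", i)
    stamp(htt$scaffold[i], htt$start[i], htt$family[i], htt$strand[i], 0L, L)
    copies[[length(copies) + 1L]] <- data.table::data.table(
      scaffold = htt$scaffold[i], start = htt$start[i],
      end = htt$start[i] + L, strand = htt$strand[i],
      family = htt$family[i], cons_start = 0L, is_htt = TRUE,
      in_cluster = FALSE)
  }

  te_copies <- data.table::rbindlist(copies)
  te_copies[, copy_id := paste0(family, "_c", seq_len(.N)), by = family]

  # miRNA and contaminant loci outside clusters, on the first scaffold
  sc1 <- names(config$genome)[1]
  avoid <- rbind(config$clusters[scaffold == sc1, .(start, end)],
                 config$decoy_regions[scaffold == sc1, .(start, end)],
                 te_copies[scaffold == sc1, .(start, end)])
  other_class <- c(rep("miRNA", 5), "rRNA", "snRNA", "simple_repeat",
                   "low_complexity")
  other_len <- c(rep(22L, 5), 2000L, 150L, 500L, 500L)
  pl <- place_nonoverlapping(length(other_len), other_len, 0L,
                             config$genome[[sc1]], avoid$start, avoid$end)
  others <- data.table::data.table(
    scaffold = sc1, start = pl$start, end = pl$end,
    strand = sample(c("+", "-"), length(pl$start), replace = TRUE),
    feature_class = other_class[seq_along(pl$start)],
    family = NA_character_, is_htt = FALSE)
  others[, name := paste0(feature_class, "_", seq_len(.N)),
         by = feature_class]

  annotations <- rbind(
    te_copies[, .(scaffold, start, end, strand, feature_class = "TE",
                  family, name = copy_id, is_htt)],
    others[, .(scaffold, start, end, strand, feature_class, family, name,
               is_htt)])

  list(genome = vapply(genome, paste, character(1), collapse = ""),
       annotations = annotations, te_copies = te_copies,
       consensus = consensus, config = config)
}
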