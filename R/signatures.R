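## Ping-pong, phasing and nucleotide-bias signature statistics.
##
## Conventions (0-based half-open genome coordinates):
##   * 5' end of a + strand read = start; of a - strand read = end - 1;
##   * 5'-5' overlap between a + read and a - read:
##       k = (minus_5p - plus_5p) + 1,
##     counted when both reads cover the shared register
##     (k <= both read lengths) and 1 <= k <= max_overlap;
##   * phasing distance between same-strand reads, measured in the
##     direction of transcription: d = 5'(downstream) - 3'(upstream) with
##     half-open ends, so immediately adjacent (head-to-tail) reads give
##     d = 0;
##   * pair counts are weighted by the product of the two mappings'
##     apportioned weights.
##
## The z-score of an offset is computed against a leave-one-out background:
## z(k) = (counts[k] - mean(counts[-k])) / sd(counts[-k]); a zero-SD
## background yields z = 0 with a `degenerate` flag.

new_signature_result <- function(offsets, counts, focal_offset) {
  z <- zscore_loo(counts)
  structure(
    list(offsets = offsets, counts = counts, zscores = z$z,
         focal = z$z[match(focal_offset, offsets)],
         focal_offset = focal_offset, degenerate = z$degenerate),
    class = "signature_result")
}

zscore_loo <- function(counts) {
  n <- length(counts)
  z <- numeric(n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    bg <- counts[-i]
    s <- sd(bg)
    if (!is.finite(s) || s == 0) {
      z[i] <- 0
      degenerate <- TRUE
    } else {
      z[i] <- (counts[i] - mean(bg)) / s
    }
  }
  list(z = z, degenerate = degenerate)
}

#' @export
print.signature_result <- function(x, ...) {
  cat("signature_result: focal offset", x$focal_offset,
      "z =", format(x$focal, digits = 4),
      if (x$degenerate) "(degenerate background)" else "", "\n")
  invisible(x)
}

## shared 5'-5' overlap pair counter between a plus-strand and a
## minus-strand read table; returns counts for k in 1..max_overlap
count_5p_overlaps <- function(plus, minus, max_overlap) {
  counts <- numeric(max_overlap)
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(counts)
  P <- data.table::data.table(scaffold = plus$scaffold,
                              p5 = five_prime(plus),
                              plen = plus$end - plus$start,
                              wp = plus$weight)
  M <- data.table::data.table(scaffold = minus$scaffold,
                              m5 = five_prime(minus),
                              mlen = minus$end - minus$start,
                              wm = minus$weight)
  for (k in seq_len(max_overlap)) {
    Pk <- P[plen >= k][, .(wp = sum(wp)), by = .(scaffold, p5)]
    Mk <- M[mlen >= k][, .(wm = sum(wm)), by = .(scaffold, p5 = m5 - (k - 1L))]
    j <- merge(Pk, Mk, by = c("scaffold", "p5"))
    if (nrow(j)) counts[k] <- sum(j$wp * j$wm)
  }
  counts
}

#' Ping-pong 5'-5' overlap histogram
#'
#' For every pair of opposite-strand mappings on the same scaffold whose
#' 5' ends overlap by `k` nucleotides, `counts[k]` gains the product of the
#' two apportioned weights. The hallmark of an active ping-pong cycle is a
#' z-score peak at `k = 10`.
#'
#' @param sense_reads,antisense_reads Aligned-read `data.table`s; pairs are
#'   formed between the two sets (opposite genomic strands only). Pass the
#'   sense and antisense subsets of a piRNA population, or a single set as
#'   `sense_reads` (with `antisense_reads = NULL`) to pair its + and -
#'   strand reads.
#' @param max_overlap Largest overlap length tallied (default 30).
#' @param focal_offset Offset whose z-score is the statistic of interest
#'   (default 10).
#' @return A `signature_result`: `offsets` 1..max_overlap, `counts`,
#'   `zscores`, `focal` = z(focal_offset), `degenerate` flag.
#' @export
pingpong_histogram <- function(sense_reads, antisense_reads = NULL,
                               max_overlap = 30L, focal_offset = 10L) {
  if (max_overlap < 1L) stop("max_overlap must be >= 1")
  counts <- if (is.null(antisense_reads)) {
    count_5p_overlaps(sense_reads[strand == "+"],
                      sense_reads[strand == "-"], max_overlap)
  } else {
    count_5p_overlaps(sense_reads[strand == "+"],
                      antisense_reads[strand == "-"], max_overlap) +
      count_5p_overlaps(antisense_reads[strand == "+"],
                        sense_reads[strand == "-"], max_overlap)
  }
  new_signature_result(seq_len(max_overlap), counts, focal_offset)
}

#' Fraction of piRNAs engaged in a 5'-5' overlapping pair
#'
#' A read is "paired" when at least one opposite-strand read 5'-overlaps
#' one of its mappings by any k in `[1, max_overlap]`.
#'
#' @param reads Aligned-read `data.table`.
#' @param max_overlap Largest overlap length considered (default 30).
#' @return Fraction of distinct read ids that are paired, or `NA` for an
#'   empty input.
#' @export
paired_fraction <- function(reads, max_overlap = 30L) {
  if (nrow(reads) == 0L) return(NA_real_)
  P <- reads[strand == "+",
             .(scaffold, p5 = start, plen = end - start, read_id)]
  M <- reads[strand == "-",
             .(scaffold, m5 = end - 1L, mlen = end - start, read_id)]
  paired <- character(0)
  for (k in seq_len(max_overlap)) {
    j <- merge(P[plen >= k], M[mlen >= k][, .(scaffold, p5 = m5 - (k - 1L),
                                              read_id)],
               by = c("scaffold", "p5"), allow.cartesian = TRUE)
    if (nrow(j)) paired <- unique(c(paired, j$read_id.x, j$read_id.y))
  }
  length(intersect(paired, unique(reads$read_id))) /
    length(unique(reads$read_id))
}

#' Phasing signature: 3'-to-5' distances between same-strand reads
#'
#' For ordered same-strand pairs on a scaffold, the distance in the
#' direction of transcription from the upstream read's 3' end to the
#' downstream read's 5' end (half-open, so head-to-tail adjacency gives
#' d = 0) is tallied for d in `[0, max_distance]`. Phased primary piRNA
#' production shows up as a z-score peak at d = 0 (the Z0 statistic).
#'
#' @param reads Aligned-read `data.table`.
#' @param max_distance Largest distance tallied (default 50).
#' @return A `signature_result` with `offsets` 0..max_distance and
#'   `focal` = Z0 = z(0).
#' @export
phasing_signature <- function(reads, max_distance = 50L) {
  counts <- numeric(max_distance + 1L)
  plus <- reads[strand == "+"]
  minus <- reads[strand == "-"]
  for (d in 0:max_distance) {
    # + strand: downstream.start == upstream.end + d
    if (nrow(plus)) {
      A <- plus[, .(w = sum(weight)), by = .(scaffold, pos = end + d)]
      B <- plus[, .(w = sum(weight)), by = .(scaffold, pos = start)]
      j <- merge(A, B, by = c("scaffold", "pos"))
      if (nrow(j)) counts[d + 1L] <- counts[d + 1L] + sum(j$w.x * j$w.y)
    }
    # - strand: upstream (rightmost) read.start == downstream.end + d
    if (nrow(minus)) {
      A <- minus[, .(w = sum(weight)), by = .(scaffold, pos = end + d)]
      B <- minus[, .(w = sum(weight)), by = .(scaffold, pos = start)]
      j <- merge(A, B, by = c("scaffold", "pos"))
      if (nrow(j)) counts[d + 1L] <- counts[d + 1L] + sum(j$w.x * j$w.y)
    }
  }
  new_signature_result(0:max_distance, counts, 0L)
}

#' Per-position nucleotide frequency matrix
#'
#' Frequencies are computed position by position over the reads long enough
#' to reach that position, weighting each mapping by its apportioned
#' weight; T is read as U. The two biological biases of interest are
#' returned directly: `u1_fraction` (U at position 1, the primary/antisense
#' piRNA hallmark) and `a10_fraction` (A at position 10, the secondary
#' piRNA hallmark).
#'
#' @param reads Aligned-read `data.table` carrying sequences (cDNA sense of
#'   the read, 5' to 3').
#' @param L Number of positions (default 30).
#' @return List of class `base_freq_matrix`: `freqs` (L x 4 matrix, columns
#'   A,C,G,U; rows sum to 1 where data exist), `n_reads`, `u1_fraction`,
#'   `a10_fraction`.
#' @export
base_frequency_matrix <- function(reads, L = 30L) {
  if (nrow(reads) == 0L) stop("no reads: base frequencies undefined")
  bases <- c("A", "C", "G", "U")
  freqs <- matrix(NA_real_, nrow = L, ncol = 4,
                  dimnames = list(NULL, bases))
  seqs <- chartr("T", "U", reads$sequence)
  lens <- nchar(seqs)
  w <- reads$weight
  for (p in seq_len(L)) {
    sel <- lens >= p
    if (!any(sel)) next
    b <- substr(seqs[sel], p, p)
    wt <- w[sel]
    tot <- sum(wt)
    for (nt in bases) freqs[p, nt] <- sum(wt[b == nt]) / tot
  }
  structure(
    list(freqs = freqs, n_reads = length(unique(reads$read_id)),
         u1_fraction = unname(freqs[1, "U"]),
         a10_fraction = if (L >= 10) unname(freqs[10, "A"]) else NA_real_),
    class = "base_freq_matrix")
}

#' @export
print.base_freq_matrix <- function(x, ...) {
  cat("base_freq_matrix:", x$n_reads, "reads,",
      nrow(x$freqs), "positions; 1U =",
      format(x$u1_fraction, digits = 3),
      ", 10A =", format(x$a10_fraction, digits = 3), "\n")
  invisible(x)
}
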