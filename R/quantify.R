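## Strand-aware sense/antisense quantification and normalization.

#' Sense/antisense apportioned counts per TE group
#'
#' A read mapping contributes its apportioned weight (split across the TE
#' records it overlaps) to the sense tally of a group when read strand
#' equals the TE record strand, otherwise to the antisense tally. The sum
#' of sense and antisense mass equals the total TE-assigned apportioned
#' mass (conservation under the strand split).
#'
#' @param reads Aligned-read `data.table`.
#' @param te_annotations Strand-bearing TE annotation `data.table`;
#'   an unstranded record raises an error naming it.
#' @param mapped_total RPM denominator; required for units other than count.
#' @param unit `"count"`, `"RPM"` or `"log10RPM1"`.
#' @param by TE grouping key (default `"family"`).
#' @return `data.table` with columns `group, sense, antisense` in the
#'   requested unit, plus attribute `unit`.
#' @export
sense_antisense_counts <- function(reads, te_annotations, mapped_total = NULL,
                                   unit = c("count", "RPM", "log10RPM1"),
                                   by = "family") {
  unit <- match.arg(unit)
  te <- te_annotations[feature_class == "TE"]
  bad <- which(!(te$strand %in% c("+", "-")))
  if (length(bad))
    stop("unstranded TE record(s): ",
         paste(head(te$name[bad], 5), collapse = ", "))
  empty <- data.table::data.table(group = character(), sense = numeric(),
                                  antisense = numeric())
  if (nrow(reads) == 0L || nrow(te) == 0L) {
    attr(empty, "unit") <- unit
    return(empty)
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges0(reads, use_strand = FALSE),
    as_granges0(te, use_strand = FALSE), ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n_feat <- tabulate(qh, nbins = nrow(reads))
  contrib <- data.table::data.table(
    group = te[[by]][sh],
    sense = reads$strand[qh] == te$strand[sh],
    w = reads$weight[qh] / n_feat[qh]
  )
  res <- contrib[, .(sense = sum(w[sense]), antisense = sum(w[!sense])),
                 by = group]
  if (unit != "count") {
    stopifnot(!is.null(mapped_total))
    res[, `:=`(sense = rpm(sense, mapped_total),
               antisense = rpm(antisense, mapped_total))]
    if (unit == "log10RPM1")
      res[, `:=`(sense = log10_rpm1(sense), antisense = log10_rpm1(antisense))]
  }
  data.table::setorder(res, -sense)
  attr(res, "unit") <- unit
  res[]
}

#' Project genomic read mappings into TE-consensus coordinates
#'
#' Maps each read mapping that falls inside a TE copy onto the copy's
#' consensus coordinate system, through the insertion's orientation: on a
#' `-` strand copy the consensus runs antiparallel to the genome, so
#' genomic coordinates are mirrored and read strand is flipped. A read is
#' "sense" in consensus space when its projected strand is `+`.
#'
#' @param reads Aligned-read `data.table`.
#' @param te_copies `data.table` of TE copies with columns
#'   `scaffold,start,end,strand,cons_start` (`cons_start` = consensus
#'   offset of the copy's consensus-5' edge, 0-based).
#' @return `data.table` with columns `start,end,strand,weight` in consensus
#'   coordinates (0-based half-open), one row per (mapping, copy) pair with
#'   the mapping fully inside the copy.
#' @export
project_to_consensus <- function(reads, te_copies) {
  out <- data.table::data.table(start = integer(), end = integer(),
                                strand = character(), weight = numeric())
  if (nrow(reads) == 0L || nrow(te_copies) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(
    as_granges0(reads, use_strand = FALSE),
    as_granges0(te_copies, use_strand = FALSE),
    type = "within", ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh) == 0L) return(out)
  cs <- te_copies$cons_start[sh]
  plus <- te_copies$strand[sh] == "+"
  rs <- reads$start[qh]; re <- reads$end[qh]
  ts <- te_copies$start[sh]; te_ <- te_copies$end[sh]
  data.table::data.table(
    start  = ifelse(plus, cs + (rs - ts), cs + (te_ - re)),
    end    = ifelse(plus, cs + (re - ts), cs + (te_ - rs)),
    strand = ifelse(plus == (reads$strand[qh] == "+"), "+", "-"),
    weight = reads$weight[qh]
  )
}

#' Signed per-position coverage along a TE consensus
#'
#' Position `p` receives the summed apportioned weight (as RPM) of sense
#' reads covering it, and minus that of antisense reads, the conventional
#' signed coverage display for sense/antisense piRNA profiles.
#'
#' @param cons_reads Reads in consensus coordinates
#'   (`start,end,strand,weight`), e.g. from [project_to_consensus()].
#' @param consensus_length Length of the consensus in nt.
#' @param mapped_total RPM denominator.
#' @return `data.table` with columns `position` (0-based),
#'   `sense_rpm`, `antisense_rpm` (antisense values are <= 0), one row per
#'   consensus position.
#' @export
consensus_profile <- function(cons_reads, consensus_length, mapped_total) {
  stopifnot(consensus_length >= 1L)
  if (nrow(cons_reads) > 0L &&
      (min(cons_reads$start) < 0L || max(cons_reads$end) > consensus_length))
    stop("read outside [0, consensus_length)")
  cover <- function(dt) {
    d <- numeric(consensus_length + 1L)
    if (nrow(dt)) {
      # difference-array accumulation of weighted coverage
      for (i in seq_len(nrow(dt))) {
        d[dt$start[i] + 1L] <- d[dt$start[i] + 1L] + dt$weight[i]
        d[dt$end[i] + 1L] <- d[dt$end[i] + 1L] - dt$weight[i]
      }
    }
    cumsum(d)[seq_len(consensus_length)]
  }
  s <- cover(cons_reads[strand == "+"])
  a <- cover(cons_reads[strand == "-"])
  data.table::data.table(
    position = 0:(consensus_length - 1L),
    sense_rpm = rpm(s, mapped_total),
    antisense_rpm = -rpm(a, mapped_total)
  )
}

#' Reads per kilobase per million (RPKM)
#'
#' @param count Raw or apportioned read count.
#' @param feature_length_nt Feature length in nucleotides (> 0).
#' @param mapped_total Library size (> 0).
#' @return `count / ((feature_length_nt/1e3) * (mapped_total/1e6))`.
#' @export
rpkm <- function(count, feature_length_nt, mapped_total) {
  if (any(feature_length_nt <= 0)) stop("feature_length_nt must be > 0")
  if (any(mapped_total <= 0)) stop("mapped_total must be > 0")
  count / ((feature_length_nt / 1e3) * (mapped_total / 1e6))
}

#' qPCR fold change from a delta-Ct value
#'
#' @param delta_ct Delta-Ct (cycles).
#' @return `2^(-delta_ct)`.
#' @export
fold_change_ddct <- function(delta_ct) 2^(-delta_ct)

#' log10(RPM + 1) transform
#'
#' Monotone and invertible on non-negative RPM values (inverse
#' `10^x - 1`), the standard compression for expression heat maps.
#'
#' @param x RPM values.
#' @export
log10_rpm1 <- function(x) log10(x + 1)
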