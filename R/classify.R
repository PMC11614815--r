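## Read classification and apportioned counting.
##
## A genome-mapped small RNA is classified by length and by annotation
## overlap: any overlap with a contaminant/structural class (miRNA, rRNA,
## snRNA, simple repeat, low complexity) excludes it from the piRNA set;
## otherwise TE-overlapping reads of 24-32 nt are piRNAs and TE-overlapping
## reads of 18-23 nt are siRNA candidates. Multi-mapping reads are counted
## fractionally: each mapping carries weight 1/mapping_count, further split
## across the features it overlaps.

# exclusion precedence when a read touches several contaminant classes
EXCLUDED_CLASSES <- c("miRNA", "rRNA", "snRNA", "simple_repeat",
                      "low_complexity")

#' Filter reads by length
#'
#' @param reads Aligned-read `data.table`.
#' @param min_nt,max_nt Inclusive length bounds in nucleotides.
#' @return The subset of rows with `min_nt <= length <= max_nt`, input
#'   order preserved.
#' @export
filter_by_length <- function(reads, min_nt, max_nt) {
  stopifnot(min_nt <= max_nt)
  len <- reads$end - reads$start
  reads[len >= min_nt & len <= max_nt]
}

#' Classify reads into small-RNA classes
#'
#' Applies the exclusion-first rule: a mapping overlapping any of miRNA,
#' rRNA, snRNA, simple repeat or low complexity annotation is labelled with
#' that class (precedence in that order) and never counted as piRNA.
#' Otherwise, TE-overlapping reads within `pirna_range` are `piRNA`, those
#' within `sirna_range` are `siRNA_candidate`, and everything else (or reads
#' overlapping no annotation) is `unassigned`. Overlap is any shared base
#' and strand-blind; strand only matters downstream in sense/antisense
#' quantification.
#'
#' @param reads Aligned-read `data.table` (one row per mapping).
#' @param annotations Feature annotation `data.table` with columns
#'   `scaffold,start,end,strand,feature_class` (and `family,name,is_htt`
#'   for TEs).
#' @param pirna_range,sirna_range Inclusive nt length windows, defaults
#'   24-32 and 18-23.
#' @param scaffold_sizes Optional named vector of scaffold lengths; when
#'   given, reads on unknown scaffolds raise an error.
#' @return Character vector of labels, one per mapping row.
#' @export
classify_reads <- function(reads, annotations,
                           pirna_range = c(24L, 32L),
                           sirna_range = c(18L, 23L),
                           scaffold_sizes = NULL) {
  if (!is.null(scaffold_sizes)) {
    unk <- setdiff(unique(reads$scaffold), names(scaffold_sizes))
    if (length(unk))
      stop("reads on unknown scaffold(s): ", paste(unk, collapse = ", "))
  }
  n <- nrow(reads)
  label <- rep("unassigned", n)
  if (n == 0L) return(character(0))
  gr_reads <- as_granges0(reads, use_strand = FALSE)
  gr_ann <- as_granges0(annotations, use_strand = FALSE)
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_ann, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  cls <- annotations$feature_class[S4Vectors::subjectHits(hits)]

  # excluded classes win, in fixed precedence order
  for (ex in rev(EXCLUDED_CLASSES)) {          # reverse so miRNA applied last
    label[unique(qh[cls == ex])] <- ex
  }
  excluded <- label != "unassigned"

  te_hit <- rep(FALSE, n)
  te_hit[unique(qh[cls == "TE"])] <- TRUE
  len <- reads$end - reads$start
  is_pi <- !excluded & te_hit & len >= pirna_range[1] & len <= pirna_range[2]
  is_si <- !excluded & te_hit & len >= sirna_range[1] & len <= sirna_range[2]
  label[is_si] <- "siRNA_candidate"
  label[is_pi] <- "piRNA"
  label
}

#' Apportioned feature counts
#'
#' Fractional counting of multi-mapping, multi-feature reads: every mapping
#' contributes `weight / n`, where `weight = 1/mapping_count` and `n` is the
#' number of annotation records the mapping overlaps. Mappings overlapping
#' nothing accumulate under `"unassigned"`. Total apportioned mass over all
#' groups (unassigned included) equals the number of distinct read ids.
#'
#' @param reads Aligned-read `data.table`.
#' @param annotations Feature annotation `data.table`.
#' @param by Grouping key of the annotation: `"name"`, `"family"` or
#'   `"feature_class"`.
#' @return `data.table` with columns `group, count`, sorted by decreasing
#'   count.
#' @export
apportioned_counts <- function(reads, annotations,
                               by = c("name", "family", "feature_class")) {
  by <- match.arg(by)
  out <- data.table::data.table(group = character(), count = numeric())
  if (nrow(reads) == 0L) return(out)
  gr_reads <- as_granges0(reads, use_strand = FALSE)
  gr_ann <- as_granges0(annotations, use_strand = FALSE)
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_ann, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n_feat <- tabulate(qh, nbins = nrow(reads))
  contrib <- data.table::data.table(
    group = annotations[[by]][sh],
    w = reads$weight[qh] / n_feat[qh]
  )
  un <- sum(reads$weight[n_feat == 0L])
  res <- contrib[, .(count = sum(w)), by = group]
  if (un > 0)
    res <- rbind(res, data.table::data.table(group = "unassigned", count = un))
  data.table::setorder(res, -count)
  res[]
}

#' Reads-per-million normalization
#'
#' @param count Raw or apportioned read count.
#' @param mapped_total Number of distinct genome-mapped reads in the library.
#' @return `count * 1e6 / mapped_total`.
#' @export
rpm <- function(count, mapped_total) {
  if (any(mapped_total <= 0)) stop("mapped_total must be > 0")
  count * 1e6 / mapped_total
}

#' Apportioned read-length histogram in RPM
#'
#' Each mapping contributes its fractional weight to its length bin, so a
#' read counted once however many places it maps. Optionally restricted to
#' TE-overlapping mappings (the transposon-associated size profile).
#'
#' @param reads Aligned-read `data.table`.
#' @param mapped_total RPM denominator (distinct mapped reads).
#' @param te_only If `TRUE`, keep only mappings overlapping a TE record.
#' @param annotations Required when `te_only = TRUE`.
#' @return `data.table` with columns `length, rpm`, sorted by length.
#' @export
length_histogram <- function(reads, mapped_total, te_only = FALSE,
                             annotations = NULL) {
  if (nrow(reads) == 0L)
    return(data.table::data.table(length = integer(), rpm = numeric()))
  if (te_only) {
    stopifnot(!is.null(annotations))
    te <- annotations[feature_class == "TE"]
    hits <- GenomicRanges::findOverlaps(
      as_granges0(reads, use_strand = FALSE),
      as_granges0(te, use_strand = FALSE), ignore.strand = TRUE)
    reads <- reads[unique(S4Vectors::queryHits(hits))]
    if (nrow(reads) == 0L)
      return(data.table::data.table(length = integer(), rpm = numeric()))
  }
  h <- reads[, .(count = sum(weight)), by = .(length = end - start)]
  h[, rpm := rpm(count, mapped_total)]
  data.table::setorder(h, length)
  h[, .(length, rpm)]
}

#' Per-class library summary
#'
#' Apportioned read counts and percentages per small-RNA class.
#'
#' @inheritParams classify_reads
#' @return `data.table` with columns `class, count, percent`.
#' @export
class_summary <- function(reads, annotations,
                          pirna_range = c(24L, 32L),
                          sirna_range = c(18L, 23L)) {
  lab <- classify_reads(reads, annotations, pirna_range, sirna_range)
  dt <- data.table::data.table(label = lab, w = reads$weight)
  res <- dt[, .(count = sum(w)), by = .(class = label)]
  res[, percent := 100 * count / sum(count)]
  data.table::setorder(res, -count)
  res[]
}
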