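## Sliding-window piRNA cluster discovery and cluster descriptors.
##
## Clusters are called from uniquely mapping piRNA-class reads: 5 kb
## windows sliding by 1 kb are retained when read density (5' ends per kb)
## strictly exceeds 5 and at least 12% of the window's bases are covered by
## read intervals; overlapping retained windows are unioned and unions
## closer than 20 kb are combined. Clusters are ranked by read support and
## named RPCL1, RPCL2, ... Comparison semantics track the defining wording
## exactly: density ">", coverage ">=", merge distance "<".

#' Cluster-caller parameters
#'
#' @param window_size Sliding window size in nt (default 5000).
#' @param step Window step in nt (default 1000).
#' @param min_density Minimum read density, reads per kb, strict `>`
#'   (default 5).
#' @param min_cov_frac Minimum covered fraction of window bases, `>=`
#'   (default 0.12).
#' @param merge_gap Merge unions separated by less than this many nt,
#'   strict `<` (default 20000).
#' @param strand_bias_threshold A cluster is strand-biased when at least
#'   this fraction of its reads sits on one strand (default 0.75).
#' @param unique_only Restrict the caller to uniquely mapping reads
#'   (default `TRUE`).
#' @return A list of validated parameters.
#' @export
cluster_params <- function(window_size = 5000L, step = 1000L,
                           min_density = 5, min_cov_frac = 0.12,
                           merge_gap = 20000L,
                           strand_bias_threshold = 0.75,
                           unique_only = TRUE) {
  stopifnot(step <= window_size, step >= 1L,
            min_cov_frac > 0, min_cov_frac <= 1,
            strand_bias_threshold > 0.5, strand_bias_threshold <= 1)
  list(window_size = as.integer(window_size), step = as.integer(step),
       min_density = min_density, min_cov_frac = min_cov_frac,
       merge_gap = as.integer(merge_gap),
       strand_bias_threshold = strand_bias_threshold,
       unique_only = unique_only)
}

#' Call piRNA clusters by sliding-window density
#'
#' A read belongs to a window by its 5'-end position; window coverage
#' counts bases covered by full read intervals. Windows are clipped at
#' scaffold ends and a terminal partial window uses its actual size in
#' both criteria. The output is deterministic and independent of read
#' input order; ties in support are broken by genomic position.
#'
#' @param unique_reads Aligned-read `data.table`; with
#'   `params$unique_only`, rows with `mapping_count > 1` are rejected.
#' @param scaffold_sizes Named vector of scaffold lengths in nt.
#' @param params A [cluster_params()] list.
#' @param mapped_total RPM denominator; defaults to the number of distinct
#'   read ids in `unique_reads`.
#' @return `data.table` of clusters: `cluster_id` (RPCL1 = most
#'   productive), `scaffold,start,end` (0-based half-open),
#'   `read_count` (supporting 5' ends), `rpm`, `fraction_plus`,
#'   `strandness` (`plus`/`minus`/`unbiased`).
#' @export
call_clusters <- function(unique_reads, scaffold_sizes, params = cluster_params(),
                          mapped_total = NULL) {
  if (length(scaffold_sizes) == 0L || is.null(names(scaffold_sizes)))
    stop("scaffold_sizes must be a non-empty named vector")
  reads <- unique_reads
  if (isTRUE(params$unique_only) && any(reads$mapping_count > 1L))
    stop("call_clusters expects uniquely mapping reads ",
         "(mapping_count == 1); filter or set unique_only = FALSE")
  unk <- setdiff(unique(reads$scaffold), names(scaffold_sizes))
  if (length(unk))
    stop("reads on unknown scaffold(s): ", paste(unk, collapse = ", "))
  if (nrow(reads) &&
      any(reads$end > scaffold_sizes[reads$scaffold]))
    stop("read interval beyond scaffold end")
  if (is.null(mapped_total))
    mapped_total <- max(1L, length(unique(reads$read_id)))

  regions <- data.table::rbindlist(lapply(names(scaffold_sizes), function(sc) {
    scan_scaffold(reads[scaffold == sc],
                  as.integer(scaffold_sizes[[sc]]), sc, params)
  }))
  if (nrow(regions) == 0L)
    return(data.table::data.table(
      cluster_id = character(), scaffold = character(),
      start = integer(), end = integer(), read_count = numeric(),
      rpm = numeric(), fraction_plus = numeric(), strandness = character()))

  # support: apportioned sum over reads whose 5' end lies in the cluster
  f5 <- five_prime(reads)
  stats <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- reads$scaffold == regions$scaffold[i] &
      f5 >= regions$start[i] & f5 < regions$end[i]
    wsum <- sum(reads$weight[sel])
    plus <- sum(reads$weight[sel & reads$strand == "+"])
    c(wsum, if (wsum > 0) plus / wsum else NA_real_)
  })
  regions[, read_count := vapply(stats, `[`, numeric(1), 1L)]
  regions[, fraction_plus := vapply(stats, `[`, numeric(1), 2L)]
  data.table::setorder(regions, -read_count, scaffold, start)
  regions[, cluster_id := paste0("RPCL", .I)]
  regions[, rpm := rpm(read_count, mapped_total)]
  regions[, strandness := strandness_label(fraction_plus,
                                           params$strand_bias_threshold)]
  regions[, .(cluster_id, scaffold, start, end, read_count, rpm,
              fraction_plus, strandness)]
}

## window scan of one scaffold; returns merged candidate regions
scan_scaffold <- function(reads, sc_len, sc, params) {
  empty <- data.table::data.table(scaffold = character(),
                                  start = integer(), end = integer())
  if (nrow(reads) == 0L) return(empty)
  w <- params$window_size; st <- params$step
  starts <- seq.int(0L, max(0L, sc_len - 1L), by = st)
  ends <- pmin(starts + w, sc_len)

  # per-base prefix sums: 5'-end counts and covered-base indicator
  f5 <- five_prime(reads)
  cnt <- tabulate(f5 + 1L, nbins = sc_len)
  cum_cnt <- c(0L, cumsum(cnt))
  # difference array of interval coverage (reads may share endpoints)
  cov <- integer(sc_len + 1L)
  for (col in c("start", "end")) {
    tb <- table(reads[[col]])
    idx <- as.integer(names(tb)) + 1L
    cov[idx] <- cov[idx] + if (col == "start") as.integer(tb) else -as.integer(tb)
  }
  covered <- as.integer(cumsum(cov)[seq_len(sc_len)] > 0L)
  cum_cov <- c(0L, cumsum(covered))

  size <- ends - starts
  n_in <- cum_cnt[ends + 1L] - cum_cnt[starts + 1L]
  covered_in <- cum_cov[ends + 1L] - cum_cov[starts + 1L]
  keep <- (n_in / (size / 1000)) > params$min_density &
    (covered_in / size) >= params$min_cov_frac
  if (!any(keep)) return(empty)

  merged <- merge_intervals(starts[keep], ends[keep], params$merge_gap)
  data.table::data.table(scaffold = sc, start = merged$start,
                         end = merged$end)
}

## union overlapping/adjacent-within-gap intervals: next interval joins the
## current run iff start - run_end < gap (strict), which also unions
## overlapping windows (gap >= 1 assumed)
merge_intervals <- function(starts, ends, gap) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me < gap) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

strandness_label <- function(fraction_plus, threshold = 0.75) {
  data.table::fcase(
    is.na(fraction_plus), NA_character_,
    fraction_plus >= threshold, "plus",
    (1 - fraction_plus) >= threshold, "minus",
    default = "unbiased"
  )
}

#' Strandness of a called cluster
#'
#' A cluster is strand-biased when at least `threshold` (default 75%) of
#' its supporting reads can be attributed to one genomic strand; exactly at
#' the boundary counts as biased, below it the cluster is unbiased.
#'
#' @param cluster One row of a [call_clusters()] table (or any list with
#'   `scaffold,start,end`).
#' @param reads Supporting reads (`data.table`).
#' @param threshold Strand-bias threshold (default 0.75).
#' @return List with `strandness` and `fraction_plus`.
#' @export
classify_cluster_strand <- function(cluster, reads, threshold = 0.75) {
  f5 <- five_prime(reads)
  sel <- reads$scaffold == cluster$scaffold &
    f5 >= cluster$start & f5 < cluster$end
  wsum <- sum(reads$weight[sel])
  if (wsum == 0) stop("cluster has no supporting reads")
  fp <- sum(reads$weight[sel & reads$strand == "+"]) / wsum
  list(strandness = strandness_label(fp, threshold), fraction_plus = fp)
}

#' Cumulative share of piRNAs per cluster rank
#'
#' @param clusters A [call_clusters()] table (or any table with
#'   `read_count`).
#' @return Numeric vector: entry k is the fraction of all in-cluster reads
#'   accounted for by the top k clusters.
#' @export
cumulative_share <- function(clusters) {
  stopifnot(nrow(clusters) >= 1L)
  s <- sort(clusters$read_count, decreasing = TRUE)
  cumsum(s) / sum(s)
}

#' Fraction of reads originating inside clusters, per group
#'
#' A read is inside a cluster when its 5' end lies in any cluster interval.
#'
#' @param reads Uniquely mapping reads with a grouping column.
#' @param clusters A [call_clusters()] table.
#' @param group_col Name of the grouping column in `reads` (e.g. the TE
#'   family of origin).
#' @return `data.table` with columns `group, fraction, n`; groups with no
#'   reads are absent (undefined).
#' @export
in_cluster_fraction <- function(reads, clusters, group_col = "family") {
  stopifnot(group_col %in% names(reads))
  if (nrow(reads) == 0L)
    return(data.table::data.table(group = character(), fraction = numeric(),
                                  n = integer()))
  f5 <- five_prime(reads)
  ins <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(clusters))) {
    ins <- ins | (reads$scaffold == clusters$scaffold[i] &
                    f5 >= clusters$start[i] & f5 < clusters$end[i])
  }
  dt <- data.table::data.table(group = reads[[group_col]], inside = ins)
  dt[, .(fraction = mean(inside), n = .N), by = group]
}

#' Count HTT copies inserted into clusters
#'
#' @param htt_annotations TE annotations flagged `is_htt`.
#' @param clusters A [call_clusters()] table.
#' @return `data.table` with columns `family, n_in_clusters`; a copy is
#'   counted when its interval intersects any cluster interval.
#' @export
count_htt_copies_in_clusters <- function(htt_annotations, clusters) {
  htt <- htt_annotations[is_htt == TRUE]
  fam <- sort(unique(htt$family))
  res <- data.table::data.table(family = fam, n_in_clusters = 0L)
  if (nrow(htt) == 0L || nrow(clusters) == 0L) return(res)
  hits <- GenomicRanges::findOverlaps(
    as_granges0(htt, use_strand = FALSE),
    as_granges0(clusters, use_strand = FALSE), ignore.strand = TRUE)
  inside <- unique(S4Vectors::queryHits(hits))
  tb <- table(htt$family[inside])
  res[match(names(tb), family), n_in_clusters := as.integer(tb)]
  res[]
}

#' TE fragment orientation within clusters
#'
#' Counts TE annotation records on each strand within every cluster and
#' labels the orientation bias with the same 75% rule used for read
#' strandness.
#'
#' @param te_annotations TE annotations.
#' @param clusters A [call_clusters()] table.
#' @param threshold Bias threshold (default 0.75).
#' @return `data.table` with columns
#'   `cluster_id, n_plus, n_minus, orientation`.
#' @export
te_orientation_in_clusters <- function(te_annotations, clusters,
                                       threshold = 0.75) {
  te <- te_annotations[feature_class == "TE"]
  out <- data.table::data.table(cluster_id = clusters$cluster_id,
                                n_plus = 0L, n_minus = 0L)
  if (nrow(te) && nrow(clusters)) {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(te, use_strand = FALSE),
      as_granges0(clusters, use_strand = FALSE), ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (i in seq_along(qh)) {
      if (te$strand[qh[i]] == "+")
        out[sh[i], n_plus := n_plus + 1L]
      else
        out[sh[i], n_minus := n_minus + 1L]
    }
  }
  tot <- out$n_plus + out$n_minus
  fp <- ifelse(tot > 0, out$n_plus / tot, NA_real_)
  out[, orientation := strandness_label(fp, threshold)]
  out[]
}
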