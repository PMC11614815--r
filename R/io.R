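## Readers and writers for the plain-text formats the pipeline touches.
##
## Conventions used everywhere in this package:
##   * genomic coordinates are 0-based half-open (BED), `end - start` is the
##     interval length;
##   * the 5' end of a + strand read is `start`, of a - strand read `end - 1`;
##   * alignments travel as a BED6+2 dialect with columns
##     scaffold, start, end, read_id, mapping_count, strand, sequence.

#' Read a genome FASTA file
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header; sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("malformed FASTA header in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' Read an alignment table (BED6+2)
#'
#' Ingests genome-mapped small-RNA reads in a tab-separated BED6+2 dialect:
#' `scaffold, start, end, read_id, mapping_count, strand, sequence`,
#' 0-based half-open, one row per genomic mapping. The fractional weight of
#' each mapping is `1 / mapping_count`, implementing apportioning of
#' multi-mapping reads.
#'
#' @param path Path to a tab-separated file without header.
#' @param max_mappings Upper cap on `mapping_count` (mirrors the upstream
#'   aligner's limit); rows above it are rejected. Default 50.
#' @return A `data.table` of aligned reads with columns
#'   `scaffold, start, end, read_id, mapping_count, strand, sequence,
#'    weight, length`.
#' @export
read_alignment_table <- function(path, max_mappings = 50L) {
  if (!file.exists(path)) stop("alignment table not found: ", path)
  dt <- data.table::fread(
    path, header = FALSE, sep = "\t",
    col.names = c("scaffold", "start", "end", "read_id",
                  "mapping_count", "strand", "sequence"),
    colClasses = list(character = c(1, 4, 6, 7), integer = c(2, 3, 5))
  )
  validate_reads(dt, max_mappings = max_mappings, file = path)
  dt[, weight := 1 / mapping_count]
  dt[, length := end - start]
  dt[]
}

#' Write an alignment table (BED6+2)
#'
#' @param reads Aligned-read `data.table` (see [read_alignment_table()]).
#' @param path Output path.
#' @export
write_alignment_table <- function(reads, path) {
  data.table::fwrite(
    reads[, .(scaffold, start, end, read_id, mapping_count, strand, sequence)],
    path, sep = "\t", col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

validate_reads <- function(dt, max_mappings = 50L, file = "<reads>") {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(file, ": ", what, " at line(s) ",
           paste(head(i, 5), collapse = ", "),
           if (length(i) > 5) " ..." else "", call. = FALSE)
  }
  bad(dt$end <= dt$start, "end <= start (empty or inverted interval)")
  bad(dt$start < 0L, "negative start")
  bad(dt$mapping_count < 1L, "mapping_count < 1")
  bad(dt$mapping_count > max_mappings,
      paste0("mapping_count above cap ", max_mappings))
  bad(!(dt$strand %in% c("+", "-")), "strand not in {+,-}")
  bad(nchar(dt$sequence) != dt$end - dt$start,
      "sequence length != interval length")
  bad(grepl("[^ACGTN]", dt$sequence), "sequence not over {A,C,G,T,N}")
  invisible(TRUE)
}

#' Write intervals to BED6
#'
#' For called piRNA clusters the score column carries RPM rounded to three
#' decimals; for plain feature annotations it is 0. Coordinates are written
#' as stored (0-based half-open).
#'
#' @param x A `data.table` of feature annotations (columns
#'   `scaffold,start,end,name,strand`) or called clusters (columns
#'   `scaffold,start,end,cluster_id,rpm`).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  is_cluster <- "cluster_id" %in% names(x)
  bed <- data.table::data.table(
    scaffold = x$scaffold,
    start    = x$start,
    end      = x$end,
    name     = if (is_cluster) x$cluster_id else x$name,
    score    = if (is_cluster) round(x$rpm, 3) else 0,
    strand   = if ("strand" %in% names(x) && !is_cluster) x$strand else "."
  )
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path Path to a BED6 file (no header).
#' @return `data.table` with columns `scaffold,start,end,name,score,strand`;
#'   zero-row table for an empty file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L)
    return(data.table::data.table(
      scaffold = character(), start = integer(), end = integer(),
      name = character(), score = numeric(), strand = character()))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("scaffold", "start", "end",
                                        "name", "score", "strand"))
  dt[, scaffold := as.character(scaffold)]
  dt[, name := as.character(name)]
  dt[]
}

#' Write an expression matrix as TSV
#'
#' Features in rows, samples in columns; the measurement unit is recorded in
#' a `#unit=` comment line so no serialization loses it.
#'
#' @param mat Numeric matrix with feature rownames and sample colnames.
#' @param unit One of `"count"`, `"RPM"`, `"RPKM"`, `"log10RPM1"`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, unit, path) {
  unit <- match.arg(unit, c("count", "RPM", "RPKM", "log10RPM1"))
  if (unit != "log10RPM1" && any(mat < 0))
    stop("negative values are not valid for unit ", unit)
  writeLines(paste0("#unit=", unit), path)
  dt <- data.table::data.table(feature = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with a `unit` attribute.
#' @export
read_expression_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#unit="))
    stop("missing '#unit=' header line in ", path)
  unit <- sub("^#unit=", "", first)
  dt <- data.table::fread(path, skip = 1L, header = TRUE, sep = "\t")
  mat <- as.matrix(dt[, -1, drop = FALSE])
  rownames(mat) <- dt[[1]]
  attr(mat, "unit") <- unit
  mat
}

#' Write a signature result (offset, count, z-score) as TSV
#'
#' @param sig A `signature_result` (see [pingpong_histogram()]).
#' @param path Output path.
#' @export
write_signature_tsv <- function(sig, path) {
  stopifnot(inherits(sig, "signature_result"))
  data.table::fwrite(
    data.table::data.table(offset = sig$offsets, count = sig$counts,
                           zscore = sig$zscores),
    path, sep = "\t"
  )
  invisible(path)
}

## GRanges bridge: 0-based half-open data.table -> GRanges (1-based closed).
as_granges0 <- function(dt, use_strand = TRUE) {
  GenomicRanges::GRanges(
    seqnames = dt$scaffold,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = if (use_strand && "strand" %in% names(dt)) dt$strand else "*"
  )
}

## 5' end (0-based genomic position) of each read.
five_prime <- function(dt) {
  data.table::fifelse(dt$strand == "+", dt$start, dt$end - 1L)
}
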