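# Brute-force reference implementations, deliberately independent of the
# package code paths: plain loops, per-base vectors, no shared helpers.

# all-windows cluster caller: per-base occupancy + run merging
bf_call_clusters <- function(reads, scaffold_sizes, window = 5000L,
                             step = 1000L, min_density = 5,
                             min_cov = 0.12, gap = 20000L) {
  out <- list()
  for (sc in names(scaffold_sizes)) {
    len <- as.integer(scaffold_sizes[[sc]])
    rr <- reads[reads$scaffold == sc, ]
    f5 <- ifelse(rr$strand == "+", rr$start, rr$end - 1L)
    covbase <- rep(FALSE, len)
    if (nrow(rr) > 0) {
      for (i in seq_len(nrow(rr)))
        covbase[(rr$start[i] + 1L):rr$end[i]] <- TRUE
    }
    keep <- rep(FALSE, len)
    for (s in seq.int(0L, max(0L, len - 1L), by = step)) {
      e <- min(s + window, len)
      size <- e - s
      n_in <- sum(f5 >= s & f5 < e)
      cov <- sum(covbase[(s + 1L):e])
      if (n_in / (size / 1000) > min_density && cov / size >= min_cov)
        keep[(s + 1L):e] <- TRUE
    }
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    runs <- cbind(starts[r$values], ends[r$values])
    cs <- runs[1, 1]; ce <- runs[1, 2]
    merged <- NULL
    if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
      if (runs[i, 1] - ce < gap) ce <- runs[i, 2]
      else { merged <- rbind(merged, c(cs, ce)); cs <- runs[i, 1]; ce <- runs[i, 2] }
    }
    merged <- rbind(merged, c(cs, ce))
    out[[sc]] <- data.frame(scaffold = sc, start = merged[, 1],
                            end = merged[, 2], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# O(n^2) 5'-5' overlap enumeration between two read tables
bf_pingpong <- function(a, b, max_overlap = 30L) {
  counts <- numeric(max_overlap)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$scaffold[i] != b$scaffold[j]) next
    if (a$strand[i] == b$strand[j]) next
    if (a$strand[i] == "+") {
      p5 <- a$start[i]; plen <- a$end[i] - a$start[i]
      m5 <- b$end[j] - 1L; mlen <- b$end[j] - b$start[j]
    } else {
      p5 <- b$start[j]; plen <- b$end[j] - b$start[j]
      m5 <- a$end[i] - 1L; mlen <- a$end[i] - a$start[i]
    }
    k <- m5 - p5 + 1L
    if (k >= 1L && k <= max_overlap && k <= plen && k <= mlen)
      counts[k] <- counts[k] + a$weight[i] * b$weight[j]
  }
  counts
}

# O(n^2) phasing distance enumeration (gap between same-strand intervals)
bf_phasing <- function(reads, max_distance = 50L) {
  counts <- numeric(max_distance + 1L)
  n <- nrow(reads)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (reads$scaffold[i] != reads$scaffold[j]) next
    if (reads$strand[i] != reads$strand[j]) next
    d <- reads$start[j] - reads$end[i]
    if (d >= 0L && d <= max_distance)
      counts[d + 1L] <- counts[d + 1L] + reads$weight[i] * reads$weight[j]
  }
  counts
}

# brute-force paired/unpaired labelling
bf_paired_fraction <- function(reads, max_overlap = 30L) {
  n <- nrow(reads)
  paired <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (reads$scaffold[i] != reads$scaffold[j]) next
    if (reads$strand[i] == reads$strand[j]) next
    if (reads$strand[i] == "+") { pi_ <- i; mi <- j } else { pi_ <- j; mi <- i }
    p5 <- reads$start[pi_]; plen <- reads$end[pi_] - reads$start[pi_]
    m5 <- reads$end[mi] - 1L; mlen <- reads$end[mi] - reads$start[mi]
    k <- m5 - p5 + 1L
    if (k >= 1L && k <= max_overlap && k <= plen && k <= mlen) {
      paired[i] <- TRUE; paired[j] <- TRUE
    }
  }
  ids <- unique(reads$read_id)
  mean(vapply(ids, function(id) any(paired[reads$read_id == id]),
              logical(1)))
}

# uniform random read set on one scaffold (both strands)
random_reads <- function(n, sc_len, scaffold = "chr", min_len = 24L,
                         max_len = 32L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  starts <- vapply(lens, function(L) sample.int(sc_len - L, 1L) - 1L,
                   integer(1))
  make_reads(scaffold, starts, starts + lens,
             sample(c("+", "-"), n, replace = TRUE))
}
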