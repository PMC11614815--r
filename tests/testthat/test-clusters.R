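# deterministic fixture: nr reads of length rl tiling from 0 at a spacing
tile_reads <- function(nr, spacing = 30L, rl = 30L, offset = 0L,
                       scaffold = "chr", strand = "+") {
  starts <- offset + (seq_len(nr) - 1L) * spacing
  make_reads(scaffold, starts, starts + rl, strand)
}

test_that("no reads give no clusters; basic dense region gives one", {
  sizes <- c(chr = 100000L)
  empty <- make_reads(character(0), integer(0), integer(0), character(0))
  expect_equal(nrow(call_clusters(empty, sizes)), 0L)

  # 300 reads tiling a 4 kb region: density and coverage far above cutoffs
  rd <- tile_reads(300L, spacing = 13L, rl = 28L, offset = 40000L)
  cl <- call_clusters(rd, sizes)
  expect_equal(nrow(cl), 1L)
  expect_lte(cl$start, 40000L)
  expect_gte(cl$end, 40000L + 300L * 13L + 28L)
  expect_identical(cl, call_clusters(rd[sample(nrow(rd))], sizes))
})

test_that("density exactly at the cutoff is rejected (strict >)", {
  sizes <- c(chr = 5000L)
  # 25 reads in the only full window: 25/5kb = 5/kb exactly
  expect_equal(nrow(call_clusters(tile_reads(25L), sizes)), 0L)
  # one more read pushes density over the cutoff
  expect_equal(nrow(call_clusters(tile_reads(26L), sizes)), 1L)
})

test_that("coverage exactly at 12% passes (>=), just below fails", {
  sizes <- c(chr = 5000L)
  # 26 stacked + tiled reads covering exactly 600 of 5000 bases
  base <- tile_reads(20L)                              # covers [0, 600)
  extra <- make_reads("chr", rep(0L, 6), rep(30L, 6), "+")
  rd <- rbind(base, extra)
  rd$read_id <- sprintf("u%03d", seq_len(nrow(rd)))
  expect_equal(nrow(call_clusters(rd, sizes)), 1L)
  # shorten one tile read: 599 covered bases, 11.98% < 12%
  rd2 <- data.table::copy(rd)
  rd2[20, `:=`(end = end - 1L, sequence = substr(sequence, 1, 29),
               length = 29L)]
  expect_equal(nrow(call_clusters(rd2, sizes)), 0L)
})

test_that("a 20 kb separation does not merge (strict <)", {
  sizes <- c(chr = 60000L)
  # two supra-threshold blocks whose retained windows end at 5000 and
  # start at 25000: separation exactly 20 kb
  a <- tile_reads(30L)                       # 5' ends in [0, 900)
  b <- tile_reads(30L, offset = 29000L)      # retained windows [25000, 34000)
  rd <- rbind(a, b)
  rd$read_id <- sprintf("u%03d", seq_len(nrow(rd)))
  cl <- call_clusters(rd, sizes)
  expect_equal(nrow(cl), 2L)
  gap <- min(cl$start[cl$start > 10000]) - max(cl$end[cl$end < 10000])
  expect_equal(gap, 20000L)
  # a merge threshold one base larger combines them
  cl2 <- call_clusters(rd, sizes, cluster_params(merge_gap = 20001L))
  expect_equal(nrow(cl2), 1L)
})

test_that("the caller equals the brute-force all-windows oracle", {
  for (s in 1:10) {
    set.seed(s)
    sizes <- c(chr = 100000L)
    n <- sample(200:3000, 1)
    rd <- random_reads(n, 100000L)
    # add a dense block half the time so clusters actually occur
    if (s %% 2 == 0) {
      blk <- tile_reads(sample(100:400, 1), spacing = 9L,
                        offset = sample(0:60000, 1))
      rd <- rbind(rd, blk)
      rd$read_id <- sprintf("u%05d", seq_len(nrow(rd)))
    }
    got <- call_clusters(rd, sizes)
    exp <- bf_call_clusters(rd, sizes)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp)) {
      o <- order(got$scaffold, got$start)
      expect_equal(got$start[o], exp$start)
      expect_equal(got$end[o], exp$end)
    }
  }
})

test_that("multimapping reads are rejected unless unique_only is off", {
  rd <- tile_reads(40L)
  rd$mapping_count <- 2L
  rd$weight <- 0.5
  expect_error(call_clusters(rd, c(chr = 5000L)), "unique")
  expect_silent(call_clusters(rd, c(chr = 5000L),
                              cluster_params(unique_only = FALSE)))
})

test_that("clusters are ranked RPCL1.. by support with RPM attached", {
  sizes <- c(chr = 100000L)
  big <- tile_reads(200L, spacing = 10L, offset = 60000L)
  small <- tile_reads(60L, spacing = 15L, offset = 10000L)
  rd <- rbind(big, small)
  rd$read_id <- sprintf("u%04d", seq_len(nrow(rd)))
  cl <- call_clusters(rd, sizes, mapped_total = 260L)
  expect_equal(cl$cluster_id, c("RPCL1", "RPCL2"))
  expect_gt(cl$read_count[1], cl$read_count[2])
  expect_equal(cl$rpm, cl$read_count * 1e6 / 260)
})

test_that("strandness obeys the 75% rule including the boundary", {
  mk <- function(n_plus, n_minus) {
    rbind(tile_reads(n_plus, strand = "+"),
          tile_reads(n_minus, strand = "-", offset = 2000L))
  }
  cl <- list(scaffold = "chr", start = 0L, end = 5000L)
  expect_equal(classify_cluster_strand(cl, mk(80L, 20L))$strandness, "plus")
  expect_equal(classify_cluster_strand(cl, mk(20L, 80L))$strandness, "minus")
  expect_equal(classify_cluster_strand(cl, mk(50L, 50L))$strandness,
               "unbiased")
  # exactly 75/25 counts as biased ("less than 75%" defines unbiased)
  r <- classify_cluster_strand(cl, mk(75L, 25L))
  expect_equal(r$fraction_plus, 0.75)
  expect_equal(r$strandness, "plus")
  expect_equal(classify_cluster_strand(cl, mk(74L, 26L))$strandness,
               "unbiased")
  expect_error(classify_cluster_strand(list(scaffold = "zz", start = 0L,
                                            end = 10L), mk(5L, 5L)),
               "no supporting reads")
})

test_that("cumulative share matches a sort-and-cumsum oracle", {
  one <- data.table::data.table(read_count = 42)
  expect_equal(cumulative_share(one), 1.0)
  ten <- data.table::data.table(read_count = rep(7, 10))
  expect_equal(cumulative_share(ten)[5], 0.5)
  set.seed(9)
  x <- data.table::data.table(read_count = runif(30, 1, 100))
  s <- sort(x$read_count, decreasing = TRUE)
  expect_equal(cumulative_share(x), cumsum(s) / sum(s))
})

test_that("in-cluster fractions match an interval-membership oracle", {
  cl <- data.table::data.table(cluster_id = "RPCL1", scaffold = "chr",
                               start = 1000L, end = 3000L)
  rd_in <- tile_reads(10L, offset = 1500L)
  rd_in$family <- "Mariner"
  expect_equal(in_cluster_fraction(rd_in, cl)$fraction, 1.0)
  rd_out <- tile_reads(10L, offset = 5000L)
  rd_out$family <- "Mariner"
  expect_equal(in_cluster_fraction(rd_out, cl)$fraction, 0.0)
  set.seed(4)
  rd <- random_reads(500, 10000L)
  rd$family <- sample(c("Mariner", "Ty3"), 500, replace = TRUE)
  got <- in_cluster_fraction(rd, cl)
  f5 <- ifelse(rd$strand == "+", rd$start, rd$end - 1L)
  ins <- f5 >= 1000 & f5 < 3000
  for (fam in c("Mariner", "Ty3"))
    expect_equal(got[group == fam]$fraction, mean(ins[rd$family == fam]))
})

test_that("HTT copy counting intersects copies with cluster intervals", {
  htt <- make_ann("chr", c(100L, 5000L, 9000L), c(900L, 5800L, 9800L),
                  "+", "TE", "OC1", is_htt = TRUE)
  cl <- data.table::data.table(cluster_id = "RPCL1", scaffold = "chr",
                               start = 0L, end = 1000L)
  expect_equal(count_htt_copies_in_clusters(htt, cl)$n_in_clusters, 1L)
  expect_equal(count_htt_copies_in_clusters(htt, cl[0])$n_in_clusters, 0L)
})

test_that("TE orientation bias in clusters uses the 75% rule", {
  cl <- data.table::data.table(cluster_id = c("RPCL1", "RPCL2"),
                               scaffold = "chr",
                               start = c(0L, 10000L), end = c(5000L, 15000L))
  te <- rbind(make_ann("chr", seq(0L, 4400L, 400L), seq(300L, 4700L, 400L),
                       "+", "TE", "Mariner"),
              make_ann("chr", seq(10000L, 12200L, 400L),
                       seq(10300L, 12500L, 400L),
                       rep(c("+", "-"), 3), "TE", "Ty3"))
  got <- te_orientation_in_clusters(te, cl)
  expect_equal(got[cluster_id == "RPCL1"]$orientation, "plus")
  expect_equal(got[cluster_id == "RPCL2"]$n_plus, 3L)
  expect_equal(got[cluster_id == "RPCL2"]$n_minus, 3L)
  expect_equal(got[cluster_id == "RPCL2"]$orientation, "unbiased")
})

test_that("tightening thresholds never yields more clusters", {
  # with sub-threshold background (3 reads/kb) separating the dense blocks
  for (s in 1:5) {
    set.seed(100 + s)
    rd <- rbind(random_reads(300, 100000L),
                tile_reads(200L, spacing = 12L, offset = 20000L),
                tile_reads(150L, spacing = 14L, offset = 70000L))
    rd$read_id <- sprintf("u%05d", seq_len(nrow(rd)))
    sizes <- c(chr = 100000L)
    n_prev <- nrow(call_clusters(rd, sizes))
    for (dens in c(8, 12, 20)) {
      n <- nrow(call_clusters(rd, sizes, cluster_params(min_density = dens)))
      expect_lte(n, n_prev)
      n_prev <- n
    }
    n_gap <- nrow(call_clusters(rd, sizes,
                                cluster_params(merge_gap = 40000L)))
    expect_lte(n_gap, nrow(call_clusters(rd, sizes)))
  }
})
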