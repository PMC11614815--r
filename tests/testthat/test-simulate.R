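test_that("simulation is deterministic under config + seed", {
  cfg <- small_sim_config(seed = 11, n_reads = 500L)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$annotations, g2$annotations)
  l1 <- simulate_library(cfg, g1); l2 <- simulate_library(cfg, g2)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$manifest, l2$manifest)
})

test_that("simulated genome has the configured size and planted features", {
  cfg <- small_sim_config(
    seed = 3,
    htt_insertions = data.frame(family = character(), scaffold = character(),
                                start = integer(), strand = character()))
  sg <- simulate_genome(cfg)
  expect_equal(nchar(sg$genome[["chr"]]), 100000L)
  te_in_cluster <- sg$annotations[feature_class == "TE" &
                                    start >= 20000 & end <= 60000]
  expect_gt(nrow(te_in_cluster), 0L)
  # planted copies carry the family consensus (reverse complemented on -)
  cp <- sg$te_copies[1]
  slice <- substring(sg$genome[[cp$scaffold]], cp$start + 1L, cp$end)
  ref <- substring(sg$consensus[[cp$family]], cp$cons_start + 1L,
                   cp$cons_start + (cp$end - cp$start))
  if (cp$strand == "-")
    ref <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
  expect_identical(slice, ref)
})

test_that("overlapping planted clusters are a config error", {
  expect_error(
    small_sim_config(seed = 1, clusters = data.frame(
      scaffold = "chr", start = c(10000L, 30000L), end = c(40000L, 60000L),
      strand = "+")),
    "overlapping")
})

test_that("HTT copies land exactly where configured and cluster membership counts", {
  cfg <- small_sim_config(seed = 5)  # 3 OC1 copies, one inside the cluster
  sg <- simulate_genome(cfg)
  htt <- sg$annotations[is_htt == TRUE]
  expect_equal(sort(htt$start), c(30000L, 65000L, 70000L))
  # interval-membership oracle: copy intersects [20000, 60000)
  expected <- sum(htt$start < 60000 & htt$end > 20000)
  clusters <- data.table::data.table(cluster_id = "RPCL1", scaffold = "chr",
                                     start = 20000L, end = 60000L)
  got <- count_htt_copies_in_clusters(htt, clusters)
  expect_equal(got[family == "OC1"]$n_in_clusters, expected)
  expect_equal(expected, 1L)
})

test_that("manifest labels recover the configured ping-pong pair fraction", {
  cfg <- small_sim_config(seed = 1, n_reads = 10000L,
                          pingpong_fraction = 0.3,
                          mirna_fraction = 0, contaminant_fraction = 0,
                          background_fraction = 0)
  lib <- simulate_library(cfg, simulate_genome(cfg))
  m28 <- lib$manifest[mode == 28]
  frac <- m28[, mean(role %in% c("pingpong_sense", "pingpong_anti"))]
  # binomial error at n ~ 6500
  expect_lt(abs(frac - 0.3), 0.03)
  # pairs have the exact configured 5'-5' overlap
  reads <- lib$reads
  pairs <- lib$manifest[role %in% c("pingpong_sense", "pingpong_anti")]
  one_pair <- pairs[pair_id == pairs$pair_id[1]]
  rr <- reads[read_id %in% one_pair$read_id]
  p5 <- ifelse(rr$strand == "+", rr$start, rr$end - 1L)
  expect_equal(abs(diff(p5)) + 1L, 10L)
})

test_that("every 28-mode read is paired when pingpong_fraction is 1", {
  cfg <- small_sim_config(seed = 2, n_reads = 200L, pingpong_fraction = 1,
                          phasing_fraction = 0, mirna_fraction = 0,
                          contaminant_fraction = 0, background_fraction = 0,
                          multimap_fraction = 0,
                          decoy_regions = data.frame(scaffold = "chr",
                                                     start = 80000L,
                                                     end = 90000L,
                                                     density = 0))
  lib <- simulate_library(cfg, simulate_genome(cfg))
  m28 <- lib$manifest[mode == 28]
  n_unpaired <- m28[, sum(!role %in% c("pingpong_sense", "pingpong_anti"))]
  expect_lte(n_unpaired, 1L)  # odd counts leave at most one single
})

test_that("read mass is conserved and sequences equal genome slices", {
  cfg <- small_sim_config(seed = 7, n_reads = 1000L)
  lib <- simulate_library(cfg, simulate_genome(cfg))
  expect_equal(sum(lib$reads$weight), lib$mapped_total, tolerance = 1e-12)
  expect_equal(data.table::uniqueN(lib$reads$read_id), lib$mapped_total)
  expect_equal(nrow(lib$manifest), lib$mapped_total)
  # unique mappings: sequence == genome slice (revcomp on -)
  uu <- lib$reads[lib$reads$mapping_count == 1L][1:50]
  slice <- unname(substring(lib$genome[uu$scaffold], uu$start + 1L, uu$end))
  neg <- uu$strand == "-"
  slice[neg] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(slice[neg])))
  expect_identical(uu$sequence, slice)
})

test_that("realized read-length histogram matches the configured mixture", {
  cfg <- small_sim_config(seed = 9, n_reads = 10000L,
                          mirna_fraction = 0, contaminant_fraction = 0)
  lib <- simulate_library(cfg, simulate_genome(cfg))
  lens <- lib$reads[!duplicated(read_id)]$length
  lm <- cfg$length_modes
  support <- c(lm$means[1] + (-1:1), lm$means[2] + (-1:1))
  probs <- c(lm$weights[1] * lm$jitter, lm$weights[2] * lm$jitter)
  obs <- table(factor(lens, levels = support))
  p <- suppressWarnings(stats::chisq.test(obs, p = probs)$p.value)
  expect_gt(p, 0.01)
})

test_that("a u1 bias of one makes every eligible read start with U", {
  cfg <- small_sim_config(seed = 4, n_reads = 500L, u1_bias = 1,
                          pingpong_fraction = 0, multimap_fraction = 0,
                          mirna_fraction = 0, contaminant_fraction = 0,
                          background_fraction = 0,
                          decoy_regions = data.frame(scaffold = "chr",
                                                     start = 80000L,
                                                     end = 90000L,
                                                     density = 0))
  lib <- simulate_library(cfg, simulate_genome(cfg))
  bf <- base_frequency_matrix(lib$reads)
  expect_equal(bf$u1_fraction, 1.0)
})

test_that("multimapped reads map at consistent consensus offsets", {
  cfg <- small_sim_config(seed = 6, n_reads = 2000L, multimap_fraction = 0.5,
                          dispersed_per_family = 3L)
  lib <- simulate_library(cfg, simulate_genome(cfg))
  mm <- lib$reads[mapping_count > 1L]
  expect_gt(nrow(mm), 0L)
  # every mapping row of a multimapper has the same interval length, and
  # the number of rows equals mapping_count
  chk <- mm[, .(n = .N, k = mapping_count[1],
                onelen = data.table::uniqueN(length)), by = read_id]
  expect_true(all(chk$n == chk$k))
  expect_true(all(chk$onelen == 1L))
  expect_equal(sum(lib$reads$weight), lib$mapped_total, tolerance = 1e-9)
})
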