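test_that("length filtering includes both boundaries and preserves order", {
  rd <- make_reads("s1", c(0, 100, 200, 300, 400),
                   c(22, 124, 228, 330, 431), "+")
  out <- filter_by_length(rd, 24L, 30L)
  expect_equal(out$length, c(24L, 28L, 30L))
  expect_equal(nrow(filter_by_length(rd[0], 24L, 30L)), 0L)
  expect_error(filter_by_length(rd, 30L, 24L))
})

test_that("classification applies exclusion-first rules and size windows", {
  ann <- rbind(
    make_ann("s1", 100L, 1300L, "+", "TE", "Mariner"),
    make_ann("s1", 150L, 300L, "+", "rRNA", NA_character_),
    make_ann("s1", 160L, 310L, "+", "miRNA", NA_character_))
  # 28 nt read over Mariner only -> piRNA
  r1 <- make_reads("s1", 500L, 528L, "+")
  expect_equal(classify_reads(r1, ann), "piRNA")
  # 28 nt read over Mariner and rRNA -> excluded as rRNA
  r2 <- make_reads("s1", 140L, 168L, "+")
  expect_equal(classify_reads(r2, ann[feature_class != "miRNA"]), "rRNA")
  # when both miRNA and rRNA overlap, miRNA takes precedence
  expect_equal(classify_reads(make_reads("s1", 170L, 198L, "+"), ann),
               "miRNA")
  # 22 nt read over a TE -> siRNA candidate
  r3 <- make_reads("s1", 500L, 522L, "+")
  expect_equal(classify_reads(r3, ann), "siRNA_candidate")
  # TE-overlap outside both windows, and no overlap at all -> unassigned
  expect_equal(classify_reads(make_reads("s1", 500L, 517L, "+"), ann),
               "unassigned")
  expect_equal(classify_reads(make_reads("s1", 5000L, 5028L, "+"), ann),
               "unassigned")
  # classification is strand-blind
  expect_equal(classify_reads(make_reads("s1", 500L, 528L, "-"), ann),
               "piRNA")
  expect_error(
    classify_reads(make_reads("s9", 0L, 28L, "+"), ann,
                   scaffold_sizes = c(s1 = 10000L)),
    "unknown scaffold")
})

test_that("piRNA size bounds are configurable (24-32 default, 24-30 variant)", {
  ann <- make_ann("s1", 100L, 1300L, "+", "TE", "Mariner")
  r <- make_reads("s1", 500L, 532L, "+")  # 32 nt
  expect_equal(classify_reads(r, ann), "piRNA")
  expect_equal(classify_reads(r, ann, pirna_range = c(24L, 30L)),
               "unassigned")
})

test_that("apportioned counts split weight across mappings and features", {
  ann <- rbind(make_ann("s1", 100L, 400L, "+", "TE", "Mariner", name = "A"),
               make_ann("s1", 1000L, 1400L, "+", "TE", "Ty3", name = "B"),
               make_ann("s1", 350L, 700L, "+", "TE", "Jockey", name = "C"))
  # one read, two mappings, each over one feature: 0.5 + 0.5
  r <- make_reads("s1", c(150L, 1100L), c(178L, 1128L), "+",
                  read_id = "r1", mapping_count = 2L)
  cnt <- apportioned_counts(r, ann, by = "name")
  expect_equal(cnt[group == "A"]$count, 0.5)
  expect_equal(cnt[group == "B"]$count, 0.5)
  expect_equal(sum(cnt$count), 1.0)
  # one unique mapping over two features: 0.5 each
  r2 <- make_reads("s1", 360L, 388L, "+")
  cnt2 <- apportioned_counts(r2, ann, by = "name")
  expect_equal(cnt2[group == "A"]$count, 0.5)
  expect_equal(cnt2[group == "C"]$count, 0.5)
  # non-overlapping mapping accumulates under unassigned
  r3 <- make_reads("s1", 5000L, 5028L, "+")
  expect_equal(apportioned_counts(r3, ann)[group == "unassigned"]$count, 1)
})

test_that("apportioned mass equals distinct reads on simulated libraries", {
  for (s in c(21, 22)) {
    cfg <- small_sim_config(seed = s, n_reads = 800L)
    lib <- simulate_library(cfg, simulate_genome(cfg))
    sg <- simulate_genome(cfg)
    cnt <- apportioned_counts(lib$reads, sg$annotations, by = "family")
    expect_equal(sum(cnt$count), lib$mapped_total, tolerance = 1e-9)
    cs <- class_summary(lib$reads, sg$annotations)
    expect_equal(sum(cs$count), lib$mapped_total, tolerance = 1e-9)
    expect_equal(sum(cs$percent), 100, tolerance = 1e-9)
  }
})

test_that("rpm matches its closed form", {
  expect_equal(rpm(5, 1e6), 5)
  expect_equal(rpm(0, 12345), 0)
  set.seed(1)
  cnt <- runif(20, 0, 1e4); tot <- sample(1e5:1e7, 20)
  expect_equal(rpm(cnt, tot), cnt * 1e6 / tot)
  expect_error(rpm(1, 0), "mapped_total")
})

test_that("length histograms are apportioned RPM and sum to total RPM", {
  rd <- make_reads("s1", c(0, 100, 200), c(28, 128, 228), "+")
  h <- length_histogram(rd, mapped_total = 3L)
  expect_equal(h$length, 28L)
  expect_equal(h$rpm, 1e6)
  expect_equal(nrow(length_histogram(rd[0], 10L)), 0L)
  # sum over lengths equals rpm of total assigned mass
  cfg <- small_sim_config(seed = 30, n_reads = 500L)
  lib <- simulate_library(cfg, simulate_genome(cfg))
  h2 <- length_histogram(lib$reads, lib$mapped_total)
  expect_equal(sum(h2$rpm), rpm(sum(lib$reads$weight), lib$mapped_total),
               tolerance = 1e-9)
})

test_that("a bimodal simulation yields the configured mode mass ratio", {
  cfg <- small_sim_config(
    seed = 31, n_reads = 10000L,
    length_modes = list(means = c(22L, 28L), weights = c(0.4, 0.6),
                        jitter = c(0.2, 0.6, 0.2)),
    mirna_fraction = 0, contaminant_fraction = 0)
  lib <- simulate_library(cfg, simulate_genome(cfg))
  h <- length_histogram(lib$reads, lib$mapped_total)
  expect_equal(h$length[which.max(h$rpm)], 28L)
  short <- sum(h[length <= 23]$rpm); long <- sum(h[length >= 27]$rpm)
  expect_lt(abs(short / (short + long) - 0.4), 0.05)
})

test_that("class labels are stable under input reordering", {
  ann <- rbind(make_ann("s1", 100L, 1300L, "+", "TE", "Mariner"),
               make_ann("s1", 2000L, 2300L, "+", "rRNA", NA_character_))
  set.seed(2)
  rd <- random_reads(200, 5000L, scaffold = "s1")
  lab <- classify_reads(rd, ann)
  o <- sample(nrow(rd))
  expect_identical(classify_reads(rd[o], ann), lab[o])
})
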