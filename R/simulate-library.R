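## Read-library simulation over a simulated genome (see simulate.R for the
## generator's conventions).

draw_lengths <- function(n, centre, jitter) {
  if (n == 0L) return(integer(0))
  centre + sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = jitter)
}

## integer allocation of n among weights, preserving the total
allocate <- function(n, w) {
  if (length(w) == 0L || n == 0L) return(integer(length(w)))
  x <- floor(n * w / sum(w))
  r <- n - sum(x)
  if (r > 0) {
    o <- order(n * w / sum(w) - x, decreasing = TRUE)
    x[o[seq_len(r)]] <- x[o[seq_len(r)]] + 1L
  }
  as.integer(x)
}

#' Simulate a small-RNA read library with ground truth
#'
#' Draws reads from the planted clusters (ping-pong pairs, phased trails
#' and independent TE-derived reads), decoy regions, miRNA loci,
#' contaminant features and genomic background; realizes 1U/10A base
#' biases by constraint-writing into the genome; duplicates a fraction of
#' independent TE reads at other copies of their family (multi-mapping);
#' and extracts every read's sequence from the final genome.
#'
#' @param config A [sim_config()].
#' @param sim_genome Output of [simulate_genome()] for the same config.
#' @param sample Sample label stored with the library.
#' @param replicate Replicate number.
#' @return List of class `sim_library`: `reads` (aligned-read
#'   `data.table`, one row per mapping), `manifest` (one row per read:
#'   `read_id, origin, role, pair_id, trail_id, mode, te_sense, family,
#'   mapping_count`), `mapped_total` (distinct read ids), `genome` (the
#'   final, constraint-written genome), `realized` (realized u1/a10
#'   fractions), `sample`, `replicate`.
#' @export
simulate_library <- function(config, sim_genome, sample = "sim",
                             replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lm <- config$length_modes
  cl <- config$clusters
  frags <- sim_genome$te_copies[in_cluster == TRUE]
  reads <- list()   # rows: scaffold,start,end,strand + manifest fields
  rid <- 0L
  emit <- function(scaffold, start, end, strand, origin, role, pair_id = NA,
                   trail_id = NA, mode = NA_integer_,
                   te_sense = NA_character_, family = NA_character_,
                   frag_idx = NA_integer_) {
    rid <<- rid + 1L
    reads[[length(reads) + 1L]] <<- list(
      read_id = sprintf("r%06d", rid), scaffold = scaffold,
      start = as.integer(start), end = as.integer(end), strand = strand,
      origin = origin, role = role,
      pair_id = as.character(pair_id), trail_id = as.character(trail_id),
      mode = as.integer(mode), te_sense = te_sense, family = family,
      frag_idx = as.integer(frag_idx))
  }

  n <- config$n_reads
  n_mirna <- round(config$mirna_fraction * n)
  n_contam <- round(config$contaminant_fraction * n)
  n_bg <- round(config$background_fraction * n)
  n_cluster <- n - n_mirna - n_contam - n_bg
  stopifnot(n_cluster >= 0)

  ## --- miRNA reads: stacked on miRNA loci ---
  mir <- sim_genome$annotations[feature_class == "miRNA"]
  if (n_mirna > 0L && nrow(mir) > 0L) {
    pick <- sample.int(nrow(mir), n_mirna, replace = TRUE)
    lens <- draw_lengths(n_mirna, lm$means[1], lm$jitter)
    for (i in seq_len(n_mirna)) {
      m <- pick[i]
      s <- mir$start[m]
      emit(mir$scaffold[m], s, s + lens[i], mir$strand[m],
           origin = "miRNA", role = "mirna", mode = lm$means[1])
    }
  }

  ## --- contaminant reads ---
  contam <- sim_genome$annotations[feature_class %in%
                                     c("rRNA", "snRNA", "simple_repeat",
                                       "low_complexity")]
  if (n_contam > 0L && nrow(contam) > 0L) {
    pick <- sample.int(nrow(contam), n_contam, replace = TRUE)
    midx <- sample.int(2L, n_contam, replace = TRUE, prob = lm$weights)
    lens <- draw_lengths(n_contam, 0L, lm$jitter) + lm$means[midx]
    for (i in seq_len(n_contam)) {
      f <- pick[i]
      L <- lens[i]
      span <- max(1L, contam$end[f] - contam$start[f] - L)
      s <- contam$start[f] + sample.int(span, 1L) - 1L
      emit(contam$scaffold[f], s, s + L,
           sample(c("+", "-"), 1L), origin = contam$feature_class[f],
           role = "contaminant", mode = lm$means[midx[i]])
    }
  }

  ## --- genomic background reads ---
  if (n_bg > 0L) {
    scs <- sample(names(config$genome), n_bg, replace = TRUE,
                  prob = as.numeric(config$genome))
    midx <- sample.int(2L, n_bg, replace = TRUE, prob = lm$weights)
    lens <- draw_lengths(n_bg, 0L, lm$jitter) + lm$means[midx]
    for (i in seq_len(n_bg)) {
      s <- sample.int(config$genome[[scs[i]]] - lens[i], 1L) - 1L
      emit(scs[i], s, s + lens[i], sample(c("+", "-"), 1L),
           origin = "background", role = "background", mode = lm$means[midx[i]])
    }
  }

  ## --- decoy reads: sub-threshold density, unique, random strand ---
  dec <- config$decoy_regions
  for (i in seq_len(nrow(dec))) {
    nd <- round(dec$density[i] * (dec$end[i] - dec$start[i]) / 1000)
    if (nd == 0L) next
    midx <- sample.int(2L, nd, replace = TRUE, prob = lm$weights)
    lens <- draw_lengths(nd, 0L, lm$jitter) + lm$means[midx]
    ss <- dec$start[i] + sample.int(dec$end[i] - dec$start[i] - max(lens),
                                    nd, replace = TRUE) - 1L
    for (j in seq_len(nd))
      emit(dec$scaffold[i], ss[j], ss[j] + lens[j], sample(c("+", "-"), 1L),
           origin = paste0("decoy", i), role = "decoy", mode = lm$means[midx[j]])
  }

  ## --- cluster reads ---
  n_per_cl <- allocate(n_cluster, cl$end - cl$start)
  for (ci in seq_len(nrow(cl))) {
    nc <- n_per_cl[ci]
    if (nc == 0L) next
    origin <- paste0("cluster", ci)
    cfr <- which(frags$scaffold == cl$scaffold[ci] &
                   frags$start >= cl$start[ci] & frags$end <= cl$end[ci])
    midx <- sample.int(2L, nc, replace = TRUE, prob = lm$weights)
    n28 <- sum(midx == 2L)
    n22 <- nc - n28
    n_pairs <- floor(config$pingpong_fraction * n28 / 2)
    n_rem28 <- n28 - 2L * n_pairs
    n_phase <- round(config$phasing_fraction * n_rem28)
    n_ind28 <- n_rem28 - n_phase

    ## ping-pong pairs inside TE fragments
    ov <- config$pingpong_overlap
    for (p in seq_len(n_pairs)) {
      Ls <- draw_lengths(1L, lm$means[2], lm$jitter)
      La <- draw_lengths(1L, lm$means[2], lm$jitter)
      fi <- if (length(cfr)) sample(cfr, 1L) else NA_integer_
      if (!is.na(fi)) {
        lo <- frags$start[fi]; hi <- frags$end[fi]
        sense_strand <- frags$strand[fi]
        fam <- frags$family[fi]
      } else {
        lo <- cl$start[ci]; hi <- cl$end[ci]
        sense_strand <- cl$strand[ci]; fam <- NA_character_
      }
      # plus-strand mate 5' sits (ov-1) upstream of the minus mate 5'
      Lp <- if (sense_strand == "+") Ls else La   # length of the + read
      Lm <- if (sense_strand == "+") La else Ls   # length of the - read
      p_min <- lo + max(0L, Lm - ov)
      p_max <- hi - max(Lp, ov)
      if (p_max < p_min) { lo <- cl$start[ci]; hi <- cl$end[ci]
                           p_min <- lo + max(0L, Lm - ov)
                           p_max <- hi - max(Lp, ov) }
      if (p_max < p_min) stop("cluster too small for a ping-pong pair")
      pp <- p_min + sample.int(p_max - p_min + 1L, 1L) - 1L
      m5 <- pp + ov - 1L
      pid <- sprintf("pp_%d_%d", ci, p)
      # + read [pp, pp+Lp); - read [m5-Lm+1, m5+1)
      if (sense_strand == "+") {
        emit(cl$scaffold[ci], pp, pp + Lp, "+", origin, "pingpong_sense",
             pair_id = pid, mode = lm$means[2], te_sense = "sense",
             family = fam, frag_idx = fi)
        emit(cl$scaffold[ci], m5 - Lm + 1L, m5 + 1L, "-", origin,
             "pingpong_anti", pair_id = pid, mode = lm$means[2],
             te_sense = "antisense", family = fam, frag_idx = fi)
      } else {
        emit(cl$scaffold[ci], m5 - Lm + 1L, m5 + 1L, "-", origin,
             "pingpong_sense", pair_id = pid, mode = lm$means[2],
             te_sense = "sense", family = fam, frag_idx = fi)
        emit(cl$scaffold[ci], pp, pp + Lp, "+", origin, "pingpong_anti",
             pair_id = pid, mode = lm$means[2], te_sense = "antisense",
             family = fam, frag_idx = fi)
      }
    }

    ## phased trails: head-to-tail on the cluster strand
    remaining <- n_phase
    tno <- 0L
    while (remaining > 0L) {
      tno <- tno + 1L
      tl <- min(remaining, sample(2:5, 1L))
      lens <- draw_lengths(tl, lm$means[2], lm$jitter)
      span <- sum(lens)
      if (cl$end[ci] - cl$start[ci] <= span)
        stop("cluster too small for requested trail length")
      s0 <- cl$start[ci] +
        sample.int(cl$end[ci] - cl$start[ci] - span, 1L) - 1L
      tid <- sprintf("tr_%d_%d", ci, tno)
      offs <- cumsum(c(0L, lens[-tl]))
      for (j in seq_len(tl)) {
        if (cl$strand[ci] == "+")
          emit(cl$scaffold[ci], s0 + offs[j], s0 + offs[j] + lens[j], "+",
               origin, "phased", trail_id = tid, mode = lm$means[2])
        else
          emit(cl$scaffold[ci], s0 + span - offs[j] - lens[j],
               s0 + span - offs[j], "-", origin, "phased", trail_id = tid,
               mode = lm$means[2])
      }
      remaining <- remaining - tl
    }

    ## independent TE-derived reads (both length modes): a uni-strand
    ## cluster emits reads from its own strand; whether a read is sense or
    ## antisense to a TE is decided by the orientation of the fragment it
    ## falls in, so the antisense fraction selects fragments accordingly
    n_ind <- n22 + n_ind28
    modes_ind <- c(rep(lm$means[1], n22), rep(lm$means[2], n_ind28))
    lens <- draw_lengths(n_ind, 0L, lm$jitter) + modes_ind
    anti <- runif(n_ind) < config$antisense_fraction
    rstrand <- cl$strand[ci]
    for (i in seq_len(n_ind)) {
      L <- lens[i]
      placed <- FALSE
      if (length(cfr)) {
        want <- if (anti[i]) (if (rstrand == "+") "-" else "+") else rstrand
        big <- cfr[frags$end[cfr] - frags$start[cfr] >= L &
                     frags$strand[cfr] == want]
        if (!length(big))   # no fragment of the wanted orientation fits
          big <- cfr[frags$end[cfr] - frags$start[cfr] >= L]
        if (length(big)) {
          fi <- big[sample.int(length(big), 1L)]
          st <- frags$start[fi] +
            sample.int(frags$end[fi] - frags$start[fi] - L + 1L, 1L) - 1L
          emit(cl$scaffold[ci], st, st + L, rstrand, origin, "independent",
               mode = modes_ind[i],
               te_sense = if (frags$strand[fi] == rstrand) "sense"
                          else "antisense",
               family = frags$family[fi], frag_idx = fi)
          placed <- TRUE
        }
      }
      if (!placed) {
        st <- cl$start[ci] +
          sample.int(cl$end[ci] - cl$start[ci] - L + 1L, 1L) - 1L
        emit(cl$scaffold[ci], st, st + L, rstrand, origin,
             "independent", mode = modes_ind[i])
      }
    }
  }

  reads <- data.table::rbindlist(reads)
  reads[, mapping_count := 1L]

  ## --- multi-mapping: duplicate independent TE reads at other copies ---
  copies <- sim_genome$te_copies
  extra <- list()
  ind_idx <- which(reads$role == "independent" & !is.na(reads$frag_idx))
  if (config$multimap_fraction > 0 && length(ind_idx)) {
    mm_sel <- ind_idx[runif(length(ind_idx)) < config$multimap_fraction]
    for (i in mm_sel) {
      fi <- reads$frag_idx[i]
      L <- reads$end[i] - reads$start[i]
      # consensus range of this mapping
      o <- if (copies$strand[fi] == "+")
        copies$cons_start[fi] + (reads$start[i] - copies$start[fi])
      else copies$cons_start[fi] + (copies$end[fi] - reads$end[i])
      elig <- which(copies$family == copies$family[fi] &
                      seq_len(nrow(copies)) != fi &
                      copies$cons_start <= o &
                      copies$cons_start + (copies$end - copies$start) >= o + L)
      if (!length(elig)) next
      k_extra <- min(sample(1:3, 1L), length(elig))
      sel <- if (length(elig) == 1L) elig else sample(elig, k_extra)
      sense <- reads$te_sense[i] == "sense"
      for (ei in sel) {
        st <- if (copies$strand[ei] == "+")
          copies$start[ei] + (o - copies$cons_start[ei])
        else copies$start[ei] + (copies$cons_start[ei] +
                                   (copies$end[ei] - copies$start[ei]) -
                                   (o + L))
        rstrand <- if (sense) copies$strand[ei] else
          (if (copies$strand[ei] == "+") "-" else "+")
        extra[[length(extra) + 1L]] <- list(
          read_id = reads$read_id[i], scaffold = copies$scaffold[ei],
          start = as.integer(st), end = as.integer(st + L),
          strand = rstrand, origin = reads$origin[i], role = "independent",
          pair_id = NA_character_, trail_id = NA_character_,
          mode = reads$mode[i], te_sense = reads$te_sense[i],
          family = reads$family[i], frag_idx = as.integer(ei))
      }
      reads[i, mapping_count := 1L + length(sel)]
    }
    if (length(extra)) {
      extra <- data.table::rbindlist(extra)
      extra[, mapping_count := 0L]   # filled below from the primary row
      reads <- rbind(reads, extra)
      reads[, mapping_count := max(mapping_count), by = read_id]
    }
  }
  reads[, weight := 1 / mapping_count]

  ## --- base-bias constraints, first-wins, then sequence extraction ---
  gvec <- lapply(sim_genome$genome, function(s) strsplit(s, "")[[1]])
  is_primary <- !duplicated(reads$read_id)
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  constraints <- list()
  # 10A of ping-pong sense mates first (the antisense mate's first base is
  # the complement of this same genomic base)
  sidx <- which(is_primary & reads$role == "pingpong_sense" &
                  (reads$end - reads$start) >= 10L)
  if (length(sidx)) {
    b <- ifelse(runif(length(sidx)) < config$a10_bias, "A",
                sample(c("C", "G", "T"), length(sidx), replace = TRUE))
    pos <- ifelse(reads$strand[sidx] == "+", reads$start[sidx] + 9L,
                  reads$end[sidx] - 10L)
    gbase <- ifelse(reads$strand[sidx] == "+", b, comp[b])
    constraints[[1L]] <- data.table::data.table(
      scaffold = reads$scaffold[sidx], pos = pos, base = gbase)
  }
  # 1U of every other uniquely mapped read
  uidx <- which(is_primary & reads$mapping_count == 1L &
                  !(reads$role %in% c("pingpong_anti")))
  if (length(uidx)) {
    b <- ifelse(runif(length(uidx)) < config$u1_bias, "T",
                sample(c("A", "C", "G"), length(uidx), replace = TRUE))
    pos <- ifelse(reads$strand[uidx] == "+", reads$start[uidx],
                  reads$end[uidx] - 1L)
    gbase <- ifelse(reads$strand[uidx] == "+", b, comp[b])
    constraints[[length(constraints) + 1L]] <- data.table::data.table(
      scaffold = reads$scaffold[uidx], pos = pos, base = gbase)
  }
  if (length(constraints)) {
    con <- data.table::rbindlist(constraints)
    con <- con[!duplicated(con[, .(scaffold, pos)])]
    for (sc in unique(con$scaffold)) {
      sub <- con[scaffold == sc]
      gvec[[sc]][sub$pos + 1L] <- sub$base
    }
  }
  genome_final <- vapply(gvec, paste, character(1), collapse = "")

  prim <- reads[is_primary]   # primary rows, in emission order
  seq_prim <- substring(genome_final[prim$scaffold], prim$start + 1L,
                        prim$end)
  neg <- prim$strand == "-"
  if (any(neg)) seq_prim[neg] <- revcomp(seq_prim[neg])
  seqmap <- setNames(seq_prim, prim$read_id)
  reads[, sequence := seqmap[read_id]]
  reads[, length := end - start]

  manifest <- reads[is_primary,
                    .(read_id, origin, role, pair_id, trail_id, mode,
                      te_sense, family, mapping_count)]
  realized <- list(
    u1 = if (length(uidx))
      mean(substr(seqmap[reads$read_id[uidx]], 1, 1) == "T") else NA_real_,
    a10 = if (length(sidx))
      mean(substr(seqmap[reads$read_id[sidx]], 10, 10) == "A") else NA_real_)

  out <- reads[, .(read_id, scaffold, start, end, strand, sequence,
                   mapping_count, weight, length)]
  structure(list(reads = out, manifest = manifest,
                 mapped_total = length(unique(out$read_id)),
                 genome = genome_final, realized = realized,
                 sample = sample, replicate = as.integer(replicate)),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat("sim_library:", x$mapped_total, "reads (",
      nrow(x$reads), "mappings ), sample", x$sample,
      "replicate", x$replicate, "\n")
  invisible(x)
}
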