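# Independent brute-force oracles and fixture builders for the test suite.
# The oracles enumerate maximal runs by exhaustive (i, j) range search over
# a merged segment table and check each scoring rule literally; they share
# no code with the engine implementations.

toy_genome <- function() load_genome("toy3")

# build a one-sample profile from terse segment rows:
# list(c(chrom, start, end, n_probes, major, minor), ...)
mk_profile <- function(rows, sample_id = "t", purity = 1, ploidy = 2) {
  seg <- as.data.frame(do.call(rbind, rows))
  names(seg) <- c("chrom", "start", "end", "n_probes", "major_cn",
                  "minor_cn")
  seg$chrom <- as.character(seg$chrom)
  for (col in names(seg)[-1]) seg[[col]] <- as.numeric(seg[[col]])
  ascn_profile(sample_id, seg, purity = purity, ploidy = ploidy)
}

# merge by repeated single-pass pair collapse (independent of
# merge_adjacent's vectorized grouping)
oracle_merge <- function(seg) {
  repeat {
    done <- TRUE
    i <- 1
    while (i < nrow(seg)) {
      if (seg$chrom[i] == seg$chrom[i + 1] &&
          seg$major_cn[i] == seg$major_cn[i + 1] &&
          seg$minor_cn[i] == seg$minor_cn[i + 1]) {
        seg$end[i] <- seg$end[i + 1]
        seg$n_probes[i] <- seg$n_probes[i] + seg$n_probes[i + 1]
        seg <- seg[-(i + 1), , drop = FALSE]
        done <- FALSE
      } else i <- i + 1
    }
    if (done) break
  }
  rownames(seg) <- NULL
  seg
}

# all maximal index ranges [i, j] on which pred holds for every row
oracle_maximal_ranges <- function(s, pred) {
  n <- nrow(s)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (!all(pred(s)[i:j])) next
    left_max <- (i == 1) || !pred(s)[i - 1]
    right_max <- (j == n) || !pred(s)[j + 1]
    if (left_max && right_max) out[[length(out) + 1]] <- c(i, j)
  }
  out
}

oracle_tai <- function(profile, genome, config = scar_config()) {
  total <- 0
  seg <- oracle_merge(profile$segments)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    rownames(s) <- NULL
    info <- genome$chromosomes[genome$chromosomes$chrom == ch, ]
    termini <- 0
    for (r in oracle_maximal_ranges(s, function(x) x$major_cn != x$minor_cn)) {
      a <- s$start[r[1]]; b <- s$end[r[2]]
      probes <- sum(s$n_probes[r[1]:r[2]])
      overlaps_cen <- !(b < info$cen_start || a > info$cen_end)
      if (overlaps_cen) next
      if (!((b - a + 1) > config$tai_min_len)) next
      if (probes < config$tai_min_probes) next
      if (a == 1) termini <- termini + 1
      if (b == info$length) termini <- termini + 1
    }
    total <- total + min(termini, 2)
  }
  total
}

oracle_loh <- function(profile, genome, config = scar_config()) {
  total <- 0
  seg <- oracle_merge(profile$segments)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    rownames(s) <- NULL
    info <- genome$chromosomes[genome$chromosomes$chrom == ch, ]
    for (r in oracle_maximal_ranges(s, function(x) x$minor_cn == 0)) {
      a <- s$start[r[1]]; b <- s$end[r[2]]
      if (!any(s$major_cn[r[1]:r[2]] >= 1)) next
      if (!((b - a + 1) > config$loh_min_len)) next
      if (a == 1 && b == info$length) next
      total <- total + 1
    }
  }
  total
}

oracle_lst <- function(profile, genome, config = scar_config()) {
  total <- 0
  seg <- oracle_merge(profile$segments)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    info <- genome$chromosomes[genome$chromosomes$chrom == ch, ]
    for (arm in list(c(1, info$cen_start - 1),
                     c(info$cen_end + 1, info$length))) {
      pieces <- list()
      for (i in seq_len(nrow(s))) {
        a <- max(s$start[i], arm[1]); b <- min(s$end[i], arm[2])
        if (a > b) next
        if ((b - a + 1) < config$lst_smooth) next
        pieces[[length(pieces) + 1]] <-
          data.frame(chrom = ch, start = a, end = b,
                     n_probes = s$n_probes[i],
                     major_cn = s$major_cn[i], minor_cn = s$minor_cn[i])
      }
      if (length(pieces) < 2) next
      p <- oracle_merge(do.call(rbind, pieces))
      if (nrow(p) < 2) next
      for (j in 1:(nrow(p) - 1)) {
        state_diff <- p$major_cn[j] != p$major_cn[j + 1] ||
          p$minor_cn[j] != p$minor_cn[j + 1]
        long_both <- (p$end[j] - p$start[j] + 1) >= config$lst_min_seg &&
          (p$end[j + 1] - p$start[j + 1] + 1) >= config$lst_min_seg
        if (state_diff && long_both) total <- total + 1
      }
    }
  }
  total
}

# literal per-segment GS classification: counts per cell over the merged
# profile plus breakpoints, checking each printed rule independently
oracle_gs_features <- function(profile, genome) {
  seg <- oracle_merge(profile$segments)
  counts <- setNames(numeric(28), gs_feature_names())
  for (i in seq_len(nrow(seg))) {
    maj <- seg$major_cn[i]; mnr <- seg$minor_cn[i]
    if (maj == 1 && mnr == 1) next
    if (maj == 0 && mnr == 0) next
    type <- if (mnr == 0) "LOH"
      else if (maj != mnr) "allele_specific"
      else "allele_balanced"
    len <- seg$end[i] - seg$start[i] + 1
    if (len < 5e6) next
    lc <- if (len > 15e6) "large" else if (len >= 10e6) "middle" else "small"
    info <- genome$chromosomes[genome$chromosomes$chrom == seg$chrom[i], ]
    sc <- if (seg$start[i] == 1 || seg$end[i] == info$length) "telomere"
      else if (!(seg$end[i] < info$cen_start ||
                 seg$start[i] > info$cen_end)) "centromere"
      else "other"
    cell <- paste(lc, sc, type, sep = "_")
    counts[cell] <- counts[cell] + 1
  }
  for (ch in unique(seg$chrom))
    counts["breakpoints"] <- counts["breakpoints"] + sum(seg$chrom == ch) - 1
  counts
}

# Mann-Whitney pair-counting AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exhaustive empirical Youden search, lowest maximizing observed score
oracle_youden <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  best_j <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    se <- sum(pos >= t) / length(pos)
    sp <- sum(neg < t) / length(neg)
    if (se + sp - 1 > best_j) {
      best_j <- se + sp - 1
      best_t <- t
    }
  }
  list(cutoff = best_t, j = best_j)
}

# random valid profile on the toy genome: contiguous random-state segments
random_profile <- function(seed, genome = toy_genome(), max_seg_chrom = 6) {
  set.seed(seed)
  states <- list(c(1, 1), c(2, 1), c(2, 0), c(1, 0), c(2, 2), c(3, 1),
                 c(0, 0), c(3, 2), c(3, 0))
  rows <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$chrom[i]
    L <- genome$chromosomes$length[i]
    k <- sample(1:max_seg_chrom, 1)
    bp <- sort(sample(seq(1e6, L - 1e6, by = 1e5), k - 1))
    starts <- c(1, bp + 1); ends <- c(bp, L)
    for (j in seq_len(k)) {
      st <- states[[sample(length(states), 1)]]
      rows[[length(rows) + 1]] <- c(ch, starts[j], ends[j],
                                    sample(10:800, 1), st[1], st[2])
    }
  }
  mk_profile(rows, sample_id = paste0("rand", seed))
}

# split every segment longer than 2 bp into two equal-state pieces at a
# random interior point, conserving probe totals
split_segments <- function(profile, seed) {
  set.seed(seed)
  seg <- profile$segments
  rows <- list()
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i] + 1
    if (len > 2 && runif(1) < 0.8) {
      cut <- seg$start[i] + sample(len - 1, 1) - 1
      p1 <- round(seg$n_probes[i] * (cut - seg$start[i] + 1) / len)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = seg$chrom[i], start = seg$start[i], end = cut,
        n_probes = p1, major_cn = seg$major_cn[i],
        minor_cn = seg$minor_cn[i])
      rows[[length(rows) + 1]] <- data.frame(
        chrom = seg$chrom[i], start = cut + 1, end = seg$end[i],
        n_probes = seg$n_probes[i] - p1, major_cn = seg$major_cn[i],
        minor_cn = seg$minor_cn[i])
    } else {
      rows[[length(rows) + 1]] <- seg[i, ]
    }
  }
  ascn_profile(profile$sample_id, do.call(rbind, rows),
               purity = profile$purity, ploidy = profile$ploidy)
}
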