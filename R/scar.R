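# Scar-count engine: LOH + telomeric allelic imbalance (TAI) + large-scale
# state transitions (LST), with the SNP-array-adapted rule set (126-probe
# TAI minimum, chromosome-specific ploidy by major copy-number fraction).
# The genomic-instability (GI) score is the plain sum of the three counts.

#' Scar engine configuration
#'
#' Tunable rule parameters of the scar-count engine. Defaults follow the
#' established scar definitions: TAI regions must be longer than 11 Mb and
#' carry at least 126 probes (the SNP-array adaptation); LOH regions must
#' exceed 15 Mb without spanning a whole chromosome; LST junctions require
#' both flanking segments to be at least 10 Mb after smoothing away
#' segments shorter than 3 Mb; GI positivity at a score of 42, inclusive by
#' default (the reference assay's published rule is "score >= 42"; the
#' strict ">" comparator used in some pipeline descriptions is available
#' via `threshold_inclusive = FALSE`).
#'
#' @param tai_min_len Minimum TAI run length in bp (exclusive bound).
#' @param tai_min_probes Minimum summed probe count in a TAI run.
#' @param loh_min_len Minimum LOH run length in bp (exclusive bound).
#' @param lst_min_seg Minimum length of both segments flanking an LST
#'   junction, in bp.
#' @param lst_smooth Segments shorter than this are removed before LST
#'   counting and equal-state flanks re-merged.
#' @param gi_threshold GI positivity threshold.
#' @param threshold_inclusive If `TRUE` (default), positive means
#'   `gi_score >= gi_threshold`; otherwise strictly greater.
#' @return A list of class `scar_config`.
#' @export
scar_config <- function(tai_min_len = 11e6, tai_min_probes = 126,
                        loh_min_len = 15e6, lst_min_seg = 10e6,
                        lst_smooth = 3e6, gi_threshold = 42,
                        threshold_inclusive = TRUE) {
  stopifnot(tai_min_len > 0, loh_min_len > 0, lst_min_seg > 0,
            lst_smooth > 0, tai_min_probes >= 0)
  structure(list(tai_min_len = tai_min_len, tai_min_probes = tai_min_probes,
                 loh_min_len = loh_min_len, lst_min_seg = lst_min_seg,
                 lst_smooth = lst_smooth, gi_threshold = gi_threshold,
                 threshold_inclusive = threshold_inclusive),
            class = "scar_config")
}

# index ranges of maximal TRUE runs
.true_runs <- function(flag) {
  if (length(flag) == 0 || !any(flag)) return(list())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(i) c(starts[i], ends[i]))
}

#' Chromosome-specific ploidy by major copy-number fraction
#'
#' The total copy number (major + minor) of the allele-specific state that
#' covers the largest summed segment length on the chromosome. Length ties
#' are broken toward the total copy number closest to `round(ploidy)`, then
#' toward the lower total.
#'
#' @param profile An `ascn_profile`.
#' @param chrom Chromosome label with at least one segment.
#' @return Integer total copy number.
#' @export
chromosome_ploidy <- function(profile, chrom) {
  seg <- profile$segments[profile$segments$chrom == as.character(chrom), ]
  if (nrow(seg) == 0)
    stop("sample ", profile$sample_id, ": no segments on chromosome ", chrom)
  total <- seg$major_cn + seg$minor_cn
  len_by_total <- tapply(.seg_len(seg), total, sum)
  totals <- as.numeric(names(len_by_total))
  best <- len_by_total == max(len_by_total)
  cand <- totals[best]
  if (length(cand) > 1) {
    d <- abs(cand - round(profile$ploidy))
    cand <- cand[d == min(d)]
    cand <- min(cand)
  }
  as.integer(cand)
}

# maximal runs of segments satisfying `flag` on one chromosome's merged
# segment table; returns per-run span, probe sum and row index range
.chrom_runs <- function(seg, flag) {
  runs <- .true_runs(flag)
  lapply(runs, function(r) {
    rows <- seq(r[1], r[2])
    list(start = seg$start[r[1]], end = seg$end[r[2]],
         length = seg$end[r[2]] - seg$start[r[1]] + 1,
         n_probes = sum(seg$n_probes[rows]),
         rows = rows)
  })
}

#' Count telomeric allelic imbalances (TAI)
#'
#' After merging equal-state neighbors, counts maximal runs of adjacent
#' allelic-imbalance segments (`major_cn != minor_cn`) that (a) contain a
#' chromosome-terminal position, (b) do not overlap the centromere
#' interval, (c) are longer than `tai_min_len`, and (d) carry at least
#' `tai_min_probes` probes in total. At most two per chromosome (one per
#' terminus).
#'
#' @param profile An `ascn_profile`.
#' @param genome A `genome_build`.
#' @param config A [scar_config()].
#' @return Integer TAI count.
#' @export
count_tai <- function(profile, genome, config = scar_config()) {
  merged <- merge_adjacent(validate_profile(profile, genome))
  seg <- merged$segments
  total <- 0L
  for (ch in unique(seg$chrom)) {
    row <- .chrom_row(genome, ch)
    s <- seg[seg$chrom == ch, ]
    runs <- .chrom_runs(s, s$major_cn != s$minor_cn)
    termini <- 0L
    for (r in runs) {
      crosses_cen <- r$start <= row$cen_end && r$end >= row$cen_start
      if (crosses_cen) next
      if (!(r$length > config$tai_min_len)) next
      if (r$n_probes < config$tai_min_probes) next
      termini <- termini + (r$start == 1) + (r$end == row$length)
    }
    total <- total + min(termini, 2L)
  }
  total
}

#' Count LOH regions
#'
#' Counts maximal merged runs of segments with `minor_cn = 0` that retain
#' at least one allele somewhere in the run (`major_cn >= 1`), are longer
#' than `loh_min_len`, and do not span the entire chromosome. Runs
#' consisting only of homozygous deletions (0+0) are not counted, since an
#' LOH scar requires a retained allele.
#'
#' @inheritParams count_tai
#' @return Integer LOH count.
#' @export
count_loh <- function(profile, genome, config = scar_config()) {
  merged <- merge_adjacent(validate_profile(profile, genome))
  seg <- merged$segments
  total <- 0L
  for (ch in unique(seg$chrom)) {
    row <- .chrom_row(genome, ch)
    s <- seg[seg$chrom == ch, ]
    runs <- .chrom_runs(s, s$minor_cn == 0)
    for (r in runs) {
      if (!any(s$major_cn[r$rows] >= 1)) next
      if (!(r$length > config$loh_min_len)) next
      if (r$start == 1 && r$end == row$length) next   # whole chromosome
      total <- total + 1L
    }
  }
  total
}

# clip a chromosome's merged segments to an arm interval
.clip_to_arm <- function(s, arm) {
  piece <- s
  piece$start <- pmax(s$start, arm[1])
  piece$end <- pmin(s$end, arm[2])
  piece[piece$start <= piece$end, , drop = FALSE]
}

#' Count large-scale state transitions (LST)
#'
#' Per chromosome arm: segments are clipped to the arm, pieces shorter than
#' `lst_smooth` are discarded, adjacent equal-state pieces re-merged, and
#' each junction between consecutive pieces of different allele-specific
#' state is counted when both pieces span at least `lst_min_seg`. Returns
#' the genome-wide sum.
#'
#' @inheritParams count_tai
#' @return Integer LST count.
#' @export
count_lst <- function(profile, genome, config = scar_config()) {
  merged <- merge_adjacent(validate_profile(profile, genome))
  seg <- merged$segments
  total <- 0L
  for (ch in unique(seg$chrom)) {
    arms <- arm_intervals(genome, ch)
    s <- seg[seg$chrom == ch, ]
    for (arm in arms) {
      piece <- .clip_to_arm(s, arm)
      piece <- piece[.seg_len(piece) >= config$lst_smooth, , drop = FALSE]
      if (nrow(piece) < 2) next
      # re-merge equal-state flanks exposed by smoothing
      prof_arm <- ascn_profile(profile$sample_id, piece)
      piece <- merge_adjacent(prof_arm)$segments
      if (nrow(piece) < 2) next
      len <- .seg_len(piece)
      for (j in seq_len(nrow(piece) - 1)) {
        differs <- piece$major_cn[j] != piece$major_cn[j + 1] ||
          piece$minor_cn[j] != piece$minor_cn[j + 1]
        if (differs && len[j] >= config$lst_min_seg &&
            len[j + 1] >= config$lst_min_seg)
          total <- total + 1L
      }
    }
  }
  total
}

#' Score one profile with the scar-count engine
#'
#' Computes the three scar components and their sum (the GI score), and
#' assigns GI status by the configured threshold rule.
#'
#' @inheritParams count_tai
#' @return A list of class `scar_scores` with `loh_count`, `tai_count`,
#'   `lst_count`, `gi_score`, `gi_status` (`"positive"`/`"negative"`), and
#'   `chromosome_ploidy`, a named integer vector of per-chromosome modal
#'   total copy numbers (reported, not used by the counting rules).
#' @examples
#' gb <- load_genome("toy3")
#' prof <- ascn_profile("s1", data.frame(
#'   chrom = "1", start = c(1, 12e6 + 1), end = c(12e6, 100e6),
#'   n_probes = c(600, 4400), major_cn = c(2, 1), minor_cn = c(1, 1)))
#' score_profile(prof, gb)$tai_count   # 1
#' @export
score_profile <- function(profile, genome, config = scar_config()) {
  loh <- count_loh(profile, genome, config)
  tai <- count_tai(profile, genome, config)
  lst <- count_lst(profile, genome, config)
  gi <- loh + tai + lst
  chroms <- unique(profile$segments$chrom)
  ploidies <- vapply(chroms, function(ch) chromosome_ploidy(profile, ch),
                     integer(1))
  names(ploidies) <- chroms
  structure(list(sample_id = profile$sample_id,
                 loh_count = loh, tai_count = tai, lst_count = lst,
                 gi_score = gi,
                 gi_status = gi_status(gi, config),
                 chromosome_ploidy = ploidies),
            class = "scar_scores")
}

#' GI status from a GI score
#'
#' @param gi_score Numeric score.
#' @param config A [scar_config()] supplying `gi_threshold` and the
#'   comparator.
#' @return `"positive"` or `"negative"`.
#' @export
gi_status <- function(gi_score, config = scar_config()) {
  pos <- if (config$threshold_inclusive) gi_score >= config$gi_threshold
         else gi_score > config$gi_threshold
  ifelse(pos, "positive", "negative")
}

#' @export
print.scar_scores <- function(x, ...) {
  cat(sprintf("scar_scores %s: LOH %d + TAI %d + LST %d = GI %d (%s)\n",
              x$sample_id, x$loh_count, x$tai_count, x$lst_count,
              x$gi_score, x$gi_status))
  invisible(x)
}

#' Score many profiles with the scar engine
#'
#' @param profiles List of `ascn_profile` objects.
#' @inheritParams count_tai
#' @return Data frame: `sample`, `loh`, `tai`, `lst`, `gi_score`,
#'   `gi_status`.
#' @export
score_profiles <- function(profiles, genome, config = scar_config()) {
  rows <- lapply(profiles, function(p) {
    s <- score_profile(p, genome, config)
    data.frame(sample = s$sample_id, loh = s$loh_count, tai = s$tai_count,
               lst = s$lst_count, gi_score = s$gi_score,
               gi_status = s$gi_status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
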