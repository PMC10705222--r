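#' Construct an allele-specific copy-number profile
#'
#' An `ascn_profile` holds one tumor's allele-specific copy-number segments
#' (as produced upstream by ASCAT- or SEQUENZA-style segmentation) together
#' with its estimated purity and ploidy. Coordinates are 1-based inclusive,
#' so segment length is `end - start + 1`. Major and minor copy numbers are
#' stored ordered (`major_cn >= minor_cn`).
#'
#' @param sample_id Sample identifier.
#' @param segments Data frame with columns `chrom`, `start`, `end`,
#'   `n_probes`, `major_cn`, `minor_cn`.
#' @param purity Tumor cell fraction in (0, 1]. Default 1.
#' @param ploidy Average tumor genome copy number. Default 2.
#' @param genome Optional `genome_build`; when given, every chromosome in
#'   `segments` must resolve to it.
#' @return A validated `ascn_profile` object.
#' @export
ascn_profile <- function(sample_id, segments, purity = 1.0, ploidy = 2.0,
                         genome = NULL) {
  segments <- as.data.frame(segments)
  required <- c("chrom", "start", "end", "n_probes", "major_cn", "minor_cn")
  missing <- setdiff(required, names(segments))
  if (length(missing) > 0)
    stop("segments for sample ", sample_id, " lack column(s): ",
         paste(missing, collapse = ", "))
  segments$chrom <- as.character(segments$chrom)
  segments <- segments[order(segments$chrom, segments$start), required,
                       drop = FALSE]
  rownames(segments) <- NULL
  prof <- structure(list(sample_id = as.character(sample_id),
                         purity = as.numeric(purity),
                         ploidy = as.numeric(ploidy),
                         segments = segments),
                    class = "ascn_profile")
  validate_profile(prof, genome = genome)
}

#' Validate an allele-specific copy-number profile
#'
#' Checks the structural invariants: `start <= end`,
#' `major_cn >= minor_cn >= 0`, non-negative probe counts, purity in (0, 1],
#' positive ploidy, and no overlapping segments on a chromosome. With a
#' `genome`, additionally checks that every chromosome is known and that no
#' segment extends past the chromosome end.
#'
#' @inheritParams ascn_profile
#' @param profile An `ascn_profile`.
#' @return The profile, invisibly usable, unchanged.
#' @export
validate_profile <- function(profile, genome = NULL) {
  stopifnot(inherits(profile, "ascn_profile"))
  seg <- profile$segments
  id <- profile$sample_id
  if (!(profile$purity > 0 && profile$purity <= 1))
    stop("sample ", id, ": purity must be in (0, 1]")
  if (!(profile$ploidy > 0))
    stop("sample ", id, ": ploidy must be positive")
  bad <- which(seg$start > seg$end)
  if (length(bad) > 0)
    stop("sample ", id, ": start > end at row ", bad[1],
         " (chrom ", seg$chrom[bad[1]], ")")
  bad <- which(seg$minor_cn > seg$major_cn)
  if (length(bad) > 0)
    stop("sample ", id, ": minor_cn > major_cn at row ", bad[1],
         " (chrom ", seg$chrom[bad[1]], ")")
  bad <- which(seg$minor_cn < 0 | seg$n_probes < 0)
  if (length(bad) > 0)
    stop("sample ", id, ": negative copy number or probe count at row ",
         bad[1])
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("sample ", id, ": overlapping segments on chromosome ", ch)
    if (!is.null(genome)) {
      row <- .chrom_row(genome, ch)   # errors on unknown chromosome
      if (any(s$end > row$length) || any(s$start < 1))
        stop("sample ", id, ": segment outside chromosome ", ch,
             " bounds [1, ", row$length, "]")
    }
  }
  profile
}

#' @export
print.ascn_profile <- function(x, ...) {
  cat("ascn_profile:", x$sample_id, "-", nrow(x$segments), "segments,",
      "purity", x$purity, "ploidy", x$ploidy, "\n")
  invisible(x)
}

#' Merge adjacent segments with identical allele-specific state
#'
#' Consecutive segments on a chromosome are merged when they carry the same
#' `(major_cn, minor_cn)` state; probe counts are summed and the merged
#' segment spans from the first start to the last end. Idempotent. All
#' scoring engines operate on merged profiles, which makes every counter
#' invariant under splitting a segment into equal-state pieces.
#'
#' @param profile An `ascn_profile`.
#' @return An `ascn_profile` in which no two adjacent segments on a
#'   chromosome share their allele-specific state.
#' @export
merge_adjacent <- function(profile) {
  stopifnot(inherits(profile, "ascn_profile"))
  seg <- profile$segments
  if (nrow(seg) <= 1) return(profile)
  new_run <- c(TRUE, seg$chrom[-1] != seg$chrom[-nrow(seg)] |
                 seg$major_cn[-1] != seg$major_cn[-nrow(seg)] |
                 seg$minor_cn[-1] != seg$minor_cn[-nrow(seg)])
  grp <- cumsum(new_run)
  merged <- data.frame(
    chrom = tapply(seg$chrom, grp, `[`, 1),
    start = as.numeric(tapply(seg$start, grp, min)),
    end = as.numeric(tapply(seg$end, grp, max)),
    n_probes = as.numeric(tapply(seg$n_probes, grp, sum)),
    major_cn = as.numeric(tapply(seg$major_cn, grp, `[`, 1)),
    minor_cn = as.numeric(tapply(seg$minor_cn, grp, `[`, 1)),
    stringsAsFactors = FALSE
  )
  rownames(merged) <- NULL
  out <- profile
  out$segments <- merged
  out
}

.seg_len <- function(seg) seg$end - seg$start + 1

#' Read allele-specific copy-number profiles from a SEG-like file
#'
#' The file is tab-separated with header
#' `sample  chrom  start  end  n_probes  major_cn  minor_cn` (1-based
#' inclusive coordinates). Optional metadata lines of the form
#' `#meta<TAB>sample<TAB>purity<TAB>ploidy` carry per-sample purity and
#' ploidy; samples without a metadata line default to purity 1.0 and
#' ploidy 2.0.
#'
#' @param path Path to the segment file.
#' @param genome Optional `genome_build` used to validate chromosome names
#'   and bounds.
#' @return A named list of `ascn_profile` objects, one per sample, in order
#'   of first appearance.
#' @export
read_segments <- function(path, genome = NULL) {
  lines <- readLines(path)
  meta_idx <- grepl("^#meta\t", lines)
  comment_idx <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[meta_idx]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 4)
      stop("malformed #meta line: ", ln)
    meta[[parts[2]]] <- list(purity = as.numeric(parts[3]),
                             ploidy = as.numeric(parts[4]))
  }
  body <- lines[!comment_idx]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           header = TRUE, stringsAsFactors = FALSE,
                           colClasses = c(sample = "character",
                                          chrom = "character"))
  required <- c("sample", "chrom", "start", "end", "n_probes",
                "major_cn", "minor_cn")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("segment file lacks column(s): ", paste(missing, collapse = ", "))
  samples <- unique(tab$sample)
  profiles <- lapply(samples, function(sid) {
    m <- meta[[sid]]
    ascn_profile(sid, tab[tab$sample == sid, required[-1]],
                 purity = if (is.null(m)) 1.0 else m$purity,
                 ploidy = if (is.null(m)) 2.0 else m$ploidy,
                 genome = genome)
  })
  names(profiles) <- samples
  profiles
}

#' Write allele-specific copy-number profiles to a SEG-like file
#'
#' Deterministic inverse of [read_segments()]: one `#meta` line per sample
#' followed by the segment table in sample order, sorted by chromosome and
#' start within sample. Writing the same profiles twice yields
#' byte-identical files.
#'
#' @param profiles A list of `ascn_profile` objects (or a single profile).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "ascn_profile")) profiles <- list(profiles)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in profiles)
    writeLines(sprintf("#meta\t%s\t%s\t%s", p$sample_id,
                       format(p$purity, scientific = FALSE),
                       format(p$ploidy, scientific = FALSE)), con)
  header <- c("sample", "chrom", "start", "end", "n_probes",
              "major_cn", "minor_cn")
  writeLines(paste(header, collapse = "\t"), con)
  for (p in profiles) {
    seg <- p$segments
    if (nrow(seg) == 0) next
    writeLines(sprintf("%s\t%s\t%.0f\t%.0f\t%.0f\t%.0f\t%.0f",
                       p$sample_id, seg$chrom, seg$start, seg$end,
                       seg$n_probes, seg$major_cn, seg$minor_cn), con)
  }
  invisible(path)
}
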