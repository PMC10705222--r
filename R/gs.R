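# Genomic Scar (GS) feature engine: 27 length x site x type cells plus a
# genome-wide breakpoint count, scored linearly. The published model's
# coefficients are proprietary; the engine takes weights from config and
# defaults to unit weights, which preserves every structural property
# (partition, split-invariance, monotonicity) that the tests rely on.

.gs_lengths <- c("small", "middle", "large")
.gs_sites <- c("telomere", "centromere", "other")
.gs_types <- c("LOH", "allele_specific", "allele_balanced")

#' Canonical GS feature names
#'
#' The 28 feature names in canonical order: length class outer (small,
#' middle, large), site class middle (telomere, centromere, other), type
#' class inner (LOH, allele_specific, allele_balanced), then `breakpoints`.
#'
#' @return Character vector of length 28.
#' @export
gs_feature_names <- function() {
  cells <- as.vector(vapply(.gs_lengths, function(l)
    vapply(.gs_sites, function(s)
      paste(l, s, .gs_types, sep = "_"), character(3)), character(9)))
  c(cells, "breakpoints")
}

#' GS engine configuration
#'
#' @param weights Numeric vector of length 28 (canonical feature order, see
#'   [gs_feature_names()]). Default: unit weights.
#' @param intercept Added to the weighted feature sum. Default 0.
#' @param gs_threshold GI positivity threshold for the GS score; positive
#'   means `score >= gs_threshold`. Default 50.
#' @param min_len Segments shorter than this are not classified into a
#'   feature cell (they still contribute to the breakpoint count). Default
#'   5 Mb, the lower bound of the smallest length class.
#' @return A list of class `gs_config`.
#' @export
gs_config <- function(weights = rep(1, 28), intercept = 0,
                      gs_threshold = 50, min_len = 5e6) {
  if (length(weights) != 28)
    stop("GS weight vector must have length 28, got ", length(weights))
  structure(list(weights = as.numeric(weights),
                 intercept = as.numeric(intercept),
                 gs_threshold = gs_threshold, min_len = min_len),
            class = "gs_config")
}

#' Classify one merged segment into the GS length/site/type grid
#'
#' Length class by segment span: small = \[5, 10) Mb, middle = \[10, 15\]
#' Mb, large = > 15 Mb; shorter than `min_len` is ineligible. Site class:
#' `telomere` if the segment contains a chromosome-terminal position (this
#' wins for whole-chromosome segments), else `centromere` if it overlaps
#' the centromere interval, else `other`. Type class: `LOH` when
#' `minor = 0, major >= 1`; `allele_specific` when `major != minor` with
#' `minor >= 1`; `allele_balanced` when `major = minor` with total copy
#' number not 2. The diploid reference state 1+1 and homozygous deletions
#' 0+0 are not copy-number events and are ineligible.
#'
#' @param segment One-row data frame (or list) with `chrom`, `start`,
#'   `end`, `major_cn`, `minor_cn`.
#' @param genome A `genome_build`.
#' @param config A [gs_config()].
#' @return A list `(length_class, site_class, type_class)`, or `NULL` when
#'   the segment is ineligible.
#' @export
classify_segment <- function(segment, genome, config = gs_config()) {
  major <- segment$major_cn
  minor <- segment$minor_cn
  type <- if (minor == 0 && major >= 1) "LOH"
    else if (major != minor && minor >= 1) "allele_specific"
    else if (major == minor && major >= 2) "allele_balanced"
    else NULL                                    # 1+1 or 0+0
  if (is.null(type)) return(NULL)
  len <- segment$end - segment$start + 1
  if (len < config$min_len) return(NULL)
  length_class <- if (len > 15e6) "large"
    else if (len >= 10e6) "middle"
    else "small"
  row <- .chrom_row(genome, segment$chrom)
  site_class <- if (segment$start == 1 || segment$end == row$length)
    "telomere"
  else if (segment$start <= row$cen_end && segment$end >= row$cen_start)
    "centromere"
  else "other"
  list(length_class = length_class, site_class = site_class,
       type_class = type)
}

#' Count breakpoints genome-wide
#'
#' Number of junctions between consecutive merged segments within each
#' chromosome, summed over chromosomes. The profile is merged first, so the
#' count is invariant under equal-state segment splitting.
#'
#' @param profile An `ascn_profile`.
#' @return Integer breakpoint count.
#' @export
count_breakpoints <- function(profile) {
  seg <- merge_adjacent(profile)$segments
  if (nrow(seg) == 0) return(0L)
  sum(vapply(unique(seg$chrom),
             function(ch) sum(seg$chrom == ch) - 1L, integer(1)))
}

#' Compute the 28-dimensional GS feature vector
#'
#' Merges the profile, classifies every eligible merged segment into
#' exactly one of the 27 length x site x type cells, and appends the
#' genome-wide breakpoint count.
#'
#' @param profile An `ascn_profile`.
#' @param genome A `genome_build`.
#' @param config A [gs_config()].
#' @return Named numeric vector of length 28 in canonical order, with
#'   class `gs_features`.
#' @examples
#' gb <- load_genome("toy3")
#' prof <- ascn_profile("s1", data.frame(
#'   chrom = "1", start = c(1, 20e6 + 1), end = c(20e6, 100e6),
#'   n_probes = c(1000, 4000), major_cn = c(2, 1), minor_cn = c(0, 1)))
#' gs_features(prof, gb)[["large_telomere_LOH"]]   # 1
#' @export
gs_features <- function(profile, genome, config = gs_config()) {
  merged <- merge_adjacent(validate_profile(profile, genome))
  seg <- merged$segments
  counts <- stats::setNames(numeric(28), gs_feature_names())
  for (i in seq_len(nrow(seg))) {
    cls <- classify_segment(seg[i, ], genome, config)
    if (is.null(cls)) next
    cell <- paste(cls$length_class, cls$site_class, cls$type_class,
                  sep = "_")
    counts[cell] <- counts[cell] + 1
  }
  counts["breakpoints"] <- count_breakpoints(merged)
  structure(counts, class = c("gs_features", "numeric"))
}

#' GS score and status from a feature vector
#'
#' Linear model: `score = intercept + weights . features` in canonical
#' feature order; status is positive when the score reaches the threshold
#' (greater than or equal).
#'
#' @param features Numeric vector of length 28 (as from [gs_features()]).
#' @param config A [gs_config()].
#' @return List with `gs_score` and `gi_status`.
#' @export
gs_score <- function(features, config = gs_config()) {
  if (length(features) != length(config$weights))
    stop("feature vector length ", length(features),
         " does not match weight vector length ", length(config$weights))
  score <- config$intercept + sum(config$weights * as.numeric(features))
  list(gs_score = score,
       gi_status = ifelse(score >= config$gs_threshold,
                          "positive", "negative"))
}

#' Score many profiles with the GS engine
#'
#' @param profiles List of `ascn_profile` objects.
#' @inheritParams gs_features
#' @return Data frame: `sample`, the 28 feature columns in canonical
#'   order, `gs_score`, `gi_status`.
#' @export
gs_score_profiles <- function(profiles, genome, config = gs_config()) {
  rows <- lapply(profiles, function(p) {
    f <- gs_features(p, genome, config)
    s <- gs_score(f, config)
    cbind(data.frame(sample = p$sample_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(f))),
          data.frame(gs_score = s$gs_score, gi_status = s$gi_status,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
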