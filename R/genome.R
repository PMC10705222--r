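#' @keywords internal
"_PACKAGE"

# hg19 autosome geometry: UCSC chromosome lengths and centromere gap
# intervals (gap table, converted to 1-based inclusive coordinates).
# Sex chromosomes are excluded: scoring uses autosomal markers only.
.hg19_chromosomes <- data.frame(
  chrom = as.character(1:22),
  length = c(249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
             171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
             135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
             90354753L, 81195210L, 78077248L, 59128983L, 63025520L,
             48129895L, 51304566L),
  cen_start = c(121535435L, 92326172L, 90504855L, 49660118L, 46405642L,
                58830167L, 58054332L, 43838888L, 47367680L, 39254936L,
                51644206L, 34856695L, 16000001L, 16000001L, 17000001L,
                35335802L, 22263007L, 15460899L, 24681783L, 26369570L,
                11288130L, 13000001L),
  cen_end = c(124535434L, 95326171L, 93504854L, 52660117L, 49405641L,
              61830166L, 61054331L, 46838887L, 50367679L, 42254935L,
              54644205L, 37856694L, 19000000L, 19000000L, 20000000L,
              38335801L, 25263006L, 18460898L, 27681782L, 29369569L,
              14288129L, 16000000L),
  stringsAsFactors = FALSE
)

.toy3_chromosomes <- data.frame(
  chrom = c("1", "2", "3"),
  length = rep(100e6, 3),
  cen_start = rep(45e6, 3),
  cen_end = rep(55e6, 3),
  stringsAsFactors = FALSE
)

.validate_chrom_table <- function(tab) {
  required <- c("chrom", "length", "cen_start", "cen_end")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("chromosome table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyNA(tab[required]))
    stop("chromosome table contains missing values (check centromere columns) for chromosome(s): ",
         paste(tab$chrom[!stats::complete.cases(tab[required])], collapse = ", "))
  if (anyDuplicated(tab$chrom))
    stop("duplicated chromosome name(s): ",
         paste(unique(tab$chrom[duplicated(tab$chrom)]), collapse = ", "))
  bad <- !(tab$cen_start > 0 & tab$cen_start < tab$cen_end &
             tab$cen_end < tab$length)
  if (any(bad))
    stop("invalid geometry (need 0 < cen_start < cen_end < length) for chromosome(s): ",
         paste(tab$chrom[bad], collapse = ", "))
  invisible(tab)
}

#' Load a genome build for scar scoring
#'
#' Returns the chromosome geometry (lengths and centromere intervals) used by
#' the scoring engines. Two builds are packaged: `"hg19"`, the 22 human
#' autosomes with UCSC lengths and centromere gap intervals (sex chromosomes
#' are excluded because genomic-instability scoring uses autosomal markers
#' only), and `"toy3"`, a three-chromosome test genome in which every
#' chromosome is 100 Mb with its centromere at \[45 Mb, 55 Mb\]. Any other
#' value is treated as a path to a tab-separated chromosome table with header
#' `chrom`, `length`, `cen_start`, `cen_end` (1-based inclusive coordinates).
#'
#' @param build_name `"hg19"`, `"toy3"`, or a path to a chromosome-table file.
#' @return A `genome_build` object: a list with `build_name` and a
#'   `chromosomes` data frame (`chrom`, `length`, `cen_start`, `cen_end`), in
#'   stable chromosome order.
#' @examples
#' gb <- load_genome("toy3")
#' arm_intervals(gb, "1")
#' @export
load_genome <- function(build_name) {
  stopifnot(is.character(build_name), length(build_name) == 1)
  if (build_name == "hg19") {
    tab <- .hg19_chromosomes
  } else if (build_name == "toy3") {
    tab <- .toy3_chromosomes
  } else if (file.exists(build_name)) {
    tab <- utils::read.delim(build_name, header = TRUE,
                             colClasses = c(chrom = "character"),
                             stringsAsFactors = FALSE)
  } else {
    stop("unknown genome build or missing file: ", build_name)
  }
  .validate_chrom_table(tab)
  structure(list(build_name = build_name,
                 chromosomes = tab[c("chrom", "length", "cen_start", "cen_end")]),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", x$build_name, "-", nrow(x$chromosomes),
      "chromosomes\n")
  invisible(x)
}

.chrom_row <- function(genome, chrom) {
  i <- match(as.character(chrom), genome$chromosomes$chrom)
  if (is.na(i))
    stop("unknown chromosome '", chrom, "' in build ", genome$build_name)
  genome$chromosomes[i, ]
}

#' Chromosome arm intervals
#'
#' The p arm is \[1, cen_start - 1\] and the q arm is
#' \[cen_end + 1, length\], both 1-based inclusive, so the two arms and the
#' centromere partition the chromosome.
#'
#' @param build A `genome_build` from [load_genome()].
#' @param chrom Chromosome label present in the build.
#' @return A list with numeric length-2 vectors `p` and `q` (start, end).
#' @export
arm_intervals <- function(build, chrom) {
  row <- .chrom_row(build, chrom)
  list(p = c(1, row$cen_start - 1),
       q = c(row$cen_end + 1, row$length))
}
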