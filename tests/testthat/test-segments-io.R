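test_that("profile validation enforces the segment invariants", {
  expect_error(mk_profile(list(c("1", 10, 5, 10, 1, 1))), "start > end")
  expect_error(mk_profile(list(c("1", 1, 10e6, 10, 1, 2))),
               "minor_cn > major_cn")
  expect_error(mk_profile(list(c("1", 1, 10e6, 10, 2, 1),
                               c("1", 5e6, 20e6, 10, 1, 1))),
               "overlapping")
  gb <- toy_genome()
  expect_error(
    ascn_profile("s", data.frame(chrom = "7", start = 1, end = 10,
                                 n_probes = 1, major_cn = 1, minor_cn = 1),
                 genome = gb),
    "unknown chromosome")
  expect_error(
    ascn_profile("s", data.frame(chrom = "1", start = 1, end = 200e6,
                                 n_probes = 1, major_cn = 1, minor_cn = 1),
                 genome = gb),
    "outside chromosome")
})

test_that("segment files round-trip and preserve counts and metadata", {
  p1 <- mk_profile(list(c("1", 1, 40e6, 100, 2, 1),
                        c("1", 40e6 + 1, 100e6, 200, 1, 1),
                        c("2", 1, 100e6, 300, 2, 0)),
                   sample_id = "A", purity = 0.62, ploidy = 3.1)
  p2 <- mk_profile(list(c("2", 1, 50e6, 10, 1, 0),
                        c("2", 50e6 + 1, 100e6, 10, 1, 1),
                        c("3", 1, 100e6, 10, 2, 2)),
                   sample_id = "B")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(list(p1, p2), path)
  back <- read_segments(path, genome = toy_genome())
  expect_named(back, c("A", "B"))
  expect_equal(vapply(back, function(p) nrow(p$segments), integer(1)),
               c(A = 3L, B = 3L))
  expect_equal(back$A$purity, 0.62)
  expect_equal(back$A$ploidy, 3.1)
  expect_equal(back$B$purity, 1.0)
  expect_equal(back$A$segments, p1$segments)
  expect_equal(back$B$segments, p2$segments)
  # repeated writes are byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_segments(list(p1, p2), path2)
  expect_identical(readLines(path), readLines(path2))
  # write after read is identity at the file level too
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_segments(back, path3)
  expect_identical(readLines(path), readLines(path3))
})

test_that("an empty profile collection writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(list(), path)
  expect_equal(readLines(path),
               "sample\tchrom\tstart\tend\tn_probes\tmajor_cn\tminor_cn")
})

test_that("merge_adjacent collapses equal states and is idempotent", {
  p <- mk_profile(list(c("1", 1, 10e6, 10, 1, 1),
                       c("1", 10e6 + 1, 30e6, 20, 1, 1),
                       c("1", 30e6 + 1, 60e6, 30, 2, 1)))
  m <- merge_adjacent(p)
  expect_equal(nrow(m$segments), 2)
  expect_equal(m$segments$end[1], 30e6)
  expect_equal(m$segments$n_probes[1], 30)
  expect_equal(merge_adjacent(m)$segments, m$segments)
  # major >= minor storage: equal ordered states always merge
  p2 <- mk_profile(list(c("1", 1, 10e6, 10, 2, 1),
                        c("1", 10e6 + 1, 30e6, 20, 2, 1)))
  expect_equal(nrow(merge_adjacent(p2)$segments), 1)
})

test_that("the packaged call table matches the published cohort structure", {
  calls <- assay_call_fixture()
  expect_equal(nrow(calls), 50)
  expect_equal(sum(calls$oncoscan_gi != "missing"), 43)
  expect_equal(sum(calls$low_tcc_excluded), 4)
  expect_equal(sum(calls$myriad_hrd == "positive"), 28)
  expect_equal(sum(calls$myriad_gi == "inconclusive"), 4)
  expect_equal(sum(calls$myriad_hrd == "inconclusive"), 2)
  expect_equal(calls$sample_id[calls$low_tcc_excluded],
               c("11", "30", "31", "40"))
  expect_equal(calls$sample_id[calls$myriad_gi == "inconclusive"],
               c("17", "29", "41", "44"))
})

test_that("call-table tokens are normalized and bad tokens rejected with location", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,Myriad_HRD,Amoy_HRD,Myriad_GI,Amoy_GI,OncoScan_GI,Myriad_BRCA,Amoy_BRCA",
               "1,POSITIVE,negative*,Inconclusive,positive,-,YES,no"), path)
  tab <- read_call_table(path)
  expect_equal(tab$myriad_hrd, "positive")
  expect_equal(tab$amoy_hrd, "negative")
  expect_equal(tab$oncoscan_gi, "missing")
  expect_true(tab$low_tcc_excluded)
  writeLines(c("ID,Myriad_HRD,Amoy_HRD,Myriad_GI,Amoy_GI,OncoScan_GI,Myriad_BRCA,Amoy_BRCA",
               "1,Positive,Negative,Perhaps,Positive,-,Yes,No"), path)
  expect_error(read_call_table(path), "'Perhaps' at row 1, column Myriad_GI")
})
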