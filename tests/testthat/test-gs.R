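gb <- toy_genome()

test_that("segment classification follows the length/site/type grid", {
  cls <- function(chrom, start, end, maj, mnr)
    classify_segment(list(chrom = chrom, start = start, end = end,
                          major_cn = maj, minor_cn = mnr), gb)
  # 20 Mb 2+0 touching position 1
  expect_equal(cls("1", 1, 20e6, 2, 0),
               list(length_class = "large", site_class = "telomere",
                    type_class = "LOH"))
  # 7 Mb interior 2+2
  expect_equal(cls("1", 20e6, 27e6 - 1, 2, 2),
               list(length_class = "small", site_class = "other",
                    type_class = "allele_balanced"))
  # diploid reference state and homozygous deletions are not CNV events
  expect_null(cls("1", 10e6, 22e6, 1, 1))
  expect_null(cls("1", 10e6, 22e6, 0, 0))
  # below 5 Mb is ineligible
  expect_null(cls("1", 10e6, 10e6 + 4e6 - 1, 2, 1))
  # length boundaries: 5 Mb -> small, 10 and 15 Mb -> middle, >15 -> large
  expect_equal(cls("1", 20e6, 20e6 + 5e6 - 1, 2, 1)$length_class, "small")
  expect_equal(cls("1", 20e6, 20e6 + 10e6 - 1, 2, 1)$length_class, "middle")
  expect_equal(cls("1", 1e6, 1e6 + 15e6 - 1, 2, 1)$length_class, "middle")
  expect_equal(cls("1", 1e6, 1e6 + 15e6, 2, 1)$length_class, "large")
  # centromere overlap; telomere contact wins for whole-chromosome spans
  expect_equal(cls("1", 40e6, 60e6, 2, 1)$site_class, "centromere")
  expect_equal(cls("1", 1, 100e6, 2, 1)$site_class, "telomere")
  # allele-specific requires a retained minor allele
  expect_equal(cls("1", 20e6, 40e6, 3, 1)$type_class, "allele_specific")
  expect_equal(cls("1", 20e6, 40e6, 3, 3)$type_class, "allele_balanced")
})

test_that("feature extraction partitions eligible segments and counts breakpoints", {
  diploid <- mk_profile(list(c("1", 1, 100e6, 100, 1, 1),
                             c("2", 1, 100e6, 100, 1, 1),
                             c("3", 1, 100e6, 100, 1, 1)))
  f <- gs_features(diploid, gb)
  expect_true(all(f == 0))
  one <- mk_profile(list(c("1", 1, 20e6, 100, 2, 0),
                         c("1", 20e6 + 1, 100e6, 100, 1, 1)))
  f1 <- gs_features(one, gb)
  expect_equal(as.numeric(f1[["large_telomere_LOH"]]), 1)
  expect_equal(as.numeric(f1[["breakpoints"]]), 1)
  expect_equal(sum(f1), 2)
  # sub-5 Mb segments add breakpoints but no cell
  tiny <- mk_profile(list(c("1", 1, 48e6, 100, 1, 1),
                          c("1", 48e6 + 1, 52e6, 10, 2, 1),
                          c("1", 52e6 + 1, 100e6, 100, 1, 1)))
  ft <- gs_features(tiny, gb)
  expect_equal(as.numeric(ft[["breakpoints"]]), 2)
  expect_equal(sum(ft[setdiff(names(ft), "breakpoints")]), 0)
})

test_that("breakpoint counting merges first and sums per chromosome", {
  p <- mk_profile(list(c("1", 1, 30e6, 100, 1, 1),
                       c("1", 30e6 + 1, 60e6, 100, 2, 1),
                       c("1", 60e6 + 1, 100e6, 100, 1, 1),
                       c("2", 1, 100e6, 100, 1, 1)))
  expect_equal(count_breakpoints(p), 2)
  expect_equal(count_breakpoints(split_segments(p, 3)), 2)
  single <- mk_profile(list(c("1", 1, 100e6, 100, 2, 0)))
  expect_equal(count_breakpoints(single), 0)
})

test_that("the GS score is linear with the inclusive threshold at 50", {
  f49 <- setNames(c(rep(0, 27), 49), gs_feature_names())
  expect_equal(gs_score(f49)$gi_status, "negative")
  f50 <- setNames(c(1, rep(0, 26), 49), gs_feature_names())
  s <- gs_score(f50)
  expect_equal(s$gs_score, 50)
  expect_equal(s$gi_status, "positive")
  # intercept dominates zero weights
  cfg <- gs_config(weights = rep(0, 28), intercept = 60)
  expect_equal(gs_score(f49, cfg)$gi_status, "positive")
  expect_error(gs_score(rep(0, 27)), "length")
  # unit-weight monotonicity in every feature
  base <- setNames(rep(1, 28), gs_feature_names())
  s0 <- gs_score(base)$gs_score
  for (i in 1:28) {
    bumped <- base; bumped[i] <- bumped[i] + 1
    expect_gt(gs_score(bumped)$gs_score, s0)
  }
})

test_that("GS features equal the literal classification oracle on random profiles", {
  for (seed in 1:60) {
    p <- random_profile(seed + 500)
    expect_equal(unclass(gs_features(p, gb)), oracle_gs_features(p, gb),
                 info = paste("seed", seed))
  }
})

test_that("GS features are invariant under equal-state splitting", {
  for (seed in 1:20) {
    p <- random_profile(seed + 900)
    expect_equal(unclass(gs_features(split_segments(p, seed), gb)),
                 unclass(gs_features(p, gb)), info = paste("seed", seed))
  }
})
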