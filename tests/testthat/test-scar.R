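gb <- toy_genome()

test_that("chromosome ploidy follows majority length with the stated tie rules", {
  p <- mk_profile(list(c("1", 1, 90e6, 100, 2, 1),
                       c("1", 90e6 + 1, 100e6, 10, 1, 1)))
  expect_equal(chromosome_ploidy(p, "1"), 3L)
  p2 <- mk_profile(list(c("1", 1, 100e6, 100, 1, 1)))
  expect_equal(chromosome_ploidy(p2, "1"), 2L)
  # 50/50 tie between totals 2 and 4 with ploidy 2 -> 2
  p3 <- mk_profile(list(c("1", 1, 50e6, 100, 1, 1),
                        c("1", 50e6 + 1, 100e6, 100, 2, 2)))
  expect_equal(chromosome_ploidy(p3, "1"), 2L)
  # tie equidistant from ploidy 3 -> lower total wins
  p4 <- mk_profile(list(c("1", 1, 50e6, 100, 1, 1),
                        c("1", 50e6 + 1, 100e6, 100, 2, 2)),
                   ploidy = 3)
  expect_equal(chromosome_ploidy(p4, "1"), 2L)
  expect_error(chromosome_ploidy(p4, "2"), "no segments")
})

test_that("TAI counting applies all four rule conditions", {
  base <- function(end1, probes1, state = c(2, 1)) mk_profile(list(
    c("1", 1, end1, probes1, state[1], state[2]),
    c("1", end1 + 1, 100e6, 4000, 1, 1)))
  # terminal, >11 Mb, enough probes, clear of centromere -> 1
  expect_equal(count_tai(base(12e6, 200), gb), 1)
  # exactly 10 Mb: not longer than 11 Mb -> 0
  expect_equal(count_tai(base(10e6, 200), gb), 0)
  # 12 Mb but only 100 probes: below the 126-probe array minimum -> 0
  expect_equal(count_tai(base(12e6, 100), gb), 0)
  # crosses the centromere -> 0
  p <- mk_profile(list(c("1", 1, 39e6, 100, 1, 1),
                       c("1", 39e6 + 1, 60e6, 300, 2, 1),
                       c("1", 60e6 + 1, 100e6, 100, 1, 1)))
  expect_equal(count_tai(p, gb), 0)
  # interior AI region does not reach a terminus -> 0
  p2 <- mk_profile(list(c("1", 1, 5e6, 100, 1, 1),
                        c("1", 5e6 + 1, 25e6, 300, 2, 1),
                        c("1", 25e6 + 1, 100e6, 100, 1, 1)))
  expect_equal(count_tai(p2, gb), 0)
  # q-terminal counts too; both termini on one chromosome -> 2
  p3 <- mk_profile(list(c("1", 1, 13e6, 300, 2, 1),
                        c("1", 13e6 + 1, 80e6, 100, 1, 1),
                        c("1", 80e6 + 1, 100e6, 400, 3, 1)))
  expect_equal(count_tai(p3, gb), 2)
})

test_that("TAI runs merge across adjacent distinct imbalance states", {
  # 6 Mb of 2+1 then 7 Mb of 3+1: one 13 Mb terminal AI run
  p <- mk_profile(list(c("1", 1, 6e6, 300, 2, 1),
                       c("1", 6e6 + 1, 13e6, 350, 3, 1),
                       c("1", 13e6 + 1, 100e6, 4000, 1, 1)))
  expect_equal(count_tai(p, gb), 1)
})

test_that("LOH counting requires length, a retained allele, and sub-chromosomal extent", {
  mid <- function(state, len) mk_profile(list(
    c("1", 1, 60e6, 100, 1, 1),
    c("1", 60e6 + 1, 60e6 + len, 200, state[1], state[2]),
    c("1", 60e6 + len + 1, 100e6, 100, 1, 1)))
  expect_equal(count_loh(mid(c(2, 0), 20e6), gb), 1)
  expect_equal(count_loh(mid(c(1, 0), 10e6), gb), 0)   # below 15 Mb
  expect_equal(count_loh(mid(c(0, 0), 20e6), gb), 0)   # no retained allele
  # whole-chromosome LOH is excluded
  whole <- mk_profile(list(c("1", 1, 100e6, 1000, 2, 0)))
  expect_equal(count_loh(whole, gb), 0)
  expect_equal(oracle_loh(whole, gb), 0)
  # 2+0 next to 1+0 merge into a single LOH run, counted once
  p <- mk_profile(list(c("1", 1, 40e6, 100, 1, 1),
                       c("1", 40e6 + 1, 50e6 - 5e6, 100, 2, 0),
                       c("1", 50e6 - 5e6 + 1, 62e6, 100, 1, 0),
                       c("1", 62e6 + 1, 100e6, 100, 1, 1)))
  expect_equal(count_loh(p, gb), 1)
})

test_that("LST counting smooths short segments and requires long flanks", {
  # 30 Mb 1+1 then 15 Mb 2+1 on the p arm -> 1 junction
  p <- mk_profile(list(c("1", 1, 30e6, 100, 1, 1),
                       c("1", 30e6 + 1, 44.9e6, 200, 2, 1),
                       c("1", 44.9e6 + 1, 100e6, 100, 1, 1)))
  expect_equal(count_lst(p, gb), 1)
  # right-hand segment below 10 Mb -> 0
  p2 <- mk_profile(list(c("1", 1, 40e6, 100, 1, 1),
                        c("1", 40e6 + 1, 44.9e6, 200, 2, 1),
                        c("1", 44.9e6 + 1, 100e6, 100, 1, 1)))
  expect_equal(count_lst(p2, gb), 0)
  # a 2 Mb interruption is smoothed away and the flanks merge -> 0
  p3 <- mk_profile(list(c("1", 1, 20e6, 100, 1, 1),
                        c("1", 20e6 + 1, 22e6, 10, 2, 2),
                        c("1", 22e6 + 1, 44e6, 100, 1, 1),
                        c("1", 44e6 + 1, 100e6, 100, 1, 1)))
  expect_equal(count_lst(p3, gb), 0)
  expect_equal(oracle_lst(p3, gb), 0)
  # junctions are counted per arm: a state switch across the centromere
  # is not an LST
  p4 <- mk_profile(list(c("1", 1, 50e6, 100, 1, 1),
                        c("1", 50e6 + 1, 100e6, 100, 2, 1)))
  expect_equal(count_lst(p4, gb), 0)
})

test_that("GI score is the component sum with the configurable threshold rule", {
  p <- mk_profile(list(c("1", 1, 12e6, 600, 2, 1),
                       c("1", 12e6 + 1, 100e6, 4000, 1, 1),
                       c("2", 1, 60e6, 100, 1, 1),
                       c("2", 60e6 + 1, 80e6, 200, 2, 0),
                       c("2", 80e6 + 1, 100e6, 100, 1, 1)))
  s <- score_profile(p, gb)
  expect_equal(s$gi_score, s$loh_count + s$tai_count + s$lst_count)
  expect_equal(s$loh_count, 1)
  expect_equal(s$tai_count, 1)
  expect_equal(s$gi_status, "negative")
  # threshold comparator: 42 is positive inclusively, negative strictly
  expect_equal(gi_status(42, scar_config()), "positive")
  expect_equal(gi_status(42, scar_config(threshold_inclusive = FALSE)),
               "negative")
  expect_equal(gi_status(43, scar_config(threshold_inclusive = FALSE)),
               "positive")
  expect_equal(gi_status(0, scar_config()), "negative")
})

test_that("all scar counters equal their brute-force oracles on random profiles", {
  cfg <- scar_config()
  for (seed in 1:100) {
    p <- random_profile(seed)
    expect_equal(count_tai(p, gb, cfg), oracle_tai(p, gb, cfg),
                 info = paste("tai seed", seed))
    expect_equal(count_loh(p, gb, cfg), oracle_loh(p, gb, cfg),
                 info = paste("loh seed", seed))
    expect_equal(count_lst(p, gb, cfg), oracle_lst(p, gb, cfg),
                 info = paste("lst seed", seed))
  }
})

test_that("scar counters are invariant under equal-state segment splitting", {
  for (seed in 1:25) {
    p <- random_profile(seed)
    s <- score_profile(p, gb)
    sp <- score_profile(split_segments(p, seed + 1000), gb)
    expect_equal(sp$loh_count, s$loh_count, info = paste("seed", seed))
    expect_equal(sp$tai_count, s$tai_count, info = paste("seed", seed))
    expect_equal(sp$lst_count, s$lst_count, info = paste("seed", seed))
  }
})

test_that("adding a disjoint qualifying TAI region never decreases the score", {
  for (seed in 1:10) {
    p <- random_profile(seed, max_seg_chrom = 3)
    seg <- p$segments
    # replace chromosome 3 entirely: plant a clean q-terminal TAI there
    seg <- seg[seg$chrom != "3", ]
    seg <- rbind(seg,
                 data.frame(chrom = "3", start = 1, end = 80e6,
                            n_probes = 100, major_cn = 1, minor_cn = 1),
                 data.frame(chrom = "3", start = 80e6 + 1, end = 100e6,
                            n_probes = 1000, major_cn = 2, minor_cn = 1))
    base <- p$segments[p$segments$chrom != "3", ]
    base <- rbind(base,
                  data.frame(chrom = "3", start = 1, end = 100e6,
                             n_probes = 1100, major_cn = 1, minor_cn = 1))
    with_tai <- ascn_profile("w", seg)
    without <- ascn_profile("wo", base)
    expect_gte(count_tai(with_tai, gb), count_tai(without, gb) + 1)
    expect_gte(score_profile(with_tai, gb)$gi_score,
               score_profile(without, gb)$gi_score)
  }
})
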