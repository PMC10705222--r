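# Synthetic data: (a) allele-specific copy-number profiles with planted
# scar events (TAI / LOH / LST) at controllable rates, for validating the
# scoring engines; (b) multi-assay call tables with controllable
# misclassification, for validating the concordance estimators by
# parameter recovery.

# derive a per-element sub-seed from a global seed (counter mode), so
# cohorts are reproducible element-wise under insertion/removal
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

# event geometry: each event occupies one chromosome arm; lengths are the
# rule minimum plus an exponential excess, so near-threshold cases occur
.draw_len <- function(min_len, max_len, length_scale) {
  min_len + 1 + min(stats::rexp(1, 1 / length_scale), max_len - min_len - 1)
}

#' Simulate one tumor's allele-specific copy-number profile
#'
#' Starts from an all-diploid (1+1) genome covering every chromosome end to
#' end, then plants a Poisson-distributed number of scar-generating events,
#' one per chromosome arm, chosen by `event_mix`:
#' * TAI-type: a terminal allelic-imbalance block (2+1) at the telomeric
#'   end of an arm, longer than the TAI rule minimum and clear of the
#'   centromere;
#' * LOH-type: an interior copy-neutral-LOH block (major 1 or 2, minor 0)
#'   longer than the LOH rule minimum, touching neither the terminus nor
#'   the centromere;
#' * LST-type: a distal allele-balanced block (2+2) producing exactly one
#'   junction between two segments of at least the LST rule minimum (a
#'   balanced state is used so the junction is counted only by the LST
#'   rule, not by TAI or LOH).
#'
#' Event lengths are the rule minimum plus an exponential excess with mean
#' `length_scale` (capped by the arm), so boundary-length cases arise with
#' positive probability. Probe counts are proportional to segment length.
#' Deterministic for a fixed seed.
#'
#' @param genome A `genome_build`.
#' @param class_label `"hrd_pos"` or `"hrd_neg"`; sets the default
#'   `event_rate` (25 and 5 events respectively) when `event_rate` is NULL.
#' @param event_rate Mean number of planted events (Poisson).
#' @param event_mix Probabilities over `c(loh, tai, lst)` event types.
#' @param length_scale Mean exponential excess length in bp.
#' @param probe_density Probes per Mb.
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return An `ascn_profile`; its `"events"` attribute is a data frame of
#'   the planted events (`type`, `chrom`, `start`, `end`) for auditing.
#' @examples
#' gb <- load_genome("hg19")
#' p <- simulate_profile(gb, "hrd_pos", seed = 7)
#' score_profile(p, gb)$gi_score
#' @export
simulate_profile <- function(genome, class_label = c("hrd_neg", "hrd_pos"),
                             event_rate = NULL,
                             event_mix = c(loh = 0.4, tai = 0.3, lst = 0.3),
                             length_scale = 5e6, probe_density = 50,
                             seed = 1, sample_id = "sim") {
  class_label <- match.arg(class_label)
  if (is.null(event_rate))
    event_rate <- if (class_label == "hrd_pos") 25 else 5
  stopifnot(event_rate >= 0, length_scale > 0, probe_density > 0,
            abs(sum(event_mix) - 1) < 1e-8, all(event_mix >= 0))
  set.seed(seed)
  cfg <- scar_config()
  n_events <- stats::rpois(1, event_rate)
  # candidate arms with enough room for the most demanding event
  arms <- list()
  for (ch in genome$chromosomes$chrom) {
    ai <- arm_intervals(genome, ch)
    for (a in c("p", "q"))
      arms[[paste0(ch, a)]] <- list(chrom = ch, arm = a,
                                    start = ai[[a]][1], end = ai[[a]][2],
                                    len = ai[[a]][2] - ai[[a]][1] + 1)
  }
  # minimum free arm length per event type (event + clearances)
  min_arm <- c(loh = cfg$loh_min_len + 4e6,
               tai = cfg$tai_min_len + 3e6,
               lst = 2 * cfg$lst_min_seg + 2e6)
  events <- list()
  free <- names(arms)
  for (k in seq_len(n_events)) {
    type <- sample(names(event_mix), 1, prob = event_mix)
    ok <- free[vapply(free, function(nm) arms[[nm]]$len >= min_arm[[type]],
                      logical(1))]
    if (length(ok) == 0)
      stop("genome too small for the requested number of events (placed ",
           k - 1, " of ", n_events, ")")
    nm <- if (length(ok) == 1) ok else sample(ok, 1)
    arm <- arms[[nm]]
    free <- setdiff(free, nm)
    ev <- switch(type,
      tai = {
        len <- .draw_len(cfg$tai_min_len, arm$len - 2e6, length_scale)
        if (arm$arm == "p")
          list(start = arm$start, end = arm$start + len - 1,
               major = 2, minor = 1)
        else
          list(start = arm$end - len + 1, end = arm$end,
               major = 2, minor = 1)
      },
      loh = {
        len <- .draw_len(cfg$loh_min_len, arm$len - 3e6, length_scale)
        lo <- arm$start + 1e6
        hi <- arm$end - 1e6 - len
        s <- floor(stats::runif(1, lo, hi + 1))
        list(start = s, end = s + len - 1,
             major = sample(1:2, 1), minor = 0)
      },
      lst = {
        len <- .draw_len(cfg$lst_min_seg, arm$len - cfg$lst_min_seg - 1e6,
                         length_scale)
        if (arm$arm == "p")
          list(start = arm$start, end = arm$start + len - 1,
               major = 2, minor = 2)
        else
          list(start = arm$end - len + 1, end = arm$end,
               major = 2, minor = 2)
      })
    ev$chrom <- arm$chrom
    ev$type <- type
    events[[length(events) + 1]] <- ev
  }
  # assemble contiguous segments: 1+1 background spliced around events
  seg_rows <- list()
  for (ch in genome$chromosomes$chrom) {
    L <- .chrom_row(genome, ch)$length
    evs <- Filter(function(e) e$chrom == ch, events)
    evs <- evs[order(vapply(evs, `[[`, numeric(1), "start"))]
    pos <- 1
    for (e in evs) {
      if (e$start > pos)
        seg_rows[[length(seg_rows) + 1]] <-
          data.frame(chrom = ch, start = pos, end = e$start - 1,
                     major_cn = 1, minor_cn = 1)
      seg_rows[[length(seg_rows) + 1]] <-
        data.frame(chrom = ch, start = e$start, end = e$end,
                   major_cn = e$major, minor_cn = e$minor)
      pos <- e$end + 1
    }
    if (pos <= L)
      seg_rows[[length(seg_rows) + 1]] <-
        data.frame(chrom = ch, start = pos, end = L,
                   major_cn = 1, minor_cn = 1)
  }
  seg <- do.call(rbind, seg_rows)
  seg$n_probes <- pmax(1, round((seg$end - seg$start + 1) / 1e6 *
                                  probe_density))
  out <- ascn_profile(sample_id, seg, purity = 1.0, ploidy = 2.0,
                      genome = genome)
  # planted-event audit trail: what was planted, where
  attr(out, "events") <- if (length(events) == 0)
    data.frame(type = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0))
  else
    data.frame(type = vapply(events, `[[`, character(1), "type"),
               chrom = vapply(events, `[[`, character(1), "chrom"),
               start = vapply(events, `[[`, numeric(1), "start"),
               end = vapply(events, `[[`, numeric(1), "end"))
  out
}

#' Simulate a cohort of profiles
#'
#' Per-sample sub-seeds are derived from the global seed in counter mode,
#' so sample `i` is identical whatever the cohort size.
#'
#' @param n Number of profiles.
#' @inheritParams simulate_profile
#' @param ... Passed to [simulate_profile()].
#' @return Named list of `ascn_profile` objects (`sim_001`, ...).
#' @export
simulate_profiles <- function(n, genome, class_label = "hrd_neg", seed = 1,
                              ...) {
  ids <- sprintf("sim_%03d", seq_len(n))
  out <- lapply(seq_len(n), function(i)
    simulate_profile(genome, class_label, seed = .sub_seed(seed, i),
                     sample_id = ids[i], ...))
  names(out) <- ids
  out
}

#' Simulate a multi-assay call table with known truth
#'
#' Emulates the structure of the study call table: a latent HRD truth per
#' sample, a reference assay that reports the truth except for an
#' inconclusive fraction, and two test assays whose calls flip
#' independently of truth with configurable probabilities. BRCA1/2
#' mutations occur at `brca_rate_given_hrd` among HRD-positive tumors (and
#' never otherwise); each assay's HRD status combines its GI call with its
#' BRCA flag via [call_hrd()]. Continuous per-assay GI scores are drawn
#' from class-conditional normal distributions whose means straddle the
#' positivity threshold. Deterministic per seed, element-wise reproducible.
#'
#' @param n_samples Number of samples.
#' @param hrd_prevalence Fraction of truly HRD-positive samples.
#' @param flip_prob Named per-assay flip probabilities,
#'   `c(amoy = ..., oncoscan = ...)`.
#' @param inconclusive_prob Probability the reference GI call is
#'   inconclusive.
#' @param brca_rate_given_hrd P(BRCA1/2 mutation | HRD-positive).
#' @param brca_flip_prob Probability the test assay's BRCA flag flips
#'   versus the reference's.
#' @param oncoscan_missing_prob Probability the OncoScan result is missing.
#' @param low_tcc_prob Probability a sample carries the low-TCC exclusion
#'   flag.
#' @param score_mean Named class-conditional score means,
#'   `c(neg = ..., pos = ...)`.
#' @param score_sd Common class-conditional score SD.
#' @param seed Integer seed.
#' @return List with `calls` (a call table as from [read_call_table()]),
#'   `truth` (logical HRD truth), and `scores`, a data frame of continuous
#'   per-assay scores (`myriad`, `amoy`, `oncoscan`).
#' @export
simulate_cohort_calls <- function(n_samples, hrd_prevalence = 0.5,
                                  flip_prob = c(amoy = 0.1, oncoscan = 0.15),
                                  inconclusive_prob = 0.04,
                                  brca_rate_given_hrd = 0.46,
                                  brca_flip_prob = 0.05,
                                  oncoscan_missing_prob = 0.14,
                                  low_tcc_prob = 0.08,
                                  score_mean = c(neg = 25, pos = 60),
                                  score_sd = 12, seed = 1) {
  stopifnot(n_samples >= 1,
            all(c(hrd_prevalence, flip_prob, inconclusive_prob,
                  brca_rate_given_hrd, brca_flip_prob,
                  oncoscan_missing_prob, low_tcc_prob) >= 0),
            all(c(hrd_prevalence, flip_prob, inconclusive_prob,
                  brca_rate_given_hrd, brca_flip_prob,
                  oncoscan_missing_prob, low_tcc_prob) <= 1))
  rows <- vector("list", n_samples)
  truth <- logical(n_samples)
  scores <- matrix(NA_real_, n_samples, 3,
                   dimnames = list(NULL, c("myriad", "amoy", "oncoscan")))
  pn <- function(flag) ifelse(flag, "positive", "negative")
  for (i in seq_len(n_samples)) {
    set.seed(.sub_seed(seed, i))
    tr <- stats::runif(1) < hrd_prevalence
    truth[i] <- tr
    mu <- if (tr) score_mean[["pos"]] else score_mean[["neg"]]
    scores[i, ] <- stats::rnorm(3, mu, score_sd)
    myriad_gi <- if (stats::runif(1) < inconclusive_prob) "inconclusive"
      else pn(tr)
    myriad_brca <- if (tr && stats::runif(1) < brca_rate_given_hrd) "yes"
      else "no"
    amoy_gi <- pn(xor(tr, stats::runif(1) < flip_prob[["amoy"]]))
    onco_gi <- if (stats::runif(1) < oncoscan_missing_prob) "missing"
      else pn(xor(tr, stats::runif(1) < flip_prob[["oncoscan"]]))
    amoy_brca <- if (stats::runif(1) < brca_flip_prob)
      ifelse(myriad_brca == "yes", "no", "yes") else myriad_brca
    rows[[i]] <- data.frame(
      sample_id = sprintf("sim_%05d", i),
      myriad_hrd = call_hrd(myriad_gi, myriad_brca),
      amoy_hrd = call_hrd(amoy_gi, amoy_brca),
      myriad_gi = myriad_gi, amoy_gi = amoy_gi, oncoscan_gi = onco_gi,
      myriad_brca = myriad_brca, amoy_brca = amoy_brca,
      low_tcc_excluded = stats::runif(1) < low_tcc_prob,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  list(calls = calls, truth = truth, scores = as.data.frame(scores))
}
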