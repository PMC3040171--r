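# Motif annotation: alignment, E-value calibration, combining, distances.

test_that("self- and reverse-complement alignments are recognized", {
  set.seed(1)
  p <- random_sharp_pwm(10)
  self <- align_pwms(p, p)
  expect_equal(self$offset, 0L)
  expect_equal(self$strand, "+")
  expect_equal(self$sim_score, 1, tolerance = 1e-9)

  rc <- align_pwms(p, reverse_complement(p))
  expect_equal(rc$strand, "-")
  expect_equal(rc$sim_score, self$sim_score, tolerance = 1e-9)

  expect_error(align_pwms(p, random_pwm(3)), "4 columns")
})

test_that("align_pwms matches the exhaustive offset-by-strand oracle", {
  set.seed(2)
  for (i in 1:50) {
    q <- random_pwm(sample(5:12, 1))
    t <- random_pwm(sample(5:12, 1))
    got <- align_pwms(q, t)
    want <- brute_align(q, t)
    expect_equal(got$sim_score, want$sim_score, tolerance = 1e-9)
  }
})

test_that("similarity E-values are calibrated and monotone", {
  db <- synthetic_db(100, seed = 1)
  null <- calibrate_null(db, n_samples = 1000, seed = 2)
  expect_error(calibrate_null(db, n_samples = 50), ">= 100")

  scores <- seq(0.2, 1, by = 0.05)
  ev <- similarity_evalue(null, scores, wmin = 10)
  expect_true(all(diff(ev) <= 1e-12))

  # a high-information PWM retrieves itself far below the E cutoff
  self_e <- similarity_evalue(null, 1, wmin = db[[1]]$width)
  expect_lt(self_e, 1e-4)

  # random queries score like the null: median E near N_db / 2
  set.seed(3)
  meds <- replicate(10, {
    median(match_database(random_pwm(10), db, null, n_best = 100)$evalue)
  })
  expect_gt(median(meds), 100 / 2 / 3)
  expect_lt(median(meds), 100 / 2 * 3)
})

test_that("match_database ranks self first with n_best default 5", {
  db <- synthetic_db(30, seed = 4)
  null <- calibrate_null(db, n_samples = 500, seed = 5)
  m <- match_database(db[[7]], db, null)
  expect_equal(nrow(m), 5L)
  expect_equal(m$target[1], names(db)[7])
  expect_error(match_database(db[[1]], list(), null), "empty")

  # a near-uniform query finds nothing confidently
  uq <- pwm(matrix(0.25, 4, 8), name = "uniform")
  mu <- match_database(uq, db, null)
  expect_true(all(mu$evalue > 1e-4))
})

test_that("filter_matches applies name and E-value criteria to motifs", {
  matches <- data.frame(
    query = c("m1", "m1", "m2", "m3"),
    target = c("STAT1", "GATA1", "GATA1", "STAT3"),
    evalue = c(1e-6, 1e-7, 1e-9, 0.5),
    stringsAsFactors = FALSE
  )
  kept <- filter_matches(matches, name_patterns = "STAT")
  expect_setequal(unique(kept$query), c("m1", "m3"))

  kept2 <- filter_matches(matches, name_patterns = "STAT", evalue_max = 1e-4)
  expect_setequal(unique(kept2$query), "m1")
  expect_equal(nrow(kept2), 2L)  # all matches of kept motifs are returned

  expect_equal(nrow(filter_matches(matches, evalue_max = 1e-12)), 0L)
  expect_equal(filter_matches(matches), matches, ignore_attr = TRUE)
})

test_that("combine pools occurrences without touching member PWMs", {
  mk <- function(name, n) {
    structure(list(
      pwm = cons_pwm("TGACTCAG", name = name),
      occurrences = data.frame(
        seq_id = sprintf("s%d", seq_len(n)), start = seq_len(n),
        end = seq_len(n) + 8L, strand = "+", score = 1, pval = 1e-5,
        chrom = NA_character_, gstart = NA_integer_, gend = NA_integer_,
        stringsAsFactors = FALSE
      ),
      logE = -5, fold_enrichment = 2, n_sites = n, round = 1L
    ), class = "motif_result")
  }
  results <- list(mk("m5", 3), mk("m10", 2), mk("m25", 4), mk("m7", 1))
  before <- lapply(results, function(r) r$pwm$probs)
  lab <- combine_motifs(results, "FOXA1", c("m5", "m10", "m25"))
  expect_equal(lab$label, "FOXA1")
  expect_setequal(lab$members, c("m5", "m10", "m25"))
  expect_equal(nrow(lab$occurrences), 3 + 2 + 4)
  expect_true(all(lab$occurrences$label == "FOXA1"))
  after <- lapply(results, function(r) r$pwm$probs)
  expect_identical(before, after)

  single <- combine_motifs(results, "solo", "m7")
  expect_equal(nrow(single$occurrences), 1L)
  expect_error(combine_motifs(results, "none", "absent"), "no motifs")
})

test_that("distance-to-peak histograms conserve mass and center correctly", {
  events <- data.frame(chrom = "chr1", mu = c(1000, 5000))
  occ <- data.frame(
    seq_id = "r1", start = 0L, end = 10L, strand = "+", score = 1,
    pval = 1e-5, chrom = c("chr1", "chr1", "chr2"),
    gstart = c(995L, 4980L, 100L), gend = c(1005L, 4990L, 110L),
    stringsAsFactors = FALSE
  )
  ds <- distance_to_peak(occ, events, bin_width = 10, span = 200)
  expect_equal(sum(ds$counts), ds$n_total)
  expect_equal(ds$n_total + ds$n_unmatched, nrow(occ))
  expect_equal(ds$n_unmatched, 1L)  # chr2 occurrence has no event
  # all matched occurrences at/near centers -> mass in the central bins
  expect_equal(sum(ds$counts[abs(ds$mids) <= 15]), 2)
})

test_that("pairwise distances spike at a fixed lag with full co-occurrence", {
  occ_at <- function(seqs, mid, w = 8) data.frame(
    seq_id = seqs, start = mid - w / 2, end = mid + w / 2, strand = "+",
    score = 1, pval = 1e-5, stringsAsFactors = FALSE
  )
  a <- occ_at(sprintf("s%d", 1:100), 50)
  b <- occ_at(sprintf("s%d", 1:40), 110)  # +60 bp on 40 of the 100
  pd <- pairwise_distances(a, b, max_gap = 200, bin_width = 10)
  expect_equal(pd$co_occurrence, 1)       # all of the rarer motif co-occurs
  expect_equal(pd$n_total, 40L)
  expect_equal(pd$mids[which.max(pd$counts)], 65)  # +60 falls in [60, 70)
  expect_equal(sum(pd$counts), pd$n_total)

  # self-pair excludes identical occurrences
  self <- pairwise_distances(a, a)
  expect_equal(self$n_total, 0L)
})

test_that("occurrence export round-trips and validates provenance", {
  occ <- data.frame(
    seq_id = c("s1", "s2"), start = c(5L, 9L), end = c(13L, 17L),
    strand = c("+", "-"), score = c(8.1, 7.5), pval = 1e-5,
    chrom = c("chr2", "chr1"), gstart = c(105L, 209L),
    gend = c(113L, 217L), label = "m1", stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile()
  export_occurrences(occ, f, format = "bed")
  back <- read.table(f, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$V1, c("chr1", "chr2"))  # sorted by position
  expect_equal(back$V2, c(209L, 105L))
  expect_equal(back$V3, c(217L, 113L))
  expect_equal(back$V6, c("-", "+"))

  empty <- occ[0, ]
  export_occurrences(empty, f, format = "bed")
  expect_equal(length(readLines(f)), 0L)

  occ$chrom[1] <- NA
  expect_error(export_occurrences(occ, f, format = "bed"), "provenance")
  export_occurrences(occ, f, format = "tsv")
  tsv <- read.delim(f)
  expect_equal(nrow(tsv), 2L)
  expect_equal(tsv$start, c(5L, 9L))
})
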