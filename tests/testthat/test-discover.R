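# De novo discovery: dyads, seeding, EM refinement, fitness, GA, masking.

test_that("dyad-to-PWM conversion follows the stated construction", {
  p <- dyad_to_pwm(spaced_dyad("ACG", 0, "TACG"))
  expect_equal(p$width, 7L)
  expect_equal(pwm_consensus(p), "ACGTACG")

  p2 <- dyad_to_pwm(spaced_dyad("AAA", 2, "CCC"))
  expect_equal(p2$probs[, 4], rep(0.25, 4), ignore_attr = TRUE)
  expect_equal(p2$probs[, 5], rep(0.25, 4), ignore_attr = TRUE)
  expect_equal(unname(dyad_to_pwm(spaced_dyad("AAA", 0, "CCC"),
                                  alpha = 0.05)$probs[1, 1]), 0.85)

  expect_error(spaced_dyad("AC", 0, "ACGT"), "3-6")
  expect_error(spaced_dyad("ACGT", -1, "ACGT"), "spacer")
})

test_that("seeded dyad words come from the input k-mer support", {
  rec <- seq_records(sprintf("r%d", 1:20), rep(strrep("ACGTAC", 10), 20))
  pop <- seed_population(rec, k_range = 3:4, max_spacer = 3, n_pop = 30,
                         seed = 5)
  all_kmers <- unique(unlist(lapply(3:4, function(k) {
    s <- strrep("ACGTAC", 10)
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  })))
  for (ind in pop) {
    expect_true(ind$dyad$word1 %in% all_kmers)
    expect_true(ind$dyad$word2 %in% all_kmers)
  }

  pop2 <- seed_population(rec, k_range = 3:4, max_spacer = 3, n_pop = 30,
                          seed = 5)
  expect_identical(pop, pop2)
})

test_that("over-represented words dominate dyad seeding", {
  p <- cons_pwm("TGACTCA", p = 0.97)
  sim <- sim_sequences(200, 100, list(list(pwm = p, occupancy = 0.6,
                                           dist = "uniform")), seed = 2)
  pop <- seed_population(sim$sequences, k_range = 4, max_spacer = 5,
                         n_pop = 100, seed = 3)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  planted4 <- substring("TGACTCA", 1:4, 4:7)
  rc4 <- substring(rc("TGACTCA"), 1:4, 4:7)
  words <- c(vapply(pop, function(x) x$dyad$word1, ""),
             vapply(pop, function(x) x$dyad$word2, ""))
  frac <- mean(words %in% c(planted4, rc4))
  expect_gte(frac, 0.5)
})

test_that("EM refinement converges to the alignment in the noiseless limit", {
  core <- "TGACTCAG"
  seqs <- paste0(strrep("A", 10), core, strrep("C", 10))
  rec <- seq_records(sprintf("s%d", 1:30), rep(seqs, 30))
  p0 <- cons_pwm(core, p = 0.6)
  ref <- em_refine(p0, rec, discovery_config())
  expect_equal(pwm_consensus(ref), core)
  expect_gt(min(apply(ref$probs, 2, max)), 0.9)
  ll <- attr(ref, "em_loglik")
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-length(ll)])))

  expect_error(em_refine(cons_pwm(strrep("ACGT", 10)), rec,
                         discovery_config()), "width")
})

test_that("EM recovers a planted PWM (column r >= 0.9)", {
  p <- cons_pwm("TGACTCAGCT")
  sim <- sim_sequences(500, 200, list(list(pwm = p, occupancy = 0.8,
                                           dist = "uniform")), seed = 2)
  ref <- em_refine(p, sim$sequences, discovery_config())
  al <- align_pwms(ref, p)
  expect_gte(al$sim_score, 0.9)
})

test_that("the centered prior helps when plants sit at sequence midpoints", {
  p <- cons_pwm("TGACTCAGCT")
  sim <- sim_sequences(200, 200, list(list(pwm = p, occupancy = 0.7,
                                           dist = "center", sd = 5)),
                       seed = 3)
  p0 <- cons_pwm("TGACTCAGCT", p = 0.55)
  run <- function(prior) {
    cfg <- discovery_config(prior = prior)
    ref <- em_refine(p0, sim$sequences, cfg)
    list(r = align_pwms(ref, p)$sim_score,
         iters = attr(ref, "em_iterations"))
  }
  u <- run("uniform")
  ce <- run("centered")
  expect_gte(ce$r, 0.9)
  expect_lte(ce$iters, u$iters)
})

test_that("fitness boundaries: no occurrences is unfit; weak PWM is null-like", {
  set.seed(4)
  bgseqs <- sim_sequences(300, 200, seed = 14)$sequences
  strong_absent <- cons_pwm("GGGGGCCCCCAAAAA", p = 0.97)
  f <- motif_fitness(strong_absent, bgseqs, p_threshold = 1e-8)
  expect_identical(f$logE, Inf)
  expect_identical(f$n_sites, 0L)

  # weakly informative PWM on background: fold enrichment near 1
  weak <- random_pwm(6, concentration = 20)
  fw <- motif_fitness(weak, bgseqs, p_threshold = 5e-3)
  expected_n <- fw$n_windows * 5e-3
  expect_lt(abs(fw$n_sites - expected_n), 3 * sqrt(expected_n))
  expect_gt(fw$logE, 0)  # background-like motifs stay unfit
})

test_that("a planted motif is fitter than its column-shuffled version", {
  p <- cons_pwm("TGACTCAGCT")
  set.seed(5)
  shuffled <- pwm(p$probs[, c(4, 9, 1, 7, 2, 10, 3, 6, 8, 5)],
                  name = "shuffled")
  wins <- 0
  for (i in 1:10) {
    sim <- sim_sequences(150, 200, list(list(pwm = p, occupancy = 0.6,
                                             dist = "uniform")),
                         seed = 300 + i)
    fa <- motif_fitness(p, sim$sequences)
    fb <- motif_fitness(shuffled, sim$sequences)
    wins <- wins + (fa$logE < fb$logE)
  }
  expect_gte(wins, 9)
})

test_that("masking replaces spans with N and blocks re-discovery", {
  rec <- seq_records("s1", "ACGTACGTAC")
  occ <- data.frame(seq_id = "s1", start = 5L, end = 9L)
  masked <- mask_sequences(rec, occ)
  expect_equal(masked$seq, "ACGTANNNNC")
  expect_equal(nchar(masked$seq), 10L)

  expect_identical(mask_sequences(rec, occ[0, ]), rec)
  expect_error(mask_sequences(rec, data.frame(seq_id = "s1", start = 8L,
                                              end = 12L)), "range")

  p <- cons_pwm("TGACTCAGT")
  sim <- sim_sequences(100, 120, list(list(pwm = p, occupancy = 0.9,
                                           dist = "uniform")), seed = 6)
  occ1 <- scan_sequences(p, sim$sequences, 2e-4)
  masked <- mask_sequences(sim$sequences, occ1)
  occ2 <- scan_sequences(p, masked, 2e-4)
  if (nrow(occ2)) {
    clash <- merge(occ1, occ2, by = "seq_id")
    expect_false(any(clash$start.x < clash$end.y & clash$start.y < clash$end.x))
  } else {
    succeed()
  }
})

test_that("a zero-generation GA returns the evaluated, filtered population", {
  p <- cons_pwm("TGACTCAGT")
  sim <- sim_sequences(60, 120, list(list(pwm = p, occupancy = 0.8,
                                          dist = "uniform")), seed = 7)
  cfg <- discovery_config(n_pop = 10, n_gen = 0, seed = 8)
  pop <- seed_population(sim$sequences, n_pop = 10, seed = 8)
  ev <- evolve_population(pop, sim$sequences, cfg, seed = 9)
  expect_true(all(vapply(ev$winners, `[[`, 0, "logE") <= cfg$logE_cutoff))
  expect_true(is.finite(ev$best$logE) || identical(ev$best$logE, Inf))

  ev2 <- evolve_population(pop, sim$sequences, cfg, seed = 9)
  expect_identical(chipmotif:::.dyad_key(ev$best$dyad),
                   chipmotif:::.dyad_key(ev2$best$dyad))
  expect_identical(ev$best$pwm$probs, ev2$best$pwm$probs)
})

test_that("two planted motifs are recovered in the first two rounds", {
  m1 <- cons_pwm("TGACTCAGCT")
  m2 <- cons_pwm("CCGGAAGTGAAA")
  sim <- sim_sequences(300, 200, list(
    list(pwm = m1, occupancy = 0.6, dist = "uniform"),
    list(pwm = m2, occupancy = 0.4, dist = "uniform")
  ), seed = 4)
  cfg <- discovery_config(n_pop = 50, n_gen = 3, max_motifs = 2, seed = 44)
  res <- discover_motifs(sim$sequences, cfg)
  expect_gte(length(res), 2L)
  r_to <- function(x, truth) align_pwms(x$pwm, truth)$sim_score
  # assign by best alignment to truth
  r11 <- r_to(res[[1]], m1); r12 <- r_to(res[[1]], m2)
  r21 <- r_to(res[[2]], m1); r22 <- r_to(res[[2]], m2)
  expect_gte(max(r11, r21), 0.85)
  expect_gte(max(r12, r22), 0.85)
})

test_that("seeded discovery recovers the planted motif and skips the GA", {
  p <- cons_pwm("TGACTCAGCT")
  sim <- sim_sequences(500, 200, list(list(pwm = p, occupancy = 0.6,
                                           dist = "uniform")), seed = 2)
  res <- seeded_discover(p, sim$sequences, discovery_config(seed = 1))
  expect_gte(align_pwms(res$pwm, p)$sim_score, 0.95)
  expect_gt(res$n_sites, 100)

  absent <- cons_pwm("GGGGGAAAAACCCCC", p = 0.97)
  null_res <- seeded_discover(absent, sim$sequences,
                              discovery_config(seed = 1))
  null_expect <- null_res$n_sites <= 2e-4 * 2 * 500 * 200 * 3 + 30
  expect_true(identical(null_res$logE, Inf) || null_expect)
})
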