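# Peak calling: segmentation, t-mixture EM, model selection, scores, FDR.

test_that("segmentation keeps bidirectional clusters and drops one-sided ones", {
  set.seed(1)
  rd <- aligned_reads(
    "chr1",
    c(round(rnorm(50, 1000, 20)), round(rnorm(50, 1150, 20))),
    c(rep("+", 50), rep("-", 50))
  )
  regs <- segment_regions(rd)
  expect_length(regs, 1L)
  expect_equal(length(regs[[1]]$fwd) + length(regs[[1]]$rev), 100L)

  one_sided <- aligned_reads("chr1", round(rnorm(60, 1000, 20)), "+")
  expect_length(segment_regions(one_sided), 0L)
})

test_that("point-mass reads give the symmetric closed-form limit", {
  reg <- list(chrom = "chr1", start = 900, end = 1400,
              fwd = rep(1000, 30), rev = rep(1180, 30))
  fit <- fit_mixture(reg, K = 1)
  expect_equal(fit$components$mu, 1090, tolerance = 2)
  # delta shrinks toward a compromise between the data (180) and prior (175)
  expect_gt(fit$components$delta, 174)
  expect_lt(fit$components$delta, 181)
})

test_that("single-event fit recovers mu within 20 bp (seed 1)", {
  sim <- sim_reads(data.frame(chrom = "chr1", mu = 5000, n_frag = 200),
                   c(chr1 = 10000), noise_rate = 0, seed = 1)
  regs <- segment_regions(sim$treatment)
  fit <- fit_mixture(regs[[1]], K = 1)
  expect_lt(abs(fit$components$mu - 5000), 20)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$loglik_trace[-1])))
})

test_that("full-region mappability gives the identical fit to no profile", {
  sim <- sim_reads(data.frame(chrom = "chr1", mu = 5000, n_frag = 100),
                   c(chr1 = 10000), noise_rate = 0, seed = 4)
  regs <- segment_regions(sim$treatment)
  all_mappable <- mappability_profile(genomic_intervals("chr1", 0, 10000))
  f1 <- fit_mixture(regs[[1]], 1)
  f2 <- fit_mixture(regs[[1]], 1, map_profile = all_mappable)
  expect_lt(max(abs(f1$components$mu - f2$components$mu)), 1e-9)
  expect_lt(max(abs(f1$components$delta - f2$components$delta)), 1e-9)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-9)
})

test_that("near-duplicate components are merged by select_K", {
  # two components closer than delta/4 collapse to one
  sim <- sim_reads(data.frame(chrom = "chr1", mu = c(5000, 5020),
                              n_frag = 80),
                   c(chr1 = 10000), noise_rate = 0, seed = 6)
  regs <- segment_regions(sim$treatment)
  sel <- select_K(regs[[1]], Kmax = 3)
  expect_equal(sel$K, 1L)
})

test_that("enrichment scores follow the stated definitions", {
  sim <- sim_reads(data.frame(chrom = "chr1", mu = 5000, n_frag = 100),
                   c(chr1 = 10000), noise_rate = 0, seed = 8)
  regs <- segment_regions(sim$treatment)
  fit <- fit_mixture(regs[[1]], 1)
  ev <- enrichment_score(fit, regs[[1]])
  expect_equal(ev$score, ev$n_frag_est)       # no control: definition
  expect_equal(ev$n_frag_est, fit$n_reads / 2, tolerance = 1e-9)
  expect_true(ev$ci_lo <= ev$mu && ev$mu <= ev$ci_hi)

  # more control reads near mu => lower score
  ctrl_near <- aligned_reads("chr1", round(rnorm(200, 5000, 80)),
                             sample(c("+", "-"), 200, replace = TRUE))
  ctrl_far <- aligned_reads("chr1", round(rnorm(20, 5000, 80)),
                            sample(c("+", "-"), 20, replace = TRUE))
  s_near <- enrichment_score(fit, regs[[1]], ctrl_near, lib_ratio = 1)$score
  s_far <- enrichment_score(fit, regs[[1]], ctrl_far, lib_ratio = 1)$score
  expect_lt(s_near, s_far)
})

test_that("doubling treatment reads doubles the score at fixed control", {
  base <- sim_reads(data.frame(chrom = "chr1", mu = 5000, n_frag = 100),
                    c(chr1 = 10000), noise_rate = 0, seed = 9)
  dbl <- sim_reads(data.frame(chrom = "chr1", mu = 5000, n_frag = 200),
                   c(chr1 = 10000), noise_rate = 0, seed = 9)
  ctrl <- sim_reads(data.frame(chrom = "chr1", mu = 5000, n_frag = 1),
                    c(chr1 = 10000), noise_rate = 2e-3, seed = 10)$control
  score_of <- function(sim) {
    regs <- segment_regions(sim$treatment)
    fit <- fit_mixture(regs[[1]], 1)
    enrichment_score(fit, regs[[1]], ctrl, lib_ratio = 1)$score
  }
  expect_equal(score_of(dbl) / score_of(base), 2, tolerance = 0.05)
})

test_that("estimate_fdr honours its boundary cases and monotonicity", {
  expect_error(estimate_fdr(numeric(), numeric()), "no treatment")

  fdr0 <- estimate_fdr(c(5, 3, 1), numeric())
  expect_equal(fdr0$fdr(c(1, 3, 5)), c(0, 0, 0))

  s <- c(4, 3, 2, 1)
  fdr1 <- estimate_fdr(s, s)
  expect_equal(fdr1$fdr(s), rep(1, 4))

  set.seed(2)
  t_sc <- rexp(50, 1 / 10)
  n_sc <- rexp(30, 1 / 3)
  est <- estimate_fdr(t_sc, n_sc)
  grid <- sort(unique(c(t_sc, n_sc)))
  vals <- est$fdr(grid)
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("call_peaks on empty input returns an empty ranked table", {
  out <- call_peaks(aligned_reads(character(), integer(), character()))
  expect_equal(nrow(out), 0L)
  expect_true(all(c("chrom", "mu", "delta", "score") %in% names(out)))
})

test_that("call_peaks ranks events by score with deterministic ties", {
  sim <- sim_reads(data.frame(chrom = "chr1", mu = c(2000, 6000),
                              n_frag = c(150, 60)),
                   c(chr1 = 10000), noise_rate = 0, seed = 12)
  out <- call_peaks(sim$treatment)
  expect_gte(nrow(out), 2L)
  expect_true(all(diff(out$score) <= 0))
  expect_lt(abs(out$mu[1] - 2000), 30)  # the stronger event ranks first
})
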