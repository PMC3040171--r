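# Iterative de novo motif discovery: spaced-dyad seeding, a
# genetic algorithm with log-E-value fitness, ZOOPS EM refinement,
# thresholded scanning, masking, and a seeded mode that refines a
# user-supplied PWM directly.

#' Discovery configuration
#'
#' @param n_pop GA population size (>= 2).
#' @param n_gen GA generations.
#' @param p_threshold scan p-value threshold for declaring binding sites.
#' @param logE_cutoff report motifs with log E-value (natural log) at or
#'   below this; the default 0 keeps motifs with fewer than one expected by
#'   chance.
#' @param max_motifs cap on discovery rounds.
#' @param prior positional prior for the EM: `"uniform"` or `"centered"`
#'   (discretized triangular prior peaking at the sequence midpoint, for
#'   peak-centered regions).
#' @param seq_weights optional per-sequence weights (e.g. normalized region
#'   enrichment scores) prioritizing high-enrichment sequences.
#' @param k_range dyad word lengths considered.
#' @param max_spacer maximum dyad spacer (bp).
#' @param mut_prob per-offspring mutation probability.
#' @param em_tol,em_max_iter ZOOPS EM stopping rule (max absolute change in
#'   the probability matrix, iteration cap) for reported and seeded motifs.
#' @param em_iter_search reduced EM iteration cap used while scoring GA
#'   candidates; the winning individual is always re-refined under the full
#'   stopping rule before being reported.
#' @param pseudo pseudocount per cell in the EM M-step.
#' @param seed RNG seed for all stochastic steps; identical seed and input
#'   give identical output.
#' @return A list of class `"discovery_config"`.
#' @export
discovery_config <- function(n_pop = 100L, n_gen = 5L, p_threshold = 2e-4,
                             logE_cutoff = 0, max_motifs = 10L,
                             prior = c("uniform", "centered"),
                             seq_weights = NULL, k_range = 3:6,
                             max_spacer = 10L, mut_prob = 0.1,
                             em_tol = 1e-4, em_max_iter = 50L,
                             em_iter_search = 8L, pseudo = 0.25,
                             seed = 1L) {
  prior <- match.arg(prior)
  if (n_pop < 2L) stop("n_pop must be >= 2")
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  structure(list(n_pop = as.integer(n_pop), n_gen = as.integer(n_gen),
                 p_threshold = p_threshold, logE_cutoff = logE_cutoff,
                 max_motifs = as.integer(max_motifs), prior = prior,
                 seq_weights = seq_weights, k_range = as.integer(k_range),
                 max_spacer = as.integer(max_spacer), mut_prob = mut_prob,
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 em_iter_search = as.integer(em_iter_search),
                 pseudo = pseudo, seed = seed),
            class = "discovery_config")
}

#' Construct a spaced dyad
#'
#' Two short conserved words separated by a fixed-length spacer; the seed
#' unit of de novo discovery.
#'
#' @param word1,word2 words over A/C/G/T, lengths 3-6.
#' @param spacer spacer length in bp (>= 0).
#' @return A list of class `"spaced_dyad"`.
#' @export
spaced_dyad <- function(word1, spacer, word2) {
  for (wd in c(word1, word2)) {
    if (!grepl("^[ACGT]{3,6}$", wd)) {
      stop("dyad words must be 3-6 letters over ACGT: ", wd)
    }
  }
  if (spacer < 0) stop("spacer must be >= 0")
  structure(list(word1 = word1, spacer = as.integer(spacer), word2 = word2),
            class = "spaced_dyad")
}

.dyad_key <- function(d) paste(d$word1, d$spacer, d$word2, sep = "|")

#' Convert a spaced dyad to a letter probability matrix
#'
#' Word positions put mass `1 - 3 * alpha` on the dyad letter and `alpha`
#' elsewhere; spacer columns are uniform.
#'
#' @param dyad a [spaced_dyad].
#' @param alpha off-consensus probability per letter.
#' @return A [pwm] of width `|word1| + spacer + |word2|`.
#' @export
dyad_to_pwm <- function(dyad, alpha = 0.05) {
  letters1 <- strsplit(dyad$word1, "")[[1]]
  letters2 <- strsplit(dyad$word2, "")[[1]]
  w <- length(letters1) + dyad$spacer + length(letters2)
  probs <- matrix(0.25, 4L, w)
  fill <- function(letters, at) {
    for (j in seq_along(letters)) {
      col <- rep(alpha, 4L)
      col[match(letters[j], DNA_BASES)] <- 1 - 3 * alpha
      probs[, at + j - 1L] <<- col
    }
  }
  fill(letters1, 1L)
  fill(letters2, length(letters1) + dyad$spacer + 1L)
  pwm(probs, name = .dyad_key(dyad), source = "denovo")
}

# Count k-mers of the input, weight them by over-representation
# (observed / background-expected count), and keep only the top-ranked
# words per length: dyad candidates come from the most enriched cores, so
# seeding does not dilute across the whole k-mer spectrum.
.kmer_weights <- function(seqs, k_range, background) {
  bg <- as.numeric(background)
  out <- list()
  for (k in k_range) {
    words <- unlist(lapply(seqs, function(s) {
      L <- nchar(s)
      if (L < k) return(character())
      substring(s, 1:(L - k + 1L), k:L)
    }), use.names = FALSE)
    words <- words[!grepl("N", words, fixed = TRUE)]
    if (!length(words)) next
    tab <- table(words)
    kmers <- names(tab)
    codes <- lapply(strsplit(kmers, ""), match, DNA_BASES)
    expfreq <- vapply(codes, function(cc) prod(bg[cc]), 0) * length(words)
    kw <- data.frame(word = kmers, weight = as.numeric(tab) / expfreq,
                     stringsAsFactors = FALSE)
    n_top <- max(8L, ceiling(0.02 * nrow(kw)))
    kw <- kw[order(-kw$weight), , drop = FALSE]
    out[[as.character(k)]] <- head(kw, n_top)
  }
  if (!length(out)) stop("sequences shorter than the smallest dyad word")
  do.call(rbind, out)
}

#' Seed a GA population of spaced dyads
#'
#' Candidate words are the most over-represented k-mers of the input (top
#' 2 percent per word length, at least 8), sampled with probability
#' proportional to their over-representation (observed count over
#' background-expected count); dyads pair two sampled words with a
#' uniform spacer.
#'
#' @param sequences a [seq_records] table.
#' @param k_range,max_spacer,n_pop see [discovery_config].
#' @param background a [background_freqs] vector.
#' @param seed RNG seed.
#' @return A list of unevaluated GA individuals (lists with a `dyad` field).
#' @export
seed_population <- function(sequences, k_range = 3:6, max_spacer = 10L,
                            n_pop = 100L, background = background_freqs(),
                            seed = NULL) {
  if (max(nchar(sequences$seq)) < max(k_range)) {
    stop("sequences shorter than the largest dyad word")
  }
  kw <- .kmer_weights(sequences$seq, k_range, background)
  with_seed(seed, {
    lapply(seq_len(n_pop), function(i) {
      idx <- sample.int(nrow(kw), 2L, replace = TRUE, prob = kw$weight)
      sp <- sample.int(max_spacer + 1L, 1L) - 1L
      list(dyad = spaced_dyad(kw$word[idx[1L]], sp, kw$word[idx[2L]]),
           fitness = NULL)
    })
  })
}

#' Refine a PWM by ZOOPS expectation-maximization
#'
#' Zero-or-one-occurrence-per-sequence EM: each sequence either has no site
#' or one site at some offset and strand, with a uniform or center-peaked
#' positional prior and optional per-sequence enrichment weights. The
#' probability matrix is updated from posterior-weighted letter counts plus
#' a pseudocount until the maximum absolute change falls below `em_tol` or
#' `em_max_iter` iterations. The observed-data log-likelihood is
#' non-decreasing; its trace is attached to the result.
#'
#' @param pwm0 starting [pwm]; used only for initialization.
#' @param sequences a [seq_records] table, all longer than the PWM width.
#' @param config a [discovery_config].
#' @param background a [background_freqs] vector.
#' @return The refined [pwm] with attributes `em_iterations`,
#'   `em_loglik` (trace) and `site_prob` (fitted occurrence probability).
#' @export
em_refine <- function(pwm0, sequences, config = discovery_config(),
                      background = background_freqs()) {
  if (pwm0$width > min(nchar(sequences$seq))) {
    stop("PWM width exceeds the shortest sequence")
  }
  enc <- encode_seq_matrix(sequences$seq)
  .em_refine_encoded(pwm0, enc, nchar(sequences$seq), config, background)
}

.em_refine_encoded <- function(pwm0, enc, lens, config, background,
                               max_iter = config$em_max_iter,
                               weights = NULL) {
  n <- nrow(enc)
  wts <- weights %||% config$seq_weights %||% rep(1, n)
  wts <- wts / mean(wts)
  res <- zoops_em_cpp(enc, as.integer(lens), pwm0$probs,
                      as.numeric(background),
                      if (config$prior == "centered") 1L else 0L,
                      wts, 0.5, config$pseudo, config$em_tol, max_iter)
  out <- pwm(res$theta, name = pwm0$name,
             source = if (pwm0$source == "database") "seeded" else pwm0$source)
  attr(out, "em_iterations") <- res$n_iter
  attr(out, "em_loglik") <- res$loglik
  attr(out, "site_prob") <- res$gamma
  out
}

# Rebin an integer-grid distribution by factor `r` (support -> floor(s/r)).
.rebin_dist <- function(support, probs, r) {
  ns <- support %/% r
  agg <- rowsum(probs, ns)
  list(support = as.integer(rownames(agg)), probs = as.numeric(agg))
}

# log P(sum of n i.i.d. single-window scores >= total), on the score grid.
# Exact convolution (binary powering; operands re-binned to a common coarser
# grid whenever their support outgrows ~2048 bins) for small n; Gaussian
# tail approximation on the log scale for large n, where exact linear-space
# convolution would underflow.
.log_aggregate_pvalue <- function(dist, n, total_int) {
  if (n <= 16L) {
    r0 <- max(1L, ceiling(length(dist$support) / 2048))
    cur <- .rebin_dist(dist$support, dist$probs, r0)
    cum_r <- r0
    acc <- NULL
    m <- n
    while (m > 0L) {
      if (m %% 2L == 1L) {
        acc <- if (is.null(acc)) cur else .conv_dist(acc, cur)
      }
      m <- m %/% 2L
      if (m > 0L) cur <- .conv_dist(cur, cur)
      len_max <- max(length(cur$probs),
                     if (is.null(acc)) 0L else length(acc$probs))
      if (m > 0L && len_max > 4096L) {
        r <- ceiling(len_max / 2048)
        cur <- .rebin_dist(cur$support, cur$probs, r)
        if (!is.null(acc)) acc <- .rebin_dist(acc$support, acc$probs, r)
        cum_r <- cum_r * r
      }
    }
    t_c <- floor(total_int / cum_r)
    p <- sum(acc$probs[acc$support >= t_c])
    log(max(min(p, 1), 1e-300))
  } else {
    m1 <- sum(dist$support * dist$probs)
    v1 <- sum(dist$support^2 * dist$probs) - m1^2
    pnorm(total_int, mean = n * m1, sd = sqrt(max(n * v1, 1e-12)),
          lower.tail = FALSE, log.p = TRUE)
  }
}

.conv_dist <- function(a, b) {
  p <- conv_dense_cpp(a$probs, b$probs)
  list(support = seq.int(a$support[1L] + b$support[1L],
                         length.out = length(p)),
       probs = p)
}

#' Fitness of a motif on a sequence set
#'
#' Scans for occurrences at `p_threshold`; the fitness is a natural-log
#' E-value `log W + log P(N >= n | background) + log P(mean site score >=
#' observed | background, n sites)`, where `W` is the number of scanned
#' windows (both strands), the count term is a Poisson tail on the number
#' of sites against its background expectation `W * p_threshold`, and the
#' score term is the aggregate tail probability of the mean site score
#' under the background single-window score distribution truncated at the
#' scan cutoff. The truncation makes the score term selection-corrected:
#' sites are only ever observed above the cutoff, so on pure background
#' both tail terms are order one and the fitness stays near `log W`, well
#' above the default reporting cutoff of 0. Fold enrichment is
#' `n / (W * p_threshold)`, the observed site count over its background
#' expectation. Lower log-E is fitter; a motif with no occurrences gets
#' the unfit sentinel `Inf`.
#'
#' @param pwm a [pwm].
#' @param sequences a [seq_records] table.
#' @param p_threshold scan p-value threshold.
#' @param background a [background_freqs] vector.
#' @return A list: `logE`, `occurrences` (as in [scan_sequences], without
#'   genomic columns when scanning plain sequences), `fold_enrichment`,
#'   `n_sites`, `n_windows`.
#' @export
motif_fitness <- function(pwm, sequences, p_threshold = 2e-4,
                          background = background_freqs()) {
  enc <- encode_seq_matrix(sequences$seq)
  fit <- .fitness_encoded(pwm, enc, nchar(sequences$seq), p_threshold,
                          background)
  occ <- fit$occ_raw
  if (nrow(occ)) {
    i <- occ$seq_row
    occ <- data.frame(
      seq_id = sequences$id[i], start = occ$start, end = occ$end,
      strand = occ$strand, score = occ$score, pval = occ$pval,
      chrom = sequences$chrom[i], gstart = sequences$start[i] + occ$start,
      gend = sequences$start[i] + occ$end, stringsAsFactors = FALSE
    )
    occ <- occ[order(occ$seq_id, occ$start, occ$strand), , drop = FALSE]
    rownames(occ) <- NULL
  } else {
    occ <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), pval = numeric(),
                      chrom = character(), gstart = integer(),
                      gend = integer(), stringsAsFactors = FALSE)
  }
  list(logE = fit$logE, occurrences = occ,
       fold_enrichment = fit$fold_enrichment, n_sites = fit$n_sites,
       n_windows = fit$n_windows)
}

# Fitness on pre-encoded sequences (shared with the GA loop).
.fitness_encoded <- function(pwm, enc, lens, p_threshold, background) {
  g <- .PWM_GRANULARITY
  dist <- score_distribution(pwm, background, g)
  occ <- .scan_encoded(pwm, enc, lens, p_threshold, background,
                       both_strands = TRUE, dist = dist)
  w <- pwm$width
  n_windows <- 2L * sum(pmax(lens - w + 1L, 0L))
  n <- nrow(occ)
  if (n == 0L) {
    return(list(logE = Inf, occ_raw = occ, fold_enrichment = 0,
                n_sites = 0L, n_windows = n_windows))
  }
  # single-window distribution: average of the two strand orientations
  bg <- as.numeric(background)
  if (max(abs(bg - 0.25)) < 1e-12) {
    sdist <- dist  # uniform background: strands have identical distributions
  } else {
    rdist <- score_distribution(reverse_complement(pwm), background, g)
    lo <- min(dist$support[1L], rdist$support[1L])
    hi <- max(dist$support[length(dist$support)],
              rdist$support[length(rdist$support)])
    probs <- numeric(hi - lo + 1L)
    probs[dist$support - lo + 1L] <- probs[dist$support - lo + 1L] +
      0.5 * dist$probs
    probs[rdist$support - lo + 1L] <- probs[rdist$support - lo + 1L] +
      0.5 * rdist$probs
    sdist <- list(support = seq.int(lo, hi), probs = probs)
  }
  # selection-corrected null: scores conditional on passing the scan cutoff
  pass <- dist$tail <= p_threshold
  cut_int <- if (any(pass)) dist$support[which(pass)[1L]] else {
    min(as.integer(round(occ$score / g)))
  }
  keep <- sdist$support >= cut_int
  tmass <- sum(sdist$probs[keep])
  tdist <- list(support = sdist$support[keep],
                probs = sdist$probs[keep] / max(tmass, 1e-300))
  total_int <- sum(as.integer(round(occ$score / g)))
  log_p_score <- .log_aggregate_pvalue(tdist, n, total_int)
  log_p_count <- stats::ppois(n - 1L, lambda = n_windows * p_threshold,
                              lower.tail = FALSE, log.p = TRUE)
  list(logE = log(n_windows) + log_p_count + log_p_score, occ_raw = occ,
       fold_enrichment = n / (n_windows * p_threshold), n_sites = n,
       n_windows = n_windows)
}

#' Mask motif occurrences in sequences
#'
#' Replaces each occurrence span with `N`, preserving length and order, so
#' that subsequent discovery rounds cannot reuse the same sites.
#'
#' @param sequences a [seq_records] table.
#' @param occurrences a `data.frame` with `seq_id`, `start`, `end` columns
#'   (sequence-relative, 0-based half-open).
#' @return The masked [seq_records] table.
#' @export
mask_sequences <- function(sequences, occurrences) {
  if (!nrow(occurrences)) return(sequences)
  out <- sequences
  for (i in seq_len(nrow(occurrences))) {
    j <- match(occurrences$seq_id[i], out$id)
    if (is.na(j)) stop("occurrence references unknown sequence: ",
                       occurrences$seq_id[i])
    s <- occurrences$start[i]
    e <- occurrences$end[i]
    if (s < 0L || e > nchar(out$seq[j]) || s >= e) {
      stop("occurrence out of range for sequence ", occurrences$seq_id[i])
    }
    substr(out$seq[j], s + 1L, e) <- strrep("N", e - s)
  }
  out
}

# Evaluate a GA individual, memoized by dyad within a run. The PWM is
# EM-refined on the training half of the sequences and its fitness is
# computed on the held-out half: a matrix overfitted to background noise
# in the training half scores at chance on the test half, so the log-E
# fitness stays honest under pure background. Evaluations are
# order-independent, so a generation could be scored concurrently with
# identical results. During the GA search the EM runs under the reduced
# em_iter_search cap; candidates near the cutoff are re-refined under the
# full stopping rule before the winners are reported.
.evaluate_chromosome <- function(ind, split, config, background, cache,
                                 max_iter = config$em_iter_search) {
  key <- .dyad_key(ind$dyad)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  p0 <- dyad_to_pwm(ind$dyad)
  refined <- .em_refine_encoded(p0, split$enc_train, split$lens_train,
                                config, background, max_iter,
                                weights = split$w_train)
  fit <- .fitness_encoded(refined, split$enc_test, split$lens_test,
                          config$p_threshold, background)
  out <- list(dyad = ind$dyad, pwm = refined, logE = fit$logE,
              n_sites = fit$n_sites, fold_enrichment = fit$fold_enrichment)
  cache[[key]] <- out
  out
}

# Deterministic alternating train/test split of an encoded sequence set.
# Tiny inputs are not split (both halves are the full set).
.fitness_split <- function(enc, lens, config = NULL) {
  n <- nrow(enc)
  wts <- config$seq_weights
  if (n < 20L) {
    return(list(enc_train = enc, lens_train = lens, enc_test = enc,
                lens_test = lens, w_train = wts))
  }
  tr <- seq(1L, n, by = 2L)
  te <- seq(2L, n, by = 2L)
  list(enc_train = enc[tr, , drop = FALSE], lens_train = lens[tr],
       enc_test = enc[te, , drop = FALSE], lens_test = lens[te],
       w_train = if (is.null(wts)) NULL else wts[tr])
}

.mutate_dyad <- function(d, max_spacer) {
  which_part <- sample(3L, 1L)
  if (which_part == 3L) {
    sp <- d$spacer + sample(c(-1L, 1L), 1L)
    d$spacer <- min(max(sp, 0L), max_spacer)
  } else {
    word <- if (which_part == 1L) d$word1 else d$word2
    pos <- sample(nchar(word), 1L)
    substr(word, pos, pos) <- sample(setdiff(DNA_BASES,
                                             substr(word, pos, pos)), 1L)
    if (which_part == 1L) d$word1 <- word else d$word2 <- word
  }
  d
}

#' Evolve a population of spaced dyads
#'
#' Per generation: tournament selection (size 2), single-point crossover
#' exchanging the spacer and second word between parents, point mutation
#' (one letter, or spacer +/- 1) with probability `mut_prob`, and elitism
#' of the best individual. Every offspring is EM-refined on the training
#' half of the sequences and scored on the held-out half, so that the
#' fitness is not inflated by the EM tailoring the matrix to the noise it
#' was fit on. Reported fitness values carry a search-size correction of
#' `log(number of distinct dyads examined)`, the number-of-starting-points
#' term of motif E-values, so that the best of many candidates is judged
#' against the size of the search. Returns the evaluated individuals with
#' `logE <= logE_cutoff`, deduplicated by dyad, best first.
#'
#' @param population from [seed_population].
#' @param sequences a [seq_records] table.
#' @param config a [discovery_config].
#' @param background a [background_freqs] vector.
#' @param seed RNG seed.
#' @return A list with `winners` (passing individuals, sorted by fitness)
#'   and `best` (the single fittest individual, regardless of cutoff).
#' @export
evolve_population <- function(population, sequences,
                              config = discovery_config(),
                              background = background_freqs(), seed = NULL) {
  enc <- encode_seq_matrix(sequences$seq)
  lens <- nchar(sequences$seq)
  split <- .fitness_split(enc, lens, config)
  cache <- new.env(parent = emptyenv())
  with_seed(seed, {
    evaled <- lapply(population, .evaluate_chromosome, split = split,
                     config = config, background = background, cache = cache)
    for (gen in seq_len(config$n_gen)) {
      fitnesses <- vapply(evaled, `[[`, 0, "logE")
      elite <- evaled[[which.min(fitnesses)]]
      nextgen <- list(elite)
      while (length(nextgen) < config$n_pop) {
        pick <- function() {
          ij <- sample.int(length(evaled), 2L, replace = TRUE)
          if (fitnesses[ij[1L]] <= fitnesses[ij[2L]]) evaled[[ij[1L]]]
          else evaled[[ij[2L]]]
        }
        p1 <- pick(); p2 <- pick()
        child <- spaced_dyad(p1$dyad$word1, p2$dyad$spacer, p2$dyad$word2)
        if (runif(1) < config$mut_prob) {
          child <- .mutate_dyad(child, config$max_spacer)
        }
        nextgen[[length(nextgen) + 1L]] <-
          .evaluate_chromosome(list(dyad = child), split, config,
                               background, cache)
      }
      evaled <- nextgen
    }
    fitnesses <- vapply(evaled, `[[`, 0, "logE")
    keys <- vapply(evaled, function(x) .dyad_key(x$dyad), "")
    o <- order(fitnesses)
    evaled <- evaled[o][!duplicated(keys[o])]
    # search-size correction: the best of n_models examined candidates is
    # only as surprising as n_models times its single-candidate E-value
    # (the number-of-starting-points term of motif E-values)
    n_models <- max(length(ls(cache)), 1L)
    # re-refine candidates near the cutoff under the full EM stopping rule
    refine_full <- function(ind) {
      .evaluate_chromosome(ind, split, config, background,
                           cache = new.env(parent = emptyenv()),
                           max_iter = config$em_max_iter)
    }
    n_final <- min(length(evaled), max(1L, sum(
      vapply(evaled, `[[`, 0, "logE") + log(n_models) <= config$logE_cutoff)))
    evaled[seq_len(n_final)] <- lapply(evaled[seq_len(n_final)], refine_full)
    evaled <- lapply(evaled, function(x) {
      x$logE <- x$logE + log(n_models)
      x
    })
    o <- order(vapply(evaled, `[[`, 0, "logE"))
    evaled <- evaled[o]
    fitnesses <- vapply(evaled, `[[`, 0, "logE")
    list(winners = evaled[fitnesses <= config$logE_cutoff],
         best = evaled[[1L]], n_models = n_models)
  })
}

.motif_result <- function(pwm, fit, round) {
  structure(
    list(pwm = pwm, occurrences = fit$occurrences, logE = fit$logE,
         fold_enrichment = fit$fold_enrichment, n_sites = fit$n_sites,
         round = round),
    class = "motif_result"
  )
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("Motif %s: %d sites, logE %.2f, fold enrichment %.2f (round %d)\n",
              pwm_consensus(x$pwm), x$n_sites, x$logE, x$fold_enrichment,
              x$round))
  invisible(x)
}

# A motif whose PWM aligns to its own reverse complement essentially
# perfectly is a palindrome/dimer; it is reported once.
.is_self_rc <- function(p) {
  al <- align_pwms(p, reverse_complement(p))
  al$sim_score >= 0.95
}

#' Iterative de novo motif discovery
#'
#' Repeats: seed a dyad population, evolve it, report the best motif,
#' mask its occurrences, and continue on the masked sequences. Stops when
#' no motif passes `logE_cutoff` or `max_motifs` rounds are done. Motifs
#' are ordered by discovery round. Each reported motif is refit on the
#' full sequence set under the full EM stopping rule, width-trimmed and
#' re-scanned for its occurrence list; its `logE` is the held-out fitness
#' that made it pass, which is the honest decision statistic (an in-sample
#' log-E would be inflated by the EM fitting the matrix to the same
#' windows it is scored on).
#'
#' @param sequences a [seq_records] table (>= 10 sequences recommended; a
#'   warning is issued below that).
#' @param config a [discovery_config].
#' @param background a [background_freqs] vector.
#' @return A list of `"motif_result"` objects.
#' @export
discover_motifs <- function(sequences, config = discovery_config(),
                            background = background_freqs()) {
  if (nrow(sequences) < 10L) {
    warning("fewer than 10 sequences; discovery may be unreliable")
  }
  current <- sequences
  results <- list()
  for (round in seq_len(config$max_motifs)) {
    round_seed <- config$seed + 1000L * (round - 1L)
    pop <- seed_population(current, config$k_range, config$max_spacer,
                           config$n_pop, background, seed = round_seed)
    ev <- evolve_population(pop, current, config, background,
                            seed = round_seed + 1L)
    if (!length(ev$winners)) break
    best <- ev$winners[[1L]]
    # refit the winner on the full set under the full stopping rule
    full <- em_refine(best$pwm, current, config, background)
    trimmed <- trim_pwm(full, ic_min = 0.1, background)
    trimmed$name <- sprintf("m%d", round)
    fit <- motif_fitness(trimmed, current, config$p_threshold, background)
    if (fit$n_sites == 0L) break
    fit$logE <- best$logE  # held-out fitness: the honest decision statistic
    res <- .motif_result(trimmed, fit, round)
    res$palindromic <- .is_self_rc(trimmed)
    results[[length(results) + 1L]] <- res
    current <- mask_sequences(current, fit$occurrences)
  }
  results
}

#' Seeded motif discovery
#'
#' Skips the genetic algorithm entirely: the user-supplied PWM initializes
#' ZOOPS EM refinement, after which the refined, trimmed motif is scanned
#' and scored exactly as in de novo discovery. The seed matrix is used only
#' for initialization, never during the EM updates.
#'
#' @param pwm0 the seeding [pwm] (e.g. a database motif).
#' @param sequences a [seq_records] table.
#' @param config a [discovery_config].
#' @param background a [background_freqs] vector.
#' @return A single `"motif_result"` (possibly unfit: check `logE`).
#' @export
seeded_discover <- function(pwm0, sequences, config = discovery_config(),
                            background = background_freqs()) {
  refined <- em_refine(pwm0, sequences, config, background)
  refined$source <- "seeded"
  trimmed <- trim_pwm(refined, ic_min = 0.1, background)
  trimmed$name <- paste0(pwm0$name, "_seeded")
  fit <- motif_fitness(trimmed, sequences, config$p_threshold, background)
  .motif_result(trimmed, fit, 1L)
}
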