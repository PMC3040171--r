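# Synthetic-data generators: directional reads around planted binding events,
# and background sequences with planted PWM sites. These emulate the
# data-generating picture of transcription-factor ChIP-Seq -- sequencing both
# ends of ~200 bp immunoprecipitated fragments centered on binding sites --
# and make every pipeline stage testable without external data.

#' Simulate directional ChIP-Seq reads around planted binding events
#'
#' Each event emits `n_frag` fragments centered on its position, with
#' lengths Normal(`frag_mean`, `frag_sd`) truncated below at `read_len`.
#' Every fragment is sequenced from one end, chosen with equal probability:
#' a `+` read whose 5' end is the fragment's left end, or a `-` read whose
#' 5' end is the fragment's right end. Uniform noise reads are added to both
#' treatment and control at `noise_rate` per bp; the control contains noise
#' only. Reads whose 5' end falls in a mappability gap are deleted from both
#' samples.
#'
#' The recorded per-event `delta_star` is the realized mean 5'-to-5'
#' separation (mean fragment length - 1).
#'
#' @param events `data.frame` with columns `chrom`, `mu` (binding position,
#'   bp) and optionally `n_frag` (default 100).
#' @param chrom_len named vector of chromosome lengths (bp).
#' @param frag_mean,frag_sd fragment length distribution (bp).
#' @param read_len read length (bp); must be below `frag_mean`.
#' @param noise_rate expected uniform noise reads per bp, applied to both
#'   samples.
#' @param map_gaps optional [genomic_intervals] of non-mappable intervals;
#'   reads with `pos5` inside a gap are removed.
#' @param seed RNG seed (the caller's RNG state is restored afterwards).
#' @return A list with [aligned_reads] tables `treatment` and `control`, and
#'   `truth` (events with realized `delta_star` and read counts, plus the
#'   seed).
#' @export
sim_reads <- function(events, chrom_len, frag_mean = 175, frag_sd = 35,
                      read_len = 35L, noise_rate = 1e-3, map_gaps = NULL,
                      seed = NULL) {
  if (frag_mean <= read_len) stop("frag_mean must exceed read_len")
  if (is.null(events$n_frag)) events$n_frag <- 100L
  with_seed(seed, {
    chrom <- character(); pos5 <- integer(); strand <- character()
    delta_star <- numeric(nrow(events))
    for (k in seq_len(nrow(events))) {
      nf <- events$n_frag[k]
      len <- rnorm(nf, frag_mean, frag_sd)
      while (any(len <= read_len)) {
        len[len <= read_len] <- rnorm(sum(len <= read_len), frag_mean, frag_sd)
      }
      len <- round(len)
      left <- as.integer(round(events$mu[k] - len / 2))
      right <- left + as.integer(len)
      fwd <- runif(nf) < 0.5
      p5 <- ifelse(fwd, left, right - 1L)
      keep <- p5 >= 0 & p5 < chrom_len[[events$chrom[k]]]
      chrom <- c(chrom, rep(events$chrom[k], sum(keep)))
      pos5 <- c(pos5, p5[keep])
      strand <- c(strand, ifelse(fwd, "+", "-")[keep])
      delta_star[k] <- mean(len) - 1
    }
    noise <- function() {
      nc <- character(); np <- integer(); ns <- character()
      for (ch in names(chrom_len)) {
        n <- rpois(1L, noise_rate * chrom_len[[ch]])
        if (n == 0L) next
        nc <- c(nc, rep(ch, n))
        np <- c(np, as.integer(floor(runif(n, 0, chrom_len[[ch]] - read_len))))
        ns <- c(ns, sample(c("+", "-"), n, replace = TRUE))
      }
      aligned_reads(nc, np, ns, read_len)
    }
    tnoise <- noise()
    treatment <- aligned_reads(c(chrom, tnoise$chrom), c(pos5, tnoise$pos5),
                               c(strand, tnoise$strand), read_len)
    control <- noise()
    drop_gapped <- function(reads) {
      if (is.null(map_gaps) || !nrow(reads)) return(reads)
      keep <- rep(TRUE, nrow(reads))
      for (ch in unique(reads$chrom)) {
        i <- reads$chrom == ch
        keep[i] <- !is_mappable(map_gaps, ch, reads$pos5[i])
      }
      reads[keep, , drop = FALSE]
    }
    treatment <- drop_gapped(treatment)
    control <- drop_gapped(control)
    rownames(treatment) <- rownames(control) <- NULL
    truth <- list(
      events = data.frame(chrom = events$chrom, mu = events$mu,
                          n_frag = events$n_frag, delta_star = delta_star,
                          stringsAsFactors = FALSE),
      seed = seed
    )
    list(treatment = treatment, control = control, truth = truth)
  })
}

#' Simulate background sequences with planted PWM sites
#'
#' Sequences are i.i.d. letters from `background`. For each sequence and
#' each motif, with probability `occupancy` one site is sampled
#' letter-by-letter from the PWM and planted on a random strand (minus
#' strand plants the reverse complement). Plant positions follow the
#' motif's `dist`: `"uniform"` over admissible offsets, `"center"` (site
#' midpoint Normal around the sequence midpoint, sd `sd`), or `"lag"` (site
#' midpoint at a fixed offset `lag` right of another motif's plant in the
#' same sequence). Plants overlapping an earlier plant are re-drawn up to 10
#' times, then skipped and recorded.
#'
#' @param n number of sequences.
#' @param length sequence length (bp).
#' @param motifs list of plant specifications, each a list with elements
#'   `pwm` (a [pwm]), `occupancy` in `[0, 1]`, `dist` (`"uniform"`,
#'   `"center"` or `"lag"`), and optionally `sd` (default 20, for
#'   `"center"`), `lag` and `anchor` (index of the anchor motif, for
#'   `"lag"`).
#' @param background a [background_freqs] vector.
#' @param seed RNG seed.
#' @return A list with `sequences` (a [seq_records] table) and `truth`
#'   (planted sites, skipped plants, the seed).
#' @export
sim_sequences <- function(n, length, motifs = list(),
                          background = background_freqs(), seed = NULL) {
  length <- as.integer(length)
  for (m in motifs) {
    if (m$pwm$width > length) stop("sequence length below motif width")
    if (m$occupancy < 0 || m$occupancy > 1) stop("occupancy must be in [0, 1]")
  }
  with_seed(seed, {
    bg <- as.numeric(background)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, length, replace = TRUE, prob = bg),
            collapse = "")
    }, "")
    ids <- sprintf("seq%04d", seq_len(n))
    sites <- list()
    skipped <- list()
    occupied <- vector("list", n)  # list of planted [start, end) per sequence
    for (mi in seq_along(motifs)) {
      spec <- motifs[[mi]]
      w <- spec$pwm$width
      for (si in seq_len(n)) {
        if (runif(1) > spec$occupancy) next
        # anchored plants require the anchor to be present in this sequence
        anchor_mid <- NA_real_
        if (identical(spec$dist, "lag")) {
          amatch <- Filter(function(x) x$seq == si && x$motif == spec$anchor,
                           sites)
          if (!length(amatch)) next
          a <- amatch[[1L]]
          anchor_mid <- (a$start + a$end) / 2
        }
        placed <- FALSE
        for (try in 1:10) {
          start <- switch(
            spec$dist,
            uniform = as.integer(floor(runif(1, 0, length - w + 1))),
            center = as.integer(round((length - w) / 2 +
                                        rnorm(1, 0, spec$sd %||% 20))),
            lag = as.integer(round(anchor_mid + spec$lag - w / 2)),
            stop("unknown position dist: ", spec$dist)
          )
          if (is.na(start) || start < 0L || start + w > length) next
          spans <- occupied[[si]]
          clash <- any(vapply(spans, function(sp) {
            start < sp[2L] && sp[1L] < start + w
          }, logical(1)))
          if (clash) next
          strand <- sample(c("+", "-"), 1L)
          word <- vapply(seq_len(w), function(j) {
            sample(DNA_BASES, 1L, prob = spec$pwm$probs[, j])
          }, "")
          if (strand == "-") {
            word <- rev(c(A = "T", C = "G", G = "C", T = "A")[word])
          }
          substr(seqs[si], start + 1L, start + w) <- paste(word, collapse = "")
          occupied[[si]] <- c(spans, list(c(start, start + w)))
          sites[[base::length(sites) + 1L]] <- list(
            seq = si, motif = mi, start = start, end = start + w,
            strand = strand
          )
          placed <- TRUE
          break
        }
        if (!placed && !identical(spec$dist, "lag")) {
          skipped[[base::length(skipped) + 1L]] <- list(seq = si, motif = mi)
        }
      }
    }
    to_df <- function(lst, cols) {
      if (!base::length(lst)) {
        return(as.data.frame(setNames(lapply(cols, function(.) integer()),
                                      cols)))
      }
      out <- do.call(rbind, lapply(lst, function(x) {
        as.data.frame(x[cols], stringsAsFactors = FALSE)
      }))
      rownames(out) <- NULL
      out
    }
    truth_sites <- to_df(sites, c("seq", "motif", "start", "end", "strand"))
    if (nrow(truth_sites)) {
      truth_sites$seq_id <- ids[truth_sites$seq]
      truth_sites$motif_name <- vapply(truth_sites$motif,
                                       function(i) motifs[[i]]$pwm$name, "")
    }
    list(
      sequences = seq_records(ids, seqs),
      truth = list(sites = truth_sites,
                   skipped = to_df(skipped, c("seq", "motif")),
                   seed = seed)
    )
  })
}
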