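# Position weight matrix model: log-odds scoring, exact score-distribution
# p-values by dynamic programming on a discretized score grid, scanning,
# information content and width trimming.

# Default discretization: 1/1000 of a log2 unit. The p-value error is bounded
# by the probability mass within w*granularity of the threshold.
.PWM_GRANULARITY <- 1e-3

#' Construct a position weight matrix
#'
#' @param probs a 4 x w column-stochastic matrix, rows in A, C, G, T order.
#'   Every column must sum to 1 (within 1e-9) with strictly positive entries.
#' @param name motif name.
#' @param source one of `"denovo"`, `"seeded"`, `"database"`.
#' @return An object of class `"pwm"` with fields `name`, `width`, `probs`,
#'   `source`.
#' @export
pwm <- function(probs, name = "motif", source = c("denovo", "seeded", "database")) {
  source <- match.arg(source)
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 1L) stop("PWM must have at least one column")
  if (any(probs <= 0)) stop("PWM entries must be strictly positive (pseudocounted)")
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("PWM columns must sum to 1 within 1e-9")
  }
  rownames(probs) <- DNA_BASES
  structure(
    list(name = as.character(name), width = ncol(probs), probs = probs,
         source = source),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%s), width %d, consensus %s\n",
              x$name, x$source, x$width, pwm_consensus(x)))
  print(round(x$probs, 3))
  invisible(x)
}

#' Background base composition
#'
#' @param freqs length-4 numeric vector of A, C, G, T frequencies; must be
#'   positive and is normalized to sum to 1.
#' @return A named numeric vector of class `"background"`.
#' @export
background_freqs <- function(freqs = c(0.25, 0.25, 0.25, 0.25)) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L || any(freqs <= 0)) {
    stop("background must be 4 positive frequencies")
  }
  structure(setNames(freqs / sum(freqs), DNA_BASES), class = "background")
}

#' Observed base composition of a sequence set
#'
#' @param records a [seq_records] table (N bases ignored).
#' @return A [background_freqs] vector.
#' @export
observed_background <- function(records) {
  tab <- table(factor(strsplit(paste(records$seq, collapse = ""), "")[[1]],
                      levels = DNA_BASES))
  if (sum(tab) == 0) return(background_freqs())
  background_freqs(pmax(as.numeric(tab), 0.5))
}

#' Log-odds score matrix
#'
#' `S[i, j] = log2(probs[i, j] / background[i])`, the per-position score of
#' base i at motif column j.
#'
#' @param pwm a [pwm].
#' @param background a [background_freqs] vector.
#' @return A 4 x w numeric matrix.
#' @export
log_odds <- function(pwm, background = background_freqs()) {
  log2(pwm$probs / as.numeric(background))
}

#' Reverse complement of a PWM
#'
#' Columns reversed, rows permuted A<->T and C<->G; an involution.
#'
#' @param pwm a [pwm].
#' @return A [pwm].
#' @export
reverse_complement <- function(pwm) {
  probs <- pwm$probs[c(4L, 3L, 2L, 1L), rev(seq_len(pwm$width)), drop = FALSE]
  rownames(probs) <- DNA_BASES
  out <- pwm
  out$probs <- probs
  out
}

#' Consensus string of a PWM
#'
#' @param pwm a [pwm].
#' @return Character scalar: the modal base of each column.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2L, which.max)], collapse = "")
}

#' Exact distribution of the PWM score of a background word
#'
#' The log-odds of each column are rounded to a grid of `granularity` log2
#' units and the distribution of the column sum under i.i.d. background
#' letters is built by dynamic-programming convolution, one column at a
#' time. The result is exact on the grid; the rounding error of any word's
#' score is at most `width * granularity / 2`.
#'
#' @param pwm a [pwm].
#' @param background a [background_freqs] vector.
#' @param granularity grid step in log2 units.
#' @return A list with integer grid `support` (score = support * granularity),
#'   `probs`, the matching tail probabilities `tail` (P(score >= support)),
#'   `granularity`, and the integer score matrix `score_int`.
#' @export
score_distribution <- function(pwm, background = background_freqs(),
                               granularity = .PWM_GRANULARITY) {
  S <- log_odds(pwm, background)
  Si <- matrix(as.integer(round(S / granularity)), nrow = 4L)
  d <- score_dist_cpp(Si, as.numeric(background))
  support <- seq.int(d$lo, d$lo + length(d$probs) - 1L)
  list(support = support, probs = d$probs,
       tail = rev(cumsum(rev(d$probs))),
       granularity = granularity, score_int = Si)
}

# Tail lookup on an integer-grid distribution: P(score_int >= s_int).
.tail_at <- function(dist, s_int) {
  lo <- dist$support[1L]
  n <- length(dist$tail)
  idx <- s_int - lo + 1
  out <- numeric(length(idx))
  out[idx <= 1] <- 1
  inside <- idx >= 1 & idx <= n
  out[inside] <- dist$tail[idx[inside]]
  out  # idx > n -> 0
}

#' p-value of a PWM score threshold
#'
#' `P(score(X) >= threshold)` for `X` an i.i.d. background word of the PWM's
#' width, computed exactly on the discretized score grid.
#'
#' @inheritParams score_distribution
#' @param threshold_score score threshold in log2 units.
#' @return A probability in `[0, 1]`.
#' @export
score_pvalue <- function(pwm, background = background_freqs(), threshold_score,
                         granularity = .PWM_GRANULARITY) {
  dist <- score_distribution(pwm, background, granularity)
  .tail_at(dist, as.integer(round(threshold_score / granularity)))
}

#' Scan sequences for PWM occurrences
#'
#' Every window of the PWM's width whose score p-value is at or below
#' `p_threshold` is reported; windows containing `N` are skipped. Scores are
#' grid-rounded log-odds so that reported p-values are exact for the
#' reported score. When sequences carry genomic origins, occurrence
#' coordinates are lifted to the genome.
#'
#' @param pwm a [pwm].
#' @param sequences a [seq_records] table.
#' @param p_threshold scan p-value threshold in (0, 1).
#' @param background a [background_freqs] vector.
#' @param both_strands also scan the reverse strand (reverse-complement PWM).
#' @return A `data.frame` of occurrences: `seq_id`, `start` (0-based offset),
#'   `end`, `strand`, `score`, `pval`, and genomic columns `chrom`,
#'   `gstart`, `gend` (NA without provenance), sorted by
#'   (`seq_id`, `start`, `strand`).
#' @export
scan_sequences <- function(pwm, sequences, p_threshold = 2e-4,
                           background = background_freqs(),
                           both_strands = TRUE) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  enc <- encode_seq_matrix(sequences$seq)
  occ <- .scan_encoded(pwm, enc, nchar(sequences$seq), p_threshold, background,
                       both_strands)
  if (!nrow(occ)) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(), pval = numeric(),
                      chrom = character(), gstart = integer(), gend = integer(),
                      stringsAsFactors = FALSE))
  }
  i <- occ$seq_row
  out <- data.frame(
    seq_id = sequences$id[i], start = occ$start, end = occ$end,
    strand = occ$strand, score = occ$score, pval = occ$pval,
    chrom = sequences$chrom[i],
    gstart = sequences$start[i] + occ$start,
    gend = sequences$start[i] + occ$end,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Scan pre-encoded sequences; returns occurrences keyed by row index.
# Shared by scan_sequences and the discovery fitness path (which reuses the
# encoding across many PWMs).
.scan_encoded <- function(pwm, enc, seq_len_vec, p_threshold, background,
                          both_strands, dist = NULL) {
  g <- .PWM_GRANULARITY
  dist <- dist %||% score_distribution(pwm, background, g)
  w <- pwm$width
  # minimal integer score with tail <= p_threshold
  ok <- dist$tail <= p_threshold
  if (!any(ok)) cutoff <- dist$support[length(dist$support)] + 1L else {
    cutoff <- dist$support[which(ok)[1L]]
  }
  res <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (str in strands) {
    Si <- if (str == "+") dist$score_int else {
      dist$score_int[c(4L, 3L, 2L, 1L), rev(seq_len(w)), drop = FALSE]
    }
    sc <- score_windows_cpp(enc, Si)   # integer-grid scores, NA at N windows
    hits <- which(!is.na(sc) & sc >= cutoff, arr.ind = TRUE)
    if (!nrow(hits)) next
    start <- hits[, 2L] - 1L
    keep <- start + w <= seq_len_vec[hits[, 1L]]
    hits <- hits[keep, , drop = FALSE]
    start <- start[keep]
    if (!nrow(hits)) next
    s_int <- sc[hits]
    res[[str]] <- data.frame(
      seq_row = hits[, 1L], start = as.integer(start),
      end = as.integer(start + w), strand = str,
      score = s_int * g, pval = .tail_at(dist, s_int),
      stringsAsFactors = FALSE
    )
  }
  if (!length(res)) {
    return(data.frame(seq_row = integer(), start = integer(), end = integer(),
                      strand = character(), score = numeric(), pval = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-column information content
#'
#' `IC_j = sum_i probs[i, j] * log2(probs[i, j] / background[i])` bits.
#'
#' @inheritParams log_odds
#' @return Numeric vector of length `width`.
#' @export
information_content <- function(pwm, background = background_freqs()) {
  colSums(pwm$probs * log2(pwm$probs / as.numeric(background)))
}

#' Trim uninformative flanking columns from a PWM
#'
#' Removes maximal runs of flanking columns with information content below
#' `ic_min` from both ends, never trimming below width 4. This is the motif
#' width-adjustment primitive used after EM refinement.
#'
#' @inheritParams log_odds
#' @param ic_min minimum information content (bits) for a flank column to be
#'   kept.
#' @return A [pwm].
#' @export
trim_pwm <- function(pwm, ic_min = 0.1, background = background_freqs()) {
  ic <- information_content(pwm, background)
  w <- pwm$width
  lo <- 1L
  hi <- w
  while (lo < hi && ic[lo] < ic_min && (hi - lo) >= 4L) lo <- lo + 1L
  while (hi > lo && ic[hi] < ic_min && (hi - lo + 1L) > 4L) hi <- hi - 1L
  if (hi - lo + 1L < 4L) {
    # re-expand symmetrically to the minimum width
    while (hi - lo + 1L < 4L && hi < w) hi <- hi + 1L
    while (hi - lo + 1L < 4L && lo > 1L) lo <- lo - 1L
  }
  out <- pwm
  out$probs <- pwm$probs[, lo:hi, drop = FALSE]
  out$width <- ncol(out$probs)
  out
}
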