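# Shared fixtures: all synthetic, built in code.

# PWM with probability `p` on the consensus letter of each column.
cons_pwm <- function(s, p = 0.9, name = s) {
  idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - p) / 3, 4, length(idx))
  m[cbind(idx, seq_along(idx))] <- p
  pwm(m, name = name)
}

# Random column-stochastic PWM (Dirichlet-ish columns via gamma draws).
random_pwm <- function(w, name = "rand", concentration = 0.5) {
  m <- matrix(stats::rgamma(4 * w, concentration) + 1e-6, 4, w)
  pwm(sweep(m, 2, colSums(m), "/"), name = name)
}

# Random high-information PWM: sharp consensus columns.
random_sharp_pwm <- function(w, name = "sharp", p = 0.85) {
  cons <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                collapse = "")
  cons_pwm(cons, p = p, name = name)
}

# A threshold lying in a wide gap between score atoms. The discretization
# bound controls score rounding, so p-value agreement holds for thresholds
# farther than the rounding slack from any attainable score; a threshold
# placed exactly on an atom flips that atom's whole mass with the rounding
# direction, which no grid method can bound.
atom_safe_threshold <- function(p, background, g = 1e-3) {
  w <- p$width
  S <- log_odds(p, background)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  for (j in seq_len(w)) sc <- sc + S[cbind(words[, j], j)]
  u <- sort(unique(sc))
  gaps <- diff(u)
  upper <- which(u[-1] >= stats::median(sc))
  cand <- upper[gaps[upper] > 10 * w * g]
  i <- if (length(cand)) cand[which.max(gaps[cand])] else which.max(gaps)
  (u[i] + u[i + 1]) / 2
}

# Exhaustive score p-value for PWMs of small width (the enumeration oracle).
enum_pvalue <- function(p, background, threshold) {
  w <- p$width
  S <- log_odds(p, background)
  bg <- as.numeric(background)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  pr <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    sc <- sc + S[cbind(words[, j], j)]
    pr <- pr * bg[words[, j]]
  }
  sum(pr[sc >= threshold])
}

# Brute-force best ungapped PWM alignment (the exhaustive oracle for
# align_pwms): all offsets x strands with >= 4 overlapping columns.
brute_align <- function(query, target, background = background_freqs()) {
  col_pcc <- function(a, b) {
    if (sd(a) < 1e-12 || sd(b) < 1e-12) return(0)
    sum((a - mean(a)) * (b - mean(b))) / (3 * sd(a) * sd(b))
  }
  best <- NULL
  for (strand in c("+", "-")) {
    tp <- if (strand == "+") target$probs else reverse_complement(target)$probs
    for (off in -(target$width - 4L):(query$width - 4L)) {
      qc <- max(1, 1 + off):min(query$width, target$width + off)
      tc <- qc - off
      sc <- mean(mapply(function(i, j) col_pcc(query$probs[, i], tp[, j]),
                        qc, tc))
      if (is.null(best) || sc > best$sim_score + 1e-12) {
        best <- list(offset = off, strand = strand, sim_score = sc)
      }
    }
  }
  best
}

# Deterministic synthetic JASPAR-style database of distinct high-information
# motifs with graded (unequal) column sharpness, as in real databases.
synthetic_db <- function(n = 100, seed = 1) {
  set.seed(seed)
  db <- list()
  seen <- character()
  while (length(db) < n) {
    w <- sample(8:14, 1)
    cons <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                  collapse = "")
    if (cons %in% seen) next
    seen <- c(seen, cons)
    idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
    p_col <- stats::runif(w, 0.6, 0.95)
    # uneven off-consensus weights, as in real count-derived matrices
    m <- matrix(0, 4, w)
    for (j in seq_len(w)) {
      eps <- stats::rgamma(3, 1) + 0.05
      m[-idx[j], j] <- (1 - p_col[j]) * eps / sum(eps)
      m[idx[j], j] <- p_col[j]
    }
    nm <- sprintf("SYN%03d_%s", length(db) + 1L, cons)
    db[[nm]] <- pwm(m, name = nm)
  }
  db
}
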