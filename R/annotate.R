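# Post-processing of discovered motifs: alignment against reference PWM
# databases with extreme-value-calibrated similarity E-values, filtering,
# virtual combining, distance-to-peak and pairwise-distance statistics, and
# occurrence export.

# All pairwise column similarities of two PWMs as a wq x wt matrix.
# PCC: Pearson correlation of probability 4-vectors (0 when a column is
# uniform); ALLR: average log-likelihood ratio against the background.
.col_sim_matrix <- function(q, t, metric, bg) {
  if (metric == "pcc") {
    z <- function(p) {
      zc <- sweep(p, 2L, colMeans(p))
      s <- sqrt(colSums(zc^2))
      zc[, s > 1e-12] <- sweep(zc[, s > 1e-12, drop = FALSE], 2L,
                               s[s > 1e-12], "/")
      zc[, s <= 1e-12] <- 0
      zc
    }
    crossprod(z(q), z(t))
  } else {
    (crossprod(q, log(t / bg)) + crossprod(log(q / bg), t)) / 2
  }
}

#' Align two PWMs without gaps
#'
#' Scores every ungapped offset with at least 4 overlapping columns, in
#' both target orientations; the score is the mean per-aligned-column
#' similarity (Pearson correlation of probability columns by default).
#' Ties are broken deterministically by smaller absolute offset, then `+`
#' strand.
#'
#' @param query,target [pwm] objects.
#' @param metric `"pcc"` (column Pearson correlation) or `"allr"` (average
#'   log-likelihood ratio).
#' @param background a [background_freqs] vector (used by `"allr"`).
#' @return A list: `offset` (target start minus query start, in columns),
#'   `strand`, `sim_score`, `overlap`. Among equal scores, larger overlaps
#'   are preferred, then smaller absolute offset, then the `+` strand.
#' @export
align_pwms <- function(query, target, metric = c("pcc", "allr"),
                       background = background_freqs()) {
  metric <- match.arg(metric)
  bg <- as.numeric(background)
  wq <- query$width
  wt <- target$width
  if (min(wq, wt) < 4L) stop("PWMs must be at least 4 columns wide to align")
  best <- NULL
  better <- function(cand, best) {
    if (is.null(best)) return(TRUE)
    if (cand$sim_score > best$sim_score + 1e-12) return(TRUE)
    if (cand$sim_score < best$sim_score - 1e-12) return(FALSE)
    if (cand$overlap != best$overlap) return(cand$overlap > best$overlap)
    if (abs(cand$offset) != abs(best$offset)) {
      return(abs(cand$offset) < abs(best$offset))
    }
    cand$strand == "+" && best$strand == "-"
  }
  for (strand in c("+", "-")) {
    tp <- if (strand == "+") target$probs else reverse_complement(target)$probs
    D <- .col_sim_matrix(query$probs, tp, metric, bg)
    for (off in seq.int(-(wt - 4L), wq - 4L)) {
      qcols <- max(1L, 1L + off):min(wq, wt + off)
      score <- mean(D[cbind(qcols, qcols - off)])
      cand <- list(offset = off, strand = strand, sim_score = score,
                   overlap = length(qcols))
      if (better(cand, best)) best <- cand
    }
  }
  best
}

# Gumbel maximum-likelihood fit (location mu, scale beta > 0).
.fit_gumbel <- function(z) {
  zbar <- mean(z)
  s <- sd(z)
  if (s < 1e-9) return(list(mu = zbar, beta = 1e-6))
  f <- function(beta) {
    e <- exp(-(z - zbar) / beta)   # centered for stability
    beta - zbar + sum(z * e) / sum(e)
  }
  lo <- s * 0.05
  hi <- s * 5
  beta <- tryCatch(uniroot(f, c(lo, hi), extendInt = "yes")$root,
                   error = function(e) s * sqrt(6) / pi)
  mu <- zbar - beta * log(mean(exp(-(z - zbar) / beta)))
  list(mu = mu, beta = beta)
}

# Fisher z-transform of a (clamped) correlation-type similarity score, the
# scale on which the extreme-value null is fitted.
.sim_z <- function(s) atanh(pmin(pmax(s, -1 + 1e-4), 1 - 1e-4))

#' Calibrate a null model for motif similarity scores
#'
#' Null alignment scores are generated by aligning column-shuffled PWM
#' pairs drawn from the database, bucketed by the smaller width of the
#' pair. Within each bucket an extreme-value (Gumbel) distribution is
#' fitted by maximum likelihood to the Fisher-z-transformed scores;
#' `E(score) = N_db * P_null(S >= score)`. Buckets with too few samples
#' are widened to their neighbours and flagged.
#'
#' @param db list of [pwm] objects (the reference database).
#' @param n_samples number of null alignments (>= 100).
#' @param metric similarity metric, as in [align_pwms].
#' @param seed RNG seed.
#' @param background a [background_freqs] vector.
#' @return A list of class `"motif_null"`: per-bucket Gumbel parameters,
#'   database size, metric and seed.
#' @export
calibrate_null <- function(db, n_samples = 1000L, metric = "pcc", seed = NULL,
                           background = background_freqs()) {
  if (n_samples < 100L) stop("n_samples must be >= 100")
  shuffle_cols <- function(p) {
    out <- p
    out$probs <- p$probs[, sample.int(p$width), drop = FALSE]
    out
  }
  with_seed(seed, {
    scores <- numeric(n_samples)
    wmin <- integer(n_samples)
    for (i in seq_len(n_samples)) {
      ij <- sample.int(length(db), 2L, replace = length(db) < 2L)
      a <- shuffle_cols(db[[ij[1L]]])
      b <- shuffle_cols(db[[ij[2L]]])
      al <- align_pwms(a, b, metric, background)
      scores[i] <- al$sim_score
      wmin[i] <- min(a$width, b$width)
    }
    # bucket by the smaller width; widen sparse buckets
    ws <- sort(unique(wmin))
    buckets <- list()
    flagged <- FALSE
    i <- 1L
    while (i <= length(ws)) {
      j <- i
      idx <- which(wmin == ws[i])
      while (length(idx) < 100L && j < length(ws)) {
        j <- j + 1L
        idx <- which(wmin >= ws[i] & wmin <= ws[j])
        flagged <- TRUE
      }
      if (length(idx) < 30L && length(buckets)) {
        # fold a tiny trailing bucket into the previous one
        prev <- buckets[[length(buckets)]]
        idx <- c(idx, which(wmin >= prev$wmin_lo & wmin <= prev$wmin_hi))
        fitp <- .fit_gumbel(.sim_z(scores[idx]))
        buckets[[length(buckets)]] <- list(
          wmin_lo = prev$wmin_lo, wmin_hi = ws[j], mu = fitp$mu,
          beta = fitp$beta, n = length(idx)
        )
        flagged <- TRUE
      } else {
        fitp <- .fit_gumbel(.sim_z(scores[idx]))
        buckets[[length(buckets) + 1L]] <- list(
          wmin_lo = ws[i], wmin_hi = ws[j], mu = fitp$mu, beta = fitp$beta,
          n = length(idx)
        )
      }
      i <- j + 1L
    }
    structure(
      list(buckets = do.call(rbind.data.frame, buckets), n_db = length(db),
           metric = metric, n_samples = n_samples, seed = seed,
           widened = flagged),
      class = "motif_null"
    )
  })
}

#' Similarity E-value under a calibrated null
#'
#' @param null a `"motif_null"` from [calibrate_null].
#' @param score alignment similarity score(s).
#' @param wmin smaller width of the aligned pair.
#' @return E-value(s): expected number of database PWMs scoring at least
#'   this well by chance; monotone non-increasing in `score`.
#' @export
similarity_evalue <- function(null, score, wmin) {
  b <- null$buckets
  k <- findInterval(wmin, b$wmin_lo)
  k <- pmin(pmax(k, 1L), nrow(b))
  z <- .sim_z(score)
  # Gumbel survival on the transformed scale
  p <- -expm1(-exp(-(z - b$mu[k]) / b$beta[k]))
  pmax(null$n_db * p, 1e-300)
}

#' Match query PWMs against a reference database
#'
#' Every query is aligned to every database motif; matches are ranked by
#' ascending E-value (ties by target name) and the top `n_best` per query
#' are returned.
#'
#' @param queries list of [pwm] objects (or a single [pwm]).
#' @param db named list of [pwm] objects.
#' @param null a `"motif_null"` calibrated on `db`.
#' @param n_best matches kept per query.
#' @param background a [background_freqs] vector.
#' @return A `data.frame`: `query`, `target`, `offset`, `strand`,
#'   `sim_score`, `overlap`, `evalue`; ties in E-value are resolved toward
#'   larger alignment overlaps, then target name.
#' @export
match_database <- function(queries, db, null, n_best = 5L,
                           background = background_freqs()) {
  if (!length(db)) stop("empty motif database")
  if (inherits(queries, "pwm")) queries <- list(queries)
  out <- list()
  for (q in queries) {
    rows <- lapply(seq_along(db), function(i) {
      t <- db[[i]]
      al <- align_pwms(q, t, null$metric, background)
      data.frame(
        query = q$name, target = t$name, offset = al$offset,
        strand = al$strand, sim_score = al$sim_score, overlap = al$overlap,
        evalue = similarity_evalue(null, al$sim_score, min(q$width, t$width)),
        stringsAsFactors = FALSE
      )
    })
    rows <- do.call(rbind, rows)
    rows <- rows[order(rows$evalue, -rows$overlap, rows$target), ,
                 drop = FALSE]
    out[[length(out) + 1L]] <- head(rows, n_best)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter match results by target name and E-value
#'
#' A query motif is kept when it has at least one match whose target name
#' contains any of the patterns (case-insensitive) and whose E-value is at
#' most `evalue_max`; both criteria are optional. All matches of kept
#' queries are returned.
#'
#' @param matches a match table from [match_database].
#' @param name_patterns character vector of substrings (e.g. `"STAT"`), or
#'   `NULL` for no name filter.
#' @param evalue_max E-value cutoff (e.g. `1e-4`), or `NULL`.
#' @return The filtered match table.
#' @export
filter_matches <- function(matches, name_patterns = NULL, evalue_max = NULL) {
  hit <- rep(TRUE, nrow(matches))
  if (!is.null(name_patterns)) {
    hit <- hit & Reduce(`|`, lapply(name_patterns, function(p) {
      grepl(p, matches$target, ignore.case = TRUE)
    }))
  }
  if (!is.null(evalue_max)) hit <- hit & matches$evalue <= evalue_max
  keep_queries <- unique(matches$query[hit])
  out <- matches[matches$query %in% keep_queries, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Virtually combine motifs under one label
#'
#' Combining is virtual: the member PWMs are never modified; the selected
#' motifs are simply assigned the same label and their occurrence lists
#' pooled.
#'
#' @param results list of `"motif_result"` objects (from discovery).
#' @param label label for the combined motif.
#' @param selector character vector of member motif names, or a predicate
#'   function over a `"motif_result"`.
#' @return A list of class `"motif_label"`: `label`, `members`,
#'   `occurrences` (pooled, with a `label` column).
#' @export
combine_motifs <- function(results, label, selector) {
  names_all <- vapply(results, function(r) r$pwm$name, "")
  keep <- if (is.function(selector)) {
    vapply(results, function(r) isTRUE(selector(r)), logical(1))
  } else {
    names_all %in% selector
  }
  if (!any(keep)) stop("selector selected no motifs")
  members <- results[keep]
  occ <- do.call(rbind, lapply(members, `[[`, "occurrences"))
  occ$label <- label
  rownames(occ) <- NULL
  structure(
    list(label = label, members = names_all[keep], occurrences = occ),
    class = "motif_label"
  )
}

.distance_summary <- function(d, span, bin_width, n_unmatched,
                              co_occurrence = NULL, n_both = NULL,
                              n_rarer = NULL) {
  breaks <- seq(-span, span, by = bin_width)
  counts <- as.numeric(table(cut(d, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  structure(
    list(breaks = breaks, mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
         counts = counts, n_total = length(d), n_unmatched = n_unmatched,
         co_occurrence = co_occurrence, n_both = n_both, n_rarer = n_rarer),
    class = "distance_summary"
  )
}

#' Distance distribution between motif occurrences and peak centers
#'
#' Signed distance from each occurrence midpoint to the nearest binding
#' event on the same chromosome (genomic mode: occurrences carry `chrom` /
#' `gstart` / `gend`; events have `chrom` and `mu`), or to per-sequence
#' centers (relative mode: `events` has `seq_id` and `center`). A
#' biologically relevant motif concentrates around zero; a flat
#' distribution indicates an artifact. Occurrences with no resolvable
#' center within `span` are tallied as unmatched, never silently dropped.
#'
#' @param occurrences an occurrence table (from [scan_sequences],
#'   [motif_fitness] or a `"motif_label"`).
#' @param events binding events (`chrom` + `mu`) or centers
#'   (`seq_id` + `center`).
#' @param bin_width histogram bin width (bp).
#' @param span histogram half-range (bp); the default matches 400-bp
#'   regions.
#' @return A `"distance_summary"`: `breaks`, `mids`, `counts`, `n_total`,
#'   `n_unmatched`.
#' @export
distance_to_peak <- function(occurrences, events, bin_width = 10, span = 200) {
  if (inherits(occurrences, "motif_label")) occurrences <- occurrences$occurrences
  if (inherits(occurrences, "motif_result")) occurrences <- occurrences$occurrences
  n <- nrow(occurrences)
  d <- numeric(0)
  unmatched <- 0L
  relative <- !is.null(events$seq_id)
  for (i in seq_len(n)) {
    if (relative) {
      ctr <- events$center[events$seq_id == occurrences$seq_id[i]]
      mid <- (occurrences$start[i] + occurrences$end[i]) / 2
    } else {
      if (is.na(occurrences$chrom[i])) { unmatched <- unmatched + 1L; next }
      ctr <- events$mu[events$chrom == occurrences$chrom[i]]
      mid <- (occurrences$gstart[i] + occurrences$gend[i]) / 2
    }
    if (!length(ctr)) { unmatched <- unmatched + 1L; next }
    di <- mid - ctr[which.min(abs(mid - ctr))]
    if (abs(di) > span) { unmatched <- unmatched + 1L; next }
    d <- c(d, di)
  }
  .distance_summary(d, span, bin_width, unmatched)
}

#' Pairwise distance distribution between two motifs
#'
#' For every sequence containing both motifs, all signed midpoint
#' differences (B minus A) within `max_gap` are collected. The
#' co-occurrence fraction is the number of sequences carrying both motifs
#' divided by the number carrying the rarer one. When both sets are the
#' same motif, zero-distance self-comparisons are excluded.
#'
#' @param occA,occB occurrence tables keyed by `seq_id`.
#' @param max_gap maximum absolute distance retained (bp).
#' @param bin_width histogram bin width (bp).
#' @return A `"distance_summary"` with `co_occurrence`, `n_both`,
#'   `n_rarer` fields.
#' @export
pairwise_distances <- function(occA, occB, max_gap = 200, bin_width = 10) {
  if (inherits(occA, "motif_result")) occA <- occA$occurrences
  if (inherits(occB, "motif_result")) occB <- occB$occurrences
  if (inherits(occA, "motif_label")) occA <- occA$occurrences
  if (inherits(occB, "motif_label")) occB <- occB$occurrences
  seqsA <- unique(occA$seq_id)
  seqsB <- unique(occB$seq_id)
  both <- intersect(seqsA, seqsB)
  d <- numeric(0)
  for (sid in both) {
    a <- occA[occA$seq_id == sid, , drop = FALSE]
    b <- occB[occB$seq_id == sid, , drop = FALSE]
    midA <- (a$start + a$end) / 2
    midB <- (b$start + b$end) / 2
    for (i in seq_along(midA)) {
      for (j in seq_along(midB)) {
        same <- a$start[i] == b$start[j] && a$end[i] == b$end[j] &&
          a$strand[i] == b$strand[j]
        if (same) next  # self-comparison (identical occurrence)
        dij <- midB[j] - midA[i]
        if (abs(dij) <= max_gap) d <- c(d, dij)
      }
    }
  }
  n_rarer <- min(length(seqsA), length(seqsB))
  .distance_summary(d, max_gap, bin_width, 0L,
                    co_occurrence = if (n_rarer) length(both) / n_rarer else NA,
                    n_both = length(both), n_rarer = n_rarer)
}

#' Export motif occurrences as BED6 or TSV
#'
#' BED6 rows are (chrom, start, end, label, score, strand), sorted by
#' position; all occurrences must carry genomic provenance, otherwise the
#' offending motif is named in the error. The TSV format is
#' sequence-relative (`seq_id`, `start`, `end`, `label`, `score`,
#' `strand`).
#'
#' @param x a `"motif_result"`, `"motif_label"`, list of either, or an
#'   occurrence table with a `label` column.
#' @param path output path.
#' @param format `"bed"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
export_occurrences <- function(x, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  gather <- function(x) {
    if (inherits(x, "motif_result")) {
      occ <- x$occurrences
      occ$label <- x$pwm$name
      return(occ)
    }
    if (inherits(x, "motif_label")) return(x$occurrences)
    if (is.data.frame(x)) {
      if (is.null(x$label)) x$label <- "occurrence"
      return(x)
    }
    do.call(rbind, lapply(x, gather))
  }
  occ <- gather(x)
  if (is.null(occ) || !nrow(occ)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (format == "bed") {
    bad <- is.na(occ$chrom) | is.na(occ$gstart)
    if (any(bad)) {
      stop("no genomic provenance for occurrences of motif '",
           occ$label[bad][1L], "'; use format = 'tsv'")
    }
    occ <- occ[order(occ$chrom, occ$gstart, occ$gend, occ$strand), ,
               drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%.4f\t%s", occ$chrom, occ$gstart,
                       occ$gend, occ$label, occ$score, occ$strand), path)
  } else {
    occ <- occ[order(occ$seq_id, occ$start, occ$strand), , drop = FALSE]
    header <- "seq_id\tstart\tend\tlabel\tscore\tstrand"
    writeLines(c(header,
                 sprintf("%s\t%d\t%d\t%s\t%.4f\t%s", occ$seq_id, occ$start,
                         occ$end, occ$label, occ$score, occ$strand)), path)
  }
  invisible(path)
}
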