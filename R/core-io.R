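# Genomic data model and standard-format readers/writers shared by all stages.
#
# Conventions: all coordinates are 0-based half-open (BED-native) internally.
# The 5' end of a minus-strand read is the rightmost base it covers, i.e.
# pos5 = BED end - 1.

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open (`start` inclusive, `end` exclusive), the
#' native BED convention used throughout the package.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` is enforced.
#' @param strand strand symbols, one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` with class `"genomic_intervals"`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start), length(end))
  strand <- rep_len(as.character(strand), if (n) n else 0L)
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must exceed start (half-open)")
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  out <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    strand = strand, stringsAsFactors = FALSE
  )
  class(out) <- c("genomic_intervals", class(out))
  out
}

#' Construct a table of aligned reads
#'
#' Each row is one mapped sequencing read, reduced to its chromosome, the
#' position of its 5' end, its strand, and its length.
#'
#' @param chrom character vector of chromosome names.
#' @param pos5 integer vector, 0-based position of the 5' end.
#' @param strand `"+"` or `"-"`.
#' @param read_len read length in bp (> 0).
#' @return A `data.frame` with class `"aligned_reads"`.
#' @export
aligned_reads <- function(chrom, pos5, strand, read_len = 35L) {
  pos5 <- as.integer(pos5)
  n <- length(pos5)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  read_len <- rep_len(as.integer(read_len), n)
  if (any(pos5 < 0L)) stop("pos5 must be >= 0")
  if (any(read_len <= 0L)) stop("read_len must be > 0")
  if (n && !all(strand %in% c("+", "-"))) stop("read strand must be '+' or '-'")
  out <- data.frame(
    chrom = chrom, pos5 = pos5, strand = strand, read_len = read_len,
    stringsAsFactors = FALSE
  )
  class(out) <- c("aligned_reads", class(out))
  out
}

#' Construct a table of sequence records
#'
#' @param id character vector of sequence identifiers.
#' @param seq character vector over A/C/G/T/N (uppercased on construction).
#' @param chrom,start,end,strand optional genomic origin of each sequence;
#'   when given, `end - start` must equal the sequence length.
#' @return A `data.frame` with class `"seq_records"`.
#' @export
seq_records <- function(id, seq, chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_, strand = NA_character_) {
  seq <- toupper(as.character(seq))
  n <- length(seq)
  if (any(!nzchar(seq))) stop("empty sequence record")
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character in sequence '%s' at position %d",
                 rep_len(id, n)[i], bad[i]))
  }
  out <- data.frame(
    id = rep_len(as.character(id), n), seq = seq,
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  has_origin <- !is.na(out$chrom)
  if (any(has_origin & (out$end - out$start) != nchar(out$seq))) {
    stop("origin interval length must equal sequence length")
  }
  class(out) <- c("seq_records", class(out))
  out
}

#' Read aligned reads from a six-column BED file
#'
#' Columns are chrom, start, end, name, score, strand. For `+` reads the 5'
#' end is the BED start; for `-` reads it is `end - 1` (the rightmost covered
#' base). Read length is `end - start`.
#'
#' @param path path to a BED6 file.
#' @param dialect only `"bed"` is supported.
#' @return An [aligned_reads] table, rows in file order.
#' @export
read_reads <- function(path, dialect = "bed") {
  dialect <- match.arg(dialect, "bed")
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(aligned_reads(character(), integer(), character()))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop(sprintf("malformed BED line %d: expected 6 columns, got %d",
                 lineno[which(nf < 6L)[1L]], nf[which(nf < 6L)[1L]]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: bad start/end fields", lineno[bad[1L]]))
  }
  strand <- m[, 6L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: read strand must be '+' or '-', got '%s'",
                 lineno[bad[1L]], strand[bad[1L]]))
  }
  pos5 <- ifelse(strand == "+", start, end - 1L)
  aligned_reads(m[, 1L], pos5, strand, end - start)
}

#' Write aligned reads as BED6
#'
#' Inverse of [read_reads]: rows are written in input order, so
#' write-then-read is the identity.
#'
#' @param reads an [aligned_reads] table.
#' @param path output path.
#' @param names optional read names (default `r1, r2, ...`).
#' @export
write_reads <- function(reads, path, names = NULL) {
  start <- ifelse(reads$strand == "+", reads$pos5,
                  reads$pos5 - reads$read_len + 1L)
  end <- start + reads$read_len
  nm <- names %||% if (nrow(reads)) paste0("r", seq_len(nrow(reads))) else character()
  writeLines(
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", reads$chrom, start, end, nm, 0L,
            reads$strand),
    path
  )
  invisible(path)
}

# "id chrom:start-end(strand)" header grammar carrying genomic origin.
.parse_fasta_header <- function(h) {
  m <- regmatches(h, regexec("^(\\S+)(?:\\s+(\\S+):(\\d+)-(\\d+)\\(([+.-])\\))?\\s*$", h))[[1]]
  if (!length(m)) return(list(id = h))
  if (!nzchar(m[3L])) return(list(id = m[2L]))
  list(id = m[2L], chrom = m[3L], start = as.integer(m[4L]),
       end = as.integer(m[5L]), strand = m[6L])
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet.
#' Headers of the form `id chrom:start-end(strand)` attach a genomic origin
#' (0-based half-open) to the record.
#'
#' @param path path to a FASTA file.
#' @return A [seq_records] table.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record: ", names(set)[!nzchar(seqs)][1L])
  }
  heads <- lapply(names(set), .parse_fasta_header)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), heads[[i]]$id, bad[i]))
  }
  seq_records(
    id = vapply(heads, `[[`, "", "id"),
    seq = unname(seqs),
    chrom = vapply(heads, function(h) h$chrom %||% NA_character_, ""),
    start = vapply(heads, function(h) h$start %||% NA_integer_, 0L),
    end = vapply(heads, function(h) h$end %||% NA_integer_, 0L),
    strand = vapply(heads, function(h) h$strand %||% NA_character_, "")
  )
}

#' Write sequences to a FASTA file
#'
#' Genomic origins, when present, are carried in the header free-text field
#' so that [read_fasta] recovers them.
#'
#' @param records a [seq_records] table.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  headers <- ifelse(
    is.na(records$chrom), records$id,
    sprintf("%s %s:%d-%d(%s)", records$id, records$chrom, records$start,
            records$end, records$strand)
  )
  set <- Biostrings::BStringSet(setNames(records$seq, headers))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Extract fixed-width windows around genomic positions
#'
#' Mirrors the hand-off from peak calling to motif discovery: fixed-width
#' regions (default use: 400 bp) centered on predicted binding positions are
#' cut out of the genome. Windows running off a chromosome end are padded
#' with `N` and flagged in the `clipped` column.
#'
#' @param genome a [seq_records] table of chromosome sequences (ids are
#'   chromosome names).
#' @param centers a `data.frame` with columns `chrom` and `pos`.
#' @param width window width in bp; must be even. The window is
#'   `[pos - width/2, pos + width/2)` so that `pos - start == width/2`.
#' @return A [seq_records] table with genomic origins set and a logical
#'   `clipped` column.
#' @export
extract_windows <- function(genome, centers, width = 400L) {
  width <- as.integer(width)
  if (width <= 0L || width %% 2L != 0L) stop("width must be a positive even integer")
  half <- width %/% 2L
  idx <- match(centers$chrom, genome$id)
  if (anyNA(idx)) {
    stop("chromosome absent from genome: ", centers$chrom[which(is.na(idx))[1L]])
  }
  n <- nrow(centers)
  out_seq <- character(n)
  clipped <- logical(n)
  starts <- integer(n)
  for (i in seq_len(n)) {
    chrom_seq <- genome$seq[idx[i]]
    L <- nchar(chrom_seq)
    s <- as.integer(centers$pos[i]) - half
    e <- s + width
    lo <- max(s, 0L)
    hi <- min(e, L)
    if (lo >= hi) stop("window entirely outside chromosome ", centers$chrom[i])
    core <- substr(chrom_seq, lo + 1L, hi)
    out_seq[i] <- paste0(strrep("N", lo - s), core, strrep("N", e - hi))
    clipped[i] <- (lo > s) || (e > hi)
    starts[i] <- s
  }
  rec <- seq_records(
    id = sprintf("%s_%d", centers$chrom, as.integer(centers$pos)),
    seq = out_seq, chrom = centers$chrom, start = starts,
    end = starts + width,
    strand = "."
  )
  rec$clipped <- clipped
  rec
}

#' Count subject intervals overlapping each query interval
#'
#' Overlap means sharing at least one base on the same chromosome; strand is
#' ignored. Coordinates are 0-based half-open, so `[10,20)` and `[20,30)` do
#' not overlap.
#'
#' @param query,subject [genomic_intervals] tables (or data.frames with
#'   `chrom`, `start`, `end` columns).
#' @return Integer vector of counts, one per query row.
#' @export
count_overlaps <- function(query, subject) {
  if (!nrow(query)) return(integer())
  if (!nrow(subject)) return(integer(nrow(query)))
  gr <- function(x) {
    GenomicRanges::GRanges(
      x$chrom,
      IRanges::IRanges(start = x$start + 1L, end = x$end)  # 1-based inclusive
    )
  }
  # disjoint chromosome sets are a legitimate zero-overlap case, not a
  # user error worth a warning
  suppressWarnings(
    as.integer(GenomicRanges::countOverlaps(gr(query), gr(subject)))
  )
}

#' Read a mappability profile from a BED file of mappable intervals
#'
#' The complement of the listed intervals is treated as non-mappable.
#' Intervals are sorted and merged per chromosome.
#'
#' @param path BED file (first three columns used).
#' @return A [genomic_intervals] table with class `"mappability"` prepended.
#' @export
read_mappability <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- genomic_intervals(character(), integer(), integer())
  } else {
    fields <- strsplit(lines, "[ \t]+")
    if (any(lengths(fields) < 3L)) stop("mappability BED needs >= 3 columns")
    m <- matrix(unlist(lapply(fields, `[`, 1:3)), ncol = 3L, byrow = TRUE)
    out <- genomic_intervals(m[, 1L], as.integer(m[, 2L]), as.integer(m[, 3L]))
  }
  mappability_profile(out)
}

#' Make a mappability profile from an interval table
#'
#' @param intervals a [genomic_intervals] table of mappable intervals; they
#'   are sorted and overlapping/adjacent intervals merged per chromosome.
#' @return The normalized table with class `"mappability"`.
#' @export
mappability_profile <- function(intervals) {
  if (nrow(intervals)) {
    o <- order(intervals$chrom, intervals$start)
    intervals <- intervals[o, , drop = FALSE]
    merged <- list()
    for (ch in unique(intervals$chrom)) {
      x <- intervals[intervals$chrom == ch, , drop = FALSE]
      s <- x$start; e <- x$end
      ks <- s[1L]; ke <- e[1L]; out_s <- integer(); out_e <- integer()
      for (i in seq_along(s)[-1L]) {
        if (s[i] <= ke) ke <- max(ke, e[i]) else {
          out_s <- c(out_s, ks); out_e <- c(out_e, ke); ks <- s[i]; ke <- e[i]
        }
      }
      merged[[ch]] <- data.frame(chrom = ch, start = c(out_s, ks),
                                 end = c(out_e, ke), strand = ".",
                                 stringsAsFactors = FALSE)
    }
    intervals <- do.call(rbind, merged)
    rownames(intervals) <- NULL
    class(intervals) <- c("genomic_intervals", "data.frame")
  }
  class(intervals) <- unique(c("mappability", class(intervals)))
  intervals
}

# Logical mappability mask over positions `pos` (0-based) on `chrom`.
# A NULL profile means everything is mappable.
is_mappable <- function(profile, chrom, pos) {
  if (is.null(profile)) return(rep(TRUE, length(pos)))
  x <- profile[profile$chrom == chrom, , drop = FALSE]
  if (!nrow(x)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(x))) {
    out <- out | (pos >= x$start[i] & pos < x$end[i])
  }
  out
}

# ---- PWM flat formats -------------------------------------------------------

# Column-count total used by the TRANSFAC/JASPAR writers. Large enough that
# the reader's +0.25/cell pseudocount perturbs probabilities by < 1e-9.
.PWM_WRITE_TOTAL <- 1e10

.normalize_counts <- function(counts, name, source, pseudocount = 0.25) {
  if (any(counts < 0)) stop("negative count in matrix '", name, "'")
  if (any(colSums(counts) == 0)) {
    stop("all-zero column in count matrix '", name, "'")
  }
  probs <- sweep(counts + pseudocount, 2L, colSums(counts) + 4 * pseudocount, "/")
  pwm(probs, name = name, source = source)
}

#' Read position matrices from a TRANSFAC flat file
#'
#' Blocks delimited by `//` with an `ID` (or `NA`/`DE`) name line and a `P0`
#' header followed by numbered count rows (columns A, C, G, T). Counts are
#' converted to probabilities with an additive pseudocount per cell.
#'
#' @param path path to the TRANSFAC file.
#' @param pseudocount added to every cell before column normalization.
#' @return A list of [pwm] objects (`source = "database"`).
#' @export
read_transfac <- function(path, pseudocount = 0.25) {
  lines <- readLines(path)
  pwms <- list()
  name <- NULL
  rows <- list()
  in_matrix <- FALSE
  flush <- function() {
    if (is.null(name) && !length(rows)) return()
    if (!length(rows)) stop("TRANSFAC block '", name, "' has no matrix rows")
    w <- lengths(rows)
    if (length(unique(w)) != 1L) stop("ragged matrix rows in block '", name, "'")
    counts <- t(matrix(unlist(rows), ncol = 4L, byrow = TRUE))
    rownames(counts) <- DNA_BASES
    pwms[[length(pwms) + 1L]] <<- .normalize_counts(counts, name %||% "motif",
                                                    "database", pseudocount)
  }
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, "//")) { flush(); name <- NULL; rows <- list(); in_matrix <- FALSE; next }
    if (grepl("^(ID|NA|DE)\\s", line)) { name <- sub("^(ID|NA|DE)\\s+", "", line); next }
    if (grepl("^P0\\b", line) || grepl("^PO\\b", line)) { in_matrix <- TRUE; next }
    if (grepl("^XX", line)) { in_matrix <- FALSE; next }
    if (grepl("^[0-9]+\\s", line)) {
      f <- strsplit(line, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(f[2:5]))
      if (anyNA(vals)) stop("malformed TRANSFAC count row: ", line)
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush()
  pwms
}

#' Write position matrices to a TRANSFAC flat file
#'
#' Probabilities are written as counts with a large fixed column total, so
#' that reading the file back reproduces the probabilities to better than
#' 1e-9 despite the reader's pseudocount.
#'
#' @param pwms a [pwm] or list of [pwm] objects.
#' @param path output path.
#' @export
write_transfac <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    counts <- p$probs * .PWM_WRITE_TOTAL
    writeLines(c(sprintf("ID %s", p$name), "XX", "P0\tA\tC\tG\tT"), con)
    for (j in seq_len(ncol(counts))) {
      writeLines(sprintf("%02d\t%.1f\t%.1f\t%.1f\t%.1f", j,
                         counts[1L, j], counts[2L, j], counts[3L, j],
                         counts[4L, j]), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read a motif database in JASPAR flat format
#'
#' Records are `>name` followed by four base rows, either bare numbers or
#' the bracketed `A [ 1 2 3 ]` style. Counts are pseudocounted and column
#' normalized as in [read_transfac].
#'
#' @inheritParams read_transfac
#' @return A named list of [pwm] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  pwms <- list()
  for (k in seq_along(starts)) {
    name <- trimws(sub("^>\\s*", "", lines[starts[k]]))
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4L) {
      stop("JASPAR record '", name, "' must have 4 base rows, got ", length(body))
    }
    rows <- lapply(body, function(line) {
      line <- gsub("^[ACGTacgt]\\s*\\[|\\]\\s*$", "", trimws(line))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
      if (anyNA(vals)) stop("malformed JASPAR row in record '", name, "': ", line)
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("ragged rows in JASPAR record '", name, "'")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- DNA_BASES
    pwms[[name]] <- .normalize_counts(counts, name, "database", pseudocount)
  }
  pwms
}

#' Write a motif database in JASPAR flat format
#'
#' @inheritParams write_transfac
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    counts <- p$probs * .PWM_WRITE_TOTAL
    writeLines(sprintf(">%s", p$name), con)
    for (i in 1:4) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[i],
                         paste(sprintf("%.1f", counts[i, ]), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
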