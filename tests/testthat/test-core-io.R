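# Data model, BED/FASTA/TRANSFAC/JASPAR I/O and interval algebra.

test_that("BED6 reads map to 5' positions by strand convention", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t135\tr1\t0\t+",
               "chr1\t100\t135\tr2\t0\t-"), f)
  rd <- read_reads(f)
  expect_equal(rd$pos5, c(100L, 134L))
  expect_equal(rd$strand, c("+", "-"))
  expect_equal(rd$read_len, c(35L, 35L))
})

test_that("BED read/write round-trips a 1000-read file", {
  set.seed(11)
  rd <- aligned_reads(
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos5 = sample.int(1e6, 1000),
    strand = sample(c("+", "-"), 1000, replace = TRUE),
    read_len = sample(30:40, 1000, replace = TRUE)
  )
  f <- withr::local_tempfile()
  write_reads(rd, f)
  back <- read_reads(f)
  expect_equal(back, rd, ignore_attr = TRUE)
})

test_that("malformed BED lines are rejected with the line number", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t1\t36\tr1\t0\t+", "chr1\tfoo\t36\tr2\t0\t+"), f)
  expect_error(read_reads(f), "line 2")
  writeLines(c("chr1\t1\t36\tr1\t0\t."), f)
  expect_error(read_reads(f), "strand")
  writeLines(c("chr1\t1\t36"), f)
  expect_error(read_reads(f), "6 columns")
})

test_that("FASTA parsing uppercases, carries origins, rejects bad input", {
  f <- withr::local_tempfile()
  writeLines(c(">s1", "acgt", ">s2 chr2:10-14(+)", "ACGT"), f)
  rec <- read_fasta(f)
  expect_equal(rec$seq, c("ACGT", "ACGT"))
  expect_equal(rec$chrom[2], "chr2")
  expect_equal(rec$start[2], 10L)
  expect_equal(rec$end[2], 14L)
  expect_true(is.na(rec$chrom[1]))

  writeLines(c(">bad", "ACXT"), f)
  expect_error(read_fasta(f), "position 3")
})

test_that("FASTA write/read is the identity on 100 random records", {
  set.seed(3)
  n <- 100
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), sample(20:80, 1),
                 replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
          collapse = "")
  }, "")
  has_origin <- seq_len(n) %% 2 == 0
  rec <- seq_records(
    id = sprintf("s%03d", seq_len(n)), seq = seqs,
    chrom = ifelse(has_origin, "chr1", NA),
    start = ifelse(has_origin, 100L, NA),
    end = ifelse(has_origin, 100L + nchar(seqs), NA),
    strand = ifelse(has_origin, "+", NA)
  )
  f <- withr::local_tempfile()
  write_fasta(rec, f)
  expect_equal(read_fasta(f), rec, ignore_attr = TRUE)
})

test_that("extract_windows centers, clips and pads with N", {
  chrom <- paste(rep("ACGT", 250), collapse = "")  # 1000 bp
  genome <- seq_records("chr1", chrom)
  win <- extract_windows(genome, data.frame(chrom = "chr1", pos = 500), 400)
  expect_equal(win$start, 300L)
  expect_equal(win$end, 700L)
  expect_equal(nchar(win$seq), 400L)
  expect_false(win$clipped)
  # string-slice oracle
  expect_equal(win$seq, substr(chrom, 301, 700))

  edge <- extract_windows(genome, data.frame(chrom = "chr1", pos = 10), 400)
  expect_true(edge$clipped)
  expect_equal(substr(edge$seq, 1, 190), strrep("N", 190))
  expect_equal(substr(edge$seq, 191, 400), substr(chrom, 1, 210))

  expect_error(
    extract_windows(genome, data.frame(chrom = "chrX", pos = 5), 400),
    "chrX"
  )
  expect_error(extract_windows(genome, data.frame(chrom = "chr1", pos = 5), 401),
               "even")
})

test_that("count_overlaps uses half-open semantics and matches brute force", {
  q <- genomic_intervals("chr1", 10, 20)
  expect_equal(count_overlaps(q, genomic_intervals("chr1", 19, 30)), 1L)
  expect_equal(count_overlaps(q, genomic_intervals("chr1", 20, 30)), 0L)
  expect_equal(count_overlaps(q, genomic_intervals("chr2", 10, 20)), 0L)

  set.seed(5)
  rand_iv <- function(n) {
    s <- sample.int(1000, n, replace = TRUE)
    genomic_intervals(sample(c("c1", "c2"), n, replace = TRUE),
                      s, s + sample.int(50, n, replace = TRUE))
  }
  q <- rand_iv(500)
  s <- rand_iv(500)
  brute <- vapply(seq_len(nrow(q)), function(i) {
    sum(q$chrom[i] == s$chrom & q$start[i] < s$end & s$start < q$end[i])
  }, 0L)
  expect_equal(count_overlaps(q, s), brute)
  expect_equal(count_overlaps(q[0, ], s), integer())
  expect_equal(count_overlaps(q, s[0, ]), integer(500))
})

test_that("TRANSFAC counts are pseudocount-normalized as documented", {
  f <- withr::local_tempfile()
  writeLines(c("ID toy", "XX", "P0\tA\tC\tG\tT",
               "01\t8\t0\t0\t0", "02\t0\t8\t0\t0", "XX", "//"), f)
  p <- read_transfac(f)[[1]]
  expect_equal(p$width, 2L)
  expect_equal(p$probs[, 1], c(A = 8.25, C = 0.25, G = 0.25, T = 0.25) / 9,
               tolerance = 1e-3)
  expect_equal(unname(p$probs[1, 1]), 0.917, tolerance = 1e-3)

  writeLines(c("ID zero", "XX", "P0\tA\tC\tG\tT",
               "01\t0\t0\t0\t0", "XX", "//"), f)
  expect_error(read_transfac(f), "all-zero column")
})

test_that("JASPAR blocks have 4 x w shape and reject ragged rows", {
  f <- withr::local_tempfile()
  writeLines(c(">M1", "A [ 1 2 3 ]", "C [ 0 1 0 ]", "G [ 2 0 1 ]",
               "T [ 1 1 0 ]"), f)
  db <- read_jaspar(f)
  expect_equal(db$M1$width, 3L)
  expect_equal(colSums(db$M1$probs), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  writeLines(c(">M2", "A [ 1 2 ]", "C [ 0 1 0 ]", "G [ 2 0 1 ]",
               "T [ 1 1 0 ]"), f)
  expect_error(read_jaspar(f), "ragged")
})

test_that("PWM flat-format write/read round-trips to 1e-9", {
  set.seed(21)
  pwms <- lapply(1:20, function(i) random_pwm(sample(4:15, 1),
                                              name = sprintf("P%02d", i)))
  ft <- withr::local_tempfile()
  write_transfac(pwms, ft)
  back <- read_transfac(ft)
  for (i in seq_along(pwms)) {
    expect_lt(max(abs(back[[i]]$probs - pwms[[i]]$probs)), 1e-9)
    expect_equal(back[[i]]$name, pwms[[i]]$name)
  }
  fj <- withr::local_tempfile()
  write_jaspar(pwms, fj)
  backj <- read_jaspar(fj)
  for (i in seq_along(pwms)) {
    expect_lt(max(abs(backj[[i]]$probs - pwms[[i]]$probs)), 1e-9)
  }
})

test_that("mappability profiles merge and sort intervals", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t50\t100", "chr1\t90\t120", "chr1\t10\t20"), f)
  mp <- read_mappability(f)
  expect_equal(mp$start, c(10L, 50L))
  expect_equal(mp$end, c(20L, 120L))
  expect_equal(chipmotif:::is_mappable(mp, "chr1", c(9, 10, 19, 20, 55, 119, 120)),
               c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
})
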