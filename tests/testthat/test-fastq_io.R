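test_that("four-line records parse with enforced invariants", {
  f <- write_tmp_fastq(entry26_lines)
  rec <- read_fastq(f)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$header, "SRR001666.1")
  expect_equal(nchar(rec$sequence), 26L)
  expect_equal(rec$quality, "IIIHIIHABBBAA=2))!!!(!!!((")

  expect_equal(nrow(read_fastq(write_tmp_fastq(character()))), 0L)

  expect_error(read_fastq(write_tmp_fastq(c("r1", "ACGT", "+", "IIII"))),
               "missing '@' at line 1")
  expect_error(read_fastq(write_tmp_fastq(c("@r1", "ACGT", "x", "IIII"))),
               "missing '\\+' at line 3")
  expect_error(read_fastq(write_tmp_fastq(c("@r1", "ACGT", "+", "III"))),
               "length mismatch")
  expect_error(read_fastq(write_tmp_fastq(c("@r1", "ACGT", "+", "IIII",
                                            "@r2", "ACGTA", "+", "IIIII"))),
               "unequal length")
  expect_error(read_fastq(write_tmp_fastq(entry26_lines[1:3])), "truncated")
})

test_that("gzipped input is accepted transparently", {
  f <- tempfile(fileext = ".fastq.gz")
  con <- gzfile(f, "wt"); writeLines(entry26_lines, con); close(con)
  expect_equal(read_fastq(f)$header, "SRR001666.1")
})

test_that("write_fastq_sorted orders by header bytewise and is pair-consistent", {
  rec <- data.frame(header = c("b.2", "a.1", "B.3"),
                    sequence = c("AC", "GT", "TT"), plus = "",
                    quality = c("II", "HH", "!!"),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".fastq")
  write_fastq_sorted(rec, f)
  back <- read_fastq(f)
  expect_equal(back$header, c("B.3", "a.1", "b.2"))  # ASCII: uppercase first

  # mate file with same headers but different content sorts identically
  rec2 <- rec[c(3, 1, 2), ]
  rec2$sequence <- c("GG", "CC", "AA")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq_sorted(rec2, f2)
  expect_equal(read_fastq(f2)$header, back$header)

  # idempotence: writing a sorted file changes nothing
  f3 <- tempfile(fileext = ".fastq")
  write_fastq_sorted(back, f3)
  expect_equal(readLines(f3), readLines(f))
})

test_that("quality decode/encode are mutually inverse with ASCII semantics", {
  rec <- data.frame(header = c("r1", "r2"),
                    sequence = c("ACGN", "NNTT"), plus = "",
                    quality = c("!I?5", "IIII"), stringsAsFactors = FALSE)
  blk <- decode_qualities(rec, offset = 33L)
  expect_equal(blk$values[1, ], utf8ToInt("!I?5"))
  expect_equal(blk$values[1, 1], 33L)   # '!' -> 33
  expect_equal(blk$values[1, 2], 73L)   # 'I' -> 73
  expect_equal(blk$n_mask, matrix(c(FALSE, FALSE, FALSE, TRUE,
                                    TRUE, TRUE, FALSE, FALSE),
                                  2, 4, byrow = TRUE))
  expect_equal(encode_qualities(blk), rec$quality)

  # first three values of the archive-style entry decode to 73
  blk26 <- decode_qualities(read_fastq(write_tmp_fastq(entry26_lines)))
  expect_equal(blk26$values[1, 1:3], c(73L, 73L, 73L))

  # below-offset and out-of-alphabet characters are errors, not clamped
  bad <- rec; bad$quality[1] <- " I?5"   # space = 32 < offset 33
  expect_error(decode_qualities(bad, 33L), "below declared offset")
  expect_error(decode_qualities(rec, 64L), "below declared offset")
  over <- rec; over$quality[2] <- "IIIJ"  # 'J' = 74 > qmax 73
  expect_error(decode_qualities(over, 33L), "outside declared alphabet")
  blk$values[2, 2] <- 74L
  expect_error(encode_qualities(blk), "outside alphabet")
})

test_that("random blocks round-trip through encode/decode", {
  set.seed(5)
  q <- matrix(sample(33:73, 200, replace = TRUE), 20, 10)
  rec <- data.frame(header = sprintf("r%02d", 1:20),
                    sequence = replicate(20, paste(sample(c("A", "C", "G", "T"),
                                                          10, TRUE), collapse = "")),
                    plus = "",
                    quality = apply(q, 1, intToUtf8),
                    stringsAsFactors = FALSE)
  blk <- decode_qualities(rec)
  expect_identical(blk$values, q)
  expect_identical(encode_qualities(blk), rec$quality)

  f <- tempfile(fileext = ".fastq")
  write_fastq_sorted(rec, f)
  expect_equal(read_fastq(f), rec[order(rec$header), ],
               ignore_attr = "row.names")
})
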