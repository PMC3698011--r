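test_that("compress/decompress conserves everything but quality", {
  f <- codec_fixture(N = 300, n = 20, seed = 5)
  orig <- read_fastq(f)
  z <- compress(f, R = 0.5, k = 2, seed = 17)
  out <- decompress(z$container, z$stub)
  expect_equal(nrow(out), nrow(orig))
  expect_identical(sort(out$header), sort(orig$header))
  srt <- orig[order(orig$header), ]
  expect_identical(out$sequence, srt$sequence)
  expect_false(is.unsorted(out$header))
  expect_true(all(nchar(out$quality) == 20L))
})

test_that("zero rate stores no payload and decodes every read to the cluster mean", {
  f <- codec_fixture(N = 200, n = 15, seed = 8)
  z <- compress(f, R = 0, k = 1, seed = 3)
  expect_equal(effective_rate(z$container)$payload_bytes, 0L)
  out <- decompress(z$container, z$stub)
  cl <- z$container$clusters[[1]]
  expected <- pmin(pmax(round(cl$mu), z$container$qmin), z$container$qmax)
  qmat <- t(vapply(out$quality, utf8ToInt, integer(15), USE.NAMES = FALSE))
  nmask <- t(vapply(out$sequence,
                    function(s) strsplit(s, "")[[1]] == "N", logical(15),
                    USE.NAMES = FALSE))
  for (j in 1:15) {
    expect_true(all(qmat[!nmask[, j], j] == expected[j]))
  }
})

test_that("'N' bases decode to the least reliable score", {
  spec <- generator_spec(N = 100, n = 12,
                         components = list(list(weight = 1, mean = 60,
                                                sd = 3, ar1 = 0.5)),
                         n_base_fraction = 0.3, seed = 44)
  f <- tempfile(fileext = ".fastq"); generate_fastq(spec, f)
  z <- compress(f, R = 2, k = 1, seed = 5)
  out <- decompress(z$container, z$stub)
  qmat <- t(vapply(out$quality, utf8ToInt, integer(12), USE.NAMES = FALSE))
  nmask <- t(vapply(out$sequence,
                    function(s) strsplit(s, "")[[1]] == "N", logical(12),
                    USE.NAMES = FALSE))
  expect_true(any(nmask))
  expect_true(all(qmat[nmask] == z$container$qmin))
  # an all-N read would be all qmin; emulate by checking rows with many Ns
  expect_true(all(qmat[nmask] == 33L))
})

test_that("the container round-trips bit-exactly through file and memory", {
  f <- codec_fixture(N = 150, n = 10, seed = 2)
  z <- compress(f, R = 1.3, k = 3, seed = 2^31 - 5)
  bytes <- serialize_container(z$container)
  expect_identical(rawToChar(bytes[1:4]), "QCMP")
  back <- parse_container(bytes)
  expect_identical(serialize_container(back), bytes)
  expect_equal(back$seed, 2^31 - 5)
  expect_equal(back$R, 1.3)
  expect_equal(sum(vapply(back$clusters, `[[`, integer(1), "count")), 150L)

  qc <- tempfile(fileext = ".qc"); write_container(z$container, qc)
  expect_identical(serialize_container(read_container(qc)), bytes)

  qcs <- tempfile(fileext = ".qcs"); write_stub(z$stub, qcs)
  expect_identical(read_stub(qcs), z$stub)
  # gzipped stub round-trips too
  qcsz <- tempfile(fileext = ".qcs.gz"); write_stub(z$stub, qcsz)
  expect_identical(read_stub(qcsz), z$stub)

  expect_error(parse_container(as.raw(c(1, 2, 3, 4, 5))), "bad magic")
})

test_that("decompression is deterministic and PRNG replay matches the encoder", {
  f <- codec_fixture(N = 250, n = 18, seed = 6)
  z <- compress(f, R = 0.7, k = 2, seed = 1234)
  out1 <- decompress(z$container, z$stub)
  out2 <- decompress(parse_container(serialize_container(z$container)), z$stub)
  expect_identical(out1, out2)

  # instrument the draw sequence: the decoder must consume exactly the
  # draws the encoder consumed, in the same order
  counts <- vapply(z$container$clusters, `[[`, integer(1), "count")
  n <- z$container$n
  enc_rng <- lehmer_rng(1234)
  enc_draws <- rng_uniform(enc_rng, sum(counts) * n)
  dec_rng <- lehmer_rng(z$container$seed)
  dec_draws <- rng_uniform(dec_rng, sum(counts) * n)
  expect_identical(enc_draws, dec_draws)

  # same seed -> identical container; different seed -> different rounding
  z2 <- compress(f, R = 0.7, k = 2, seed = 1234)
  expect_identical(serialize_container(z2$container),
                   serialize_container(z$container))
})

test_that("MSE is non-increasing in rate and zero at effectively lossless rates", {
  f <- codec_fixture(N = 800, n = 25, seed = 3)
  orig <- read_fastq(f)
  mses <- vapply(c(0, 0.2, 0.5, 1, 2, 4), function(R) {
    z <- compress(f, R = R, k = 1, seed = 9)
    mse_distortion(orig, decompress(z$container, z$stub))$mse
  }, numeric(1))
  expect_true(all(diff(mses) <= 1e-9))
  expect_gt(mses[1], mses[6])

  z <- compress(f, R = 12, k = 1, seed = 9)
  expect_equal(mse_distortion(orig, decompress(z$container, z$stub))$mse, 0)
})

test_that("clustering does not hurt at fixed rate on bimodal data", {
  f <- tempfile(fileext = ".fastq")
  generate_fastq(two_blob_spec(N = 1200, n = 20, seed = 19), f)
  orig <- read_fastq(f)
  m <- vapply(c(1, 3), function(k) {
    z <- compress(f, R = 0.5, k = k, seed = 7)
    mse_distortion(orig, decompress(z$container, z$stub))$mse
  }, numeric(1))
  expect_lte(m[2], m[1])
})

test_that("paired files with the same headers decompress to the same order", {
  f1 <- codec_fixture(N = 120, n = 14, seed = 12)
  rec2 <- read_fastq(f1)
  set.seed(1)
  rec2$sequence <- vapply(seq_len(nrow(rec2)), function(i)
    paste(sample(c("A", "C", "G", "T"), 14, TRUE), collapse = ""),
    character(1))
  rec2 <- rec2[rev(seq_len(nrow(rec2))), ]
  f2 <- tempfile(fileext = ".fastq")
  qualpress:::write_records_plain(rec2, f2)
  out1 <- decompress2 <- local({
    z <- compress(f1, R = 0.3, k = 2, seed = 5)
    decompress(z$container, z$stub)
  })
  out2 <- local({
    z <- compress(f2, R = 0.3, k = 2, seed = 99)
    decompress(z$container, z$stub)
  })
  expect_identical(out1$header, out2$header)
})

test_that("defective inputs are rejected with useful errors", {
  f <- codec_fixture(N = 60, n = 10, seed = 15)
  expect_error(compress(f, R = -1), "nonnegative")
  expect_error(compress(f, R = 16), "cap")
  z <- compress(f, R = 1, k = 1, seed = 1)
  stub_short <- z$stub[-1, ]
  expect_error(decompress(z$container, stub_short), "mismatch")
  # truncated payload
  broken <- z$container
  broken$clusters[[1]]$payload <-
    broken$clusters[[1]]$payload[1:10]
  expect_error(decompress(broken, z$stub), "truncated")
})

test_that("effective rate accounts payload plus side information", {
  f <- codec_fixture(N = 400, n = 12, seed = 22)
  z <- compress(f, R = 1, k = 1, seed = 3)
  er <- effective_rate(z$container)
  expect_equal(er$total_bytes, er$payload_bytes + er$overhead_bytes)
  expect_equal(er$rate_effective,
               8 * er$total_bytes / (z$container$n * z$container$N))
  expect_gt(er$rate_effective, er$rate_requested)  # overhead is never free
  # side information scales as ~8(n^2 + 3n) bytes per cluster plus header
  expect_gt(er$overhead_bytes, 8 * (12^2 + 3 * 12))
  z0 <- compress(f, R = 0, k = 1, seed = 3)
  expect_identical(effective_rate(z0$container)$payload_bytes, 0L)
})
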