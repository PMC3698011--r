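#' Compress the quality scores of a FASTQ file
#'
#' The encoder pipeline: reads are clustered on their quality vectors
#' (k-means with constant-vector initialization), per-cluster Gaussian
#' statistics (mu, Sigma) are estimated, Sigma is factored as V diag(s) V'
#' and each read is decorrelated as Q' = V'(Q - mu). A single bit
#' allocation per cluster distributes the budget of n*R bits per read
#' over the transform coefficients by reverse water-filling; each read
#' then realizes the fractional allocation as integers by randomized
#' rounding (shared seeded PRNG, replayed by the decoder), normalizes
#' each coefficient to unit variance and quantizes it with the Lloyd-Max
#' codebook of its realized bit depth. Indices are packed MSB-first into
#' a per-cluster bitstream. Headers, sequences and '+' lines go to a
#' plain-text stub in the same cluster-grouped read order.
#'
#' @param input Path to a fixed-read-length FASTQ file (gzip accepted).
#' @param R Rate in bits per quality score (>= 0). `R = 0` stores only
#'   the side information; every read then decodes to the rounded
#'   cluster mean.
#' @param k Number of quality clusters (default 3).
#' @param seed PRNG seed for the randomized rounding; stored in the
#'   container.
#' @param offset,qmin,qmax Quality scale; see [decode_qualities()].
#' @param max_bits Per-coefficient cap on allocated bits (default 15).
#' @return A list with `container` (a `qc_container`) and `stub` (a
#'   `data.frame` of header/sequence/plus in payload order).
#' @seealso [decompress()], [write_container()], [write_stub()]
#' @export
compress <- function(input, R, k = 3L, seed = 1L, offset = 33L,
                     qmin = NULL, qmax = NULL, max_bits = 15L) {
  if (R < 0) stop("rate must be nonnegative")
  if (R > max_bits)
    stop("rate ", R, " exceeds the per-position cap of ", max_bits,
         " bits (budget n*R > n*max_bits)")
  records <- if (is.data.frame(input)) input else read_fastq(input)
  if (nrow(records) < 1L) stop("no reads in input")
  block <- decode_qualities(records, offset, qmin, qmax)
  N <- nrow(block$values); n <- ncol(block$values)
  km <- kmeans_quality(block, k)
  ord <- order(km$labels)           # stable: cluster-grouped, input order kept
  rng <- lehmer_rng(seed)
  clusters <- vector("list", k)
  for (c in seq_len(k)) {
    idx <- ord[km$labels[ord] == c]
    rows <- block$values[idx, , drop = FALSE]
    storage.mode(rows) <- "double"
    Nc <- nrow(rows)
    if (Nc >= 2L) {
      stats <- compute_statistics(rows)
    } else {
      mu <- if (Nc == 1L) drop(rows) else rep((block$qmin + block$qmax) / 2, n)
      stats <- structure(list(mu = mu, sigma = matrix(0, n, n), count = Nc),
                         class = "cluster_stats")
    }
    model <- spectral_decompose(stats)
    alloc <- solve_allocation(model$s, R, max_bits)
    payload <- raw(0)
    if (Nc > 0L) {
      qp <- decorrelate(rows, model)
      divisor <- pmax(sqrt(model$s), 1e-12)
      z <- sweep(qp, 2L, divisor, `/`)
      # one rounding draw per position per read, read-major order
      u <- matrix(rng_uniform(rng, Nc * n), nrow = Nc, byrow = TRUE)
      lo <- floor(alloc$rho)
      widths <- sweep(u, 2L, alloc$rho - lo, `<`) + rep(lo, each = Nc)
      storage.mode(widths) <- "integer"
      indices <- matrix(0L, Nc, n)
      for (b in setdiff(sort(unique(as.vector(widths))), 0L)) {
        cb <- lloyd_max(b)
        sel <- widths == b
        indices[sel] <- quantize(z[sel], cb)
      }
      payload <- pack_bits(as.vector(t(indices)), as.vector(t(widths)))
    }
    clusters[[c]] <- list(count = Nc, mu = model$mu, V = model$V,
                          s = model$s, rho = alloc$rho, payload = payload)
  }
  container <- structure(
    list(version = 1L, n = n, N = N, offset = block$offset,
         qmin = block$qmin, qmax = block$qmax, k = as.integer(k),
         max_bits = as.integer(max_bits), R = R, seed = as.numeric(seed),
         clusters = clusters),
    class = "qc_container")
  stub <- records[ord, c("header", "sequence", "plus"), drop = FALSE]
  rownames(stub) <- NULL
  list(container = container, stub = stub)
}

#' Decompress a container back to FASTQ records
#'
#' Runs the encoder's steps in reverse: per cluster, the randomized
#' rounding draws are replayed from the stored seed (same PRNG, same
#' consumption order), giving each read's per-position bit depths; the
#' payload is unpacked, indices are dequantized to unit-Gaussian
#' representatives, rescaled by sqrt(s_j), recorrelated as
#' round(V Q' + mu) and clamped into the quality alphabet. Positions
#' whose stub base is 'N' are set to the least reliable score `qmin`.
#' Output records are sorted by header, so mates of paired files sort
#' identically.
#'
#' @param container A `qc_container` (from [compress()] or
#'   [read_container()]).
#' @param stub The matching stub `data.frame` (or path to a `.qcs` file).
#' @return A record `data.frame` (header/sequence/plus/quality), sorted
#'   by header.
#' @export
decompress <- function(container, stub) {
  stopifnot(inherits(container, "qc_container"))
  if (is.character(stub)) stub <- read_stub(stub)
  n <- container$n
  counts <- vapply(container$clusters, `[[`, integer(1), "count")
  if (sum(counts) != container$N || nrow(stub) != container$N)
    stop("container/stub mismatch: container declares ", container$N,
         " reads, clusters sum to ", sum(counts), ", stub has ", nrow(stub))
  if (any(nchar(stub$sequence) != n))
    stop("stub sequence length differs from container read length ", n)
  rng <- lehmer_rng(container$seed)
  qual <- character(container$N)
  at <- 0L
  for (cl in container$clusters) {
    Nc <- cl$count
    if (Nc == 0L) next
    u <- matrix(rng_uniform(rng, Nc * n), nrow = Nc, byrow = TRUE)
    lo <- floor(cl$rho)
    widths <- sweep(u, 2L, cl$rho - lo, `<`) + rep(lo, each = Nc)
    storage.mode(widths) <- "integer"
    flat <- unpack_bits(cl$payload, as.vector(t(widths)))
    indices <- matrix(as.integer(flat), Nc, n, byrow = TRUE)
    z <- matrix(0, Nc, n)
    for (b in setdiff(sort(unique(as.vector(widths))), 0L)) {
      cb <- lloyd_max(b)
      sel <- widths == b
      z[sel] <- dequantize(indices[sel], cb)
    }
    # zero-variance coefficients were never quantized; they stay 0 and
    # reconstruct to the mean along that direction
    qp <- sweep(z, 2L, pmax(sqrt(cl$s), 1e-12), `*`)
    model <- structure(list(mu = cl$mu, V = cl$V, s = cl$s),
                       class = "spectral_model")
    vals <- recorrelate(qp, model, container$qmin, container$qmax)
    qual[at + seq_len(Nc)] <- apply(vals, 1L, intToUtf8)
    at <- at + Nc
  }
  # 'N' bases get the least reliable score
  qual <- mapply(function(s, q) {
    npos <- which(strsplit(s, "", fixed = TRUE)[[1L]] %in% c("N", "n"))
    if (length(npos)) {
      qv <- utf8ToInt(q); qv[npos] <- container$qmin; intToUtf8(qv)
    } else q
  }, stub$sequence, qual, USE.NAMES = FALSE)
  out <- data.frame(header = stub$header, sequence = stub$sequence,
                    plus = stub$plus, quality = qual,
                    stringsAsFactors = FALSE)
  out <- out[order_bytewise(out$header), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- container serialization --------------------------------------------
# Layout (all integers little-endian):
#   magic "QCMP" | version uint8 | n,N,offset,qmin,qmax,k,max_bits int32
#   R float64 | seed uint64 (two uint32 words, low first)
#   per cluster: count int32 | mu n*f64 | V n^2*f64 (column-major)
#                | s n*f64 | rho n*f64 | payload_len int32 | payload bytes

#' Serialize a container to raw bytes
#'
#' The byte layout is fixed and documented in the source; serialization
#' followed by [parse_container()] is bit-exact.
#'
#' @param container A `qc_container`.
#' @return A raw vector.
#' @export
serialize_container <- function(container) {
  stopifnot(inherits(container, "qc_container"))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("QCMP"), con)
  writeBin(as.raw(container$version), con)
  writeBin(as.integer(c(container$n, container$N, container$offset,
                        container$qmin, container$qmax, container$k,
                        container$max_bits)),
           con, size = 4L, endian = "little")
  writeBin(as.numeric(container$R), con, size = 8L, endian = "little")
  seed <- as.numeric(container$seed)
  seed_words <- c(seed %% 2^32, seed %/% 2^32)
  # uint32 words written via double trick to avoid 32-bit signed overflow
  for (wd in seed_words) {
    bytes <- as.raw((wd %/% 2^(c(0, 8, 16, 24))) %% 256)
    writeBin(bytes, con)
  }
  for (cl in container$clusters) {
    writeBin(as.integer(cl$count), con, size = 4L, endian = "little")
    writeBin(as.numeric(cl$mu), con, size = 8L, endian = "little")
    writeBin(as.numeric(cl$V), con, size = 8L, endian = "little")
    writeBin(as.numeric(cl$s), con, size = 8L, endian = "little")
    writeBin(as.numeric(cl$rho), con, size = 8L, endian = "little")
    writeBin(length(cl$payload), con, size = 4L, endian = "little")
    writeBin(cl$payload, con)
  }
  rawConnectionValue(con)
}

#' Parse raw bytes into a container
#'
#' @param bytes Raw vector produced by [serialize_container()].
#' @return A `qc_container`.
#' @export
parse_container <- function(bytes) {
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic), "QCMP"))
    stop("bad magic: not a quality-score container")
  version <- as.integer(readBin(con, "raw", 1L))
  if (version != 1L) stop("unsupported container version ", version)
  ints <- readBin(con, "integer", 7L, size = 4L, endian = "little")
  n <- ints[1L]; N <- ints[2L]; k <- ints[6L]
  R <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  w <- vapply(1:2, function(i)
    sum(as.numeric(readBin(con, "raw", 4L)) * 2^(c(0, 8, 16, 24))),
    numeric(1))
  seed <- w[1L] + w[2L] * 2^32
  clusters <- vector("list", k)
  for (c in seq_len(k)) {
    count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    mu <- readBin(con, "numeric", n, size = 8L, endian = "little")
    V <- matrix(readBin(con, "numeric", n * n, size = 8L, endian = "little"), n, n)
    s <- readBin(con, "numeric", n, size = 8L, endian = "little")
    rho <- readBin(con, "numeric", n, size = 8L, endian = "little")
    plen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    payload <- readBin(con, "raw", plen)
    if (length(payload) != plen)
      stop("truncated container: cluster ", c, " payload short by ",
           plen - length(payload), " bytes")
    clusters[[c]] <- list(count = count, mu = mu, V = V, s = s,
                          rho = rho, payload = payload)
  }
  structure(list(version = version, n = n, N = N, offset = ints[3L],
                 qmin = ints[4L], qmax = ints[5L], k = k,
                 max_bits = ints[7L], R = R, seed = seed,
                 clusters = clusters),
            class = "qc_container")
}

#' @rdname serialize_container
#' @param path File path (conventionally `.qc`).
#' @export
write_container <- function(container, path) {
  writeBin(serialize_container(container), path)
  invisible(path)
}

#' @rdname parse_container
#' @param path File path.
#' @export
read_container <- function(path) {
  parse_container(readBin(path, "raw", file.size(path)))
}

#' Write / read the sequence stub
#'
#' The stub is the non-quality part of the FASTQ (header, sequence, '+'
#' line), three text lines per read, in the container's cluster-grouped
#' payload order. Its own compression is out of scope here and it is
#' excluded from the effective-rate accounting, which covers quality
#' scores only.
#'
#' @param stub Stub `data.frame`.
#' @param path File path (conventionally `.qcs`; `.gz` accepted).
#' @return `write_stub` invisibly returns the path; `read_stub` returns
#'   the stub `data.frame`.
#' @export
write_stub <- function(stub, path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", stub$header), stub$sequence,
                             paste0("+", stub$plus))), con)
  invisible(path)
}

#' @rdname write_stub
#' @export
read_stub <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 3L != 0L)
    stop("truncated stub: ", length(lines), " lines is not a multiple of 3")
  i <- seq(1L, length(lines), by = 3L)
  if (length(i) && any(!startsWith(lines[i], "@")))
    stop("malformed stub: header line without '@'")
  data.frame(header = substring(lines[i], 2L),
             sequence = lines[i + 1L],
             plus = substring(lines[i + 2L], 2L),
             stringsAsFactors = FALSE)
}

#' Effective rate of a compressed container
#'
#' The requested rate R counts only payload bits; the container also
#' carries side information (per-cluster mu, V, s, rho, counts, seed and
#' header fields) that the decoder needs. The effective rate is
#' R' = total container bits / (n * N). The difference R' - R is the
#' overhead per quality score; for a 100 KB overhead (KB = 1024 bytes)
#' at n = 100, N = 13310768 it is 6.15e-4 bits.
#'
#' @param container A `qc_container`.
#' @return A list with `rate_effective` (R'), `rate_requested`,
#'   `payload_bytes`, `overhead_bytes` and `total_bytes`. The stub is
#'   excluded: the accounting covers quality scores only.
#' @export
effective_rate <- function(container) {
  stopifnot(inherits(container, "qc_container"))
  total <- length(serialize_container(container))
  payload <- sum(vapply(container$clusters,
                        function(cl) length(cl$payload), integer(1)))
  list(rate_effective = 8 * total / (container$n * container$N),
       rate_requested = container$R,
       payload_bytes = payload,
       overhead_bytes = total - payload,
       total_bytes = total)
}

#' @export
print.qc_container <- function(x, ...) {
  er <- effective_rate(x)
  cat("<qc_container v", x$version, "> ", x$N, " reads x ", x$n,
      " positions, k = ", x$k, ", R = ", x$R,
      sprintf(" (R' = %.4g)", er$rate_effective),
      ", payload ", er$payload_bytes, " B + side info ",
      er$overhead_bytes, " B\n", sep = "")
  invisible(x)
}
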