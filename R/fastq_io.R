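#' Read a FASTQ file into a record table
#'
#' Parses a standard four-line-per-record FASTQ file (plain or gzipped).
#' All reads must have the same length: the codec allocates bits per
#' position and requires a fixed read length `n` across the file.
#'
#' @param path Path to a FASTQ file (`.gz` accepted transparently) or a
#'   readable connection.
#' @return A `data.frame` with character columns `header` (line 1 without
#'   the leading `@`), `sequence`, `plus` (line 3 without the leading `+`)
#'   and `quality`, one row per record.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  lines <- if (inherits(path, "connection")) readLines(path, warn = FALSE)
           else { con <- gzfile(path, "rt"); on.exit(close(con)); readLines(con, warn = FALSE) }
  # drop a single trailing blank line (common on hand-edited files)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L)
    return(data.frame(header = character(), sequence = character(),
                      plus = character(), quality = character(),
                      stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines),
         " lines is not a multiple of 4 (last complete record ends at line ",
         4L * (length(lines) %/% 4L), ")")
  i <- seq(1L, length(lines), by = 4L)
  hdr <- lines[i]; seqs <- lines[i + 1L]; plus <- lines[i + 2L]; qual <- lines[i + 3L]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ: missing '@' at line ", 4L * (bad[1L] - 1L) + 1L)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ: missing '+' at line ", 4L * (bad[1L] - 1L) + 3L)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ: sequence/quality length mismatch at record ",
         bad[1L], " (line ", 4L * (bad[1L] - 1L) + 1L, ")")
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    stop("reads of unequal length (", paste(sort(n), collapse = ", "),
         "); this tool requires a fixed read length per file")
  hdr <- substring(hdr, 2L)
  if (any(!nzchar(hdr)))
    stop("malformed FASTQ: empty header at record ", which(!nzchar(hdr))[1L])
  data.frame(header = hdr, sequence = seqs, plus = substring(plus, 2L),
             quality = qual, stringsAsFactors = FALSE)
}

#' Write FASTQ records sorted by header
#'
#' Records are emitted in bytewise-lexicographic header order. Because the
#' codec groups reads by cluster and does not preserve input order, sorting
#' on output guarantees that two related files with the same header set
#' (e.g. paired-end mates) come out in the same order.
#'
#' @param records A record `data.frame` as returned by [read_fastq()].
#' @param path Output file path or writable connection.
#' @return Invisibly, the sorted record data.frame.
#' @export
write_fastq_sorted <- function(records, path) {
  ord <- order_bytewise(records$header)
  records <- records[ord, , drop = FALSE]
  lines <- as.vector(rbind(paste0("@", records$header),
                           records$sequence,
                           paste0("+", records$plus),
                           records$quality))
  if (inherits(path, "connection")) writeLines(lines, path)
  else writeLines(lines, path)
  invisible(records)
}

# bytewise (C-locale) order, independent of the session locale
order_bytewise <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(x, method = "radix")
}

#' Decode ASCII quality strings to an integer quality block
#'
#' Converts per-read quality strings to an N x n integer matrix under a
#' declared ASCII offset convention (Phred+33 or Phred+64/Solexa+64). The
#' stored values are the raw ASCII codes (e.g. 'I' -> 73 under Phred+33,
#' matching the [33, 73] alphabet of that scale); the offset is carried
#' along so characters below the declared scale are rejected rather than
#' silently clamped.
#'
#' @param records Record `data.frame` from [read_fastq()].
#' @param offset ASCII offset of the quality scale: 33 or 64.
#' @param qmin,qmax Alphabet bounds (ASCII codes). Defaults: `[33, 73]` for
#'   offset 33, `[59, 104]` for offset 64 (covers Solexa's -5).
#' @return A `quality_block`: list with `values` (integer matrix, reads in
#'   rows), `offset`, `qmin`, `qmax`, and `n_mask` (logical matrix, TRUE
#'   where the called base is 'N').
#' @export
decode_qualities <- function(records, offset = 33L,
                             qmin = NULL, qmax = NULL) {
  stopifnot(offset %in% c(33L, 64L))
  if (is.null(qmin)) qmin <- if (offset == 33L) 33L else 59L
  if (is.null(qmax)) qmax <- if (offset == 33L) 73L else 104L
  nr <- nrow(records)
  n <- if (nr) nchar(records$quality[1L]) else 0L
  vals <- matrix(0L, nrow = nr, ncol = n)
  mask <- matrix(FALSE, nrow = nr, ncol = n)
  if (nr) {
    vals[] <- as.integer(t(vapply(records$quality,
                                  function(q) utf8ToInt(q),
                                  integer(n), USE.NAMES = FALSE)))
    mask[] <- t(vapply(records$sequence,
                       function(s) strsplit(s, "", fixed = TRUE)[[1L]] %in% c("N", "n"),
                       logical(n), USE.NAMES = FALSE))
    low <- which(vals < offset, arr.ind = TRUE)
    if (nrow(low))
      stop("quality character below declared offset ", offset, " in read '",
           records$header[low[1L, 1L]], "' position ", low[1L, 2L])
    out <- which(vals < qmin | vals > qmax, arr.ind = TRUE)
    if (nrow(out))
      stop("quality value ", vals[out[1L, , drop = FALSE]],
           " outside declared alphabet [", qmin, ", ", qmax, "] in read '",
           records$header[out[1L, 1L]], "' position ", out[1L, 2L])
  }
  structure(list(values = vals, offset = as.integer(offset),
                 qmin = as.integer(qmin), qmax = as.integer(qmax),
                 n_mask = mask),
            class = "quality_block")
}

#' Encode a quality block back to ASCII quality strings
#'
#' Inverse of [decode_qualities()]: every integer value becomes the ASCII
#' character with that code. Values outside the block's `[qmin, qmax]`
#' alphabet are an error (the codec clamps before encoding).
#'
#' @param block A `quality_block`.
#' @return Character vector of quality strings, one per read.
#' @export
encode_qualities <- function(block) {
  stopifnot(inherits(block, "quality_block"))
  v <- block$values
  if (any(v < block$qmin | v > block$qmax))
    stop("quality value outside alphabet [", block$qmin, ", ", block$qmax, "]")
  if (nrow(v) == 0L) return(character())
  apply(v, 1L, intToUtf8)
}

#' @export
print.quality_block <- function(x, ...) {
  cat("<quality_block> ", nrow(x$values), " reads x ", ncol(x$values),
      " positions, offset ", x$offset, ", alphabet [", x$qmin, ", ",
      x$qmax, "], ", sum(x$n_mask), " N-masked entries\n", sep = "")
  invisible(x)
}
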