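# MSB-first variable-width bit packing over raw vectors.
# Each value v[i] occupies exactly width[i] bits; zero-width entries are
# skipped; the final byte is zero-padded. The layout is part of the
# container format contract, so both directions are implemented here with
# no tolerance for platform variation.

pack_bits <- function(values, widths) {
  stopifnot(length(values) == length(widths))
  keep <- widths > 0L
  v <- as.numeric(values[keep])
  w <- as.integer(widths[keep])
  total <- sum(w)
  if (total == 0L) return(raw(0))
  entry <- rep.int(seq_along(w), w)
  shift <- w[entry] - sequence(w)            # bit position, MSB first
  bits <- (v[entry] %/% 2^shift) %% 2
  pad <- (-total) %% 8L
  if (pad) bits <- c(bits, numeric(pad))
  bm <- matrix(bits, nrow = 8L)
  bytes <- as.integer(crossprod(bm, 2^(7:0)))
  as.raw(bytes)
}

unpack_bits <- function(payload, widths) {
  w <- as.integer(widths)
  keep <- w > 0L
  total <- sum(w[keep])
  out <- numeric(length(w))
  if (total == 0L) return(out)
  if (length(payload) * 8L < total)
    stop("truncated payload: need ", total, " bits, have ",
         length(payload) * 8L)
  # rawToBits is LSB-first within each byte; flip to the stream order
  bm <- matrix(as.integer(rawToBits(payload)), nrow = 8L)
  bits <- as.vector(bm[8:1, , drop = FALSE])[seq_len(total)]
  wk <- w[keep]
  entry <- rep.int(seq_along(wk), wk)
  shift <- wk[entry] - sequence(wk)
  vals <- rowsum(bits * 2^shift, entry, reorder = FALSE)
  out[keep] <- as.vector(vals)
  out
}
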