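#' Distortion between original and reconstructed quality scores
#'
#' Computes the codec's distortion measure: per read,
#' D(i) = (1/n) sum_j (Q_i(j) - Qhat_i(j))^2, and overall
#' D = (1/N) sum_i D(i). Reads are matched by header, not file position,
#' because the codec reorders its output; duplicate headers are matched
#' in sorted order.
#'
#' @param original,reconstructed Record `data.frame`s (from
#'   [read_fastq()]) or `quality_block`s with matching dimensions. Record
#'   inputs are header-matched first.
#' @return A `distortion_report`: list with `mse` (D), `per_read_mse`
#'   (D(i), in the matched read order) and `n_reads`.
#' @export
mse_distortion <- function(original, reconstructed) {
  as_vals <- function(x) {
    if (inherits(x, "quality_block")) return(x$values)
    if (is.data.frame(x)) {
      v <- t(vapply(x$quality, utf8ToInt,
                    integer(nchar(x$quality[1L])), USE.NAMES = FALSE))
      rownames(v) <- NULL
      return(v)
    }
    as.matrix(x)
  }
  if (is.data.frame(original) && is.data.frame(reconstructed)) {
    if (nrow(original) != nrow(reconstructed) ||
        !identical(sort(original$header), sort(reconstructed$header)))
      stop("record sets differ: headers do not match")
    original <- original[order_bytewise(original$header), , drop = FALSE]
    reconstructed <- reconstructed[order_bytewise(reconstructed$header), ,
                                   drop = FALSE]
  }
  a <- as_vals(original); b <- as_vals(reconstructed)
  if (!all(dim(a) == dim(b)))
    stop("dimension mismatch: ", nrow(a), "x", ncol(a), " vs ",
         nrow(b), "x", ncol(b))
  per_read <- rowMeans((a - b)^2)
  structure(list(mse = mean(per_read), per_read_mse = per_read,
                 n_reads = nrow(a)),
            class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat("<distortion_report> D =", format(x$mse), "over", x$n_reads, "reads\n")
  invisible(x)
}

#' Projected storage for quality scores at a given rate
#'
#' Storage in bytes for a total number of quality scores compressed at
#' `R` bits per score (overhead excluded): `total * R / 8`. Reported in
#' GB = 1e9 bytes, the convention of dataset-scale projections: 268e9
#' scores at R = 0.05 need 1.675 GB; 576.7e9 at a lossless 2.5 bits need
#' ~180 GB.
#'
#' @param total_quality_scores Total number of quality scores (e.g.
#'   gigabases * 1e9).
#' @param R Rate in bits per quality score.
#' @return Storage in bytes; divide by 1e9 for GB.
#' @export
storage_projection <- function(total_quality_scores, R) {
  if (total_quality_scores < 0 || R < 0) stop("inputs must be nonnegative")
  total_quality_scores * R / 8
}

#' Rate increase from side-information overhead
#'
#' The per-score rate cost of `overhead_bytes` of side information on a
#' file of N reads of length n: `overhead_bytes * 8 / (n * N)`. Overhead
#' is conventionally quoted in KB = 1024 bytes: 100 KB at n = 100,
#' N = 13310768 costs 6.15e-4 bits per quality score.
#'
#' @param overhead_bytes Side-information size in bytes.
#' @param n Read length.
#' @param N Number of reads.
#' @return Rate increase in bits per quality score.
#' @export
rate_overhead <- function(overhead_bytes, n, N) {
  overhead_bytes * 8 / (n * N)
}

#' Evaluate a compression run end to end
#'
#' Convenience wrapper: compares an original FASTQ with its
#' reconstruction and merges in the container's rate accounting.
#'
#' @param original Path to the original FASTQ (or its record data.frame).
#' @param reconstructed Path to the reconstructed FASTQ (or records).
#' @param container Optional `qc_container` for rate fields.
#' @return A one-row `data.frame`: `mse`, and when a container is given,
#'   `rate_requested`, `rate_effective`, `payload_bytes`,
#'   `overhead_bytes`.
#' @export
evaluate_compression <- function(original, reconstructed, container = NULL) {
  orig <- if (is.character(original)) read_fastq(original) else original
  reco <- if (is.character(reconstructed)) read_fastq(reconstructed) else reconstructed
  rep <- mse_distortion(orig, reco)
  out <- data.frame(mse = rep$mse)
  if (!is.null(container)) {
    er <- effective_rate(container)
    out$rate_requested <- er$rate_requested
    out$rate_effective <- er$rate_effective
    out$payload_bytes <- er$payload_bytes
    out$overhead_bytes <- er$overhead_bytes
  }
  out
}
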