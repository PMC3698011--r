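#' Specification for a synthetic FASTQ generator
#'
#' Describes a mixture of multivariate-Gaussian quality models — the
#' statistical structure the codec assumes — so every pipeline stage can
#' be exercised without real sequencing data. Each mixture component has
#' a mean quality profile, a per-position standard-deviation profile and
#' an AR(1) within-read correlation coefficient, giving the covariance
#' Sigma[j, l] = sd_j * sd_l * ar1^|j - l|. Within-read correlation is
#' the premise the codec's decorrelation step exploits, which is why
#' AR(1) is the default correlation family.
#'
#' @param N Number of reads.
#' @param n Read length.
#' @param components List of components; each a list with `weight`,
#'   `mean` (scalar or length-n profile), `sd` (scalar or length-n) and
#'   `ar1` (correlation coefficient in `[0, 1)`). Weights must sum to 1.
#' @param offset,qmin,qmax Quality scale (defaults Phred+33, `[33, 73]`).
#' @param n_base_fraction Fraction of bases replaced by 'N' (default 0).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(N, n, components, offset = 33L,
                           qmin = 33L, qmax = 73L,
                           n_base_fraction = 0, seed = 1L) {
  if (N < 1L || n < 1L) stop("N and n must be positive")
  if (n_base_fraction < 0 || n_base_fraction > 1)
    stop("n_base_fraction must be in [0, 1]")
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("component weights must sum to 1")
  components <- lapply(components, function(cmp) {
    cmp$mean <- rep_len(cmp$mean, n)
    cmp$sd <- rep_len(cmp$sd, n)
    if (is.null(cmp$ar1)) cmp$ar1 <- 0
    if (cmp$ar1 < 0 || cmp$ar1 >= 1) stop("ar1 must be in [0, 1)")
    if (any(cmp$sd < 0)) stop("sd must be nonnegative")
    if (any(round(cmp$mean) < qmin | round(cmp$mean) > qmax))
      stop("rounded mean profile outside [qmin, qmax]")
    cmp
  })
  structure(list(N = as.integer(N), n = as.integer(n),
                 components = components, offset = as.integer(offset),
                 qmin = as.integer(qmin), qmax = as.integer(qmax),
                 n_base_fraction = n_base_fraction,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic FASTQ file
#'
#' Draws each read's quality vector from the mixture in `spec`:
#' component sampled by weight, vector from the component's Gaussian
#' (via the Cholesky factor of its AR(1) covariance), then rounded and
#' clamped into `[qmin, qmax]` — so the emitted marginal is only
#' approximately Gaussian, as with real data, where the Gaussian is
#' itself a modeling assumption. Nucleotides are uniform over ACGT with
#' `n_base_fraction` positions replaced by 'N'. Headers are
#' `SYN.<index>`. R's global RNG state is saved and restored, and the
#' same spec always yields a byte-identical file.
#'
#' @param spec A `generator_spec`.
#' @param path Optional output path; when `NULL` the records are only
#'   returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the record
#'   `data.frame`, with an extra `component` column giving each read's
#'   generating mixture component (1-based) for parameter-recovery
#'   checks.
#' @export
generate_fastq <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  N <- spec$N; n <- spec$n
  w <- vapply(spec$components, `[[`, numeric(1), "weight")
  comp <- sample.int(length(w), N, replace = TRUE, prob = w)
  qmat <- matrix(0L, N, n)
  for (ci in seq_along(spec$components)) {
    cmp <- spec$components[[ci]]
    rows <- which(comp == ci)
    if (!length(rows)) next
    sigma <- outer(cmp$sd, cmp$sd) * cmp$ar1^abs(outer(seq_len(n), seq_len(n), `-`))
    z <- matrix(stats::rnorm(length(rows) * n), length(rows), n)
    L <- if (all(cmp$sd > 0)) chol(sigma) else {
      # degenerate (zero-variance) positions: fall back to sqrt of diagonal
      diag(cmp$sd, n)
    }
    x <- z %*% L
    x <- sweep(x, 2L, cmp$mean, `+`)
    qmat[rows, ] <- pmin(pmax(round_half_away(x), spec$qmin), spec$qmax)
  }
  seqs <- matrix(sample(c("A", "C", "G", "T"), N * n, replace = TRUE), N, n)
  if (spec$n_base_fraction > 0) {
    nn <- matrix(stats::runif(N * n) < spec$n_base_fraction, N, n)
    seqs[nn] <- "N"
  }
  records <- data.frame(
    header = sprintf("SYN.%d", seq_len(N)),
    sequence = apply(seqs, 1L, paste0, collapse = ""),
    plus = "",
    quality = apply(qmat, 1L, intToUtf8),
    component = comp,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write_records_plain(records, path)
    return(invisible(records))
  }
  records
}

# write records in given order (generator output keeps SYN.<i> order)
write_records_plain <- function(records, path) {
  lines <- as.vector(rbind(paste0("@", records$header), records$sequence,
                           paste0("+", records$plus), records$quality))
  writeLines(lines, path)
  invisible(path)
}
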