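#' Empirical Gaussian statistics of a set of quality vectors
#'
#' Computes the sample mean mu and the maximum-likelihood covariance
#' Sigma (divide-by-N) of the rows of a quality matrix. These are the
#' parameters of the multivariate Gaussian under which the codec models
#' quality vectors; within a cluster every read is assumed drawn i.i.d.
#' from N(mu, Sigma).
#'
#' @param rows Numeric matrix, reads in rows (at least 2).
#' @return A `cluster_stats`: list with `mu` (length-n vector), `sigma`
#'   (symmetric n x n matrix) and `count`.
#' @export
compute_statistics <- function(rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L)
    stop("need at least 2 reads to estimate a covariance (got ", nrow(rows), ")")
  cnt <- nrow(rows)
  mu <- colMeans(rows)
  centered <- sweep(rows, 2L, mu)
  sigma <- crossprod(centered) / cnt
  sigma <- (sigma + t(sigma)) / 2  # kill asymmetry from floating-point
  structure(list(mu = mu, sigma = sigma, count = cnt),
            class = "cluster_stats")
}

#' Spectral decomposition of the quality covariance
#'
#' Factors Sigma = V diag(s) V' with V orthogonal and s non-increasing.
#' Sigma is symmetric positive semidefinite, so its SVD coincides with its
#' eigendecomposition; the symmetric eigensolver is used and a
#' deterministic sign convention applied (the largest-magnitude entry of
#' each column of V is made positive, ties broken by lowest row index).
#' Determinism matters because V is stored verbatim in the container and
#' the decoder must reproduce the encoder's transform bit-exactly.
#'
#' @param stats A `cluster_stats` object.
#' @return A `spectral_model`: list with `mu`, `V` (n x n orthogonal
#'   matrix) and `s` (nonnegative, non-increasing eigenvalues).
#' @export
spectral_decompose <- function(stats) {
  stopifnot(inherits(stats, "cluster_stats"))
  eig <- eigen(stats$sigma, symmetric = TRUE)
  s <- eig$values
  V <- eig$vectors
  tol <- 1e-8 * max(abs(s), 1)
  if (any(s < -tol))
    stop("covariance not positive semidefinite (min eigenvalue ", min(s), ")")
  s <- pmax(s, 0)
  # eigen() returns non-increasing values already; enforce defensively
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; V <- V[, ord, drop = FALSE]
  pivots <- integer(ncol(V))
  for (j in seq_len(ncol(V))) {
    pivots[j] <- which.max(abs(V[, j]))  # lowest index on ties
    if (V[pivots[j], j] < 0) V[, j] <- -V[, j]
  }
  # tie-break exactly equal eigenvalues by pivot row, so degenerate
  # spectra (e.g. the zero matrix) still factor deterministically
  ord <- order(-s, pivots)
  s <- s[ord]; V <- V[, ord, drop = FALSE]
  structure(list(mu = stats$mu, V = V, s = s), class = "spectral_model")
}

#' Decorrelate quality vectors
#'
#' Applies the Karhunen-Loeve transform Q' = V'(Q - mu). Under the
#' Gaussian model the components of Q' are independent N(0, s_j), which
#' is what lets bits be allocated to positions independently.
#'
#' @param q Numeric vector of length n, or an N x n matrix (rows
#'   transformed independently).
#' @param model A `spectral_model`.
#' @return Transformed vector, or matrix with transformed rows.
#' @export
decorrelate <- function(q, model) {
  stopifnot(inherits(model, "spectral_model"))
  n <- length(model$mu)
  if (is.matrix(q)) {
    if (ncol(q) != n) stop("expected ", n, " columns, got ", ncol(q))
    return(sweep(q, 2L, model$mu) %*% model$V)
  }
  if (length(q) != n) stop("expected length ", n, ", got ", length(q))
  drop(crossprod(model$V, q - model$mu))
}

#' Recorrelate transform coefficients into integer quality values
#'
#' Inverse transform: round(V Q' + mu), rounding half away from zero,
#' then clamped into the quality alphabet `[qmin, qmax]` so decoded files
#' never contain out-of-scale characters. With Q' = 0 (the zero-rate
#' reconstruction) this returns the rounded cluster mean.
#'
#' @param qprime Numeric vector of length n, or an N x n matrix.
#' @param model A `spectral_model`.
#' @param qmin,qmax Integer alphabet bounds for clamping.
#' @return Integer vector (or matrix) of reconstructed quality values.
#' @export
recorrelate <- function(qprime, model, qmin, qmax) {
  stopifnot(inherits(model, "spectral_model"))
  n <- length(model$mu)
  if (is.matrix(qprime)) {
    if (ncol(qprime) != n) stop("expected ", n, " columns, got ", ncol(qprime))
    raw <- sweep(qprime %*% t(model$V), 2L, model$mu, `+`)
  } else {
    if (length(qprime) != n) stop("expected length ", n, ", got ", length(qprime))
    raw <- drop(model$V %*% qprime) + model$mu
  }
  out <- round_half_away(raw)
  out[out < qmin] <- as.integer(qmin)
  out[out > qmax] <- as.integer(qmax)
  out
}

# round half away from zero (base round() goes to even)
round_half_away <- function(x) {
  r <- sign(x) * floor(abs(x) + 0.5)
  storage.mode(r) <- "integer"
  r
}
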