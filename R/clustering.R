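#' Constant-vector initial cluster means
#'
#' Initializes k cluster means as constant vectors whose values are
#' equally spaced between the minimum and maximum quality score: with
#' alphabet [33, 73] and k = 3 the means start as all 33's, all 53's and
#' all 73's. For k = 1 the midpoint is used (the single-cluster
#' assignment does not depend on the value).
#'
#' @param k Number of clusters (>= 1).
#' @param qmin,qmax Quality alphabet bounds.
#' @param n Read length.
#' @return A k x n numeric matrix, one mean per row.
#' @export
init_means <- function(k, qmin, qmax, n) {
  if (k < 1L) stop("k must be >= 1")
  vals <- if (k == 1L) (qmin + qmax) / 2
          else qmin + (0:(k - 1L)) * (qmax - qmin) / (k - 1L)
  matrix(rep(vals, n), nrow = k, ncol = n)
}

#' Assign quality vectors to the nearest cluster mean
#'
#' Each vector goes to the cluster minimizing the per-position MSE
#' (1/n) sum_j (Q(j) - V(j))^2; ties break to the lowest cluster index.
#'
#' @param q Numeric vector of length n, or an N x n matrix.
#' @param means k x n matrix of cluster means.
#' @return Integer cluster index (1-based), or a vector of them.
#' @export
assign_cluster <- function(q, means) {
  if (!is.matrix(q)) q <- matrix(q, nrow = 1L)
  if (ncol(q) != ncol(means))
    stop("dimension mismatch: vectors have ", ncol(q),
         " positions, means have ", ncol(means))
  # squared distances via ||q||^2 - 2 q.m + ||m||^2; constant ||q||^2 dropped
  cross <- q %*% t(means)                       # N x k
  m2 <- rowSums(means^2)
  d <- sweep(-2 * cross, 2L, m2, `+`)
  lab <- max.col(-d, ties.method = "first")
  if (nrow(q) == 1L) lab[1L] else lab
}

#' k-means clustering of quality vectors
#'
#' Lloyd's algorithm with the constant-vector initialization of
#' [init_means()]: assign every vector to its MSE-nearest mean, recompute
#' each mean as the empirical average of its members, and repeat until no
#' vector changes cluster or `max_iter` is reached. A cluster that loses
#' all members keeps its previous mean.
#'
#' @param block A `quality_block`, or a plain numeric matrix of quality
#'   vectors (reads in rows).
#' @param k Number of clusters; `N >= k` required.
#' @param max_iter Iteration cap (default 100).
#' @param qmin,qmax Alphabet bounds for initialization; taken from the
#'   block when it carries them.
#' @return A `cluster_state`: list with `means` (k x n matrix), `labels`
#'   (1-based integer vector of length N), `iterations`, and `converged`.
#' @export
kmeans_quality <- function(block, k, max_iter = 100L,
                           qmin = NULL, qmax = NULL) {
  if (inherits(block, "quality_block")) {
    if (is.null(qmin)) qmin <- block$qmin
    if (is.null(qmax)) qmax <- block$qmax
    x <- block$values
  } else {
    x <- as.matrix(block)
    if (is.null(qmin)) qmin <- min(x)
    if (is.null(qmax)) qmax <- max(x)
  }
  storage.mode(x) <- "double"
  N <- nrow(x)
  if (N < k) stop("need at least k = ", k, " reads, got ", N)
  means <- init_means(k, qmin, qmax, ncol(x))
  labels <- rep(0L, N)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    new_labels <- assign_cluster(x, means)
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
    for (c in seq_len(k)) {
      members <- labels == c
      if (any(members)) means[c, ] <- colMeans(x[members, , drop = FALSE])
      # empty cluster: keep previous mean
    }
  }
  structure(list(means = means, labels = labels,
                 iterations = iter, converged = converged),
            class = "cluster_state")
}

#' Total within-cluster MSE of a clustering
#'
#' Mean over reads of the per-read MSE to its assigned cluster mean;
#' the quantity k-means monotonically decreases.
#'
#' @param x Numeric matrix of quality vectors.
#' @param state A `cluster_state`.
#' @return A single nonnegative number.
#' @export
within_cluster_mse <- function(x, state) {
  x <- as.matrix(x)
  d <- x - state$means[state$labels, , drop = FALSE]
  mean(rowMeans(d^2))
}
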