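#' Lloyd-Max scalar quantizer for the standard Gaussian
#'
#' Computes the MSE-optimal b-bit scalar quantizer of N(0,1) as the fixed
#' point of the two Lloyd conditions: each representative is the
#' conditional mean of its decision region,
#' r_i = (phi(a_i) - phi(b_i)) / (Phi(b_i) - Phi(a_i)),
#' and each threshold is the midpoint of adjacent representatives.
#' Conditional means use the closed-form Gaussian expressions, not
#' sampling. The 1-bit codebook has thresholds {0} and representatives
#' -sqrt(2/pi), +sqrt(2/pi) = -0.79788, +0.79788. Codebooks are cached
#' after first construction, since they depend only on the bit depth.
#'
#' @param bits Bit depth b >= 0; the codebook has 2^b levels.
#' @param tol Convergence tolerance on the maximum representative change
#'   (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return A `lm_codebook`: list with `bits`, `thresholds` (length
#'   2^b - 1, strictly increasing) and `representatives` (length 2^b,
#'   strictly increasing, symmetric about 0).
#' @export
lloyd_max <- function(bits, tol = 1e-10, max_iter = 10000L) {
  bits <- as.integer(bits)
  if (bits < 0L) stop("bits must be >= 0")
  key <- as.character(bits)
  cached <- .codebook_cache[[key]]
  if (!is.null(cached)) return(cached)
  L <- 2L^bits
  if (bits == 0L) {
    cb <- structure(list(bits = 0L, thresholds = numeric(),
                         representatives = 0),
                    class = "lm_codebook")
    .codebook_cache[[key]] <- cb
    return(cb)
  }
  # region probability Phi(b) - Phi(a), computed from whichever tail
  # avoids cancellation (matters for the outer regions of deep codebooks)
  region_prob <- function(a, b) {
    p <- stats::pnorm(b) - stats::pnorm(a)
    hi <- a >= 0
    p[hi] <- stats::pnorm(a[hi], lower.tail = FALSE) -
      stats::pnorm(b[hi], lower.tail = FALSE)
    p
  }
  # conditional mean of N(0,1) on (a, b)
  cond_mean <- function(a, b, p) (stats::dnorm(a) - stats::dnorm(b)) / p

  # Fixed-point (Lloyd) sweeps converge only linearly, with rate
  # degrading as the level count grows; a few warm-up sweeps from the
  # Gaussian-quantile start are followed by damped Newton on the
  # threshold system t_i = (m_i + m_{i+1})/2, whose Jacobian is
  # tridiagonal with closed-form truncated-normal derivatives.
  reps <- stats::qnorm((seq_len(L) - 0.5) / L)
  for (sweep_i in 1:20) {
    thr <- (reps[-L] + reps[-1L]) / 2
    a <- c(-Inf, thr); b <- c(thr, Inf)
    reps <- cond_mean(a, b, region_prob(a, b))
  }
  thr <- (reps[-L] + reps[-1L]) / 2
  residual <- function(t) {
    a <- c(-Inf, t); b <- c(t, Inf)
    p <- region_prob(a, b)
    m <- cond_mean(a, b, p)
    list(H = t - (m[-L] + m[-1L]) / 2, m = m, p = p)
  }
  st <- residual(thr)
  converged <- max(abs(st$H)) < tol
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    a <- c(-Inf, thr); b <- c(thr, Inf)
    m <- st$m; p <- st$p
    phi_t <- stats::dnorm(thr)
    # d m_i / d(upper bound) and d m_{i+1} / d(lower bound) at t_i
    dm_upper <- phi_t * (thr - m[-L]) / p[-L]
    dm_lower <- phi_t * (m[-1L] - thr) / p[-1L]
    diag_main <- 1 - (dm_upper + dm_lower) / 2
    # off-diagonals: d m_i / d t_{i-1} (lower bound of region i) and
    # d m_{i+1} / d t_{i+1} (upper bound of region i+1)
    if (L > 2L) {
      sub <- -(stats::dnorm(thr[-(L - 1L)]) *
                 (m[2:(L - 1L)] - thr[-(L - 1L)]) / p[2:(L - 1L)]) / 2
      sup <- -(stats::dnorm(thr[-1L]) *
                 (thr[-1L] - m[2:(L - 1L)]) / p[2:(L - 1L)]) / 2
    } else sub <- sup <- numeric(0)
    step <- solve_tridiag(sub, diag_main, sup, st$H)
    lambda <- 1
    repeat {
      cand <- thr - lambda * step
      ok <- !is.unsorted(cand, strictly = TRUE)
      if (ok) {
        st_new <- residual(cand)
        ok <- all(is.finite(st_new$H)) &&
          max(abs(st_new$H)) <= max(abs(st$H))
      }
      if (ok || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-8) {
      # residual can no longer be reduced: accept if it sits at the
      # floating-point floor of the tail probabilities, else fail
      if (max(abs(st$H)) < 1e-6) { converged <- TRUE; break }
      stop("Lloyd-Max did not converge for ", bits, " bits (stalled at ",
           max(abs(st$H)), ")")
    }
    thr <- cand; st <- st_new
    converged <- max(abs(st$H)) < tol
  }
  if (!converged)
    stop("Lloyd-Max did not converge for ", bits, " bits in ",
         max_iter, " iterations")
  reps <- st$m
  # exact symmetrization (iteration preserves symmetry up to rounding)
  reps <- (reps - rev(reps)) / 2
  thr <- (reps[-L] + reps[-1L]) / 2
  cb <- structure(list(bits = bits, thresholds = thr,
                       representatives = reps),
                  class = "lm_codebook")
  .codebook_cache[[key]] <- cb
  cb
}

.codebook_cache <- new.env(parent = emptyenv())

# Thomas algorithm for a tridiagonal system; sub/sup have length L-2
solve_tridiag <- function(sub, diag_main, sup, rhs) {
  n <- length(diag_main)
  if (n == 1L) return(rhs / diag_main)
  cp <- numeric(n - 1L); dp <- numeric(n)
  cp[1L] <- sup[1L] / diag_main[1L]
  dp[1L] <- rhs[1L] / diag_main[1L]
  for (i in 2:n) {
    denom <- diag_main[i] - sub[i - 1L] * cp[i - 1L]
    if (i < n) cp[i] <- sup[i] / denom
    dp[i] <- (rhs[i] - sub[i - 1L] * dp[i - 1L]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

#' Quantize values to decision-region indices
#'
#' Returns the 0-based index of the decision region containing each
#' value: region i is the interval between thresholds i-1 and i (the
#' outermost regions are unbounded). A value exactly on a threshold goes
#' to the upper region, so with 1 bit the boundary 0 encodes as region 1
#' and any negative value (e.g. -0.344) as region 0.
#'
#' @param x Finite numeric vector.
#' @param codebook A `lm_codebook`.
#' @return Integer vector of indices in `[0, 2^bits)`.
#' @export
quantize <- function(x, codebook) {
  stopifnot(inherits(codebook, "lm_codebook"))
  if (codebook$bits == 0L) return(integer(length(x)))
  # default closed-left convention puts threshold values in the upper region
  findInterval(x, codebook$thresholds)
}

#' Decode decision-region indices to representative values
#'
#' @param index Integer vector of 0-based region indices.
#' @param codebook A `lm_codebook`.
#' @return Numeric vector of representatives; with 1 bit, index 0 decodes
#'   to -0.79788 and index 1 to +0.79788.
#' @export
dequantize <- function(index, codebook) {
  stopifnot(inherits(codebook, "lm_codebook"))
  if (any(index < 0L | index >= 2L^codebook$bits))
    stop("index out of range [0, ", 2L^codebook$bits, ")")
  codebook$representatives[index + 1L]
}

#' Quantizer distortion under the unit Gaussian
#'
#' E[(X - Q(X))^2] for X ~ N(0,1), evaluated in closed form per region
#' from the truncated-Gaussian partial moments (no sampling, no numeric
#' integration error beyond pnorm/dnorm). D(0) = 1 and D(1) = 1 - 2/pi.
#'
#' @param codebook A `lm_codebook`.
#' @return The mean squared quantization error.
#' @export
codebook_distortion <- function(codebook) {
  stopifnot(inherits(codebook, "lm_codebook"))
  r <- codebook$representatives
  a <- c(-Inf, codebook$thresholds)
  b <- c(codebook$thresholds, Inf)
  p  <- stats::pnorm(b) - stats::pnorm(a)                 # zeroth moment
  m1 <- stats::dnorm(a) - stats::dnorm(b)                 # first moment
  da <- ifelse(is.finite(a), a * stats::dnorm(a), 0)
  db <- ifelse(is.finite(b), b * stats::dnorm(b), 0)
  m2 <- p + da - db                                       # second moment
  sum(m2 - 2 * r * m1 + r^2 * p)
}
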