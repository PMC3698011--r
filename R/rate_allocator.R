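#' Rate-distortion optimal bit allocation by reverse water-filling
#'
#' Minimizes the expected distortion (1/n) sum_j s_j 2^(-2 rho_j) subject
#' to sum_j rho_j <= n*R and 0 <= rho_j <= max_bits, where s_j are the
#' variances of the decorrelated coefficients. The solution has the
#' reverse water-filling form rho_j = clip(0.5*log2(s_j / theta), 0,
#' max_bits): coefficients with variance above a common water level theta
#' get bits in proportion to their log-variance, coefficients below get
#' none. theta is found by bisection so the budget is tight (unless every
#' positive-variance coefficient is capped at `max_bits`, in which case
#' the budget cannot be exhausted).
#'
#' @param s Nonnegative variance vector (length n).
#' @param R Rate in bits per quality score (>= 0); the total budget is
#'   `n * R`.
#' @param max_bits Per-position cap on bits (default 15).
#' @return A `bit_allocation`: list with `rho` (fractional bits per
#'   position), `budget` (= n*R), `water_level` (theta; NA when R = 0 or
#'   all variances are zero), and `max_bits`.
#' @export
solve_allocation <- function(s, R, max_bits = 15L) {
  if (any(s < 0)) stop("variances must be nonnegative")
  if (R < 0) stop("rate must be nonnegative")
  n <- length(s)
  budget <- n * R
  rho <- numeric(n)
  pos <- s > 0
  mk_result <- function(rho, theta)
    structure(list(rho = rho, budget = budget, water_level = theta,
                   max_bits = as.integer(max_bits)),
              class = "bit_allocation")
  if (budget == 0 || !any(pos)) return(mk_result(rho, NA_real_))

  alloc_at <- function(theta)
    pmin(pmax(0.5 * log2(s[pos] / theta), 0), max_bits)
  # full cap on every positive-variance coefficient still fits the budget
  if (sum(pos) * max_bits <= budget) {
    rho[pos] <- max_bits
    return(mk_result(rho, NA_real_))
  }
  # bisect theta: sum(alloc) is decreasing in theta
  lo <- min(s[pos]) * 2^(-2 * max_bits)   # alloc = cap everywhere
  hi <- max(s[pos])                       # alloc = 0 everywhere
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (sum(alloc_at(mid)) > budget) lo <- mid else hi <- mid
    if (hi - lo < 1e-15 * max(hi, 1)) break
  }
  theta <- hi
  a <- alloc_at(theta)
  # bisection leaves a residual below the budget; spread it over the
  # uncapped active set so the constraint is exactly tight
  resid <- budget - sum(a)
  free <- a > 0 & a < max_bits
  if (resid > 0 && any(free)) {
    a[free] <- a[free] + resid / sum(free)
    a <- pmin(a, max_bits)
  }
  rho[pos] <- a
  mk_result(rho, theta)
}

#' Expected distortion of a bit allocation
#'
#' Evaluates (1/n) sum_j s_j 2^(-2 rho_j), the model MSE of quantizing
#' independent N(0, s_j) coefficients with rho_j bits each.
#'
#' @param s Variance vector.
#' @param rho Bits per position (same length as `s`), or a
#'   `bit_allocation`.
#' @return A single nonnegative number.
#' @export
expected_distortion <- function(s, rho) {
  if (inherits(rho, "bit_allocation")) rho <- rho$rho
  if (length(s) != length(rho)) stop("s and rho must have equal length")
  mean(s * 2^(-2 * rho))
}

#' Randomized rounding of a fractional bit allocation
#'
#' Maps each fractional rho_j to floor(rho_j) + 1 with probability
#' frac(rho_j) and floor(rho_j) otherwise, so that E[rho'_j] = rho_j and
#' per-read integer allocations average to the fractional optimum.
#' Exactly one PRNG draw is consumed per position, in position order,
#' whether or not rho_j is integral — this fixed consumption pattern is
#' what keeps the encoder's and decoder's generators in lockstep.
#'
#' @param rho Nonnegative fractional bits per position.
#' @param rng A `lehmer_rng` stream (see [lehmer_rng()]); advanced in
#'   place.
#' @return Integer vector of realized bits per position.
#' @export
randomize_rounding <- function(rho, rng) {
  u <- rng_uniform(rng, length(rho))
  lo <- floor(rho)
  as.integer(lo + (u < (rho - lo)))
}

#' Minimal-standard Lehmer pseudorandom stream
#'
#' The multiplicative congruential generator x <- (16807 * x) mod
#' (2^31 - 1), with uniforms u = x / (2^31 - 1). All arithmetic stays
#' below 2^53, so the stream is exactly reproducible in double-precision
#' arithmetic on any platform — a requirement here, because the decoder
#' must replay the encoder's randomized-rounding draws bit-for-bit and
#' the seed is part of the container format. Seeds are reduced into the
#' valid state range [1, 2^31 - 2].
#'
#' @param seed A nonnegative integer-valued number.
#' @return A `lehmer_rng` environment with the current state.
#' @export
lehmer_rng <- function(seed) {
  m <- 2147483647  # 2^31 - 1
  state <- (as.numeric(seed) %% (m - 1)) + 1  # in [1, m-1]
  e <- new.env(parent = emptyenv())
  e$state <- state
  class(e) <- "lehmer_rng"
  e
}

#' Draw uniforms from a Lehmer stream
#'
#' @param rng A `lehmer_rng`.
#' @param k Number of draws.
#' @return Numeric vector of `k` uniforms in (0, 1); the stream advances.
#' @export
rng_uniform <- function(rng, k) {
  m <- 2147483647
  x <- rng$state
  out <- numeric(k)
  for (i in seq_len(k)) {
    x <- (16807 * x) %% m
    out[i] <- x / m
  }
  rng$state <- x
  out
}
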