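# shared fixtures and independent oracles

write_tmp_fastq <- function(lines) {
  f <- tempfile(fileext = ".fastq")
  writeLines(lines, f)
  f
}

# a classic public-archive-style entry: 26-base read with a quality
# string spanning the full Phred+33 alphabet
entry26_lines <- c(
  "@SRR001666.1",
  "GATTTGGGGTTCAAAGCAGTATCGAT",
  "+",
  "IIIHIIHABBBAA=2))!!!(!!!((")

# single-component synthetic quality file used across codec tests
codec_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(N = 5000, n = 50, seed = 404) {
    key <- paste(N, n, seed, sep = "_")
    if (is.null(cache[[key]])) {
      spec <- generator_spec(
        N = N, n = n,
        components = list(list(weight = 1,
                               mean = 38 + 25 * exp(-(seq_len(n) - 1) / (n / 2)),
                               sd = 4, ar1 = 0.8)),
        seed = seed)
      path <- tempfile(fileext = ".fastq")
      generate_fastq(spec, path)
      cache[[key]] <- path
    }
    cache[[key]]
  }
})

# two well-separated quality populations (low- and high-quality blobs)
two_blob_spec <- function(N = 2000, n = 30, seed = 11) {
  generator_spec(
    N = N, n = n,
    components = list(
      list(weight = 0.5, mean = 35, sd = 1.5, ar1 = 0.5),
      list(weight = 0.5, mean = 70, sd = 1.0, ar1 = 0.5)),
    seed = seed)
}

# Exact dynamic-programming oracle for the bit-allocation program:
# minimizes (1/n) sum_j s_j 2^(-2 rho_j) over rho_j on a regular grid
# with sum rho_j <= budget. Independent of the water-filling solver.
oracle_allocation_dp <- function(s, budget, step = 0.01, cap = 15) {
  n <- length(s)
  B <- round(budget / step)
  kmax <- min(B, round(cap / step))
  grid_cost <- function(sj) sj * 2^(-2 * step * (0:kmax)) / n
  dp <- c(0, rep(Inf, B))
  for (j in seq_len(n)) {
    cost <- grid_cost(s[j])
    new <- rep(Inf, B + 1L)
    for (b in 0:B) {
      k <- 0:min(b, kmax)
      new[b + 1L] <- min(dp[b - k + 1L] + cost[k + 1L])
    }
    dp <- new
  }
  min(dp)
}
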