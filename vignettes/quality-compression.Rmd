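---
title: "Rate-distortion compression of FASTQ quality scores: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-distortion compression of FASTQ quality scores: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualpress)
```

## The problem

A FASTQ record stores, for every called base, an integer quality score
$Q = -10\log_{10}P$ (Phred) encoded as the ASCII character with code
$Q + \text{offset}$. Quality strings are the high-entropy half of a FASTQ
file — they compress poorly losslessly (around 2.5 bits per score is
typical) — yet most downstream consumers tolerate controlled distortion in
them. `qualpress` compresses the quality stream of a fixed-read-length
FASTQ file to a user-chosen budget of $R$ bits per quality score ($nR$
bits per read of length $n$), minimizing the mean squared error

$$D = \frac{1}{N}\sum_{i=1}^N D(i), \qquad
  D(i) = \frac{1}{n}\sum_{j=1}^n \big(Q_i(j) - \hat Q_i(j)\big)^2 .$$

Headers and nucleotide sequences are carried unmodified in a plain-text
"stub"; only quality strings are lossy.

## The model

Quality scores are integers in a finite alphabet, but for design purposes
each read's quality vector $Q_i \in \mathbb{R}^n$ is modelled as
multivariate Gaussian, $Q_i \sim N(\mu_Q, \Sigma_Q)$, i.i.d. across reads,
with correlation only *within* a read. Two facts justify this: the
Gaussian is the least-compressible source with a given covariance, so a
code designed for it does no worse on the true source with the same second
moments; and $\mu_Q, \Sigma_Q$ are cheap to estimate empirically (we use
the maximum-likelihood, divide-by-$N$ covariance — at the read counts
involved the distinction from $N-1$ is far below sampling noise).

The encoder pipeline is:

1. **Clustering (optional, $k \ge 1$).** k-means on the quality vectors
   under per-position MSE, initialized at constant vectors equally spaced
   over the quality alphabet (with alphabet $[33, 73]$ and $k = 3$: all
   33's, all 53's, all 73's). Iteration stops when no read changes
   cluster or after `max_iter` (default 100). Each cluster is then coded
   independently with its own statistics, which sharpens the model when
   the file mixes distinct quality populations.
2. **Decorrelation.** Per cluster, $\Sigma_Q = V\,\mathrm{diag}(s)\,V^T$
   (the SVD of a symmetric PSD matrix, computed as a symmetric
   eigendecomposition), and $Q'_i = V^T(Q_i - \mu_Q)$. Under the model the
   coefficients of $Q'_i$ are independent $N(0, s_j)$.
3. **Bit allocation.** The budget $nR$ is split across coefficients by
   solving
   $\min_\rho \frac{1}{n}\sum_j s_j 2^{-2\rho_j}$ s.t. $\sum_j \rho_j \le nR$,
   whose solution is reverse water-filling:
   $\rho_j = \mathrm{clip}\big(\tfrac12\log_2(s_j/\theta),\,0,\,\text{max\_bits}\big)$
   with the water level $\theta$ found by bisection until the budget is
   tight. The allocation is solved once per cluster — every read shares it.
4. **Randomized rounding.** Fractional $\rho_j$ are realized per read as
   integers $\rho'_j \in \{\lfloor\rho_j\rfloor, \lceil\rho_j\rceil\}$ with
   $E[\rho'_j] = \rho_j$, so the average realized rate meets the target.
   The draws come from a shared seeded PRNG replayed identically by the
   decoder (below).
5. **Quantization.** Each coefficient is normalized to unit variance
   (divisor $\sqrt{s_j}$, floored at $10^{-12}$) and quantized with the
   Lloyd-Max codebook for $N(0,1)$ at $\rho'_j$ bits; indices are packed
   MSB-first into the cluster's bitstream.

The decoder replays the rounding draws, unpacks and dequantizes,
rescales by $\sqrt{s_j}$, reconstructs
$\hat Q_i = \mathrm{round}(V Q'_i + \mu_Q)$ (rounding half away from
zero), clamps into the quality alphabet, and finally overwrites positions
whose base is `N` with the least reliable score `qmin`. At $R = 0$ nothing
is quantized and every read in a cluster decodes to the rounded cluster
mean — still more informative than discarding qualities outright, since
the mean profile varies along the read.

## Numerical choices

**Lloyd-Max construction.** The $b$-bit codebook is the fixed point of
the two optimality conditions: representatives are conditional means of
their regions (closed-form truncated-Gaussian expressions, no sampling)
and thresholds are midpoints of adjacent representatives. Plain Lloyd
iteration converges only linearly and degrades badly as $2^b$ grows, so
after 20 warm-up sweeps from a Gaussian-quantile start the fixed point is
found by damped Newton on the threshold system, whose Jacobian is
tridiagonal with analytic truncated-normal derivatives; region
probabilities are computed from whichever Gaussian tail avoids
cancellation. Convergence tolerance is $10^{-10}$ (residuals at very deep
codebooks may bottom out at the floating-point floor of the tail
probabilities, which is accepted); codebooks are cached after first
construction. The 1-bit codebook is $\pm\sqrt{2/\pi} \approx \pm 0.7979$
with threshold 0; a value on a threshold quantizes to the upper region (a
documented convention — either choice is MSE-optimal).

**Determinism of the factorization.** The container stores $\mu$, $V$ and
$s$ explicitly (not $\Sigma$), so the decoder never refactors anything and
sign/order ambiguity of the eigendecomposition cannot desynchronize the
transform. The encoder canonicalizes: eigenvalues non-increasing, each
column's largest-magnitude entry positive (ties to the lowest row index),
exactly equal eigenvalues ordered by pivot row.

**The PRNG is part of the file format.** Encoder and decoder must consume
*bit-identical* rounding draws. R's own RNG is not a contract we can
freeze into a container format, so the stream is a minimal-standard Lehmer
generator, $x_{t+1} = 16807\,x_t \bmod (2^{31}-1)$, whose arithmetic stays
below $2^{53}$ and is therefore exact in doubles on any platform. The seed
is stored in the container; state is seeded as
$x_0 = (\text{seed} \bmod (2^{31}-2)) + 1$. One draw is consumed per
position per read — including positions with integer $\rho_j$ — in read
order within each cluster, making the consumption pattern independent of
the allocation values.

**Allocation details.** `max_bits` caps any single coefficient at 15 bits
(codebook construction cost grows as $2^b$ and the marginal MSE gain is
negligible far earlier). $\theta$-bisection runs on
$[\min_j s_j 2^{-2\,\text{max\_bits}}, \max_j s_j]$ to a relative interval
of $10^{-15}$, and the residual slack is spread uniformly over the
uncapped active coefficients so the budget constraint is exactly tight.
Zero-variance coefficients never receive bits and decode to zero, i.e. to
the cluster mean along that direction.

**Degenerate inputs.** Clusters with fewer than two reads get a zero
covariance (the mean is the read itself, or the alphabet midpoint when
empty); empty clusters keep their previous k-means mean. Decoded values
are clamped into $[q_{\min}, q_{\max}]$ so the output FASTQ can never
contain out-of-scale characters. Equidistant k-means assignments break to
the lower cluster index.

**Rate accounting conventions.** The effective rate
$R' = 8\,\text{(container bytes)} / (nN)$ counts payload plus side
information ($\approx 8(n^2 + 3n)$ bytes per cluster for $\mu, V, s, \rho$
stored as IEEE-754 doubles, little-endian). Side-information sizes are
quoted in KB of 1024 bytes; dataset-scale storage projections
(`storage_projection()`) use GB of $10^9$ bytes. The stub is excluded
from $R'$: the accounting covers quality scores only, and stub
compression is a separate, lossless concern out of scope here. Read order
is deliberately not preserved (output is sorted by header, bytewise), so
paired-end mates with equal header sets always emerge in the same order.

## The synthetic generator

`generator_spec()`/`generate_fastq()` produce FASTQ whose quality vectors
have exactly the structure the codec assumes: a mixture of multivariate
Gaussians with per-component mean profile, standard-deviation profile and
AR(1) within-read correlation, $\Sigma_{jl} = \sigma_j\sigma_l\,r^{|j-l|}$
— AR(1) because within-read correlation decaying with positional distance
is the phenomenon the decorrelation step exploits. Values are rounded and
clamped into the alphabet, so the emitted marginal is only approximately
Gaussian; parameter-recovery tolerances in the tests allow for the
$\tfrac{1}{12}$ variance inflation of integer rounding. Nucleotides are
uniform ACGT with a configurable `N` fraction; generation is deterministic
given the spec and restores R's global RNG state.

What passing tests on this generator do **not** show: real quality data
are not Gaussian (they are skewed, bounded, platform-dependent, and
correlated with base identity and machine cycle), and the distortion a
real pipeline cares about is downstream (alignment, variant calls), not
MSE. The generator validates the machinery — transform identities,
bit-exact container round-trips, rate-distortion monotonicity — not
platform-specific compression ratios.

## Problem sizes in the test suite

The suite exercises the full codec at $N = 5000$ reads of length
$n = 50$ for the rate sweep $R \in \{0, 0.2, 0.5, 1, 2, 4\}$, 20000 reads
for parameter-recovery checks, and smaller files elsewhere; these sizes
put sampling error well below the asserted tolerances while keeping the
whole suite around ten seconds. Distortion decreases monotonically in $R$
on these runs, pre-clustering bimodal data never increases MSE at fixed
rate, and at $R = 12$ quantization error falls below integer rounding
granularity and reconstruction is exact.

## Known limitations

* Fixed read length per file; no variable-length, wrapped-line, or
  colorspace FASTQ.
* Scalar (not vector) quantization — chosen for simplicity at a known,
  small performance cost.
* No entropy coding of the payload or side information; gains there are
  small and orthogonal.
* The per-cluster $V$ matrix makes side information $O(n^2)$ doubles per
  cluster; for very long reads (large $n$) the overhead term in $R'$
  grows accordingly.
* Statistics include `N`-masked positions unchanged; the `N` rule is
  applied only at decode time.
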