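# Independent brute-force oracles and fixture builders shared by the suite.
# The oracles deliberately avoid the code paths (and distribution tails)
# they are used to check.

# P(X >= k), X ~ Hypergeometric(population total, K_i successes, K_j draws),
# by direct enumeration of binomial coefficients.
oracle_hyper_tail <- function(k, K_i, K_j, total) {
  hi <- min(K_i, K_j)
  if (k > hi) return(0)
  x <- k:hi
  sum(choose(K_i, x) * choose(total - K_i, K_j - x)) / choose(total, K_j)
}

# P(X >= k), X ~ Poisson(lambda), by direct upper-tail pmf summation
# (summing the tail itself avoids the 1 - (almost 1) cancellation that
# would cap the oracle's own accuracy).
oracle_pois_tail <- function(k, lambda, n_terms = 5000L) {
  if (k <= 0) return(1)
  x <- k:(k + n_terms)
  sum(exp(-lambda + x * log(lambda) - lgamma(x + 1)))
}

# P(X >= k) under NB with mean mu and variance mu + phi * mu^2.
oracle_nb_tail <- function(k, mu, phi, n_terms = 20000L) {
  if (k <= 0) return(1)
  r <- 1 / phi
  pr <- r / (r + mu)
  x <- k:(k + n_terms)
  sum(exp(lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
          r * log(pr) + x * log(1 - pr)))
}

# P(X >= k), X ~ Binomial(n, pr), by partial pmf summation.
oracle_binom_tail <- function(k, n, pr) {
  if (k <= 0) return(1)
  x <- k:n
  sum(exp(lchoose(n, x) + x * log(pr) + (n - x) * log(1 - pr)))
}

# Literal step-up definition of Benjamini-Hochberg q-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
  }
  q
}

# Single-bin anchors at the given 0-based bins.
make_anchors <- function(bins, resolution = 10000L, chrom = "chrS") {
  data.frame(chrom = chrom, start = bins * resolution,
             end = (bins + 1) * resolution,
             name = sprintf("a%d", bins), bin_start = as.integer(bins),
             bin_end = as.integer(bins), stringsAsFactors = FALSE)
}

# Equal-width contiguous domains tiling bins [0, n_dom * width).
make_domains <- function(n_dom, width, resolution = 10000L,
                         chrom = "chrS") {
  s <- (0:(n_dom - 1)) * width
  data.frame(chrom = chrom, start = s * resolution,
             end = (s + width) * resolution, level = 0L,
             bin_start = as.integer(s), bin_end = as.integer(s + width - 1L),
             stringsAsFactors = FALSE)
}

# Null map with pixels set deterministically to `fold` times the diagonal
# scale lambda0 / d (mirrored), returning the modified map.
plant_pixels <- function(map, anchors_bins, partner_bins, fold,
                         lambda0 = 100) {
  M <- map$matrix
  for (k in seq_along(anchors_bins)) {
    d <- abs(partner_bins[k] - anchors_bins[k])
    v <- fold * lambda0 / d
    M[anchors_bins[k] + 1L, partner_bins[k] + 1L] <- v
    M[partner_bins[k] + 1L, anchors_bins[k] + 1L] <- v
  }
  hic_map(M, map$resolution, map$chromosome)
}
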