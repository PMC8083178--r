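#' Aggregate a bin map into a domain-pair contact matrix
#'
#' Builds the N x N matrix `M` whose entry `M[i, j]` is the total number of
#' Hi-C contacts between all bin pairs of domains `i` and `j`. Bins not
#' covered by any domain contribute to no entry. For the discrete count
#' tests the sums are rounded to the nearest integer (with a warning when
#' the input map is non-integer, e.g. a normalized map); the raw sums are
#' retained. Marginals `K_i = sum_j M[i, j]` include the intra-domain
#' diagonal, and the grand total is `T = sum_{i <= j} M[i, j]`.
#'
#' @param map a [hic_map()].
#' @param domains domain data.frame from [read_domains()] (needs
#'   `bin_start`, `bin_end`).
#' @return object of class `domain_matrix`: list with `domains`, `M`
#'   (integer counts), `M_raw` (raw sums), `K`, `total`.
#' @export
aggregate_domains <- function(map, domains) {
  stopifnot(inherits(map, "hic_map"))
  if (is.null(domains) || nrow(domains) == 0L) {
    stop("empty domain list", call. = FALSE)
  }
  n_dom <- nrow(domains)
  if (any(domains$bin_start < 0L) || any(domains$bin_end >= map$n_bins)) {
    stop("domain bins outside map", call. = FALSE)
  }
  bins <- lapply(seq_len(n_dom), function(i) {
    (domains$bin_start[i]:domains$bin_end[i]) + 1L
  })
  M_raw <- matrix(0, n_dom, n_dom)
  for (i in seq_len(n_dom)) {
    for (j in i:n_dom) {
      s <- sum(map$matrix[bins[[i]], bins[[j]], drop = FALSE])
      M_raw[i, j] <- s
      M_raw[j, i] <- s
    }
  }
  M <- round(M_raw)
  if (max(abs(M - M_raw)) > 1e-9) {
    warning("non-integer map: domain-pair counts rounded for discrete tests",
            call. = FALSE)
  }
  K <- rowSums(M)
  total <- sum(M[upper.tri(M, diag = TRUE)])
  structure(list(domains = domains, M = M, M_raw = M_raw, K = K,
                 total = total),
            class = "domain_matrix")
}

#' @export
print.domain_matrix <- function(x, ...) {
  cat(sprintf("domain_matrix: %d domains, total contacts %.4g\n",
              nrow(x$M), x$total))
  invisible(x)
}

#' Hypergeometric enrichment p-value for one domain pair
#'
#' Models the `K_j` contact ends of domain `j` as draws without replacement
#' from the `total` contacts of the chromosome, of which `K_i` touch domain
#' `i`; the p-value is the upper tail `P(X >= M[i, j])`. When
#' `K_i + K_j > total` the draw count is clipped with a warning so the
#' parameters stay admissible.
#'
#' @param dm a [aggregate_domains()] result.
#' @param i,j domain indices with `i < j`.
#' @return one-sided p-value.
#' @export
hypergeom_pvalue <- function(dm, i, j) {
  stopifnot(i < j)
  k <- dm$M[i, j]
  K_i <- dm$K[i]
  K_j <- dm$K[j]
  total <- dm$total
  if (k > min(K_i, K_j)) {
    stop("M[i,j] exceeds a marginal: matrix invariant violated",
         call. = FALSE)
  }
  if (K_i + K_j > total) {
    # overlapping margins force a minimum overlap; the hypergeometric
    # support handles this natively, so no clipping is needed
    warning("K_i + K_j > total: overlap partially forced", call. = FALSE)
  }
  stats::phyper(k - 1, m = K_i, n = total - K_i, k = K_j,
                lower.tail = FALSE)
}

# Expected contacts of pair (i, j) under the margin-product null.
domain_mu <- function(dm, i, j) {
  dm$K[i] * dm$K[j] / (2 * dm$total)
}

#' Poisson enrichment p-value for one domain pair
#'
#' The null expectation is the margin product `mu_ij = K_i * K_j / (2 T)`;
#' the p-value is the Poisson upper tail `P(X >= M[i, j])`.
#'
#' @inheritParams hypergeom_pvalue
#' @return one-sided p-value.
#' @export
poisson_pvalue <- function(dm, i, j) {
  stopifnot(i < j)
  k <- dm$M[i, j]
  mu <- domain_mu(dm, i, j)
  if (mu == 0) {
    if (k > 0) {
      warning("zero expectation with positive count: p = 0", call. = FALSE)
      return(0)
    }
    return(1)
  }
  stats::ppois(k - 1, lambda = mu, lower.tail = FALSE)
}

#' Negative-binomial enrichment p-value for one domain pair
#'
#' Same margin-product expectation as the Poisson test but with variance
#' `mu + phi * mu^2`; `phi` is the dispersion fitted from the whole domain
#' matrix by [fit_dispersion()]. `phi <= 0` degenerates to the Poisson
#' test.
#'
#' @inheritParams hypergeom_pvalue
#' @param dispersion dispersion `phi` (>= 0).
#' @return one-sided p-value.
#' @export
nbinom_pvalue <- function(dm, i, j, dispersion) {
  stopifnot(i < j)
  if (!is.finite(dispersion) || dispersion <= 0) {
    return(poisson_pvalue(dm, i, j))
  }
  k <- dm$M[i, j]
  mu <- domain_mu(dm, i, j)
  if (mu == 0) {
    if (k > 0) {
      warning("zero expectation with positive count: p = 0", call. = FALSE)
      return(0)
    }
    return(1)
  }
  stats::pnbinom(k - 1, size = 1 / dispersion, mu = mu, lower.tail = FALSE)
}

#' Method-of-moments dispersion of a domain matrix
#'
#' Estimates the common negative-binomial dispersion over all off-diagonal
#' pairs: `phi = max(0, sum((k_ij - mu_ij)^2 - mu_ij) / sum(mu_ij^2))` with
#' `mu_ij` the margin-product expectation. Requires at least 10 pairs.
#'
#' @param dm a [aggregate_domains()] result.
#' @return dispersion estimate `phi >= 0`.
#' @export
fit_dispersion <- function(dm) {
  n <- nrow(dm$M)
  pairs <- which(upper.tri(dm$M), arr.ind = TRUE)
  if (nrow(pairs) < 10L) {
    stop("fewer than 10 off-diagonal pairs: use the Poisson test",
         call. = FALSE)
  }
  k <- dm$M[pairs]
  mu <- dm$K[pairs[, 1L]] * dm$K[pairs[, 2L]] / (2 * dm$total)
  max(0, sum((k - mu)^2 - mu) / sum(mu^2))
}

#' Call significant domain-domain interactions
#'
#' Aggregates the bin map over the supplied domains, scores every `i < j`
#' pair under the chosen count null, Benjamini-Hochberg-corrects over all
#' tested pairs of the chromosome, and returns pairs with `q <= alpha`. The
#' intra-domain diagonal is part of the marginals but never tested (TAD
#' interiors are enriched by definition). Pairs closer than
#' `min_separation` (in domain index) can be excluded since near-diagonal
#' distance decay inflates adjacent pairs.
#'
#' @param map a [hic_map()].
#' @param domains domain data.frame.
#' @param test `"hypergeometric"`, `"poisson"` or `"nbinom"`.
#' @param alpha q-value threshold (default 0.01).
#' @param min_separation smallest `j - i` tested (default 1: adjacent pairs
#'   are tested).
#' @return object of classes `domain_call_set`/`data.frame`: all tested
#'   pairs with `i`, `j`, coordinates, `count`, `expected`, `p`, `q`,
#'   `significant`; attributes `test`, `alpha`, `dispersion`,
#'   `domain_matrix`.
#' @export
call_domain_interactions <- function(map, domains,
                                     test = c("hypergeometric", "poisson",
                                              "nbinom"),
                                     alpha = 0.01, min_separation = 1L) {
  if (is.character(test) && length(test) == 1L &&
      !test %in% c("hypergeometric", "poisson", "nbinom")) {
    stop(sprintf("unknown test '%s' (use hypergeometric, poisson or nbinom)",
                 test), call. = FALSE)
  }
  test <- match.arg(test)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]",
                                       call. = FALSE)
  dm <- aggregate_domains(map, domains)
  phi <- if (test == "nbinom") fit_dispersion(dm) else NA_real_
  pairs <- which(upper.tri(dm$M), arr.ind = TRUE)
  sep_ok <- (pairs[, 2L] - pairs[, 1L]) >= min_separation
  pairs <- pairs[sep_ok, , drop = FALSE]
  p <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    switch(test,
           hypergeometric = hypergeom_pvalue(dm, i, j),
           poisson = poisson_pvalue(dm, i, j),
           nbinom = nbinom_pvalue(dm, i, j, phi))
  }, numeric(1))
  q <- bh_fdr(p)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  df <- data.frame(
    i = i, j = j,
    chrom = dm$domains$chrom[i],
    start_i = dm$domains$start[i], end_i = dm$domains$end[i],
    start_j = dm$domains$start[j], end_j = dm$domains$end[j],
    count = dm$M[cbind(i, j)],
    expected = dm$K[i] * dm$K[j] / (2 * dm$total),
    p = p, q = q, significant = q <= alpha,
    stringsAsFactors = FALSE)
  structure(df, test = test, alpha = alpha, dispersion = phi,
            domain_matrix = dm,
            class = c("domain_call_set", "data.frame"))
}

#' Write domain-pair p- and q-value tables
#'
#' Emits the two tab-separated text files of the domains pipeline (one for
#' p-values, one for q-values; rows `chrom, start_i, end_i, start_j, end_j,
#' value`) and optionally a significant-pairs file at the call threshold.
#'
#' @param calls a [call_domain_interactions()] result.
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix (default the test name).
#' @return character vector of files written, invisibly.
#' @export
write_domain_calls <- function(calls, outdir, prefix = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(prefix)) prefix <- attr(calls, "test")
  write_one <- function(value, path) {
    lines <- c(paste(c("chrom", "start_i", "end_i", "start_j", "end_j",
                       "value"), collapse = "\t"),
               paste(calls$chrom, fmt_num(calls$start_i),
                     fmt_num(calls$end_i), fmt_num(calls$start_j),
                     fmt_num(calls$end_j), fmt_num(value), sep = "\t"))
    writeLines(lines, path)
    path
  }
  p_path <- file.path(outdir, sprintf("%s_pvalues.txt", prefix))
  q_path <- file.path(outdir, sprintf("%s_qvalues.txt", prefix))
  write_one(calls$p, p_path)
  write_one(calls$q, q_path)
  sig <- calls[calls$significant, , drop = FALSE]
  s_path <- file.path(outdir, sprintf("%s_significant.txt", prefix))
  lines <- c(paste(c("chrom", "start_i", "end_i", "start_j", "end_j",
                     "count", "expected", "p", "q"), collapse = "\t"),
             if (nrow(sig) > 0L)
               paste(sig$chrom, fmt_num(sig$start_i), fmt_num(sig$end_i),
                     fmt_num(sig$start_j), fmt_num(sig$end_j),
                     fmt_num(sig$count), fmt_num(sig$expected),
                     fmt_num(sig$p), fmt_num(sig$q), sep = "\t"))
  writeLines(lines, s_path)
  invisible(c(p_path, q_path, s_path))
}
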