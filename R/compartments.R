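#' Per-bin first principal component of a contact map
#'
#' The standard compartment recipe: divide each map entry by the mean of its
#' diagonal (observed/expected transform), take the Pearson correlation
#' matrix of the result over non-empty bins, and extract its first
#' principal component. Bins with an empty (all-zero) row receive `NA`.
#' Because an eigenvector's sign is arbitrary, the vector is oriented so
#' that its correlation with bin coverage (row sums of the raw map) is
#' positive; positive PC1 then tags the open, contact-rich class.
#'
#' @param map a [hic_map()].
#' @return numeric vector of length `n_bins` with the oriented PC1 (NA for
#'   empty bins).
#' @export
compartment_pc1 <- function(map) {
  stopifnot(inherits(map, "hic_map"))
  M <- map$matrix
  n <- nrow(M)
  nonempty <- which(rowSums(M) > 0)
  if (length(nonempty) < 10L) {
    stop("need at least 10 non-empty bins for PCA", call. = FALSE)
  }
  A <- M[nonempty, nonempty, drop = FALSE]
  m <- nrow(A)
  # observed / expected: divide by the mean of each |i-j| diagonal
  d_idx <- abs(row(A) - col(A))
  exp_d <- vapply(0:(m - 1L), function(d) mean(A[d_idx == d]), numeric(1))
  denom <- exp_d[d_idx + 1L]
  OE <- A
  OE[denom > 0] <- A[denom > 0] / denom[denom > 0]
  OE[denom == 0] <- 0
  sds <- apply(OE, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate map: observed/expected matrix has constant columns, correlation undefined",
         call. = FALSE)
  }
  C <- stats::cor(OE)
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  cov <- rowSums(M)[nonempty]
  if (stats::sd(cov) > 0) {
    cov_cor <- stats::cor(v, cov)
    if (is.finite(cov_cor) && cov_cor < 0) v <- -v
  }
  out <- rep(NA_real_, n)
  out[nonempty] <- v
  out
}

#' Classify domains into compartments by PC1 majority vote
#'
#' Each domain is labelled `positive` or `negative` according to the
#' majority sign of the PC1 values of its bins; bins with missing PC1
#' abstain. Ties are broken to the sign of the summed PC1 over the domain
#' and flagged. Domains whose bins are all missing are left unclassified.
#'
#' @param pc1 per-bin PC1 vector from [compartment_pc1()].
#' @param domains domain data.frame with `bin_start`, `bin_end`.
#' @return object of classes `compartment_assignment`/`data.frame` with
#'   columns `label` (`"positive"`, `"negative"` or `NA`), `n_pos`,
#'   `n_neg`, `tie`.
#' @export
classify_domains <- function(pc1, domains) {
  rows <- lapply(seq_len(nrow(domains)), function(i) {
    b <- (domains$bin_start[i]:domains$bin_end[i]) + 1L
    b <- b[b >= 1L & b <= length(pc1)]
    v <- pc1[b]
    v <- v[!is.na(v)]
    n_pos <- sum(v > 0)
    n_neg <- sum(v < 0)
    if (length(v) == 0L) {
      return(data.frame(label = NA_character_, n_pos = 0L, n_neg = 0L,
                        tie = FALSE, stringsAsFactors = FALSE))
    }
    tie <- n_pos == n_neg
    label <- if (n_pos > n_neg) "positive"
             else if (n_neg > n_pos) "negative"
             else if (sum(v) >= 0) "positive" else "negative"
    data.frame(label = label, n_pos = n_pos, n_neg = n_neg, tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- cbind(domains[, c("chrom", "start", "end", "bin_start", "bin_end"),
                       drop = FALSE],
               do.call(rbind, rows))
  if (any(out$tie)) {
    message(sprintf("%d domain(s) with tied PC1 votes broken by summed PC1",
                    sum(out$tie)))
  }
  rownames(out) <- NULL
  structure(out, class = c("compartment_assignment", "data.frame"))
}

#' Same-compartment preference among significant domain pairs
#'
#' Tests whether significantly interacting domain pairs prefer partners of
#' their own compartment. With `p` positive and `n` negative classified
#' domains, unordered pairs are expected in proportions
#' `p^2 : n^2 : 2 p n` for (++, --, +-) categories (normalized). Reports a
#' chi-square goodness-of-fit over the three categories (2 df) and a
#' one-sided exact binomial test for depletion of mixed (+-) pairs below
#' their expected share.
#'
#' @param calls a [call_domain_interactions()] result (its significant
#'   pairs are used).
#' @param assignment a [classify_domains()] result for the same domains.
#' @return list with `observed` (named counts), `expected_prop`,
#'   `expected`, `chisq_stat`, `chisq_df`, `chisq_p`, `binom_p`
#'   (depletion of `+-`), `n_pairs`, `n_pos_domains`, `n_neg_domains`.
#' @export
compartment_enrichment <- function(calls, assignment) {
  lab <- assignment$label
  n_pos <- sum(lab == "positive", na.rm = TRUE)
  n_neg <- sum(lab == "negative", na.rm = TRUE)
  if (n_pos + n_neg < 2L) {
    stop("fewer than 2 classified domains", call. = FALSE)
  }
  sig <- calls[calls$significant, , drop = FALSE]
  li <- lab[sig$i]
  lj <- lab[sig$j]
  keep <- !is.na(li) & !is.na(lj)
  li <- li[keep]; lj <- lj[keep]
  if (length(li) < 1L) stop("no significant pair with classified domains",
                            call. = FALSE)
  cat3 <- ifelse(li == lj, ifelse(li == "positive", "pp", "nn"), "pn")
  observed <- c(pp = sum(cat3 == "pp"), nn = sum(cat3 == "nn"),
                pn = sum(cat3 == "pn"))
  w <- c(pp = n_pos^2, nn = n_neg^2, pn = 2 * n_pos * n_neg)
  expected_prop <- w / sum(w)
  n_pairs <- sum(observed)
  expected <- expected_prop * n_pairs
  nz <- expected > 0
  chisq_stat <- sum((observed[nz] - expected[nz])^2 / expected[nz])
  chisq_df <- 2L
  chisq_p <- stats::pchisq(chisq_stat, df = chisq_df, lower.tail = FALSE)
  binom_p <- stats::pbinom(observed[["pn"]], size = n_pairs,
                           prob = expected_prop[["pn"]])
  list(observed = observed, expected_prop = expected_prop,
       expected = expected, chisq_stat = chisq_stat, chisq_df = chisq_df,
       chisq_p = chisq_p, binom_p = binom_p, n_pairs = n_pairs,
       n_pos_domains = n_pos, n_neg_domains = n_neg)
}

#' Write a compartment enrichment report
#'
#' Tab-separated key-value block mirroring the list returned by
#' [compartment_enrichment()].
#'
#' @param report a [compartment_enrichment()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_compartment_report <- function(report, path) {
  kv <- c(
    sprintf("n_pos_domains\t%d", report$n_pos_domains),
    sprintf("n_neg_domains\t%d", report$n_neg_domains),
    sprintf("n_pairs\t%d", report$n_pairs),
    sprintf("observed_pp\t%d", report$observed[["pp"]]),
    sprintf("observed_nn\t%d", report$observed[["nn"]]),
    sprintf("observed_pn\t%d", report$observed[["pn"]]),
    sprintf("expected_pp\t%s", fmt_num(report$expected[["pp"]])),
    sprintf("expected_nn\t%s", fmt_num(report$expected[["nn"]])),
    sprintf("expected_pn\t%s", fmt_num(report$expected[["pn"]])),
    sprintf("chisq_stat\t%s", fmt_num(report$chisq_stat)),
    sprintf("chisq_df\t%d", report$chisq_df),
    sprintf("chisq_p\t%s", fmt_num(report$chisq_p)),
    sprintf("binom_depletion_p\t%s", fmt_num(report$binom_p)))
  writeLines(kv, path)
  invisible(path)
}
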