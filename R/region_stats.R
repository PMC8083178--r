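#' Extract a horizontal interaction profile around an anchor
#'
#' Because a cis contact map is symmetric, the interaction profile of a
#' region sitting on the diagonal is read off horizontally: the contact
#' intensity at signed bin offset `delta` is the matrix entry between the
#' anchor bin and the bin `delta` positions away. For multi-bin (2-3 bin)
#' anchors the constituent bin rows are averaged element-wise; left offsets
#' count from the anchor's first bin and right offsets from its last bin, so
#' the window never overlaps the anchor itself. Offsets that fall outside
#' the map are `NA` (missing), not zero.
#'
#' @param map a [hic_map()].
#' @param anchor one row of a region data.frame (needs `bin_start`,
#'   `bin_end`, `name`).
#' @param window_bins window half-width D in bins (default 30).
#' @return object of class `interaction_profile`: a list with `anchor_name`,
#'   `bin_start`, `bin_end`, `delta` (offsets -D..-1, 1..D), `partner_bin`,
#'   `intensity`, and empty `p`, `q` slots.
#' @export
extract_profile <- function(map, anchor, window_bins = 30L) {
  stopifnot(inherits(map, "hic_map"))
  D <- as.integer(window_bins)
  if (D < 1L) stop("window_bins must be >= 1", call. = FALSE)
  b0 <- as.integer(anchor$bin_start)
  b1 <- as.integer(anchor$bin_end)
  n <- map$n_bins
  if (b0 < 0L || b1 >= n || b0 > b1) {
    stop(sprintf("anchor '%s' bins [%d,%d] outside map with %d bins",
                 anchor$name, b0, b1, n), call. = FALSE)
  }
  rows <- map$matrix[(b0:b1) + 1L, , drop = FALSE]
  mean_row <- colMeans(rows)
  delta <- c(-D:-1L, 1L:D)
  partner <- ifelse(delta < 0L, b0 + delta, b1 + delta)
  intensity <- rep(NA_real_, length(delta))
  ok <- partner >= 0L & partner < n
  intensity[ok] <- mean_row[partner[ok] + 1L]
  structure(
    list(anchor_name = anchor$name, bin_start = b0, bin_end = b1,
         window_bins = D, delta = delta, partner_bin = as.integer(partner),
         intensity = intensity, p = rep(NA_real_, length(delta)),
         q = rep(NA_real_, length(delta))),
    class = "interaction_profile")
}

# Two-parameter Weibull maximum likelihood on strictly positive samples.
# The shape k solves sum(x^k log x)/sum(x^k) - 1/k - mean(log x) = 0
# (profile likelihood); the scale is then lambda = mean(x^k)^(1/k).
# Falls back to method of moments if the root search fails.
fit_weibull <- function(x, max_iter = 200L, tol = 1e-8) {
  x <- x[x > 0]
  n <- length(x)
  if (n < 2L || stats::var(x) == 0) {
    return(list(shape = NA_real_, scale = NA_real_, converged = FALSE))
  }
  lx <- log(x)
  mlx <- mean(lx)
  g <- function(k) {
    xk <- x^k
    sum(xk * lx) / sum(xk) - 1 / k - mlx
  }
  k_hat <- tryCatch({
    r <- stats::uniroot(g, interval = c(1e-2, 50), extendInt = "upX",
                        tol = tol, maxiter = max_iter)
    r$root
  }, error = function(e) NA_real_)
  if (!is.finite(k_hat)) {
    # method-of-moments fallback: match the coefficient of variation
    cv2 <- stats::var(x) / mean(x)^2
    h <- function(k) gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1 - cv2
    k_hat <- tryCatch(stats::uniroot(h, c(0.05, 50), tol = tol,
                                     maxiter = max_iter)$root,
                      error = function(e) NA_real_)
    if (!is.finite(k_hat)) {
      return(list(shape = NA_real_, scale = NA_real_, converged = FALSE))
    }
  }
  lambda_hat <- mean(x^k_hat)^(1 / k_hat)
  list(shape = k_hat, scale = lambda_hat, converged = TRUE)
}

#' Fit the distance-matched Weibull background of a map
#'
#' For every bin distance `d` in `1..window_bins` a two-parameter Weibull is
#' fitted by maximum likelihood to the strictly positive entries of diagonal
#' `d`. Structural zeros are excluded from the fit and their fraction `z_d`
#' is recorded; it re-enters the p-value as a point mass (see
#' [profile_pvalues()]). Distances with fewer than `min_samples` positive
#' entries, or with a degenerate (zero-variance) diagonal, are flagged
#' unusable and yield missing p-values rather than extrapolated ones.
#'
#' @param map a [hic_map()].
#' @param window_bins largest distance to fit (default 30).
#' @param min_samples minimum positive entries per diagonal (default 50).
#' @return object of class `weibull_background`: data.frame with columns
#'   `d`, `shape`, `scale`, `n`, `n_pos`, `zero_frac`, `usable`.
#' @export
fit_background <- function(map, window_bins = 30L, min_samples = 50L) {
  stopifnot(inherits(map, "hic_map"))
  D <- min(as.integer(window_bins), map$n_bins - 1L)
  n <- map$n_bins
  rows <- lapply(seq_len(D), function(d) {
    idx <- seq_len(n - d)
    vals <- map$matrix[cbind(idx, idx + d)]
    pos <- vals[vals > 0]
    z <- 1 - length(pos) / length(vals)
    if (length(pos) < min_samples) {
      return(data.frame(d = d, shape = NA_real_, scale = NA_real_,
                        n = length(vals), n_pos = length(pos),
                        zero_frac = z, usable = FALSE))
    }
    fit <- fit_weibull(pos)
    data.frame(d = d, shape = fit$shape, scale = fit$scale,
               n = length(vals), n_pos = length(pos), zero_frac = z,
               usable = isTRUE(fit$converged))
  })
  bg <- do.call(rbind, rows)
  class(bg) <- c("weibull_background", "data.frame")
  bg
}

#' Upper-tail p-values for an interaction profile
#'
#' Under the zero-inflated Weibull background of distance `d` the
#' probability of seeing an intensity at least as large as `x > 0` is
#' `(1 - z_d) * exp(-(x / lambda_d)^k_d)`; an intensity of zero is never an
#' enrichment, so its p-value is 1. Distances whose background is unusable
#' get missing p-values.
#'
#' @param profile an [extract_profile()] result.
#' @param background a [fit_background()] result.
#' @return the profile with its `p` slot filled.
#' @export
profile_pvalues <- function(profile, background) {
  stopifnot(inherits(profile, "interaction_profile"))
  if (any(profile$intensity < 0, na.rm = TRUE)) {
    stop("negative intensity in profile", call. = FALSE)
  }
  d_abs <- abs(profile$delta)
  idx <- match(d_abs, background$d)
  p <- rep(NA_real_, length(d_abs))
  for (i in seq_along(d_abs)) {
    j <- idx[i]
    x <- profile$intensity[i]
    if (is.na(j) || is.na(x) || !background$usable[j]) next
    p[i] <- weibull_tail_p(x, background$shape[j], background$scale[j],
                           background$zero_frac[j])
  }
  profile$p <- p
  profile
}

# P(X >= x) under the zero-inflated Weibull null; x = 0 is not an
# enrichment so p = 1 there.
weibull_tail_p <- function(x, shape, scale, zero_frac = 0) {
  ifelse(x <= 0, 1, (1 - zero_frac) * exp(-(x / scale)^shape))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1 and
#' mapped back to the input order. Missing entries are excluded from the
#' number of tests `m` and stay missing. Sorting is stable, so tied
#' p-values receive equal q-values and the result is invariant to input
#' permutation.
#'
#' @param p vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(q)
  o <- order(p[ok])
  ps <- p[ok][o]
  # multiply by the ratio (>= 1, and exactly 1 at j = m) rather than
  # computing (p * m) / j, whose double rounding can dip below p
  qs <- rev(cummin(rev(ps * (m / seq_len(m)))))
  qs <- pmin(qs, 1)
  q[ok[o]] <- qs
  q
}

#' Call significant region interactions across replicates
#'
#' Runs the full region pipeline: per replicate map, fit the distance-matched
#' Weibull background, score every (anchor, offset) cell of every anchor's
#' profile, then Benjamini-Hochberg-correct all tests of that replicate
#' jointly (one FDR family per chromosome per replicate). A contact is
#' called significant only when its q-value is at or below `alpha` in every
#' replicate.
#'
#' @param maps a [hic_map()] or list of replicate maps (same shape).
#' @param anchors region data.frame from [read_regions_bed()] or
#'   [read_enhancer_fasta()].
#' @param window_bins profile half-width D (default 30).
#' @param alpha q-value threshold (default 0.01).
#' @param min_samples minimum positive entries per fitted diagonal.
#' @return a [call_set()] of significant calls, with attributes `p_mat` /
#'   `q_mat` (tests x replicates, for the called rows), `n_tests` and
#'   `profiles` (per-replicate scored profiles of the first replicate).
#' @export
call_interactions <- function(maps, anchors, window_bins = 30L, alpha = 0.01,
                              min_samples = 50L) {
  if (inherits(maps, "hic_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L, all(vapply(maps, inherits, TRUE, "hic_map")))
  shapes <- vapply(maps, function(m) m$n_bins, 1L)
  if (length(unique(shapes)) != 1L ||
      length(unique(vapply(maps, function(m) m$resolution, 1L))) != 1L) {
    stop("replicate maps must share shape and resolution", call. = FALSE)
  }
  if (!(alpha >= 0 && alpha < 1)) {
    stop("alpha must lie in [0, 1)", call. = FALSE)
  }
  if (nrow(anchors) == 0L) stop("no anchors supplied", call. = FALSE)
  map1 <- maps[[1]]
  n_rep <- length(maps)
  p_list <- vector("list", n_rep)
  q_list <- vector("list", n_rep)
  key <- NULL
  for (r in seq_len(n_rep)) {
    bg <- fit_background(maps[[r]], window_bins = window_bins,
                         min_samples = min_samples)
    profs <- lapply(seq_len(nrow(anchors)), function(a) {
      profile_pvalues(extract_profile(maps[[r]], anchors[a, ], window_bins),
                      bg)
    })
    p_all <- unlist(lapply(profs, `[[`, "p"))
    q_all <- bh_fdr(p_all)
    p_list[[r]] <- p_all
    q_list[[r]] <- q_all
    if (r == 1L) {
      key <- do.call(rbind, lapply(seq_along(profs), function(a) {
        pr <- profs[[a]]
        data.frame(anchor_idx = a, anchor_name = pr$anchor_name,
                   anchor_bin = pr$bin_start, partner_bin = pr$partner_bin,
                   intensity = pr$intensity, stringsAsFactors = FALSE)
      }))
    }
  }
  p_mat <- do.call(cbind, p_list)
  q_mat <- do.call(cbind, q_list)
  sig <- rowSums(q_mat <= alpha) == n_rep
  sig[is.na(sig)] <- FALSE
  df <- key[sig, , drop = FALSE]
  df$p <- do.call(pmax, as.data.frame(p_mat))[sig]
  df$q <- do.call(pmax, as.data.frame(q_mat))[sig]
  bp <- bin_to_bp(df$partner_bin, map1$resolution)
  df$partner_start <- bp[, "start"]
  df$partner_end <- bp[, "end"]
  out <- call_set(df[, c("anchor_name", "anchor_bin", "partner_bin",
                         "partner_start", "partner_end", "p", "q")],
                  chromosome = map1$chromosome,
                  resolution = map1$resolution, alpha = alpha)
  attr(out, "p_mat") <- p_mat[sig, , drop = FALSE]
  attr(out, "q_mat") <- q_mat[sig, , drop = FALSE]
  attr(out, "n_tests") <- sum(!is.na(p_mat[, 1L]))
  out
}

#' Cluster consecutive calls of one anchor
#'
#' Called partner bins of the same anchor frequently form stretches of
#' adjacent bins reflecting one underlying contact. Maximal runs of
#' consecutive partner bins per anchor are merged into clusters carrying the
#' partner-bin span, the run length and the best (smallest) q-value.
#'
#' @param calls a [call_set()].
#' @return data.frame with columns `anchor_name`, `anchor_bin`,
#'   `partner_bin_start`, `partner_bin_end`, `size`, `min_q`.
#' @export
cluster_consecutive <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(anchor_name = character(), anchor_bin = integer(),
                      partner_bin_start = integer(),
                      partner_bin_end = integer(), size = integer(),
                      min_q = numeric(), stringsAsFactors = FALSE))
  }
  df <- as.data.frame(calls)
  df <- df[order(df$anchor_name, df$anchor_bin, df$partner_bin), ,
           drop = FALSE]
  grp <- interaction(df$anchor_name, df$anchor_bin, drop = TRUE)
  out <- lapply(split(df, grp), function(g) {
    pb <- g$partner_bin
    run <- cumsum(c(1L, diff(pb) != 1L))
    do.call(rbind, lapply(split(seq_along(pb), run), function(i) {
      data.frame(anchor_name = g$anchor_name[1L],
                 anchor_bin = g$anchor_bin[1L],
                 partner_bin_start = pb[i[1L]],
                 partner_bin_end = pb[i[length(i)]],
                 size = length(i), min_q = min(g$q[i]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$anchor_name, out$anchor_bin, out$partner_bin_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
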