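#' Intersect two call lists with a bin tolerance
#'
#' Compares (anchor bin, partner bin) call lists from different tools.
#' Calls `x` from list `a` and `y` from list `b` are candidate matches when
#' both `|anchor_x - anchor_y| <= tol` and `|partner_x - partner_y| <= tol`.
#' Matching is greedy one-to-one in order of increasing total bin distance
#' (ties broken by the lower partner bin), so a single call cannot absorb
#' several matches and inflate the overlap. Lists are deduplicated first.
#'
#' @param a,b data.frames with columns `anchor_bin`, `partner_bin` (a
#'   `tool` attribute or column is carried along if present).
#' @param tol tolerance in bins (0 = exact).
#' @return list with `matched` (data.frame of matched index pairs and
#'   distances), `n_matched`, `n_a_only`, `n_b_only`, `n_a`, `n_b`.
#' @export
tolerant_intersection <- function(a, b, tol = 0L) {
  stopifnot(tol >= 0)
  dedup <- function(d) {
    d <- d[, c("anchor_bin", "partner_bin"), drop = FALSE]
    d <- unique(d)
    d <- d[order(d$anchor_bin, d$partner_bin), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  a <- dedup(a); b <- dedup(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) {
    return(list(matched = data.frame(a_idx = integer(), b_idx = integer(),
                                     dist = integer()),
                n_matched = 0L, n_a_only = na, n_b_only = nb,
                n_a = na, n_b = nb))
  }
  cand <- do.call(rbind, lapply(seq_len(na), function(i) {
    da <- abs(a$anchor_bin[i] - b$anchor_bin)
    dp <- abs(a$partner_bin[i] - b$partner_bin)
    j <- which(da <= tol & dp <= tol)
    if (length(j) == 0L) return(NULL)
    data.frame(a_idx = i, b_idx = j, dist = da[j] + dp[j],
               partner_b = b$partner_bin[j])
  }))
  matched <- data.frame(a_idx = integer(), b_idx = integer(),
                        dist = integer())
  if (!is.null(cand) && nrow(cand) > 0L) {
    cand <- cand[order(cand$dist, cand$partner_b, cand$a_idx,
                       cand$b_idx), , drop = FALSE]
    used_a <- logical(na); used_b <- logical(nb)
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      ia <- cand$a_idx[r]; ib <- cand$b_idx[r]
      if (!used_a[ia] && !used_b[ib]) {
        keep[r] <- TRUE
        used_a[ia] <- TRUE
        used_b[ib] <- TRUE
      }
    }
    matched <- cand[keep, c("a_idx", "b_idx", "dist"), drop = FALSE]
    rownames(matched) <- NULL
  }
  list(matched = matched, n_matched = nrow(matched),
       n_a_only = na - nrow(matched), n_b_only = nb - nrow(matched),
       n_a = na, n_b = nb)
}

#' Binomial significance of a call-set overlap
#'
#' Scores `n_common` shared calls between two tools as the upper tail of
#' `Binomial(n_a, n_b / universe)`: the chance of seeing at least
#' `n_common` of tool a's calls land on tool b's calls if b's calls were
#' scattered over the universe of testable pairs.
#'
#' @param n_common shared calls.
#' @param n_a,n_b calls of each tool.
#' @param universe number of testable (anchor, partner) pairs; must be
#'   supplied explicitly.
#' @return one-sided p-value.
#' @export
overlap_significance <- function(n_common, n_a, n_b, universe) {
  if (universe <= 0) stop("universe must be positive", call. = FALSE)
  if (n_common > min(n_a, n_b)) {
    stop("n_common exceeds a list size", call. = FALSE)
  }
  if (n_b > universe || n_a > universe) {
    stop("universe smaller than a call list", call. = FALSE)
  }
  stats::pbinom(n_common - 1, size = n_a, prob = n_b / universe,
                lower.tail = FALSE)
}

#' ChIP-seq peak enrichment of called partner bins
#'
#' Asks whether the partner bins of significant calls overlap peaks (CTCF,
#' RAD21, ...) more often than the bins queried in the run. The background
#' rate is the fraction of all queried bins whose bp interval intersects at
#' least one peak; the test is a one-sided binomial on the number of
#' distinct called partner bins overlapping a peak. A depletion note is set
#' when the called rate falls below background.
#'
#' @param calls a [call_set()].
#' @param peaks data.frame of peak intervals with `start`, `end` (bp,
#'   0-based half-open), e.g. from [read_regions_bed()] without the span
#'   cap, or any BED reader.
#' @param queried_bins integer vector of all bins tested in the run (the
#'   background universe).
#' @param resolution bin size in bp (defaults to the call set's).
#' @return list with `n_called`, `n_called_in_peak`, `background_rate`,
#'   `called_rate`, `p`, `depleted`.
#' @export
peak_enrichment <- function(calls, peaks, queried_bins, resolution = NULL) {
  if (is.null(resolution)) resolution <- attr(calls, "resolution")
  if (is.null(peaks) || nrow(peaks) == 0L) {
    stop("empty peak set", call. = FALSE)
  }
  queried_bins <- sort(unique(as.integer(queried_bins)))
  if (length(queried_bins) == 0L) stop("no queried bins", call. = FALSE)
  peak_ir <- IRanges::IRanges(start = as.integer(peaks$start) + 1L,
                              end = as.integer(peaks$end))
  bin_overlaps <- function(bins) {
    if (length(bins) == 0L) return(logical(0))
    ir <- IRanges::IRanges(start = bins * resolution + 1L,
                           end = (bins + 1L) * resolution)
    IRanges::overlapsAny(ir, peak_ir)
  }
  bg_rate <- mean(bin_overlaps(queried_bins))
  called_bins <- sort(unique(calls$partner_bin))
  n_called <- length(called_bins)
  n_in_peak <- sum(bin_overlaps(called_bins))
  p <- if (n_called == 0L) 1 else {
    stats::pbinom(n_in_peak - 1, size = n_called, prob = bg_rate,
                  lower.tail = FALSE)
  }
  called_rate <- if (n_called == 0L) NA_real_ else n_in_peak / n_called
  list(n_called = n_called, n_called_in_peak = n_in_peak,
       background_rate = bg_rate, called_rate = called_rate, p = p,
       depleted = isTRUE(called_rate < bg_rate))
}

#' Read third-party calls from the adapter TSV format
#'
#' Plain five-column format for comparing against other loop callers:
#' `chrom, anchor_start, anchor_end, partner_start, partner_end` (bp,
#' 0-based half-open, tab-separated, optional header). Bins are assigned by
#' the interval start.
#'
#' @param path adapter TSV file.
#' @param resolution bin size in bp.
#' @return data.frame with `anchor_bin`, `partner_bin` columns (plus the bp
#'   coordinates).
#' @export
read_adapter_calls <- function(path, resolution) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|chrom\t)", lines)]
  f <- strsplit(lines, "[ \t]+")
  df <- data.frame(
    chrom = vapply(f, `[`, "", 1L),
    anchor_start = as.numeric(vapply(f, `[`, "", 2L)),
    anchor_end = as.numeric(vapply(f, `[`, "", 3L)),
    partner_start = as.numeric(vapply(f, `[`, "", 4L)),
    partner_end = as.numeric(vapply(f, `[`, "", 5L)),
    stringsAsFactors = FALSE)
  df$anchor_bin <- bp_to_bin(df$anchor_start, resolution)
  df$partner_bin <- bp_to_bin(df$partner_start, resolution)
  df
}
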