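#' Specify a synthetic cis Hi-C map
#'
#' The generator draws the upper triangle from the same family the region
#' statistics assume: the entry at bin distance `d` is Weibull with shape
#' `shape` and scale `lambda0 * d^-gamma` times the fold product of every
#' planted signal covering the cell, then zeroed with probability
#' `zero_frac(d)`. The lower triangle mirrors the upper one, so generated
#' maps always satisfy the map invariants. Planted signals (ground truth)
#' are loops (single pixels), domains (on-diagonal blocks), domain-pair
#' blocks (off-diagonal rectangles) and compartments (same-label cells).
#' A `lognormal` noise family is available to probe model misspecification.
#'
#' @param n_bins number of bins.
#' @param seed mandatory integer seed.
#' @param shape Weibull shape `k` (default 1.5, a right-skewed,
#'   heavier-than-exponential decay typical of contact counts).
#' @param lambda0 scale at distance 1 (default 100 contacts).
#' @param gamma distance-decay exponent (default 1, broadly Hi-C-like).
#' @param zero_frac structural-zero probability: a scalar or a function of
#'   distance (default 0).
#' @param loops list of `list(bin_a, bin_b, fold)` planted pixels.
#' @param domains list of `list(bins = from:to, fold)` on-diagonal blocks.
#' @param domain_blocks list of `list(bins_i, bins_j, fold)` off-diagonal
#'   blocks.
#' @param compartments optional `list(labels = <per-bin labels>, fold)`;
#'   cells whose bins share a label get the fold.
#' @param family `"weibull"` (default) or `"lognormal"` (same mean and a
#'   matched coefficient of variation).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins, seed, shape = 1.5, lambda0 = 100,
                           gamma = 1, zero_frac = 0, loops = list(),
                           domains = list(), domain_blocks = list(),
                           compartments = NULL,
                           family = c("weibull", "lognormal")) {
  family <- match.arg(family)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_bins >= 2L, shape > 0, lambda0 > 0)
  zf <- if (is.function(zero_frac)) zero_frac else function(d) {
    rep(zero_frac, length(d))
  }
  check_bins <- function(b) {
    if (any(b < 0L | b >= n_bins)) {
      stop("planted coordinates outside map", call. = FALSE)
    }
  }
  for (lp in loops) {
    check_bins(c(lp$bin_a, lp$bin_b))
    stopifnot(lp$fold > 0)
  }
  for (dm in domains) { check_bins(dm$bins); stopifnot(dm$fold > 0) }
  for (db in domain_blocks) {
    check_bins(c(db$bins_i, db$bins_j)); stopifnot(db$fold > 0)
  }
  if (!is.null(compartments)) {
    stopifnot(length(compartments$labels) == n_bins,
              compartments$fold > 0)
  }
  structure(list(n_bins = as.integer(n_bins), seed = as.integer(seed),
                 shape = shape, lambda0 = lambda0, gamma = gamma,
                 zero_frac = zf, loops = loops, domains = domains,
                 domain_blocks = domain_blocks, compartments = compartments,
                 family = family),
            class = "synthetic_spec")
}

#' Generate a synthetic map with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @param resolution bin size in bp attached to the map (default 10000).
#' @param chromosome chromosome label (default `"chrS"`).
#' @return list with `map` (a [hic_map()]) and `truth`, a list recording
#'   every planted coordinate (`loops`, `domains`, `domain_blocks`,
#'   `compartment_labels`).
#' @export
generate_map <- function(spec, resolution = 10000L, chromosome = "chrS") {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_bins
  set.seed(spec$seed)
  # fold multiplier per upper-triangle cell
  fold <- matrix(1, n, n)
  for (lp in spec$loops) {
    i <- min(lp$bin_a, lp$bin_b) + 1L
    j <- max(lp$bin_a, lp$bin_b) + 1L
    fold[i, j] <- fold[i, j] * lp$fold
  }
  for (dmn in spec$domains) {
    b <- dmn$bins + 1L
    fold[b, b] <- fold[b, b] * dmn$fold
  }
  for (db in spec$domain_blocks) {
    bi <- db$bins_i + 1L
    bj <- db$bins_j + 1L
    fold[bi, bj] <- fold[bi, bj] * db$fold
    fold[bj, bi] <- fold[bj, bi] * db$fold
  }
  if (!is.null(spec$compartments)) {
    lab <- spec$compartments$labels
    same <- outer(lab, lab, `==`)
    fold[same] <- fold[same] * spec$compartments$fold
  }
  M <- matrix(0, n, n)
  for (d in 0:(n - 1L)) {
    idx <- seq_len(n - d)
    cells <- cbind(idx, idx + d)
    lam <- spec$lambda0 * max(d, 1L)^(-spec$gamma) * fold[cells]
    m <- length(idx)
    vals <- if (spec$family == "weibull") {
      stats::rweibull(m, shape = spec$shape, scale = lam)
    } else {
      # lognormal with the Weibull's mean and coefficient of variation
      mu_w <- lam * gamma(1 + 1 / spec$shape)
      cv2 <- gamma(1 + 2 / spec$shape) / gamma(1 + 1 / spec$shape)^2 - 1
      sdlog <- sqrt(log(1 + cv2))
      stats::rlnorm(m, meanlog = log(mu_w) - sdlog^2 / 2, sdlog = sdlog)
    }
    z <- spec$zero_frac(d)
    if (any(z > 0)) {
      vals[stats::runif(m) < z] <- 0
    }
    M[cells] <- vals
    M[cells[, c(2L, 1L), drop = FALSE]] <- vals
  }
  truth <- list(
    loops = spec$loops,
    domains = spec$domains,
    domain_blocks = spec$domain_blocks,
    compartment_labels = if (is.null(spec$compartments)) NULL
                         else spec$compartments$labels)
  list(map = hic_map(M, resolution = resolution, chromosome = chromosome),
       truth = truth)
}

#' Write the standard synthetic fixture scenarios
#'
#' Produces a small self-contained test-bed from fixed seeds: a null map
#' (pure decay), two replicate maps sharing planted loops, and a map with a
#' boosted domain-pair block on top of a two-compartment checkerboard,
#' together with the matching anchors BED, domain-border table and a peaks
#' BED covering the planted loop partners. All outputs are plain text, so
#' reruns are byte-identical.
#'
#' @param outdir writable output directory (created if needed).
#' @param n_bins map size (default 100).
#' @param resolution bin size in bp (default 10000).
#' @param seed base seed (default 421); scenario seeds are derived from it.
#' @return named character vector of the files written.
#' @export
generate_fixtures <- function(outdir, n_bins = 100L, resolution = 10000L,
                              seed = 421L) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, mode = 2L) != 0L) {
    stop(sprintf("cannot write to %s", outdir), call. = FALSE)
  }
  anchor_bin <- n_bins %/% 2L
  loop_partners <- c(anchor_bin + 10L, anchor_bin - 15L)
  # fixture loops are smoke-test strength (50x), not a power benchmark
  loops <- lapply(loop_partners, function(pb) {
    list(bin_a = anchor_bin, bin_b = pb, fold = 50)
  })
  null_map <- generate_map(synthetic_spec(n_bins, seed = seed),
                           resolution = resolution)$map
  rep1 <- generate_map(synthetic_spec(n_bins, seed = seed + 1L,
                                      loops = loops),
                       resolution = resolution)$map
  rep2 <- generate_map(synthetic_spec(n_bins, seed = seed + 2L,
                                      loops = loops),
                       resolution = resolution)$map
  # compartments as an 8-domain checkerboard plus one boosted domain pair
  dom_w <- n_bins %/% 8L
  dom_start <- (0:7) * dom_w
  labels <- rep(rep(c("A", "B"), 4L), each = dom_w)
  labels <- c(labels, rep("B", n_bins - length(labels)))
  block <- generate_map(synthetic_spec(
    n_bins, seed = seed + 3L,
    compartments = list(labels = labels, fold = 2),
    domain_blocks = list(list(bins_i = dom_start[1]:(dom_start[1] + dom_w - 1L),
                              bins_j = dom_start[5]:(dom_start[5] + dom_w - 1L),
                              fold = 10))),
    resolution = resolution)$map
  files <- c(
    null_map = file.path(outdir, "null_map.tsv"),
    loops_rep1 = file.path(outdir, "loops_rep1.tsv"),
    loops_rep2 = file.path(outdir, "loops_rep2.tsv"),
    block_map = file.path(outdir, "block_map.tsv"),
    regions = file.path(outdir, "regions.bed"),
    domains = file.path(outdir, "domains.tsv"),
    peaks = file.path(outdir, "peaks.bed"))
  save_hic_map(null_map, files[["null_map"]])
  save_hic_map(rep1, files[["loops_rep1"]])
  save_hic_map(rep2, files[["loops_rep2"]])
  save_hic_map(block, files[["block_map"]])
  writeLines(sprintf("chrS\t%d\t%d\tanchor_mid",
                     anchor_bin * resolution,
                     (anchor_bin + 1L) * resolution),
             files[["regions"]])
  writeLines(sprintf("chrS\t%d\t%d\t0", dom_start * resolution,
                     (dom_start + dom_w) * resolution),
             files[["domains"]])
  writeLines(sprintf("chrS\t%d\t%d\tpeak_%d",
                     loop_partners * resolution + 100L,
                     loop_partners * resolution + 600L,
                     seq_along(loop_partners)),
             files[["peaks"]])
  files
}
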