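#' Read anchor regions from a BED file
#'
#' Regions of interest must span 1-3 bins at the map resolution; wider
#' intervals are skipped with a warning so that anchors stay point-like.
#' BED coordinates are 0-based half-open; the inclusive bin range of a region
#' is `floor(start/res) .. floor((end-1)/res)`.
#'
#' @param path BED3+ file (tab- or space-separated).
#' @param resolution bin size in bp.
#' @param max_span_bins maximum allowed anchor width in bins (default 3).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `bin_start`, `bin_end` (0-based, inclusive).
#' @export
read_regions_bed <- function(path, resolution, max_span_bins = 3L) {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(empty_regions())
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(f) < 3L) {
      stop(sprintf("cannot parse BED line %d: fewer than 3 fields", i),
           call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("cannot parse BED line %d: non-numeric coordinates", i),
           call. = FALSE)
    }
    if (start >= end) {
      stop(sprintf("cannot parse BED line %d: start >= end", i),
           call. = FALSE)
    }
    name <- if (length(f) >= 4L) f[4] else sprintf("region_%d", i)
    data.frame(chrom = f[1], start = start, end = end, name = name,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  annotate_region_bins(df, resolution, max_span_bins)
}

empty_regions <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), bin_start = integer(), bin_end = integer(),
             stringsAsFactors = FALSE)
}

annotate_region_bins <- function(df, resolution, max_span_bins = 3L) {
  df$bin_start <- bp_to_bin(df$start, resolution)
  df$bin_end <- bp_to_bin(df$end - 1, resolution)
  span <- df$bin_end - df$bin_start + 1L
  wide <- span > max_span_bins
  if (any(wide)) {
    warning(sprintf("%d region(s) spanning > %d bins skipped: %s",
                    sum(wide), max_span_bins,
                    paste(utils::head(df$name[wide], 5L), collapse = ", ")),
            call. = FALSE)
    df <- df[!wide, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read anchor regions from an enhancer FASTA file
#'
#' Parses coordinates from FASTA headers of the EnhancerAtlas dialect: the
#' first `chrN:start-end` token found anywhere in a header line becomes the
#' region; sequences are ignored. Headers without parseable coordinates are
#' skipped with a warning.
#'
#' @inheritParams read_regions_bed
#' @return data.frame in the same layout as [read_regions_bed()].
#' @export
read_enhancer_fasta <- function(path, resolution, max_span_bins = 3L) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  headers <- lines[startsWith(lines, ">")]
  if (length(headers) == 0L) return(empty_regions())
  pat <- "(chr[0-9A-Za-z]+):([0-9]+)-([0-9]+)"
  m <- regmatches(headers, regexpr(pat, headers))
  has <- grepl(pat, headers)
  if (any(!has)) {
    warning(sprintf("%d FASTA header(s) without chrN:start-end coordinates skipped",
                    sum(!has)), call. = FALSE)
  }
  if (!any(has)) return(empty_regions())
  tok <- regmatches(headers[has], regexec(pat, headers[has]))
  df <- do.call(rbind, lapply(tok, function(t) {
    data.frame(chrom = t[2], start = as.numeric(t[3]), end = as.numeric(t[4]),
               stringsAsFactors = FALSE)
  }))
  df$name <- sprintf("%s:%g-%g", df$chrom, df$start, df$end)
  bad <- df$start >= df$end
  if (any(bad)) {
    warning(sprintf("%d header(s) with start >= end skipped", sum(bad)),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  annotate_region_bins(df, resolution, max_span_bins)
}

#' Read domain (TAD) borders
#'
#' Accepts a BED-like tab-separated table: `chrom`, `start`, `end` and an
#' optional fourth column with the hierarchy level assigned by a hierarchical
#' TAD caller. When a level column is present only rows at the requested
#' level are returned; files without a level column return all rows. Within
#' the returned level, domains must be non-overlapping; they are sorted by
#' start.
#'
#' @param path domain-border file.
#' @param resolution bin size in bp.
#' @param level requested hierarchy level (default 0).
#' @param units `"bp"` (default) or `"bins"` when the file stores bin
#'   indices rather than base pairs.
#' @return data.frame with columns `chrom`, `start`, `end`, `level`,
#'   `bin_start`, `bin_end` (0-based inclusive bin range).
#' @export
read_domains <- function(path, resolution, level = 0L, units = c("bp", "bins")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("domain file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = paste0("V", 1:10), fill = TRUE)[, 1:4]
  if (is.numeric(df$V1) || suppressWarnings(!any(is.na(as.numeric(df$V1))))) {
    # headerless two/three-column numeric dialect: no chrom column
    df <- data.frame(V1 = "chr1", V2 = as.numeric(df$V1),
                     V3 = as.numeric(df$V2), V4 = df$V3,
                     stringsAsFactors = FALSE)
  }
  has_level <- !all(is.na(suppressWarnings(as.numeric(df$V4)))) &&
    !all(is.na(df$V4))
  lev <- if (has_level) as.integer(df$V4) else rep(as.integer(level),
                                                   nrow(df))
  out <- data.frame(chrom = df$V1, start = as.numeric(df$V2),
                    end = as.numeric(df$V3), level = lev,
                    stringsAsFactors = FALSE)
  out <- out[out$level == as.integer(level), , drop = FALSE]
  if (any(out$start >= out$end)) {
    stop("domain with start >= end", call. = FALSE)
  }
  if (units == "bins") {
    out$bin_start <- as.integer(out$start)
    out$bin_end <- as.integer(out$end) - 1L
    out$start <- out$bin_start * resolution
    out$end <- (out$bin_end + 1L) * resolution
  } else {
    out$bin_start <- bp_to_bin(out$start, resolution)
    out$bin_end <- bp_to_bin(out$end - 1, resolution)
  }
  out <- out[order(out$start), , drop = FALSE]
  if (nrow(out) > 1L) {
    ov <- which(out$start[-1L] < out$end[-nrow(out)])
    if (length(ov) > 0L) {
      stop(sprintf("overlapping domains at level %d: rows %s",
                   level, paste(ov, collapse = ", ")), call. = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}
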