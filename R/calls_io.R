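#' Construct a call set
#'
#' A `call_set` is a data.frame of significant (anchor, partner) contacts on
#' one chromosome with their p- and q-values, plus metadata (chromosome,
#' resolution, significance threshold). When several replicate maps were
#' analysed, `p` and `q` are the worst (largest) value across replicates —
#' the value that had to clear the threshold under the all-replicates rule —
#' and per-replicate matrices are kept in attributes `p_mat` / `q_mat`.
#'
#' @param calls data.frame with columns `anchor_name`, `anchor_bin`,
#'   `partner_bin`, `partner_start`, `partner_end`, `p`, `q`.
#' @param chromosome chromosome label.
#' @param resolution bin size in bp.
#' @param alpha q-value threshold the calls were made at.
#' @return object of classes `call_set` and `data.frame`.
#' @export
call_set <- function(calls, chromosome, resolution, alpha = 0.01) {
  need <- c("anchor_name", "anchor_bin", "partner_bin",
            "partner_start", "partner_end", "p", "q")
  miss <- setdiff(need, names(calls))
  if (length(miss) > 0L) {
    stop(sprintf("call_set missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  calls <- calls[order(calls$anchor_name, calls$anchor_bin,
                       calls$partner_bin), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls,
            chromosome = as.character(chromosome),
            resolution = as.integer(resolution),
            alpha = alpha,
            class = c("call_set", "data.frame"))
}

calls_meta <- function(calls) {
  list(chromosome = attr(calls, "chromosome"),
       resolution = attr(calls, "resolution"),
       alpha = attr(calls, "alpha"))
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write calls to disk
#'
#' Three output dialects are supported, all tab-separated UTF-8 with LF
#' endings and a deterministic row order (anchor, then partner bin):
#' \describe{
#'   \item{txt}{`anchor_name, anchor_bin, partner_bin, partner_start,
#'     partner_end, p, q`.}
#'   \item{bed}{BED6+3: partner interval, `name` = anchor name, `score` =
#'     `-log10(q)` capped at 1000, strand `.`, then `anchor_bin`, `p`, `q`
#'     so the record stays lossless.}
#'   \item{gff}{GFF3-flavoured, feature type `contact`, 1-based inclusive
#'     coordinates; attributes carry anchor, anchor_bin, p and q.}
#' }
#'
#' @param calls a [call_set()].
#' @param path output file.
#' @param format one of `"txt"`, `"bed"`, `"gff"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, format = c("txt", "bed", "gff")) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("txt", "bed", "gff")) {
    stop(sprintf("unknown output format '%s' (use txt, bed or gff)", format),
         call. = FALSE)
  }
  format <- match.arg(format)
  meta <- calls_meta(calls)
  chrom <- meta$chromosome
  lines <- switch(format,
    txt = c(paste(c("anchor_name", "anchor_bin", "partner_bin",
                    "partner_start", "partner_end", "p", "q"),
                  collapse = "\t"),
            if (nrow(calls) > 0L)
              paste(calls$anchor_name, calls$anchor_bin, calls$partner_bin,
                    fmt_num(calls$partner_start), fmt_num(calls$partner_end),
                    fmt_num(calls$p), fmt_num(calls$q), sep = "\t")),
    bed = c(sprintf("track name=contacts description=\"significant contacts %s\"",
                    chrom),
            if (nrow(calls) > 0L)
              paste(chrom, fmt_num(calls$partner_start),
                    fmt_num(calls$partner_end), calls$anchor_name,
                    fmt_num(pmin(-log10(calls$q), 1000)), ".",
                    calls$anchor_bin, fmt_num(calls$p), fmt_num(calls$q),
                    sep = "\t")),
    gff = c("##gff-version 3",
            if (nrow(calls) > 0L)
              paste(chrom, "hicsig", "contact",
                    fmt_num(calls$partner_start + 1),
                    fmt_num(calls$partner_end), ".", ".", ".",
                    sprintf("anchor=%s;anchor_bin=%d;partner_bin=%d;p=%s;q=%s",
                            calls$anchor_name, calls$anchor_bin,
                            calls$partner_bin, fmt_num(calls$p),
                            fmt_num(calls$q)),
                    sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read calls written by [write_calls()]
#'
#' @param path file produced by [write_calls()].
#' @param format dialect of the file.
#' @param resolution bin size in bp (needed to rebuild bin indices for the
#'   `bed` and `gff` dialects).
#' @param alpha threshold recorded in the returned object.
#' @return a [call_set()].
#' @export
read_calls <- function(path, format = c("txt", "bed", "gff"), resolution,
                       alpha = 0.01) {
  format <- match.arg(format)
  lines <- readLines(path)
  empty <- function(chrom) {
    call_set(data.frame(anchor_name = character(), anchor_bin = integer(),
                        partner_bin = integer(), partner_start = numeric(),
                        partner_end = numeric(), p = numeric(),
                        q = numeric(), stringsAsFactors = FALSE),
             chromosome = chrom, resolution = resolution, alpha = alpha)
  }
  if (format == "txt") {
    body <- lines[-1L]
    if (length(body) == 0L) return(empty(NA_character_))
    f <- strsplit(body, "\t", fixed = TRUE)
    df <- data.frame(
      anchor_name = vapply(f, `[`, "", 1L),
      anchor_bin = as.integer(vapply(f, `[`, "", 2L)),
      partner_bin = as.integer(vapply(f, `[`, "", 3L)),
      partner_start = as.numeric(vapply(f, `[`, "", 4L)),
      partner_end = as.numeric(vapply(f, `[`, "", 5L)),
      p = as.numeric(vapply(f, `[`, "", 6L)),
      q = as.numeric(vapply(f, `[`, "", 7L)),
      stringsAsFactors = FALSE)
    return(call_set(df, chromosome = NA_character_, resolution = resolution,
                    alpha = alpha))
  }
  if (format == "bed") {
    body <- lines[!grepl("^(track|browser|#)", lines)]
    if (length(body) == 0L) return(empty(NA_character_))
    f <- strsplit(body, "\t", fixed = TRUE)
    df <- data.frame(
      anchor_name = vapply(f, `[`, "", 4L),
      anchor_bin = as.integer(vapply(f, `[`, "", 7L)),
      partner_start = as.numeric(vapply(f, `[`, "", 2L)),
      partner_end = as.numeric(vapply(f, `[`, "", 3L)),
      p = as.numeric(vapply(f, `[`, "", 8L)),
      q = as.numeric(vapply(f, `[`, "", 9L)),
      stringsAsFactors = FALSE)
    df$partner_bin <- bp_to_bin(df$partner_start, resolution)
    chrom <- vapply(f, `[`, "", 1L)[1]
    return(call_set(df, chromosome = chrom, resolution = resolution,
                    alpha = alpha))
  }
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) return(empty(NA_character_))
  f <- strsplit(body, "\t", fixed = TRUE)
  attr_field <- vapply(f, `[`, "", 9L)
  get_attr <- function(key) {
    sub(sprintf(".*%s=([^;]*).*", key), "\\1", attr_field)
  }
  df <- data.frame(
    anchor_name = get_attr("anchor"),
    anchor_bin = as.integer(get_attr("anchor_bin")),
    partner_bin = as.integer(get_attr("partner_bin")),
    partner_start = as.numeric(vapply(f, `[`, "", 4L)) - 1,
    partner_end = as.numeric(vapply(f, `[`, "", 5L)),
    p = as.numeric(get_attr("p")),
    q = as.numeric(get_attr("q")),
    stringsAsFactors = FALSE)
  chrom <- vapply(f, `[`, "", 1L)[1]
  call_set(df, chromosome = chrom, resolution = resolution, alpha = alpha)
}

#' Remap call coordinates between genome assemblies
#'
#' Lifts the partner base-pair intervals of a call set through a UCSC chain
#' file. Calls whose interval does not map (deleted or split in the target
#' assembly) are dropped and their number reported; p- and q-values are left
#' untouched. Partner bin indices are recomputed from the lifted start.
#'
#' @param calls a [call_set()].
#' @param chain_path path to an uncompressed UCSC chain file.
#' @return a [call_set()] on the target assembly, with attribute
#'   `n_unmapped` giving the number of dropped calls.
#' @export
liftover_calls <- function(calls, chain_path) {
  if (!file.exists(chain_path)) {
    stop(sprintf("chain file not found: %s", chain_path), call. = FALSE)
  }
  meta <- calls_meta(calls)
  if (nrow(calls) == 0L) return(calls)
  chain <- rtracklayer::import.chain(chain_path)
  gr <- GenomicRanges::GRanges(
    seqnames = meta$chromosome,
    ranges = IRanges::IRanges(start = calls$partner_start + 1,
                              end = calls$partner_end))
  lifted <- rtracklayer::liftOver(gr, chain)
  n_hits <- lengths(lifted)
  mapped <- n_hits == 1L
  n_unmapped <- sum(!mapped)
  if (n_unmapped > 0L) {
    message(sprintf("liftover: %d call(s) dropped (unmapped or split)",
                    n_unmapped))
  }
  out <- calls[mapped, , drop = FALSE]
  hit <- unlist(lifted[mapped])
  out$partner_start <- GenomicRanges::start(hit) - 1
  out$partner_end <- GenomicRanges::end(hit)
  out$partner_bin <- bp_to_bin(out$partner_start, meta$resolution)
  res <- call_set(out, chromosome = meta$chromosome,
                  resolution = meta$resolution, alpha = meta$alpha)
  attr(res, "n_unmapped") <- n_unmapped
  res
}
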