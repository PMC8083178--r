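#' Construct a cis Hi-C contact map
#'
#' A `hic_map` holds one chromosome's dense symmetric contact matrix together
#' with the map resolution and chromosome label. Matrices are symmetrized as
#' `(M + t(M))/2` (with a warning when the asymmetry exceeds numerical
#' tolerance) and NaN entries are replaced by zero with a logged count, since
#' all downstream fits require finite non-negative values.
#'
#' @param matrix square numeric matrix of contact counts.
#' @param resolution bin size in base pairs (positive integer).
#' @param chromosome chromosome label, e.g. `"chr1"`.
#' @return an object of class `hic_map` with elements `matrix`, `resolution`,
#'   `chromosome`, `n_bins` and `n_nan` (count of NaN entries zeroed on load).
#' @export
hic_map <- function(matrix, resolution, chromosome = "chr1") {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(matrix) != ncol(matrix)) {
    stop(sprintf("contact matrix must be square, got %d x %d",
                 nrow(matrix), ncol(matrix)), call. = FALSE)
  }
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0 ||
      resolution != round(resolution)) {
    stop("`resolution` must be a single positive integer (bp per bin)",
         call. = FALSE)
  }
  n_nan <- sum(!is.finite(matrix))
  if (n_nan > 0L) {
    warning(sprintf("%d non-finite entries replaced by 0", n_nan),
            call. = FALSE)
    matrix[!is.finite(matrix)] <- 0
  }
  if (any(matrix < 0)) {
    stop("contact matrix has negative entries", call. = FALSE)
  }
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-9) {
    warning(sprintf("asymmetric matrix symmetrized as (M + t(M))/2 (max |M - t(M)| = %.3g)",
                    asym), call. = FALSE)
  }
  matrix <- (matrix + t(matrix)) / 2
  dimnames(matrix) <- NULL
  structure(
    list(matrix = matrix, resolution = as.integer(resolution),
         chromosome = as.character(chromosome), n_bins = nrow(matrix),
         n_nan = n_nan),
    class = "hic_map"
  )
}

#' @export
print.hic_map <- function(x, ...) {
  cat(sprintf("hic_map: %s, %d bins @ %d bp, total signal %.4g\n",
              x$chromosome, x$n_bins, x$resolution, sum(x$matrix)))
  invisible(x)
}

#' Load a dense contact map from disk
#'
#' Reads either a whitespace-delimited text matrix or a NumPy `.npy` binary
#' array (chosen by file extension). The result is validated and symmetrized
#' through [hic_map()].
#'
#' @param path path to the matrix file.
#' @param resolution bin size in bp.
#' @param chromosome chromosome label.
#' @return a [hic_map()] object.
#' @export
load_hic_map <- function(path, resolution, chromosome = "chr1") {
  if (!file.exists(path)) {
    stop(sprintf("map file not found: %s", path), call. = FALSE)
  }
  m <- if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    read_npy_matrix(path)
  } else {
    as.matrix(utils::read.table(path, header = FALSE,
                                colClasses = "numeric",
                                blank.lines.skip = TRUE))
  }
  hic_map(m, resolution = resolution, chromosome = chromosome)
}

#' Save a contact map to disk
#'
#' Writes the text dialect (tab-separated, `%.17g` so doubles round-trip
#' exactly) or the `.npy` binary dialect, chosen by the path's extension.
#'
#' @param map a [hic_map()].
#' @param path output path; `.npy` selects the binary format.
#' @return `path`, invisibly.
#' @export
save_hic_map <- function(map, path) {
  stopifnot(inherits(map, "hic_map"))
  if (grepl("\\.npy$", path, ignore.case = TRUE)) {
    write_npy_matrix(map$matrix, path)
  } else {
    lines <- apply(map$matrix, 1L, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    })
    writeLines(lines, path)
  }
  invisible(path)
}

# Minimal NumPy .npy (version 1.0) reader for 2-D little-endian arrays.
# Supports the dtypes a Hi-C map realistically ships with: f8, f4, i8, i4.
read_npy_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (!identical(magic, as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))) {
    stop("not a .npy file (bad magic)", call. = FALSE)
  }
  ver <- readBin(con, "raw", n = 2L)
  hlen <- if (as.integer(ver[1]) >= 2L) {
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
            endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  if (length(shape) != 2L) {
    stop(sprintf(".npy array must be 2-D, got shape (%s)", shape_str),
         call. = FALSE)
  }
  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n = n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "double", n = n, size = 8L, endian = "little"),
    "<i4" = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    stop(sprintf("unsupported .npy dtype: %s", descr), call. = FALSE)
  )
  if (descr == "<i8") {
    # re-read as 64-bit integers via double pairs is lossy; decode manually
    close(con)
    on.exit(NULL)
    con2 <- file(path, "rb")
    on.exit(close(con2))
    readBin(con2, "raw", n = 10L + hlen)
    lo <- readBin(con2, "integer", n = 2L * n, size = 4L, endian = "little")
    lo_u <- ifelse(lo[seq(1L, 2L * n, 2L)] < 0,
                   lo[seq(1L, 2L * n, 2L)] + 2^32,
                   lo[seq(1L, 2L * n, 2L)])
    vals <- lo_u + lo[seq(2L, 2L * n, 2L)] * 2^32
  }
  m <- matrix(as.numeric(vals), nrow = shape[1], ncol = shape[2],
              byrow = !fortran)
  m
}

# Writes a C-order float64 .npy (version 1.0), header padded to 64 bytes.
write_npy_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  unpadded <- 10L + nchar(header) + 1L
  pad <- (64L - unpadded %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(t(m)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Map base-pair coordinates to bin indices
#'
#' Bins are 0-based: bin `b` covers the half-open bp interval
#' `[b * resolution, (b + 1) * resolution)`.
#'
#' @param bp base-pair position(s), 0-based.
#' @param resolution bin size in bp.
#' @return integer bin indices.
#' @export
bp_to_bin <- function(bp, resolution) {
  as.integer(floor(bp / resolution))
}

#' @rdname bp_to_bin
#' @param bin 0-based bin index or indices.
#' @return for `bin_to_bp`, a two-column matrix of `start`, `end` bp
#'   (half-open interval of each bin).
#' @export
bin_to_bp <- function(bin, resolution) {
  cbind(start = as.numeric(bin) * resolution,
        end = (as.numeric(bin) + 1) * resolution)
}
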