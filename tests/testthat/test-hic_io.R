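test_that("map loading validates, symmetrizes and round-trips", {
  # identity round-trip of a symmetric text matrix
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(apply(m, 1, paste, collapse = "\t"), f)
  hm <- load_hic_map(f, resolution = 10000, chromosome = "chr1")
  expect_identical(hm$n_bins, 3L)
  expect_equal(hm$matrix, m)

  # asymmetric input is averaged with a warning
  ma <- m
  ma[1, 2] <- 5; ma[2, 1] <- 3
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(apply(ma, 1, paste, collapse = "\t"), f2)
  expect_warning(hm2 <- load_hic_map(f2, 10000), "symmetrized")
  expect_equal(hm2$matrix[1, 2], 4)
  expect_equal(hm2$matrix[2, 1], 4)

  # non-square input is a format error
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2\t3", "4\t5\t6"), f3)
  expect_error(load_hic_map(f3, 10000), "square")

  # NaN entries are zeroed with a count
  mn <- m; mn[1, 3] <- NaN; mn[3, 1] <- NaN
  expect_warning(hm3 <- hic_map(mn, 10000), "non-finite")
  expect_equal(hm3$n_nan, 2)
  expect_equal(hm3$matrix[1, 3], 0)

  # negative entries are a data error
  expect_error(hic_map(matrix(c(0, -1, -1, 0), 2, 2), 10000), "negative")

  # save -> load of the text dialect is bit-identical
  g <- generate_map(synthetic_spec(12, seed = 11))
  f4 <- withr::local_tempfile(fileext = ".tsv")
  save_hic_map(g$map, f4)
  re <- load_hic_map(f4, 10000)
  expect_identical(re$matrix, g$map$matrix)
  save_hic_map(re, paste0(f4, "b"))
  expect_identical(readLines(f4), readLines(paste0(f4, "b")))
})

test_that("npy dialect is value-identical and numpy-compatible", {
  g <- generate_map(synthetic_spec(9, seed = 3))
  f <- withr::local_tempfile(fileext = ".npy")
  save_hic_map(g$map, f)
  re <- load_hic_map(f, 10000)
  expect_identical(re$matrix, g$map$matrix)

  # cross-check against numpy itself (present in the runtime image)
  py <- Sys.which("python")
  expect_true(nzchar(py))
  out <- system2(py, c("-c", shQuote(sprintf(
    "import numpy as np; a = np.load('%s'); print('%%.17g' %% a.sum())", f))),
    stdout = TRUE)
  expect_equal(as.numeric(out[length(out)]), sum(g$map$matrix))
  f2 <- withr::local_tempfile(fileext = ".npy")
  system2(py, c("-c", shQuote(sprintf(
    "import numpy as np; np.save('%s', np.arange(6, dtype=float).reshape(2, 3))",
    f2))))
  expect_equal(hicsig:::read_npy_matrix(f2),
               matrix(as.numeric(0:5), 2, 3, byrow = TRUE))
})

test_that("BED regions map to bins and wide regions are skipped", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t20000\t30000\tr1",
               "chr1\t15000\t30000\tr2",
               "chr1\t0\t50000\twide"), f)
  expect_warning(r <- read_regions_bed(f, 10000), "skipped")
  expect_equal(nrow(r), 2L)
  expect_equal(r$bin_start, c(2L, 1L))
  expect_equal(r$bin_end, c(2L, 2L))

  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tok", "chr1\tfoo\t200\tbad"), f2)
  expect_error(read_regions_bed(f2, 10000), "line 2")

  # coordinate mapping consistency: any bp of a bin maps back to it
  for (b in c(0L, 7L, 31L)) {
    iv <- bin_to_bp(b, 5000)
    expect_equal(bp_to_bin(iv[, "start"], 5000), b)
    expect_equal(bp_to_bin(iv[, "end"] - 1, 5000), b)
  }
})

test_that("enhancer FASTA headers parse to regions", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1:100000-100500|gene", "ACGT",
               ">no_coords_here", "TTTT"), f)
  expect_warning(r <- read_enhancer_fasta(f, 10000), "1 FASTA header")
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 100000)
  expect_equal(r$end, 100500)
  expect_equal(r$bin_start, 10L)
  expect_equal(r$bin_end, 10L)

  fe <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), fe)
  expect_equal(nrow(read_enhancer_fasta(fe, 10000)), 0L)
})

test_that("domain files respect levels and reject overlaps", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t300000\t0", "chr1\t300000\t600000\t0",
               "chr1\t0\t600000\t1"), f)
  d0 <- read_domains(f, 150000, level = 0)
  expect_equal(nrow(d0), 2L)
  expect_equal(d0$bin_start, c(0L, 2L))
  expect_equal(d0$bin_end, c(1L, 3L))
  d1 <- read_domains(f, 150000, level = 1)
  expect_equal(nrow(d1), 1L)

  # no level column: all rows at any requested level
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t300000", "chr1\t300000\t600000"), f2)
  expect_equal(nrow(read_domains(f2, 150000, level = 0)), 2L)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t300000\t0", "chr1\t150000\t450000\t0"), f3)
  expect_error(read_domains(f3, 150000, level = 0), "overlap")
})

make_toy_calls <- function() {
  call_set(data.frame(
    anchor_name = c("a", "a", "b"), anchor_bin = c(10L, 10L, 3L),
    partner_bin = c(40L, 41L, 9L),
    partner_start = c(400000, 410000, 90000),
    partner_end = c(410000, 420000, 100000),
    p = c(1e-5, 2e-4, 3.1e-3), q = c(1e-3, 4e-3, 9e-3),
    stringsAsFactors = FALSE), chromosome = "chr1",
    resolution = 10000, alpha = 0.01)
}

test_that("call writers round-trip all three formats", {
  calls <- make_toy_calls()
  for (fmt in c("txt", "bed", "gff")) {
    f <- withr::local_tempfile()
    write_calls(calls, f, format = fmt)
    re <- read_calls(f, format = fmt, resolution = 10000)
    for (col in c("anchor_name", "anchor_bin", "partner_bin",
                  "partner_start", "partner_end", "p", "q")) {
      expect_identical(re[[col]], calls[[col]], label = paste(fmt, col))
    }
  }
  # BED score is -log10(q)
  f <- withr::local_tempfile()
  write_calls(calls, f, format = "bed")
  first <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_equal(as.numeric(first[5]), -log10(calls$q[1]))
  expect_equal(as.numeric(first[2]), 400000)

  # empty call set writes a header-only file
  empty <- calls[0, , drop = FALSE]
  attr(empty, "chromosome") <- "chr1"
  f2 <- withr::local_tempfile()
  write_calls(empty, f2, format = "txt")
  expect_length(readLines(f2), 1L)
  expect_error(write_calls(calls, withr::local_tempfile(), format = "xlsx"),
               "unknown output format")
})

write_chain <- function(path, t_start, t_end, q_start, size = 10^7) {
  writeLines(c(sprintf("chain 1000 chr1 %d + %d %d chr1 %d + %d %d 1",
                       size, t_start, t_end, size, q_start,
                       q_start + (t_end - t_start)),
               sprintf("%d", t_end - t_start), ""), path)
}

test_that("liftover remaps, shifts and drops calls", {
  calls <- make_toy_calls()
  ident <- withr::local_tempfile(fileext = ".chain")
  write_chain(ident, 0, 10^6, 0)
  out <- liftover_calls(calls, ident)
  expect_equal(out$partner_start, calls$partner_start)
  expect_equal(out$q, calls$q)

  shift <- withr::local_tempfile(fileext = ".chain")
  write_chain(shift, 0, 10^6, 1000)
  out2 <- liftover_calls(calls, shift)
  expect_equal(out2$partner_start, calls$partner_start + 1000)
  expect_equal(out2$partner_end, calls$partner_end + 1000)
  expect_equal(out2$p, calls$p)

  # chain covering only the first 100 kb: the two distal calls drop
  partial <- withr::local_tempfile(fileext = ".chain")
  write_chain(partial, 0, 10^5, 0)
  expect_message(out3 <- liftover_calls(calls, partial), "2 call")
  expect_equal(nrow(out3), 1L)
  expect_equal(attr(out3, "n_unmapped"), 2L)

  expect_error(liftover_calls(calls, "/nonexistent.chain"), "not found")
})
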