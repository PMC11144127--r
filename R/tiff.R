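# Minimal baseline TIFF codec for grayscale image stacks.
#
# The frame-stack interchange format is multi-page uncompressed grayscale
# TIFF (16-bit for video channels, 8-bit for label masks). No TIFF package
# is available in the target R environment, so the small baseline subset
# needed here is implemented directly: little-endian, one strip per page,
# no compression. Round-trip compatibility with tifffile/ImageJ-style
# readers is covered by the IO tests.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

tiff_entry <- function(tag, type, count, value) {
  con <- raw()
  buf <- rawConnection(con, "wb")
  on.exit(close(buf))
  writeBin(as.integer(c(tag, type)), buf, size = 2, endian = "little")
  writeBin(as.integer(count), buf, size = 4, endian = "little")
  if (type == TIFF_TYPE_SHORT) {
    writeBin(as.integer(c(value, 0L)), buf, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), buf, size = 4, endian = "little")
  }
  rawConnectionValue(buf)
}

#' Write a grayscale image stack as a multi-page TIFF
#'
#' Frames are written as uncompressed little-endian baseline TIFF pages,
#' one strip per page, photometric "black is zero".
#'
#' @param stack Integer array `rows x cols x frames` (a single matrix is
#'   treated as one frame). Values must fit the sample depth.
#' @param path Output file path.
#' @param bits Bits per sample: 16 (video channels) or 8 (label masks).
#' @return `path`, invisibly.
#' @seealso [read_tiff_stack()]
#' @export
write_tiff_stack <- function(stack, path, bits = 16) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  assert_that(is.array(stack) && length(dim(stack)) == 3L,
              "`stack` must be a rows x cols x frames array")
  assert_that(bits %in% c(8L, 16L), "`bits` must be 8 or 16")
  maxval <- 2^bits - 1
  assert_that(all(stack >= 0 & stack <= maxval),
              "pixel values must lie in [0, %d] for %d-bit output",
              as.integer(maxval), as.integer(bits))
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nf <- dim(stack)[3]
  bytes_pp <- bits / 8L
  page_bytes <- nr * nc * bytes_pp

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  data_start <- 8L
  first_ifd <- data_start + nf * page_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")

  # pixel data: TIFF pages are row-major, R arrays column-major
  px <- as.integer(aperm(stack, c(2L, 1L, 3L)))
  writeBin(px, con, size = bytes_pp, endian = "little")

  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  for (f in seq_len(nf)) {
    entries <- c(
      tiff_entry(256L, TIFF_TYPE_LONG, 1L, nc),
      tiff_entry(257L, TIFF_TYPE_LONG, 1L, nr),
      tiff_entry(258L, TIFF_TYPE_SHORT, 1L, bits),
      tiff_entry(259L, TIFF_TYPE_SHORT, 1L, 1L),   # no compression
      tiff_entry(262L, TIFF_TYPE_SHORT, 1L, 1L),   # BlackIsZero
      tiff_entry(273L, TIFF_TYPE_LONG, 1L, data_start + (f - 1L) * page_bytes),
      tiff_entry(277L, TIFF_TYPE_SHORT, 1L, 1L),
      tiff_entry(278L, TIFF_TYPE_LONG, 1L, nr),
      tiff_entry(279L, TIFF_TYPE_LONG, 1L, page_bytes))
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    writeBin(entries, con)
    nxt <- if (f < nf) first_ifd + f * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_uint <- function(raw, offset, size, n = 1L) {
  end <- offset + size * n - 1L
  if (end > length(raw)) stop_fp("truncated TIFF: need byte %d, file has %d",
                                 end, length(raw))
  readBin(raw[offset:end], "integer", n = n, size = size,
          signed = size == 4L, endian = "little")
}

#' Read a multi-page grayscale TIFF stack
#'
#' Reads the baseline subset produced by [write_tiff_stack()] (uncompressed
#' little-endian grayscale, 8 or 16 bits per sample, one or more strips).
#'
#' @param path TIFF file path.
#' @return Integer array `rows x cols x frames`, with attribute `bits`.
#' @export
read_tiff_stack <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  raw <- readBin(path, "raw", n = file.size(path))
  assert_that(length(raw) >= 8L, "truncated TIFF: %s", path)
  assert_that(rawToChar(raw[1:2]) == "II",
              "unsupported TIFF byte order (only little-endian 'II'): %s", path)
  assert_that(read_uint(raw, 3L, 2L) == 42L, "not a TIFF file: %s", path)

  frames <- list()
  bits_seen <- NULL
  ifd_off <- read_uint(raw, 5L, 4L)
  while (ifd_off != 0L) {
    n <- read_uint(raw, ifd_off + 1L, 2L)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2L + (i - 1L) * 12L + 1L
      tag <- read_uint(raw, e, 2L)
      type <- read_uint(raw, e + 2L, 2L)
      count <- read_uint(raw, e + 4L, 4L)
      size <- if (type == TIFF_TYPE_SHORT) 2L else 4L
      if (!type %in% c(TIFF_TYPE_SHORT, TIFF_TYPE_LONG)) next
      if (count * size <= 4L) {
        val <- read_uint(raw, e + 8L, size, count)
      } else {
        off <- read_uint(raw, e + 8L, 4L)
        val <- read_uint(raw, off + 1L, size, count)
      }
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag) {
      v <- tags[[as.character(tag)]]
      assert_that(!is.null(v), "TIFF page missing required tag %d: %s",
                  tag, path)
      v
    }
    wd <- need(256L); ht <- need(257L)
    bits <- tags[["258"]] %||% 1L
    comp <- tags[["259"]] %||% 1L
    assert_that(comp == 1L, "unsupported TIFF compression %d: %s", comp, path)
    assert_that(bits %in% c(8L, 16L),
                "unsupported bits per sample %d: %s", bits, path)
    assert_that((tags[["277"]] %||% 1L) == 1L,
                "only single-sample grayscale TIFF supported: %s", path)
    offs <- need(273L); counts <- need(279L)
    bpp <- bits / 8L
    px <- integer(0)
    for (s in seq_along(offs)) {
      px <- c(px, read_uint_samples(raw, offs[s], counts[s], bpp, path))
    }
    assert_that(length(px) == wd * ht,
                "TIFF page pixel count mismatch (%d vs %d): %s",
                length(px), wd * ht, path)
    frames[[length(frames) + 1L]] <- matrix(px, nrow = ht, ncol = wd,
                                            byrow = TRUE)
    bits_seen <- c(bits_seen, bits)
    ifd_off <- read_uint(raw, ifd_off + 2L + n * 12L + 1L, 4L)
  }
  assert_that(length(frames) > 0L, "TIFF contains no pages: %s", path)
  dims <- vapply(frames, dim, integer(2))
  assert_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "TIFF pages have differing dimensions: %s", path)
  out <- array(unlist(frames), c(dims[1, 1], dims[2, 1], length(frames)))
  attr(out, "bits") <- bits_seen[1]
  out
}

read_uint_samples <- function(raw, offset, nbytes, bpp, path) {
  end <- offset + nbytes
  assert_that(end <= length(raw), "truncated TIFF strip at byte %d: %s",
              end, path)
  readBin(raw[(offset + 1L):end], "integer", n = nbytes / bpp, size = bpp,
          signed = FALSE, endian = "little")
}
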