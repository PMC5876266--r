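# Reformatted-image output: DICOM (1-HU precision, rescale tags), 16-bit PNG
# (HU + 1024 as unsigned 16-bit, lossless for integer HU), and windowed 8-bit
# PNG. The 16-bit PNG encoder is written here because png::writePNG only
# emits 8-bit; reads go through png::readPNG, an independent decoder.

png_crc_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    cc <- n
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(cc, 1L)) else bitwShiftR(cc, 1L)
    tab[n + 1] <- cc
  }
  tab
})

png_crc32 <- function(bytes) {
  cc <- -1L
  for (b in as.integer(bytes))
    cc <- bitwXor(png_crc_table[bitwAnd(bitwXor(cc, b), 255L) + 1L],
                  bitwShiftR(cc, 8L))
  bitwXor(cc, -1L)
}

int_be <- function(x, nbytes = 4) {
  x <- as.numeric(x)
  as.raw((x %/% 256^((nbytes - 1):0)) %% 256)
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_be(length(data)), body, int_be(bitwAnd2_unsigned(png_crc32(body))))
}

# map signed 32-bit CRC onto the unsigned value for big-endian serialisation
bitwAnd2_unsigned <- function(x) if (x < 0) x + 2^32 else x

write_png16 <- function(gray, path) {
  # gray: integer matrix in [0, 65535]; rows become PNG scanlines
  h <- nrow(gray); w <- ncol(gray)
  v <- as.integer(t(gray)) # scanline order: row 1 left-to-right, then row 2...
  if (any(v < 0 | v > 65535)) stop("png16 sample out of range")
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  sl <- matrix(raw(2 * w * h), nrow = 2 * w)
  sl[seq(1, 2 * w, by = 2), ] <- matrix(hi, nrow = w)
  sl[seq(2, 2 * w, by = 2), ] <- matrix(lo, nrow = w)
  scan <- rbind(raw(h), sl) # prepend filter byte 0 per scanline
  idat <- memCompress(as.raw(scan), "gzip") # R emits a zlib stream
  ihdr <- c(int_be(w), int_be(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

image_pixels <- function(img) {
  if (inherits(img, "reformat_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("`img` must be a reformat_image or an HU matrix")
}

#' Write a reformatted image
#'
#' `dicom` and `png16` store attenuation losslessly at 1-HU precision
#' (`png16` as HU + 1024 unsigned 16-bit; `dicom` as unsigned 16-bit with
#' rescale intercept -1024). `png8` applies a linear window and requires
#' `window`.
#'
#' @param img a `reformat_image` (see [render_cpr]) or an HU matrix with
#'   rows = slices.
#' @param path output file.
#' @param format one of `"dicom"`, `"png16"`, `"png8"`.
#' @param window length-2 numeric `c(center, width)` in HU; mandatory for
#'   `png8`, ignored otherwise.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = c("dicom", "png16", "png8"),
                        window = NULL) {
  format <- match.arg(format)
  px <- image_pixels(img)
  rs <- if (inherits(img, "reformat_image")) img$row_spacing else 1
  cs <- if (inherits(img, "reformat_image")) img$col_spacing else 1
  if (format == "dicom") {
    dcm_write_file(t(px), path, spacing = c(cs, rs, 1),
                   position = c(0, 0, 0), series_uid = dcm_uid(), instance = 1)
  } else if (format == "png16") {
    stored <- round(px) + 1024
    if (any(stored < 0 | stored > 65535)) stop("attenuation outside storable range")
    write_png16(stored, path)
  } else {
    if (is.null(window) || length(window) != 2)
      stop("png8 requires `window = c(center, width)` in HU")
    lo <- window[1] - window[2] / 2
    g <- round(255 * (px - lo) / window[2])
    g[g < 0] <- 0; g[g > 255] <- 255
    png::writePNG(g / 255, path)
  }
  invisible(path)
}

#' Read back a written image
#'
#' Inverse of [write_image] for `dicom` and `png16` (returns HU); for `png8`
#' returns the windowed 8-bit gray levels (0-255), which are not invertible.
#'
#' @param path file written by [write_image].
#' @param format one of `"dicom"`, `"png16"`, `"png8"`.
#' @return numeric matrix, rows = slices.
#' @export
read_image <- function(path, format = c("dicom", "png16", "png8")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dicom") {
    tags <- dcm_read_file(path)
    t(dcm_slice_matrix(tags, path))
  } else {
    g <- png::readPNG(path)
    if (length(dim(g)) == 3) g <- g[, , 1]
    if (format == "png16") round(g * 65535) - 1024 else round(g * 255)
  }
}
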