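# Minimal DICOM codec: uncompressed explicit-VR little-endian only.
# Covers exactly what the package writes (CT-style secondary capture slices
# with rescale tags) plus series read with slope/intercept applied. Other
# transfer syntaxes, sequences and oblique orientations are rejected.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_uid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0("2.25.", format(as.integer(Sys.time()) %% 1e9, scientific = FALSE),
           ".", Sys.getpid() %% 1e5, ".", counter)
  }
})

uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_le <- function(x) {
  # writeBin has no unsigned 32-bit; values here stay far below 2^31
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

dcm_element <- function(group, element, vr, value) {
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH", "DA", "TM", "PN")) {
    v <- charToRaw(as.character(value))
    if (length(v) %% 2 == 1)
      v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  } else if (vr == "US") {
    v <- uint16_le(value)
  } else if (vr %in% c("OW", "OB")) {
    v <- value # already raw
  } else stop("unsupported VR: ", vr)
  head <- c(uint16_le(group), uint16_le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), uint32_le(length(v)), v)
  } else {
    if (length(v) > 65534) stop("value too long for short-form VR")
    c(head, uint16_le(length(v)), v)
  }
}

dcm_ds <- function(...) paste(formatC(c(...), format = "fg", digits = 10), collapse = "\\")

# Write one slice / one 2-D image. `pixels` is an nx x ny HU matrix (x fastest,
# matching DICOM row-major with Columns = nx, Rows = ny). Stored as uint16
# with RescaleIntercept -1024, i.e. 1-HU precision.
dcm_write_file <- function(pixels, file, spacing, position,
                           series_uid, instance, extra = list()) {
  stored <- round(pixels) + 1024
  if (any(stored < 0) || any(stored > 65535))
    stop("attenuation out of the storable range")
  nx <- nrow(pixels); ny <- ncol(pixels)
  sop_uid <- dcm_uid()
  meta <- c(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002L, 0x0002L, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dcm_element(0x0002L, 0x0003L, "UI", sop_uid),
    dcm_element(0x0002L, 0x0010L, "UI", DCM_EXPLICIT_LE)
  )
  # group length element written by hand (UL, 4 bytes)
  meta_len <- c(uint16_le(0x0002L), uint16_le(0x0000L), charToRaw("UL"),
                uint16_le(4L), uint32_le(length(meta)))
  pix <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
  ds <- c(
    dcm_element(0x0008L, 0x0016L, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dcm_element(0x0008L, 0x0018L, "UI", sop_uid),
    dcm_element(0x0008L, 0x0060L, "CS", "OT"),
    dcm_element(0x0018L, 0x0050L, "DS", dcm_ds(spacing[3])),
    dcm_element(0x0018L, 0x0088L, "DS", dcm_ds(spacing[3])),
    dcm_element(0x0020L, 0x000EL, "UI", series_uid),
    dcm_element(0x0020L, 0x0013L, "IS", as.character(instance)),
    dcm_element(0x0020L, 0x0032L, "DS", dcm_ds(position)),
    dcm_element(0x0020L, 0x0037L, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028L, 0x0002L, "US", 1L),
    dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dcm_element(0x0028L, 0x0010L, "US", ny),  # Rows
    dcm_element(0x0028L, 0x0011L, "US", nx),  # Columns
    dcm_element(0x0028L, 0x0030L, "DS", dcm_ds(spacing[2], spacing[1])),
    dcm_element(0x0028L, 0x0100L, "US", 16L),
    dcm_element(0x0028L, 0x0101L, "US", 16L),
    dcm_element(0x0028L, 0x0102L, "US", 15L),
    dcm_element(0x0028L, 0x0103L, "US", 0L),
    dcm_element(0x0028L, 0x1052L, "DS", dcm_ds(-1024)),
    dcm_element(0x0028L, 0x1053L, "DS", dcm_ds(1)),
    dcm_element(0x7FE0L, 0x0010L, "OW", pix)
  )
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta_len, con)
  writeBin(meta, con)
  writeBin(ds, con)
  invisible(file)
}

dcm_read_file <- function(file) {
  raw <- readBin(file, "raw", n = file.info(file)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", file)
  pos <- 133L
  tags <- list()
  ts <- NULL
  rd16 <- function(at) readBin(raw[at:(at + 1)], "integer", size = 2,
                               endian = "little", signed = FALSE)
  rd32 <- function(at) readBin(raw[at:(at + 3)], "integer", size = 4,
                               endian = "little")
  n <- length(raw)
  while (pos + 7 <= n) {
    group <- rd16(pos); element <- rd16(pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or unsupported encoding in ", file)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- rd32(pos + 8)
      if (len < 0) stop("undefined-length element not supported in ", file)
      vstart <- pos + 12
    } else {
      len <- rd16(pos + 6)
      vstart <- pos + 8
    }
    value <- if (len > 0) raw[vstart:(vstart + len - 1)] else raw(0)
    key <- sprintf("%04X%04X", group, element)
    tags[[key]] <- list(vr = vr, value = value)
    if (key == "00020010") ts <- dcm_trim(value)
    pos <- vstart + len
  }
  if (!is.null(ts) && ts != DCM_EXPLICIT_LE)
    stop("unsupported transfer syntax ", ts, " in ", file)
  tags
}

dcm_trim <- function(value) {
  while (length(value) && value[length(value)] == as.raw(0))
    value <- value[-length(value)]
  sub(" +$", "", rawToChar(value))
}

dcm_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  dcm_trim(t$value)
}
dcm_num <- function(tags, key) {
  s <- dcm_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$value, "integer", size = 2, endian = "little", signed = FALSE)
}

dcm_slice_matrix <- function(tags, file) {
  ncol_ <- dcm_us(tags, "00280011"); nrow_ <- dcm_us(tags, "00280010")
  pr <- dcm_us(tags, "00280103"); if (is.null(pr)) pr <- 0L
  pix <- tags[["7FE00010"]]
  if (is.null(pix)) stop("no pixel data in ", file)
  vals <- readBin(pix$value, "integer", n = ncol_ * nrow_, size = 2,
                  endian = "little", signed = pr == 1L)
  slope <- dcm_num(tags, "00281053"); if (is.null(slope)) slope <- 1
  inter <- dcm_num(tags, "00281052"); if (is.null(inter)) inter <- 0
  matrix(vals * slope + inter, nrow = ncol_, ncol = nrow_) # x fastest
}

write_dicom_series <- function(vol, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  series_uid <- dcm_uid()
  nz <- dim(vol$voxels)[3]
  zs <- slice_z(vol)
  for (k in seq_len(nz)) {
    dcm_write_file(vol$voxels[, , k],
                   file.path(dir, sprintf("slice_%04d.dcm", k)),
                   spacing = vol$spacing,
                   position = c(vol$origin[1], vol$origin[2], zs[k]),
                   series_uid = series_uid, instance = k)
  }
  invisible(dir)
}

read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no .dcm files in ", dir)
  slices <- lapply(files, dcm_read_file)
  orient <- lapply(slices, function(t) dcm_num(t, "00200037"))
  for (i in seq_along(orient)) {
    o <- orient[[i]]
    if (!is.null(o) && any(abs(o - c(1, 0, 0, 0, 1, 0)) > 1e-6))
      stop("oblique DICOM orientation not supported: ", files[i])
  }
  pos <- t(vapply(slices, function(t) dcm_num(t, "00200032"), numeric(3)))
  ord <- order(pos[, 3])
  files <- files[ord]; slices <- slices[ord]; pos <- pos[ord, , drop = FALSE]
  nz <- length(slices)
  if (nz > 1) {
    dz <- diff(pos[, 3])
    if (any(dz <= 0)) stop("duplicate slice position at ", files[which(dz <= 0)[1] + 1])
    if (diff(range(dz)) > 1e-3 * mean(dz)) {
      bad <- which.max(abs(dz - stats::median(dz)))
      stop("inconsistent slice spacing in DICOM series at ", files[bad + 1])
    }
    dz <- mean(dz)
  } else {
    dz <- dcm_num(slices[[1]], "00180050")
    if (is.null(dz)) dz <- 1
  }
  ps <- dcm_num(slices[[1]], "00280030") # (row spacing = dy, col spacing = dx)
  mats <- lapply(seq_len(nz), function(i) dcm_slice_matrix(slices[[i]], files[i]))
  vox <- array(0, c(dim(mats[[1]]), nz))
  for (k in seq_len(nz)) vox[, , k] <- mats[[k]]
  ct_volume(vox, spacing = c(ps[2], ps[1], dz),
            origin = c(pos[1, 1], pos[1, 2], pos[1, 3]))
}
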