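#' Read a CT angiography volume
#'
#' Reads a NIfTI-1 file or an uncompressed explicit-VR little-endian DICOM
#' series into a [ct_volume] in Hounsfield units. DICOM rescale
#' slope/intercept are applied on read. Only axis-aligned geometry is
#' supported; oblique orientations are rejected rather than silently
#' mis-rendered.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`.
#' @return a [ct_volume].
#' @export
read_volume <- function(path, format = c("nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!file.exists(path)) stop("file not found: ", path)
    im <- RNifti::readNifti(path)
    xf <- RNifti::xform(im)
    sp <- abs(c(xf[1, 1], xf[2, 2], xf[3, 3]))
    off <- xf[seq_len(3), 4]
    offdiag <- xf[seq_len(3), seq_len(3)]
    diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-6 * max(sp)))
      stop("oblique NIfTI orientation is not supported (non-diagonal xform)")
    if (any(sp <= 0) || any(!is.finite(sp)))
      sp <- abs(RNifti::pixdim(im))[seq_len(3)]
    arr <- array(as.numeric(im), dim = dim(im)[seq_len(3)])
    ct_volume(arr, spacing = sp, origin = off)
  } else {
    read_dicom_series(path)
  }
}

#' Write a CT angiography volume
#'
#' NIfTI output is lossless (float voxels, spacing and origin in the sform).
#' DICOM series output stores attenuation at 1-HU precision as unsigned
#' 16-bit with rescale intercept -1024.
#'
#' @param vol a [ct_volume].
#' @param path output file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("nifti", "dicom_series")) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "ct_volume"))
  if (format == "nifti") {
    im <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(im) <- vol$spacing
    m <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
    im <- RNifti::`qform<-`(im, value = structure(m, code = 2L))
    RNifti::writeNifti(im, path)
  } else {
    write_dicom_series(vol, path)
  }
  invisible(path)
}
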