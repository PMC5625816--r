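## NIfTI fixture I/O. Volumes are stored with the geometry in the sform
## (affine = orientation %*% diag(spacing) | origin), float64 data so HU and
## dose arrays round-trip exactly.

.geomToAffine <- function(geom) {
  rbind(cbind(geom@orientation %*% diag(geom@spacing), geom@origin),
        c(0, 0, 0, 1))
}

.affineToGeom <- function(aff, dims) {
  A <- aff[1:3, 1:3]
  sp <- sqrt(colSums(A^2))
  volumeGeometry(dims, spacing = sp, origin = aff[1:3, 4],
                 orientation = sweep(A, 2L, sp, `/`))
}

#' Read and write volumes as NIfTI-1 files
#'
#' The fixture format used alongside DICOM: one `.nii.gz` per volume, geometry
#' carried in the sform affine, values stored as float64 (exact round trip).
#'
#' @param x a [CtVolume-class], [DoseVolume-class] or [BinaryMask-class].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `writeVolume()` returns `path` invisibly. The readers return the
#'   corresponding volume object.
#' @export
writeVolume <- function(x, path) {
  arr <- x@voxels
  if (is.logical(arr)) arr <- array(as.double(arr), dim = dim(arr))
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- spacing(x)
  im <- RNifti::`sform<-`(im, structure(.geomToAffine(geometry(x)), code = 2L))
  RNifti::writeNifti(im, path, datatype = "double")
  invisible(path)
}

.readNiftiRaw <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3L) stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  geom <- .affineToGeom(unclass(RNifti::xform(im)), d)
  list(values = array(as.vector(im), dim = d), geom = geom)
}

#' @rdname writeVolume
#' @param path file path of a 3D NIfTI volume.
#' @param breathingPhase phase tag attached to the CT (not stored in NIfTI).
#' @export
readCtVolume <- function(path, breathingPhase = "free_breathing") {
  r <- .readNiftiRaw(path)
  ctVolume(r$values, r$geom, breathingPhase = breathingPhase)
}

#' @rdname writeVolume
#' @export
readDoseVolume <- function(path) {
  r <- .readNiftiRaw(path)
  doseVolume(r$values, r$geom)
}

#' @rdname writeVolume
#' @export
readMaskVolume <- function(path) {
  r <- .readNiftiRaw(path)
  binaryMask(r$values != 0, r$geom)
}
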