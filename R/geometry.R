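#' Geometry accessors and helpers
#'
#' `dims()`, `spacing()`, `origin()`, `orientation()` extract geometry fields;
#' `geometry()` extracts the [VolumeGeometry-class] from any volume; `voxels()`
#' extracts the value array; `voxelVolumeCc()` gives the volume of one voxel in
#' cc (spacing product / 1000).
#'
#' @param x a [VolumeGeometry-class] or any [ScalarVolume-class] object.
#' @name geometry-accessors
NULL

#' @rdname geometry-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname geometry-accessors
#' @export
setMethod("geometry", "ScalarVolume", function(x) x@geometry)
#' @rdname geometry-accessors
#' @export
setMethod("geometry", "VolumeGeometry", function(x) x)

#' @rdname geometry-accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname geometry-accessors
#' @export
setMethod("voxels", "ScalarVolume", function(x) x@voxels)

#' @rdname geometry-accessors
#' @export
setGeneric("dims", function(x) standardGeneric("dims"))
#' @rdname geometry-accessors
#' @export
setMethod("dims", "VolumeGeometry", function(x) x@dims)
#' @rdname geometry-accessors
#' @export
setMethod("dims", "ScalarVolume", function(x) x@geometry@dims)

#' @rdname geometry-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname geometry-accessors
#' @export
setMethod("spacing", "VolumeGeometry", function(x) x@spacing)
#' @rdname geometry-accessors
#' @export
setMethod("spacing", "ScalarVolume", function(x) x@geometry@spacing)

#' @rdname geometry-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname geometry-accessors
#' @export
setMethod("origin", "VolumeGeometry", function(x) x@origin)

#' @rdname geometry-accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname geometry-accessors
#' @export
setMethod("orientation", "VolumeGeometry", function(x) x@orientation)

#' @rdname geometry-accessors
#' @export
setGeneric("voxelVolumeCc", function(x) standardGeneric("voxelVolumeCc"))
#' @rdname geometry-accessors
#' @export
setMethod("voxelVolumeCc", "VolumeGeometry", function(x) prod(x@spacing) / 1000)
#' @rdname geometry-accessors
#' @export
setMethod("voxelVolumeCc", "ScalarVolume", function(x) prod(x@geometry@spacing) / 1000)

#' Physical coordinates of voxel centers
#'
#' Returns an `n x 3` matrix of patient-coordinate positions (mm) of voxel
#' centers, in column-major voxel order (first axis fastest), matching the
#' storage order of the value arrays. Indices are 0-based: the first row is
#' the position of voxel (0,0,0), i.e. the geometry origin.
#'
#' @param geom a [VolumeGeometry-class].
#' @return numeric matrix with `prod(dims(geom))` rows.
#' @export
voxelCenters <- function(geom) {
  d <- geom@dims
  idx <- cbind(
    rep.int(0:(d[1] - 1L), times = d[2] * d[3]),
    rep.int(rep(0:(d[2] - 1L), each = d[1]), times = d[3]),
    rep(0:(d[3] - 1L), each = d[1] * d[2]))
  scaled <- sweep(idx, 2L, geom@spacing, `*`)
  sweep(scaled %*% t(geom@orientation), 2L, geom@origin, `+`)
}

#' Test whether two geometries coincide
#'
#' @param a,b [VolumeGeometry-class] objects.
#' @param tol absolute tolerance in mm (and unitless for cosines).
#' @return logical.
#' @export
sameGeometry <- function(a, b, tol = 1e-6) {
  identical(a@dims, b@dims) &&
    max(abs(a@spacing - b@spacing)) <= tol &&
    max(abs(a@origin - b@origin)) <= tol &&
    max(abs(a@orientation - b@orientation)) <= tol
}

.stopIfGeometryMismatch <- function(a, b, what = "volumes") {
  if (!sameGeometry(geometry(a), geometry(b)))
    stop(sprintf("geometry mismatch: %s must share a voxel lattice", what),
         call. = FALSE)
  invisible(TRUE)
}

setMethod("show", "VolumeGeometry", function(object) {
  cat(sprintf("VolumeGeometry: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (mm): %.2f %.2f %.2f\n",
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "CtVolume", function(object) {
  cat(sprintf("CtVolume (%s): HU range [%g, %g]\n", object@breathingPhase,
              min(object@voxels), max(object@voxels)))
  show(object@geometry)
})

setMethod("show", "DoseVolume", function(object) {
  cat(sprintf("DoseVolume: max %.2f Gy, mean %.3f Gy\n",
              max(object@voxels), mean(object@voxels)))
  show(object@geometry)
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d member voxels (%.2f cc)\n",
              sum(object@voxels), sum(object@voxels) * voxelVolumeCc(object)))
  show(object@geometry)
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet: %d structure(s)\n", length(object@structures)))
  for (nm in names(object@structures))
    cat(sprintf("  %s: %d contour(s)\n", nm, length(object@structures[[nm]])))
})

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d patients (source: %s)\n",
              nrow(object@records), object@provenance))
  cat("  RP grades: ")
  print(table(factor(object@records$rp_grade, levels = 0:5)))
})

#' Extract the records of a cohort table
#' @param x a [CohortTable-class].
#' @return data.frame of clinical records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname records
#' @export
setMethod("records", "CohortTable", function(x) x@records)
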