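## Contour rasterization: planar closed polygons -> voxel mask.

## Even-odd ray-casting membership, vectorized over points. Points lying
## exactly on an edge (within tol) count as inside — a deterministic tie-break
## the DICOM standard leaves open.
.pointInPolygonEO <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xInt <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xInt))
    }
    ## on-segment test via cross product + bounding box
    dx <- x2 - x1; dy <- y2 - y1
    segLen2 <- dx * dx + dy * dy
    if (segLen2 > 0) {
      crossp <- (px - x1) * dy - (py - y1) * dx
      t <- ((px - x1) * dx + (py - y1) * dy) / segLen2
      onEdge <- onEdge | (abs(crossp) <= tol * sqrt(segLen2) & t >= -tol & t <= 1 + tol)
    } else {
      onEdge <- onEdge | (abs(px - x1) <= tol & abs(py - y1) <= tol)
    }
    j <- i
  }
  inside | onEdge
}

#' Rasterize a contoured structure onto a voxel lattice
#'
#' Converts the named structure's planar closed polygons into a
#' [BinaryMask-class] on `geom`. A voxel is a member iff its center lies inside
#' any polygon assigned to that voxel's slice, by the even-odd rule; points
#' exactly on a polygon edge count as inside. Each contour plane is assigned to
#' the nearest slice of `geom`; a plane further than half the slice spacing
#' from every slice is an error (misaligned inputs surface instead of being
#' silently shifted).
#'
#' @param ss a [StructureSet-class].
#' @param name structure name to rasterize.
#' @param geom target [VolumeGeometry-class].
#' @return a [BinaryMask-class]. A structure with zero polygons gives an empty
#'   mask.
#' @export
rasterizeStructure <- function(ss, name, geom) {
  validObject(ss)
  if (!(name %in% names(ss@structures)))
    stop(sprintf("unknown structure '%s'; available: %s", name,
                 paste(names(ss@structures), collapse = ", ")), call. = FALSE)
  d <- geom@dims
  member <- array(FALSE, dim = d)
  Rt <- t(geom@orientation)
  ## voxel centers of one slice, in continuous index coordinates (exact ints)
  pix <- rep(0:(d[1] - 1L), times = d[2])
  piy <- rep(0:(d[2] - 1L), each = d[1])
  for (poly in ss@structures[[name]]) {
    np <- length(poly$x)
    ## vertices -> continuous voxel indices
    pts <- rbind(poly$x, poly$y, rep(poly$z, np))
    idx <- sweep(Rt %*% (pts - geom@origin), 1L, geom@spacing, `/`)
    zIdx <- mean(idx[3, ])
    k <- round(zIdx)
    if (abs(zIdx - k) > 0.5 + 1e-9 || k < 0 || k > d[3] - 1L)
      stop(sprintf("contour plane z=%.3f mm of '%s' is farther than half the slice spacing from every slice",
                   poly$z, name), call. = FALSE)
    hit <- .pointInPolygonEO(pix, piy, idx[1, ], idx[2, ])
    slice <- member[, , k + 1L]
    slice[hit] <- TRUE
    member[, , k + 1L] <- slice
  }
  binaryMask(member, geom)
}
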