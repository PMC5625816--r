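#' Resample a dose grid onto a target geometry
#'
#' Trilinear interpolation of the dose at every target voxel center, in
#' physical (patient) coordinates. Target centers that fall outside the dose
#' grid's convex hull of voxel centers receive 0 Gy (no extrapolation). With
#' an identical geometry the values are returned unchanged. The analysis
#' convention is to bring the dose onto the CT grid (LAV is defined on CT
#' voxels), never the reverse.
#'
#' @param dose a [DoseVolume-class].
#' @param target a [VolumeGeometry-class].
#' @return a [DoseVolume-class] on `target`.
#' @export
resampleDose <- function(dose, target) {
  validObject(target)   # validity enforces orthonormal orientation
  src <- geometry(dose)
  if (sameGeometry(src, target)) return(dose)
  ctr <- voxelCenters(target)
  rel <- sweep(ctr, 2L, src@origin, `-`) %*% src@orientation  # R^T (p - o)
  idx <- sweep(rel, 2L, src@spacing, `/`)
  d <- src@dims
  eps <- 1e-9
  insideGrid <- idx[, 1] >= -eps & idx[, 1] <= d[1] - 1 + eps &
                idx[, 2] >= -eps & idx[, 2] <= d[2] - 1 + eps &
                idx[, 3] >= -eps & idx[, 3] <= d[3] - 1 + eps
  out <- numeric(nrow(idx))
  if (any(insideGrid)) {
    p <- idx[insideGrid, , drop = FALSE]
    p <- pmin(pmax(p, 0), matrix(d - 1L, nrow(p), 3, byrow = TRUE))
    i0 <- floor(p)
    f <- p - i0
    i1 <- pmin(i0 + 1, matrix(d - 1L, nrow(p), 3, byrow = TRUE))
    v <- dose@voxels
    at <- function(ix, iy, iz) v[1L + ix + d[1] * (iy + d[2] * iz)]
    c000 <- at(i0[, 1], i0[, 2], i0[, 3]); c100 <- at(i1[, 1], i0[, 2], i0[, 3])
    c010 <- at(i0[, 1], i1[, 2], i0[, 3]); c110 <- at(i1[, 1], i1[, 2], i0[, 3])
    c001 <- at(i0[, 1], i0[, 2], i1[, 3]); c101 <- at(i1[, 1], i0[, 2], i1[, 3])
    c011 <- at(i0[, 1], i1[, 2], i1[, 3]); c111 <- at(i1[, 1], i1[, 2], i1[, 3])
    fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
    c00 <- c000 * (1 - fx) + c100 * fx
    c10 <- c010 * (1 - fx) + c110 * fx
    c01 <- c001 * (1 - fx) + c101 * fx
    c11 <- c011 * (1 - fx) + c111 * fx
    c0 <- c00 * (1 - fy) + c10 * fy
    c1 <- c01 * (1 - fy) + c11 * fy
    out[insideGrid] <- pmax(c0 * (1 - fz) + c1 * fz, 0)
  }
  doseVolume(array(out, dim = target@dims), target)
}

#' Volume receiving at least a given dose
#'
#' Volume (cc) of mask-member voxels whose dose is `>= cutoffGy` — the
#' inclusive boundary convention of Vx ("receiving a dose >= x Gy").
#'
#' @param dose a [DoseVolume-class].
#' @param mask a [BinaryMask-class] on the same geometry.
#' @param cutoffGy dose cutoff in Gy.
#' @return volume in cc.
#' @export
volumeAbove <- function(dose, mask, cutoffGy) {
  .stopIfGeometryMismatch(dose, mask, "dose and mask")
  sum(mask@voxels & dose@voxels >= cutoffGy) * voxelVolumeCc(mask)
}

#' Mean dose over a mask
#'
#' Arithmetic mean of the dose over member voxels. Applied to the lung, LAV
#' and lung-minus-LAV masks this gives MLD, MED and MLWED. An empty mask is an
#' error (the mean is undefined, not zero).
#'
#' @param dose a [DoseVolume-class].
#' @param mask a nonempty [BinaryMask-class] on the same geometry.
#' @return mean dose in Gy.
#' @export
meanDose <- function(dose, mask) {
  .stopIfGeometryMismatch(dose, mask, "dose and mask")
  n <- sum(mask@voxels)
  if (n == 0L) stop("mean dose over an empty mask is undefined", call. = FALSE)
  sum(dose@voxels[mask@voxels]) / n
}

#' Names of the dosimetric comparison parameters
#'
#' The parameter set entering the model comparison: for each cutoff x the
#' absolute volumes `Vx`, `Vx_minus_LAVx`, `LAVx`, the percentage `Vx_pct`,
#' and the ratios `ratio_tlv_x` and `ratio_nonlav_x`; plus `LAV`,
#' `LAV_fraction`, `TLV_minus_LAV`, `MLD`, `MED`, `MLWED`. With the default
#' five cutoffs this is 36 parameters.
#'
#' @param cutoffsGy dose cutoffs in Gy.
#' @return character vector of parameter names.
#' @export
profileParameterNames <- function(cutoffsGy = c(2, 5, 10, 20, 30)) {
  x <- cutoffsGy
  c(sprintf("V%g", x), sprintf("V%g_minus_LAV%g", x, x), sprintf("LAV%g", x),
    sprintf("V%g_pct", x), sprintf("ratio_tlv_%g", x), sprintf("ratio_nonlav_%g", x),
    "LAV", "LAV_fraction", "TLV_minus_LAV", "MLD", "MED", "MLWED")
}

#' Compute the full dosimetric profile of one patient
#'
#' Partitions the lung into LAV (emphysema, by HU threshold) and non-LAV
#' compartments and computes every dose-volume parameter on that partition:
#' absolute threshold volumes (`Vx`, `Vx - LAVx`, `LAVx`, cc), percentages
#' (`Vx_pct`, 0-100), compartment ratios (`(Vx-LAVx)/TLV` and
#' `(Vx-LAVx)/(TLV-LAV)`, 0-1), compartment volumes (`TLV`, `LAV`,
#' `TLV - LAV`, cc; `LAV_fraction` 0-1) and mean doses (`MLD`, `MED`,
#' `MLWED`, Gy). If the dose grid differs from the CT grid it is first
#' resampled onto the CT geometry. `MED` is `NA` when there is no LAV;
#' `MLWED` is `NA` when LAV fills the lung. Absolute `Vx` is stored as
#' `(Vx - LAVx) + LAVx`, so the partition identity holds exactly.
#'
#' @param ct a [CtVolume-class].
#' @param dose a [DoseVolume-class] (any geometry overlapping the CT).
#' @param lung a nonempty [BinaryMask-class] on the CT geometry.
#' @param cfg a [LavConfig-class].
#' @param cutoffsGy dose cutoffs in Gy (default 2, 5, 10, 20, 30).
#' @param irradiatedOnly if `TRUE`, MED/MLWED average only voxels with
#'   dose > 0 in their compartment; default `FALSE` averages all compartment
#'   voxels, which makes the volume-weighted decomposition
#'   `MLD*TLV = MED*LAV + MLWED*(TLV-LAV)` an exact identity.
#' @return a [DosimetricProfile-class].
#' @export
dosimetricProfile <- function(ct, dose, lung, cfg = lavConfig(),
                              cutoffsGy = c(2, 5, 10, 20, 30),
                              irradiatedOnly = FALSE) {
  .stopIfGeometryMismatch(ct, lung, "CT and lung mask")
  if (!sameGeometry(geometry(dose), geometry(ct)))
    dose <- resampleDose(dose, geometry(ct))
  if (!sum(lung@voxels)) stop("empty lung mask", call. = FALSE)
  lav <- segmentLav(ct, lung, cfg)

  vv <- voxelVolumeCc(ct)
  inLung <- as.vector(lung@voxels)
  inLav <- as.vector(lav@voxels)
  dvec <- as.vector(dose@voxels)
  nLung <- sum(inLung); nLav <- sum(inLav); nNon <- nLung - nLav

  vals <- c()
  for (x in cutoffsGy) {
    above <- dvec >= x
    cLav <- sum(above & inLav)
    cNon <- sum(above & inLung & !inLav)
    vMinus <- cNon * vv; lavX <- cLav * vv
    vals[sprintf("V%g", x)] <- vMinus + lavX
    vals[sprintf("V%g_minus_LAV%g", x, x)] <- vMinus
    vals[sprintf("LAV%g", x)] <- lavX
    vals[sprintf("V%g_pct", x)] <- 100 * (cLav + cNon) / nLung
    vals[sprintf("ratio_tlv_%g", x)] <- cNon / nLung
    vals[sprintf("ratio_nonlav_%g", x)] <- if (nNon > 0) cNon / nNon else NA_real_
  }
  vals["TLV"] <- nLung * vv
  vals["LAV"] <- nLav * vv
  vals["LAV_fraction"] <- nLav / nLung
  vals["TLV_minus_LAV"] <- nNon * vv
  vals["MLD"] <- sum(dvec[inLung]) / nLung
  medDomain <- if (irradiatedOnly) inLav & dvec > 0 else inLav
  mlwedDomain <- if (irradiatedOnly) inLung & !inLav & dvec > 0 else inLung & !inLav
  vals["MED"] <- if (sum(medDomain)) sum(dvec[medDomain]) / sum(medDomain) else NA_real_
  vals["MLWED"] <- if (sum(mlwedDomain)) sum(dvec[mlwedDomain]) / sum(mlwedDomain) else NA_real_

  new("DosimetricProfile", values = vals, cutoffsGy = as.numeric(cutoffsGy))
}

#' @rdname DosimetricProfile-class
#' @param x a [DosimetricProfile-class].
#' @export
profileValues <- function(x) x@values

#' @describeIn DosimetricProfile-class one-row data.frame of all parameters.
#' @param row.names,optional,... passed for S3 consistency; unused.
#' @export
as.data.frame.DosimetricProfile <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  as.data.frame(as.list(x@values))
}

setMethod("show", "DosimetricProfile", function(object) {
  v <- object@values
  cat(sprintf("DosimetricProfile: TLV %.1f cc, LAV %.1f cc (LAV%% %.3f), MLD %.2f Gy\n",
              v["TLV"], v["LAV"], v["LAV_fraction"], v["MLD"]))
  cat(sprintf("  V20 %.1f cc (%.1f%%), (V30-LAV30)/(TLV-LAV) %.3f\n",
              v["V20"], v["V20_pct"], v["ratio_nonlav_30"]))
})
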