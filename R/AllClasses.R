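#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Voxel-lattice geometry
#'
#' Describes a regular 3D voxel lattice in patient coordinates: the number of
#' voxels per axis, the spacing between voxel centers (mm), the position of the
#' first voxel center (mm), and the direction cosines of the three lattice axes.
#' Voxel indices are 0-based; the center of voxel `(i, j, k)` lies at
#' `origin + orientation %*% (c(i, j, k) * spacing)`.
#'
#' @slot dims integer(3), voxels per axis; all >= 1.
#' @slot spacing numeric(3), mm per axis; all > 0.
#' @slot origin numeric(3), mm, patient coordinates of the first voxel center.
#' @slot orientation 3x3 matrix of direction cosines; must be orthonormal
#'   (`|det| = 1` within 1e-6).
#' @seealso [volumeGeometry()], [voxelVolumeCc()], [voxelCenters()]
#' @export
setClass("VolumeGeometry",
  representation(dims = "integer", spacing = "numeric",
                 origin = "numeric", orientation = "matrix"))

setValidity("VolumeGeometry", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(is.na(object@dims)) || any(object@dims < 1L))
    msg <- c(msg, "dims must be three integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three finite positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values (mm)")
  R <- object@orientation
  if (!is.numeric(R) || !identical(dim(R), c(3L, 3L))) {
    msg <- c(msg, "orientation must be a numeric 3x3 matrix")
  } else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(abs(det(R)) - 1) > 1e-6)
      msg <- c(msg, "orientation must be orthonormal (|det| = 1 within 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeGeometry
#'
#' @param dims integer(3) voxel counts per axis.
#' @param spacing numeric(3) voxel spacing in mm (default 1 mm isotropic).
#' @param origin numeric(3) patient-coordinate position (mm) of the center of
#'   voxel (0, 0, 0). Default `c(0, 0, 0)`.
#' @param orientation 3x3 direction-cosine matrix (default identity, i.e. the
#'   lattice axes coincide with the patient axes).
#' @return A [VolumeGeometry-class] object.
#' @examples
#' geom <- volumeGeometry(c(4, 4, 2), spacing = c(2, 2, 2.5))
#' voxelVolumeCc(geom)
#' @export
volumeGeometry <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           orientation = diag(3)) {
  new("VolumeGeometry", dims = as.integer(dims), spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

## Coerce per-voxel values to an array matching the geometry, refusing any
## shape mismatch (no silent recycling).
.asVoxelArray <- function(values, geometry, what) {
  d <- geometry@dims
  if (!is.null(dim(values))) {
    if (!identical(as.integer(dim(values)), d))
      stop(sprintf("%s array shape (%s) does not match geometry dims (%s)",
                   what, paste(dim(values), collapse = "x"),
                   paste(d, collapse = "x")), call. = FALSE)
  } else if (length(values) != prod(d)) {
    stop(sprintf("%s has %d values but the geometry has %d voxels",
                 what, length(values), prod(d)), call. = FALSE)
  }
  values
}

## Scalar volumes ------------------------------------------------------------

#' Virtual parent for voxelized scalar fields
#'
#' Holds a [VolumeGeometry-class] and a numeric array whose shape matches the
#' geometry's `dims`. Concrete subclasses are [CtVolume-class],
#' [DoseVolume-class] and [BinaryMask-class].
#'
#' @slot geometry a [VolumeGeometry-class].
#' @slot voxels array of per-voxel values with `dim == dims(geometry)`.
#' @export
setClass("ScalarVolume", representation("VIRTUAL",
  geometry = "VolumeGeometry", voxels = "array"))

setValidity("ScalarVolume", function(object) {
  if (!identical(dim(object@voxels), object@geometry@dims))
    return("voxel array shape does not match geometry dims")
  TRUE
})

#' CT volume in Hounsfield units
#'
#' @slot geometry,voxels see [ScalarVolume-class]; `voxels` holds HU values.
#' @slot breathingPhase `"free_breathing"` or `"inspiratory"`. Free-breathing
#'   acquisitions are near-expiratory, which is why emphysema thresholding uses
#'   -856 HU on them rather than the full-inspiration -950 HU convention.
#' @seealso [ctVolume()], [segmentLav()]
#' @export
setClass("CtVolume", contains = "ScalarVolume",
  representation(breathingPhase = "character"))

setValidity("CtVolume", function(object) {
  if (!(object@breathingPhase %in% c("free_breathing", "inspiratory")))
    return("breathingPhase must be 'free_breathing' or 'inspiratory'")
  if (any(!is.finite(object@voxels)))
    return("HU values must be finite")
  TRUE
})

#' @param hu numeric array of Hounsfield units with shape `dims(geometry)`.
#' @param geometry a [VolumeGeometry-class].
#' @param breathingPhase acquisition phase, `"free_breathing"` (default) or
#'   `"inspiratory"`.
#' @rdname CtVolume-class
#' @export
ctVolume <- function(hu, geometry, breathingPhase = "free_breathing") {
  hu <- .asVoxelArray(hu, geometry, "HU")
  new("CtVolume", geometry = geometry,
      voxels = array(as.double(hu), dim = geometry@dims),
      breathingPhase = breathingPhase)
}

#' Radiotherapy dose grid in Gy
#'
#' @slot geometry,voxels see [ScalarVolume-class]; `voxels` holds absorbed dose
#'   in Gy, all finite and >= 0.
#' @seealso [doseVolume()], [resampleDose()], [volumeAbove()]
#' @export
setClass("DoseVolume", contains = "ScalarVolume")

setValidity("DoseVolume", function(object) {
  if (any(!is.finite(object@voxels)) || any(object@voxels < 0))
    return("dose values must be finite and >= 0 Gy")
  TRUE
})

#' @param doseGy numeric array of doses (Gy) with shape `dims(geometry)`.
#' @param geometry a [VolumeGeometry-class].
#' @rdname DoseVolume-class
#' @export
doseVolume <- function(doseGy, geometry) {
  doseGy <- .asVoxelArray(doseGy, geometry, "dose")
  new("DoseVolume", geometry = geometry,
      voxels = array(as.double(doseGy), dim = geometry@dims))
}

#' Binary voxel mask
#'
#' Membership indicator on a voxel lattice (lung, LAV, or derived partitions).
#'
#' @slot geometry,voxels see [ScalarVolume-class]; `voxels` is logical.
#' @seealso [binaryMask()], [maskVolumeCc()], [rasterizeStructure()]
#' @export
setClass("BinaryMask", contains = "ScalarVolume")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@voxels)) return("mask voxels must be logical")
  if (any(is.na(object@voxels))) return("mask voxels must not be NA")
  TRUE
})

#' @param member logical array with shape `dims(geometry)`.
#' @param geometry a [VolumeGeometry-class].
#' @rdname BinaryMask-class
#' @export
binaryMask <- function(member, geometry) {
  member <- .asVoxelArray(member, geometry, "mask")
  new("BinaryMask", geometry = geometry,
      voxels = array(as.logical(member), dim = geometry@dims))
}

## Structure set -------------------------------------------------------------

#' Planar contour set (RT Structure Set content)
#'
#' Named structures, each a list of closed planar polygons. A polygon is a list
#' with elements `x`, `y` (vertex coordinates in mm, >= 3 vertices) and `z`
#' (the plane position in mm).
#'
#' @slot structures named list; each element is a list of polygons.
#' @seealso [structureSet()], [rasterizeStructure()]
#' @export
setClass("StructureSet", representation(structures = "list"))

setValidity("StructureSet", function(object) {
  s <- object@structures
  if (length(s) && (is.null(names(s)) || any(!nzchar(names(s)))))
    return("all structures must be named")
  for (nm in names(s)) {
    for (poly in s[[nm]]) {
      if (!all(c("x", "y", "z") %in% names(poly)))
        return(sprintf("structure '%s': polygon lacks x/y/z", nm))
      if (length(poly$x) < 3L || length(poly$y) != length(poly$x))
        return(sprintf("structure '%s': degenerate polygon (< 3 vertices)", nm))
      if (length(poly$z) != 1L || !is.finite(poly$z))
        return(sprintf("structure '%s': polygon needs one finite z plane", nm))
    }
  }
  TRUE
})

#' @param structures named list of polygon lists (see class description).
#' @rdname StructureSet-class
#' @export
structureSet <- function(structures = list()) {
  new("StructureSet", structures = structures)
}

## Cohort table --------------------------------------------------------------

.cohortRequiredCols <- c("patient_id", "age", "sex", "stage", "histology",
                         "treatment_type", "chemotherapy", "ild",
                         "smoking_pack_years", "bmi", "rp_grade")

#' Clinical cohort table
#'
#' One row per patient: demographics, treatment covariates and the CTCAE
#' radiation pneumonitis grade (0-5). Binary flags (`chemotherapy`, `ild`)
#' must be 0/1; `stage` must be in 1-4; patient ids must be unique.
#'
#' @slot records data.frame with the required columns.
#' @slot provenance character, where the table came from (file path or
#'   `"simulated"`).
#' @seealso [cohortTable()], [readCohortTable()], [deriveEndpoint()]
#' @export
setClass("CohortTable",
  representation(records = "data.frame", provenance = "character"))

setValidity("CohortTable", function(object) {
  df <- object@records
  missing <- setdiff(.cohortRequiredCols, names(df))
  if (length(missing))
    return(paste("missing required columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(df$patient_id))
    return(paste("duplicate patient_id:",
                 paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", ")))
  bad <- which(!(df$rp_grade %in% 0:5))
  if (length(bad))
    return(sprintf("rp_grade out of range {0..5} in row %d", bad[1]))
  for (col in c("chemotherapy", "ild")) {
    bad <- which(!(df[[col]] %in% c(0, 1)))
    if (length(bad))
      return(sprintf("%s must be 0/1; offending row %d", col, bad[1]))
  }
  bad <- which(!(df$stage %in% 1:4))
  if (length(bad))
    return(sprintf("stage must be in {1,2,3,4}; offending row %d", bad[1]))
  TRUE
})

#' @param records data.frame of clinical records.
#' @param provenance character tag recording the source.
#' @rdname CohortTable-class
#' @export
cohortTable <- function(records, provenance = "in-memory") {
  new("CohortTable", records = as.data.frame(records), provenance = provenance)
}

## Dosimetric profile --------------------------------------------------------

#' Per-patient dosimetric parameter profile
#'
#' The full set of dose-volume parameters computed from the lung/LAV partition:
#' for each dose cutoff x in the configured set (default 2, 5, 10, 20, 30 Gy)
#' the absolute volumes `Vx`, `Vx_minus_LAVx`, `LAVx` (cc), the percentage
#' `Vx_pct` (0-100), and the ratios `ratio_tlv_x` = (Vx-LAVx)/TLV and
#' `ratio_nonlav_x` = (Vx-LAVx)/(TLV-LAV) (0-1); plus `TLV`, `LAV`,
#' `TLV_minus_LAV` (cc), `LAV_fraction` (0-1), and the mean doses `MLD`,
#' `MED`, `MLWED` (Gy). `MED` is `NA` when the LAV compartment is empty and
#' `MLWED` is `NA` when LAV fills the whole lung.
#'
#' @slot values named numeric vector of parameters.
#' @slot cutoffsGy numeric, the dose cutoffs used.
#' @seealso [dosimetricProfile()], [profileParameterNames()]
#' @export
setClass("DosimetricProfile",
  representation(values = "numeric", cutoffsGy = "numeric"))

setValidity("DosimetricProfile", function(object) {
  if (is.null(names(object@values)) || any(!nzchar(names(object@values))))
    return("profile values must be named")
  TRUE
})

## Logistic fit --------------------------------------------------------------

#' Covariate-adjusted logistic model fit
#'
#' A maximum-likelihood logistic regression of a binary pneumonitis endpoint on
#' one SD-standardized dosimetric parameter plus adjustment covariates, with
#' the quantities used for model comparison.
#'
#' @slot coefficients named numeric, MLE coefficients.
#' @slot se named numeric, standard errors.
#' @slot oddsRatio numeric, odds ratio per SD for the dosimetric term.
#' @slot orCi numeric(2), Wald 95% CI for the odds ratio.
#' @slot pValue numeric, two-sided Wald p for the dosimetric term.
#' @slot logLik numeric, maximized log-likelihood.
#' @slot k integer, number of estimated parameters.
#' @slot n integer, cohort size used in the fit.
#' @slot aic,bic numeric, `2k - 2 logLik` and `k log(n) - 2 logLik`.
#' @slot fitted numeric, fitted event probabilities (in (0,1)).
#' @slot outcome integer, the 0/1 outcome used.
#' @slot parameter character, name of the dosimetric term.
#' @slot method character, `"mle"` or `"firth"`.
#' @seealso [fitRpModel()], [idi()], [nriContinuous()]
#' @export
setClass("RpLogisticFit",
  representation(coefficients = "numeric", se = "numeric", oddsRatio = "numeric",
                 orCi = "numeric", pValue = "numeric", logLik = "numeric",
                 k = "integer", n = "integer", aic = "numeric", bic = "numeric",
                 fitted = "numeric", outcome = "integer", parameter = "character",
                 method = "character"))

setValidity("RpLogisticFit", function(object) {
  if (abs(object@aic - (2 * object@k - 2 * object@logLik)) > 1e-8)
    return("AIC identity violated")
  if (abs(object@bic - (object@k * log(object@n) - 2 * object@logLik)) > 1e-8)
    return("BIC identity violated")
  if (any(object@fitted <= 0 | object@fitted >= 1))
    return("fitted probabilities must lie strictly in (0,1)")
  if (length(object@fitted) != length(object@outcome))
    return("fitted and outcome lengths differ")
  TRUE
})
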