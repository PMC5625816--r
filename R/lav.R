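#' Emphysema segmentation configuration
#'
#' Low attenuation volume (LAV) is segmented by a plain HU threshold on the
#' lung: -856 HU on free-breathing CT (near-expiratory acquisition) and
#' -950 HU on full-inspiration CT, the standard quantitative-CT conventions.
#' A voxel whose HU equals the threshold counts as LAV when `inclusive = TRUE`
#' (the default, matching common LAA% practice).
#'
#' @slot thresholdHu HU cutoff, in \[-1024, 0\].
#' @slot inclusive logical; `TRUE` uses `hu <= threshold`, `FALSE` strict `<`.
#' @export
setClass("LavConfig", representation(thresholdHu = "numeric", inclusive = "logical"))

setValidity("LavConfig", function(object) {
  if (length(object@thresholdHu) != 1L || !is.finite(object@thresholdHu) ||
      object@thresholdHu < -1024 || object@thresholdHu > 0)
    return("thresholdHu must be a single value in [-1024, 0]")
  TRUE
})

#' @param phase `"free_breathing"` (threshold -856 HU) or `"inspiratory"`
#'   (threshold -950 HU); ignored when `thresholdHu` is given explicitly.
#' @param thresholdHu optional explicit HU cutoff.
#' @param inclusive whether HU equal to the threshold counts as LAV.
#' @rdname LavConfig-class
#' @export
lavConfig <- function(phase = c("free_breathing", "inspiratory"),
                      thresholdHu = NULL, inclusive = TRUE) {
  phase <- match.arg(phase)
  if (is.null(thresholdHu))
    thresholdHu <- if (phase == "free_breathing") -856 else -950
  new("LavConfig", thresholdHu = as.numeric(thresholdHu), inclusive = inclusive)
}

#' Segment low attenuation volume (emphysema) within the lung
#'
#' Thresholds the CT inside the lung mask: a voxel is LAV iff it is a lung
#' member and its HU is at or below (`inclusive`) / strictly below the
#' configured cutoff. No smoothing or connected-component cleanup is applied;
#' the result is always a subset of the lung mask.
#'
#' @param ct a [CtVolume-class].
#' @param lung a [BinaryMask-class] on the same geometry.
#' @param cfg a [LavConfig-class]; default free-breathing (-856 HU, inclusive).
#' @return a [BinaryMask-class] of LAV voxels.
#' @export
segmentLav <- function(ct, lung, cfg = lavConfig()) {
  .stopIfGeometryMismatch(ct, lung, "CT and lung mask")
  validObject(cfg)
  below <- if (cfg@inclusive) ct@voxels <= cfg@thresholdHu else ct@voxels < cfg@thresholdHu
  binaryMask(lung@voxels & below, geometry(ct))
}

#' Volume of a binary mask in cc
#'
#' Member-voxel count times voxel volume (spacing product / 1000). Applied to
#' the lung, LAV and lung-minus-LAV masks this yields TLV, LAV and TLV-LAV.
#'
#' @param mask a [BinaryMask-class].
#' @return volume in cc.
#' @export
maskVolumeCc <- function(mask) sum(mask@voxels) * voxelVolumeCc(mask)

#' LAV as a fraction of total lung volume
#'
#' @param lavCc LAV volume in cc, `0 <= lavCc <= tlvCc`.
#' @param tlvCc total lung volume in cc, > 0.
#' @return LAV% on the 0-1 scale (e.g. 0.103 for 412 cc of LAV in a 4000 cc
#'   lung).
#' @export
lavPercent <- function(lavCc, tlvCc) {
  if (any(tlvCc <= 0)) stop("total lung volume must be positive", call. = FALSE)
  if (any(lavCc < 0 | lavCc > tlvCc))
    stop("LAV volume must lie in [0, TLV]", call. = FALSE)
  lavCc / tlvCc
}

#' Free-breathing vs inspiratory LAV calibration
#'
#' Ordinary least-squares regression of free-breathing LAV (cc) on inspiratory
#' LAV (cc) across patients scanned under both conditions, with Pearson and
#' Spearman correlations. Used to validate that near-expiratory thresholding
#' at -856 HU tracks the inspiratory -950 HU measurement.
#'
#' @param inspiratoryCc numeric, LAV (cc) on inspiratory CT (-950 HU).
#' @param freeBreathingCc numeric, LAV (cc) on free-breathing CT (-856 HU).
#' @return a list of class `lavCalibration`: `slope` (unitless), `intercept`
#'   (cc), `r` (Pearson), `spearmanRho`, `n`.
#' @export
calibrateLav <- function(inspiratoryCc, freeBreathingCc) {
  if (length(inspiratoryCc) != length(freeBreathingCc))
    stop("paired measurements must have equal length", call. = FALSE)
  keep <- is.finite(inspiratoryCc) & is.finite(freeBreathingCc)
  x <- inspiratoryCc[keep]; y <- freeBreathingCc[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in the inspiratory measurement", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- if (stats::var(y) == 0) NA_real_ else stats::cor(x, y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r = r,
                 spearmanRho = suppressWarnings(stats::cor(x, y, method = "spearman")),
                 n = length(x)),
            class = "lavCalibration")
}

#' @export
print.lavCalibration <- function(x, ...) {
  cat(sprintf("LAV calibration (n = %d): free-breathing = %.3f x inspiratory + %.1f cc, r = %.3f (Spearman rho = %.3f)\n",
              x$n, x$slope, x$intercept, x$r, x$spearmanRho))
  invisible(x)
}
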