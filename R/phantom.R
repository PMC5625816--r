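## Synthetic thoracic phantom: ellipsoid lung pair, spatially clustered
## low-attenuation (emphysema) compartment, and a cylindrical beam dose field
## with Gaussian lateral falloff and linear depth attenuation. Stands in for
## clinical CT / RT Dose inputs at desk scale.

#' Phantom generator configuration
#'
#' Defaults emulate the summary statistics of a thoracic radiotherapy cohort:
#' LAV fraction around 0.10, mean lung dose around 7 Gy and V20% around 14
#' when combined with the default beam settings.
#'
#' @param dims integer(3), grid size in voxels (default 48 x 48 x 32).
#' @param spacingMm numeric(3), voxel spacing in mm (default 4 mm isotropic).
#' @param targetLavFraction target emphysema fraction of the lung, in \[0, 1).
#' @param emphysemaRadiusMm numeric(2), min/max radius (mm) of the random
#'   emphysema spheres.
#' @param parenchymaHu,parenchymaSd normal-lung HU mean / SD (HU are rounded
#'   to integers, as on CT).
#' @param emphysemaHu,emphysemaSd emphysema HU mean / SD; with the defaults
#'   (-950 +/- 30 vs -750 +/- 50) thresholding at -856 HU recovers the
#'   clusters with ~2% noise-tail contamination.
#' @param beamDoseGyRange numeric(2), prescribed dose range (Gy); each phantom
#'   draws uniformly (the cohort mixes palliative ~30 Gy and curative ~66 Gy
#'   prescriptions).
#' @param beamRadiusMmRange numeric(2), beam cylinder radius range (mm).
#' @param beamSigmaMm lateral Gaussian penumbra scale (mm).
#' @param depthAttenuationPerMm linear depth attenuation of the beam per mm.
#' @param measuredAtThresholdHu HU threshold at which `targetLavFraction` is
#'   meant to be *measured*. The structural sphere target is reduced by the
#'   expected parenchyma noise-tail fraction below this threshold, so the
#'   segmented LAV fraction, not just the sphere volume, centers on the
#'   target.
#' @param beamJitterMm SD (mm) of the beam-axis position jitter around the
#'   right-lung center.
#' @param lungScaleRange numeric(2), per-patient uniform scale factor applied
#'   to the lung ellipsoid semi-axes (anatomical size variability, so TLV
#'   varies across the cohort).
#' @param maxPlacementAttempts cap on emphysema sphere placements.
#' @return a list of class `phantomConfig`.
#' @export
phantomConfig <- function(dims = c(48L, 48L, 32L), spacingMm = c(4, 4, 4),
                          targetLavFraction = 0.103,
                          emphysemaRadiusMm = c(8, 16),
                          parenchymaHu = -750, parenchymaSd = 50,
                          emphysemaHu = -950, emphysemaSd = 30,
                          beamDoseGyRange = c(30, 66),
                          beamRadiusMmRange = c(10, 18),
                          beamSigmaMm = 6,
                          measuredAtThresholdHu = -856,
                          depthAttenuationPerMm = 0.003,
                          beamJitterMm = 8,
                          lungScaleRange = c(0.88, 1.12),
                          maxPlacementAttempts = 1000L) {
  stopifnot(targetLavFraction >= 0, targetLavFraction < 1,
            all(beamDoseGyRange > 0), all(spacingMm > 0), all(dims >= 4))
  structure(as.list(environment()), class = "phantomConfig")
}

#' Outcome-model configuration for the cohort simulator
#'
#' The event probability is `plogis(intercept + coefPerSd * z +
#' coefChemotherapy * chemo + coefIld * ild)` where `z` is the cohort z-score
#' of the driving dosimetric parameter. Covariate prevalences follow the
#' clinical cohort (chemotherapy 40%, ILD 6%). Simulated events receive CTCAE
#' grades 2:3:4:5 in proportion 12:13:1:1 and non-events grades 0:1 in
#' proportion 49:24, so both endpoint cutoffs are exercisable.
#'
#' @param drivingParameter profile column that drives the outcome.
#' @param intercept,coefPerSd logistic intercept and per-SD slope.
#' @param coefChemotherapy,coefIld covariate log-odds effects.
#' @param chemotherapyPrevalence,ildPrevalence Bernoulli prevalences.
#' @return a list of class `outcomeModelConfig`.
#' @export
outcomeModelConfig <- function(drivingParameter = "ratio_nonlav_30",
                               intercept = -1.5, coefPerSd = 1.2,
                               coefChemotherapy = 1.0, coefIld = 1.2,
                               chemotherapyPrevalence = 0.40,
                               ildPrevalence = 0.06) {
  stopifnot(chemotherapyPrevalence >= 0, chemotherapyPrevalence <= 1,
            ildPrevalence >= 0, ildPrevalence <= 1)
  structure(as.list(environment()), class = "outcomeModelConfig")
}

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

## Counter-based per-patient seed: stable under patient reordering and
## kept below 2^31.
.patientSeed <- function(masterSeed, index, stream = 0L) {
  as.integer((as.double(masterSeed) * 48271 + index * 15485863 +
                stream * 69621) %% 2147483647)
}

## Deterministic per-geometry statics (coordinates, lung mask), cached.
.phantomCache <- new.env(parent = emptyenv())

.phantomStatics <- function(cfg) {
  key <- paste(c(cfg$dims, cfg$spacingMm), collapse = "_")
  if (!is.null(.phantomCache[[key]])) return(.phantomCache[[key]])
  d <- as.integer(cfg$dims); sp <- cfg$spacingMm
  geom <- volumeGeometry(d, spacing = sp)
  ext <- (d - 1) * sp
  xs <- (0:(d[1] - 1)) * sp[1]; ys <- (0:(d[2] - 1)) * sp[2]; zs <- (0:(d[3] - 1)) * sp[3]
  X <- rep(xs, times = d[2] * d[3])
  Y <- rep(rep(ys, each = d[1]), times = d[3])
  Z <- rep(zs, each = d[1] * d[2])
  mid <- ext / 2
  body <- ((X - mid[1]) / (0.48 * ext[1]))^2 + ((Y - mid[2]) / (0.45 * ext[2]))^2 <= 1
  out <- list(geom = geom, X = X, Y = Y, Z = Z, body = body, ext = ext,
              mid = mid, semi = c(0.18 * ext[1], 0.34 * ext[2], 0.40 * ext[3]),
              sep = 0.24 * ext[1], d = d)
  .phantomCache[[key]] <- out
  out
}

#' Generate one synthetic thoracic phantom
#'
#' Produces a CT volume, a lung mask and a dose grid on a shared geometry.
#' The lung is a voxelized ellipsoid pair; emphysema is a union of random
#' spheres inside the lung whose HU are drawn low enough that -856 HU
#' thresholding recovers them; the dose is a prescribed-dose cylinder through
#' the right lung with Gaussian lateral falloff and linear depth attenuation,
#' quantized to 0.001 Gy so DICOM/NIfTI round trips are exact. The same seed
#' yields bit-identical volumes.
#'
#' @param cfg a [phantomConfig()].
#' @param seed integer seed; fully determines the output.
#' @return list with elements `ct` ([CtVolume-class]), `lung`
#'   ([BinaryMask-class]) and `dose` ([DoseVolume-class]).
#' @export
generatePhantom <- function(cfg = phantomConfig(), seed = 1L) {
  st <- .phantomStatics(cfg)
  .withSeed(seed, {
    n <- prod(st$d)
    ## per-patient lung size, then voxelized ellipsoid pair
    sc <- stats::runif(1, cfg$lungScaleRange[1], cfg$lungScaleRange[2])
    a <- sc * st$semi[1]; b <- sc * st$semi[2]; cc <- sc * st$semi[3]
    mid <- st$mid; sep <- st$sep
    lung <- (((st$X - (mid[1] + sep)) / a)^2 + ((st$Y - mid[2]) / b)^2 +
               ((st$Z - mid[3]) / cc)^2 <= 1) |
            (((st$X - (mid[1] - sep)) / a)^2 + ((st$Y - mid[2]) / b)^2 +
               ((st$Z - mid[3]) / cc)^2 <= 1)
    if (!any(lung)) stop("lung empty after voxelization", call. = FALSE)
    lungIdx <- which(lung)
    nLung <- length(lungIdx)

    ## emphysema clusters; correct the structural target for the parenchyma
    ## noise tail that thresholding will also pick up
    emph <- logical(n)
    tail <- stats::pnorm((cfg$measuredAtThresholdHu - cfg$parenchymaHu) /
                           cfg$parenchymaSd)
    structuralFraction <- max(0, (cfg$targetLavFraction - tail) / (1 - tail))
    if (cfg$targetLavFraction == 0) structuralFraction <- 0
    target <- structuralFraction * nLung
    if (target > 0) {
      lx <- st$X[lungIdx]; ly <- st$Y[lungIdx]; lz <- st$Z[lungIdx]
      emphL <- logical(nLung)
      attempts <- 0L
      while (sum(emphL) < target) {
        attempts <- attempts + 1L
        if (attempts > cfg$maxPlacementAttempts)
          stop("could not reach target LAV fraction within placement attempts",
               call. = FALSE)
        ci <- sample.int(nLung, 1L)
        r <- stats::runif(1, cfg$emphysemaRadiusMm[1], cfg$emphysemaRadiusMm[2])
        emphL <- emphL | ((lx - lx[ci])^2 + (ly - ly[ci])^2 + (lz - lz[ci])^2 <= r * r)
      }
      emph[lungIdx] <- emphL
    }

    ## CT in integer HU
    hu <- rep(-1000, n)
    hu[st$body] <- 40 + stats::rnorm(sum(st$body), 0, 20)
    hu[lung] <- cfg$parenchymaHu + stats::rnorm(nLung, 0, cfg$parenchymaSd)
    if (any(emph)) hu[emph] <- cfg$emphysemaHu + stats::rnorm(sum(emph), 0, cfg$emphysemaSd)
    hu <- pmax(-1024, pmin(3071, round(hu)))

    ## beam dose field
    d0 <- stats::runif(1, cfg$beamDoseGyRange[1], cfg$beamDoseGyRange[2])
    R <- stats::runif(1, cfg$beamRadiusMmRange[1], cfg$beamRadiusMmRange[2])
    bx <- (mid[1] + sep) + stats::rnorm(1, 0, cfg$beamJitterMm)
    bz <- mid[3] + stats::rnorm(1, 0, cfg$beamJitterMm)
    rlat <- sqrt((st$X - bx)^2 + (st$Z - bz)^2)
    lateral <- ifelse(rlat <= R, 1, exp(-((rlat - R)^2) / (2 * cfg$beamSigmaMm^2)))
    depth <- pmax(0, 1 - cfg$depthAttenuationPerMm * st$Y)
    doseGy <- round(d0 * lateral * depth / 1e-3) * 1e-3

    geom <- st$geom
    list(ct = ctVolume(array(hu, st$d), geom),
         lung = binaryMask(array(lung, st$d), geom),
         dose = doseVolume(array(doseGy, st$d), geom))
  })
}
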