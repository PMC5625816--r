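# Small in-code fixtures shared across tests.

makeGeom <- function(dims = c(4, 4, 2), spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  volumeGeometry(dims, spacing = spacing, origin = origin)
}

uniformCt <- function(hu, geom = makeGeom(), phase = "free_breathing") {
  ctVolume(array(hu, dim = dims(geom)), geom, breathingPhase = phase)
}

uniformDose <- function(gy, geom = makeGeom()) {
  doseVolume(array(gy, dim = dims(geom)), geom)
}

fullMask <- function(geom = makeGeom()) {
  binaryMask(array(TRUE, dim = dims(geom)), geom)
}

# Random small instance for enumeration-oracle tests: integer HU, integer
# doses, random nonempty lung.
randomInstance <- function(maxDim = 6L) {
  d <- sample(2:maxDim, 3, replace = TRUE)
  geom <- volumeGeometry(d, spacing = runif(3, 0.8, 3))
  hu <- array(sample(-1000:-600, prod(d), replace = TRUE), dim = d)
  dose <- array(sample(0:40, prod(d), replace = TRUE), dim = d)
  lung <- array(runif(prod(d)) < 0.7, dim = d)
  if (!any(lung)) lung[1] <- TRUE
  list(ct = ctVolume(hu, geom), dose = doseVolume(dose, geom),
       lung = binaryMask(lung, geom), geom = geom)
}

# Independent per-voxel enumeration of every dosimetric parameter, written as
# plain scalar loops (no shared code with the package implementation).
oracleProfile <- function(ct, dose, lung, thresholdHu = -856,
                          cutoffs = c(2, 5, 10, 20, 30)) {
  d <- dims(ct)
  vv <- prod(spacing(ct)) / 1000
  hu <- voxels(ct); dg <- voxels(dose); lm <- voxels(lung)
  nLung <- 0L; nLav <- 0L
  sumLung <- 0; sumLav <- 0; sumNon <- 0
  cLavX <- setNames(integer(length(cutoffs)), as.character(cutoffs))
  cNonX <- cLavX
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!lm[i, j, k]) next
    nLung <- nLung + 1L
    isLav <- hu[i, j, k] <= thresholdHu
    sumLung <- sumLung + dg[i, j, k]
    if (isLav) { nLav <- nLav + 1L; sumLav <- sumLav + dg[i, j, k] }
    else sumNon <- sumNon + dg[i, j, k]
    for (x in cutoffs) {
      if (dg[i, j, k] >= x) {
        if (isLav) cLavX[as.character(x)] <- cLavX[as.character(x)] + 1L
        else cNonX[as.character(x)] <- cNonX[as.character(x)] + 1L
      }
    }
  }
  nNon <- nLung - nLav
  vals <- c()
  for (x in cutoffs) {
    cl <- cLavX[as.character(x)]; cn <- cNonX[as.character(x)]
    vals[sprintf("V%g", x)] <- cn * vv + cl * vv
    vals[sprintf("V%g_minus_LAV%g", x, x)] <- cn * vv
    vals[sprintf("LAV%g", x)] <- cl * vv
    vals[sprintf("V%g_pct", x)] <- 100 * (cl + cn) / nLung
    vals[sprintf("ratio_tlv_%g", x)] <- cn / nLung
    vals[sprintf("ratio_nonlav_%g", x)] <- if (nNon > 0) cn / nNon else NA_real_
  }
  vals["TLV"] <- nLung * vv
  vals["LAV"] <- nLav * vv
  vals["LAV_fraction"] <- nLav / nLung
  vals["TLV_minus_LAV"] <- nNon * vv
  vals["MLD"] <- sumLung / nLung
  vals["MED"] <- if (nLav > 0) sumLav / nLav else NA_real_
  vals["MLWED"] <- if (nNon > 0) sumNon / nNon else NA_real_
  vals
}

# Scalar-loop even-odd point-in-polygon oracle (crossing count, edges count
# as inside).
oracleInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-edge check
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx^2 + dy^2
    if (L2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / L2
      if (t >= 0 && t <= 1) {
        cx <- x1 + t * dx; cy <- y1 + t * dy
        if (abs(px - cx) < 1e-9 && abs(py - cy) < 1e-9) return(TRUE)
      }
    }
    if ((y1 > py) != (y2 > py)) {
      xInt <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xInt) inside <- !inside
    }
  }
  inside
}

smallPhantomConfig <- function(...) {
  phantomConfig(dims = c(24, 24, 16), spacingMm = c(8, 8, 8), ...)
}
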