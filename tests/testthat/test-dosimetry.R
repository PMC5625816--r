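test_that("resampling onto the same geometry is the identity", {
  geom <- makeGeom(c(4, 4, 3))
  dose <- doseVolume(array(runif(48, 0, 50), c(4, 4, 3)), geom)
  expect_identical(voxels(resampleDose(dose, geom)), voxels(dose))
})

test_that("a constant field stays constant under any interior resampling", {
  src <- volumeGeometry(c(10, 10, 10), spacing = c(4, 4, 4))
  dose <- uniformDose(10, src)
  tgt <- volumeGeometry(c(5, 5, 5), spacing = c(3, 3, 3), origin = c(5, 5, 5))
  expect_true(all(voxels(resampleDose(dose, tgt)) == 10))
})

test_that("trilinear interpolation is exact on an affine dose field", {
  src <- volumeGeometry(c(6, 6, 8), spacing = c(2, 2, 2))
  z <- voxelCenters(src)[, 3]
  dose <- doseVolume(array(1.5 * z + 4, dims(src)), src)
  # target shifted half a voxel along z, strictly inside the source grid
  tgt <- volumeGeometry(c(4, 4, 6), spacing = c(2, 2, 2), origin = c(2, 2, 1))
  res <- resampleDose(dose, tgt)
  expect_equal(as.vector(voxels(res)), 1.5 * voxelCenters(tgt)[, 3] + 4,
               tolerance = 1e-12)
})

test_that("target centers outside the dose grid receive zero", {
  src <- volumeGeometry(c(4, 4, 4), spacing = c(1, 1, 1))
  dose <- uniformDose(20, src)
  tgt <- volumeGeometry(c(4, 4, 4), spacing = c(1, 1, 1), origin = c(10, 0, 0))
  expect_true(all(voxels(resampleDose(dose, tgt)) == 0))
})

test_that("threshold volumes use the inclusive boundary", {
  geom <- makeGeom(c(4, 4, 2))
  mask <- fullMask(geom)
  expect_equal(volumeAbove(uniformDose(0, geom), mask, 2), 0)
  expect_equal(volumeAbove(uniformDose(30, geom), mask, 30), maskVolumeCc(mask))
})

test_that("threshold volumes match per-voxel enumeration", {
  set.seed(17)
  geom <- volumeGeometry(c(5, 5, 5), spacing = c(1.2, 2, 0.8))
  dg <- array(sample(0:40, 125, TRUE), c(5, 5, 5))
  mv <- array(runif(125) < 0.6, c(5, 5, 5))
  dose <- doseVolume(dg, geom); mask <- binaryMask(mv, geom)
  for (cutoff in c(0, 2, 17, 40, 41)) {
    cnt <- 0L
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      if (mv[i, j, k] && dg[i, j, k] >= cutoff) cnt <- cnt + 1L
    expect_identical(volumeAbove(dose, mask, cutoff), cnt * voxelVolumeCc(geom))
  }
})

test_that("mean dose is the arithmetic mean over the mask", {
  geom <- makeGeom(c(4, 4, 1))
  expect_equal(meanDose(uniformDose(7.5, geom), fullMask(geom)), 7.5)
  half <- array(rep(c(0, 20), each = 8), c(4, 4, 1))
  expect_equal(meanDose(doseVolume(half, geom), fullMask(geom)), 10)
  set.seed(3)
  g4 <- makeGeom(c(4, 4, 4))
  dg <- array(runif(64, 0, 60), c(4, 4, 4))
  mv <- array(runif(64) < 0.5, c(4, 4, 4)); mv[1] <- TRUE
  expect_equal(meanDose(doseVolume(dg, g4), binaryMask(mv, g4)),
               sum(dg[mv]) / sum(mv))
  expect_error(meanDose(uniformDose(1, geom),
                        binaryMask(array(FALSE, c(4, 4, 1)), geom)), "undefined")
})

test_that("an emphysema-free lung degenerates the profile as expected", {
  geom <- makeGeom(c(4, 4, 2))
  ct <- uniformCt(-700, geom)              # nothing below -856
  dg <- array(sample(0:35, 32, TRUE), c(4, 4, 2))
  dose <- doseVolume(dg, geom)
  prof <- profileValues(dosimetricProfile(ct, dose, fullMask(geom)))
  for (x in c(2, 5, 10, 20, 30)) {
    expect_identical(prof[[sprintf("V%g_minus_LAV%g", x, x)]], prof[[sprintf("V%g", x)]])
    expect_identical(prof[[sprintf("LAV%g", x)]], 0)
    expect_equal(prof[[sprintf("ratio_nonlav_%g", x)]],
                 prof[[sprintf("V%g_pct", x)]] / 100)
  }
  expect_identical(prof[["MLWED"]], prof[["MLD"]])
  expect_true(is.na(prof[["MED"]]))
})

test_that("a hand-built phantom reproduces the enumeration oracle exactly", {
  geom <- volumeGeometry(c(4, 4, 2), spacing = c(2, 2, 2.5))
  hu <- array(rep(c(-900, -700), 16), c(4, 4, 2))
  dg <- array(rep(c(0, 3, 12, 33), 8), c(4, 4, 2))
  lung <- array(c(rep(TRUE, 24), rep(FALSE, 8)), c(4, 4, 2))
  ct <- ctVolume(hu, geom); dose <- doseVolume(dg, geom)
  mask <- binaryMask(lung, geom)
  got <- profileValues(dosimetricProfile(ct, dose, mask))
  want <- oracleProfile(ct, dose, mask)
  expect_identical(got[names(want)], want)
})

test_that("a 31 Gy field on 16.1% of the healthy lung gives ratio 0.161", {
  # 1000 non-LAV voxels, 161 of them at 31 Gy: (V30-LAV30)/(TLV-LAV) = 0.161
  geom <- volumeGeometry(c(10, 10, 12))
  hu <- array(-700, c(10, 10, 12)); hu[, , 11:12] <- -950   # 200 LAV voxels
  dg <- array(0, c(10, 10, 12)); dg[seq_len(161)] <- 31
  prof <- profileValues(dosimetricProfile(ctVolume(hu, geom),
                                          doseVolume(dg, geom), fullMask(geom)))
  expect_equal(prof[["ratio_nonlav_30"]], 0.161)
})

test_that("random small grids reproduce the oracle bit-for-bit", {
  set.seed(41)
  for (rep in 1:15) {
    inst <- randomInstance()
    got <- profileValues(dosimetricProfile(inst$ct, inst$dose, inst$lung))
    want <- oracleProfile(inst$ct, inst$dose, inst$lung)
    expect_identical(got[names(want)], want)
  }
})

test_that("partition counts are conserved and volumes decrease in the cutoff", {
  set.seed(43)
  for (rep in 1:10) {
    inst <- randomInstance()
    lav <- segmentLav(inst$ct, inst$lung)
    nonLav <- binaryMask(voxels(inst$lung) & !voxels(lav), inst$geom)
    vv <- voxelVolumeCc(inst$geom)
    prev <- Inf
    for (x in c(2, 5, 10, 20, 30)) {
      cAll <- volumeAbove(inst$dose, inst$lung, x) / vv
      cNon <- volumeAbove(inst$dose, nonLav, x) / vv
      cLav <- volumeAbove(inst$dose, lav, x) / vv
      expect_identical(round(cAll), round(cNon) + round(cLav))
      expect_lte(cAll, prev)
      prev <- cAll
    }
  }
})

test_that("the volume-weighted mean decomposition holds to 1e-9 relative", {
  set.seed(47)
  for (rep in 1:10) {
    inst <- randomInstance()
    v <- profileValues(dosimetricProfile(inst$ct, inst$dose, inst$lung))
    if (is.na(v["MED"]) || is.na(v["MLWED"])) next
    lhs <- v[["MLD"]] * v[["TLV"]]
    rhs <- v[["MED"]] * v[["LAV"]] + v[["MLWED"]] * v[["TLV_minus_LAV"]]
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-12), 1e-9)
  }
})

test_that("a redundant resampling call leaves the profile invariant", {
  inst <- randomInstance()
  p1 <- profileValues(dosimetricProfile(inst$ct, inst$dose, inst$lung))
  p2 <- profileValues(dosimetricProfile(inst$ct,
                                        resampleDose(inst$dose, inst$geom),
                                        inst$lung))
  expect_identical(p1, p2)
})
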