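test_that("CT rescale reconstructs HU from stored values", {
  # stored 0 with slope 1 / intercept -1024 must read back as -1024 HU
  geom <- makeGeom(c(4, 3, 2))
  ct <- uniformCt(-1024, geom)
  d <- withr::local_tempdir()
  writeCtSeries(ct, d)
  ct2 <- readCtSeries(d)
  expect_true(all(voxels(ct2) == -1024))
})

test_that("CT series round-trips voxel-identically through DICOM", {
  geom <- volumeGeometry(c(6, 5, 4), spacing = c(1.5, 2, 2.5),
                         origin = c(-10, 5, 40))
  hu <- array(sample(-1024:2000, 120, TRUE), c(6, 5, 4))
  ct <- ctVolume(hu, geom)
  d <- withr::local_tempdir()
  writeCtSeries(ct, d)
  ct2 <- readCtSeries(d)
  expect_identical(voxels(ct2), voxels(ct))
  expect_true(sameGeometry(geometry(ct2), geometry(ct)))
})

test_that("slice files are sorted by position regardless of read order", {
  geom <- volumeGeometry(c(4, 4, 5), spacing = c(2, 2, 3))
  ct <- ctVolume(array(sample(-1000:500, 80, TRUE), c(4, 4, 5)), geom)
  d <- withr::local_tempdir()
  paths <- writeCtSeries(ct, d)
  set.seed(2)
  shuffled <- readCtSeries(sample(paths))
  ordered <- readCtSeries(paths)
  expect_identical(voxels(shuffled), voxels(ordered))
  expect_identical(voxels(shuffled), voxels(ct))
})

test_that("mixed series and non-uniform slice gaps are rejected", {
  geomA <- volumeGeometry(c(4, 4, 2), spacing = c(1, 1, 2))
  geomB <- volumeGeometry(c(4, 4, 1), spacing = c(1, 1, 2), origin = c(0, 0, 9))
  ctA <- uniformCt(0, geomA); ctB <- uniformCt(0, geomB)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  pA <- writeCtSeries(ctA, d1, seriesUid = "1.2.3.1")
  pB <- writeCtSeries(ctB, d2, seriesUid = "1.2.3.2")
  expect_error(readCtSeries(c(pA, pB)), "mixed series")
  # same series UID but a 2 mm then 7 mm gap
  pB2 <- writeCtSeries(ctB, withr::local_tempdir(), seriesUid = "1.2.3.1")
  expect_error(readCtSeries(c(pA, pB2)), "non-uniform")
})

test_that("RT Dose scaling arithmetic and round trip are exact", {
  geom <- makeGeom(c(3, 3, 3))
  # stored 1000 x scaling 0.001 -> 1 Gy
  dose <- uniformDose(1, geom)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRtDose(dose, f, scaling = 1e-3)
  expect_true(all(voxels(readRtDose(f)) == 1))
  # all-zero grid stays zero
  writeRtDose(uniformDose(0, geom), f)
  expect_true(all(voxels(readRtDose(f)) == 0))
  # quantized random grid is bit-identical
  gy <- array(round(runif(27, 0, 70) / 1e-3) * 1e-3, c(3, 3, 3))
  dv <- doseVolume(gy, geom)
  writeRtDose(dv, f)
  expect_identical(voxels(readRtDose(f)), voxels(dv))
})

test_that("structure sets round-trip through DICOM RT Structure Set", {
  ss <- structureSet(list(
    lung_R = list(list(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10), z = 2),
                  list(x = c(1, 5, 3), y = c(1, 1, 6), z = 4)),
    lung_L = list(list(x = c(-5, -1, -3), y = c(0, 0, 4), z = 2))))
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRtStruct(ss, f)
  ss2 <- readRtStruct(f)
  expect_equal(names(ss2@structures), c("lung_R", "lung_L"))
  expect_equal(ss2@structures$lung_R[[1]]$x, c(0, 10, 10, 0))
  expect_equal(ss2@structures$lung_R[[2]]$z, 4)
  expect_equal(ss2@structures$lung_L[[1]]$y, c(0, 0, 4))
})

test_that("pydicom independently reads what the fixture writer produces", {
  geom <- volumeGeometry(c(5, 4, 2), spacing = c(2, 2.5, 3), origin = c(1, 2, 3))
  hu <- array(sample(-1024:1000, 40, TRUE), c(5, 4, 2))
  ct <- ctVolume(hu, geom)
  d <- withr::local_tempdir()
  paths <- writeCtSeries(ct, d)
  out <- withr::local_tempfile(fileext = ".txt")
  script <- sprintf(paste0(
    "import pydicom, sys\n",
    "ds = pydicom.dcmread(r'%s')\n",
    "arr = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)\n",
    "vals = [int(v) for v in arr.flatten()]\n",
    "print(ds.Rows, ds.Columns, *vals)\n"), paths[1])
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  res <- system2("python", sf, stdout = TRUE)
  nums <- as.numeric(strsplit(res, " ")[[1]])
  expect_equal(nums[1:2], c(4, 5))                       # rows, columns
  # pydicom flattens row-major: rows of length Columns, i.e. x fastest
  expect_equal(nums[-(1:2)], as.vector(hu[, , 1]))
})
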