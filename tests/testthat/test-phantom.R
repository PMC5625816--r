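test_that("the same seed reproduces the phantom bit for bit", {
  cfg <- smallPhantomConfig()
  a <- generatePhantom(cfg, seed = 9)
  b <- generatePhantom(cfg, seed = 9)
  expect_identical(voxels(a$ct), voxels(b$ct))
  expect_identical(voxels(a$dose), voxels(b$dose))
  expect_identical(voxels(a$lung), voxels(b$lung))
  # and byte-for-byte through the fixture writer
  f1 <- withr::local_tempfile(fileext = ".nii.gz")
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(a$ct, f1); writeVolume(b$ct, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("phantom volumes are internally consistent", {
  ph <- generatePhantom(smallPhantomConfig(), seed = 3)
  expect_true(all(voxels(ph$dose) >= 0))
  expect_true(all(voxels(ph$ct) >= -1024 & voxels(ph$ct) <= 3071))
  expect_true(all(voxels(ph$ct) == round(voxels(ph$ct))))   # integer HU
  expect_gt(maskVolumeCc(ph$lung), 0)
})

test_that("zero emphysema target leaves only the noise tail below -856 HU", {
  cfg <- smallPhantomConfig(targetLavFraction = 0)
  fracs <- vapply(1:20, function(s) {
    ph <- generatePhantom(cfg, seed = s)
    maskVolumeCc(segmentLav(ph$ct, ph$lung)) / maskVolumeCc(ph$lung)
  }, numeric(1))
  expect_lt(mean(fracs), 0.02)
})

test_that("the default emphysema target is recovered by segmentation", {
  fracs <- vapply(1:40, function(s) {
    ph <- generatePhantom(smallPhantomConfig(), seed = 100 + s)
    maskVolumeCc(segmentLav(ph$ct, ph$lung)) / maskVolumeCc(ph$lung)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.103), 0.03)
})

test_that("simulated cohorts are deterministic in the master seed", {
  cfg <- smallPhantomConfig()
  a <- simulateCohort(n = 12, masterSeed = 5, phantom = cfg)
  b <- simulateCohort(n = 12, masterSeed = 5, phantom = cfg)
  expect_identical(a$profiles, b$profiles)
  expect_identical(records(a$cohort), records(b$cohort))
})

test_that("null outcome coefficients give the intercept's event rate", {
  nullCfg <- outcomeModelConfig(intercept = qlogis(0.27), coefPerSd = 0,
                                coefChemotherapy = 0, coefIld = 0)
  sim <- simulateCohort(n = 100, masterSeed = 77, phantom = smallPhantomConfig(),
                        outcome = nullCfg)
  rate <- mean(deriveEndpoint(records(sim$cohort)$rp_grade, 2))
  expect_lt(abs(rate - 0.27), 0.09)   # binomial 95% envelope at n = 100
})

test_that("grades respect the event split and a huge effect saturates AUC", {
  sim <- simulateCohort(n = 60, masterSeed = 13, phantom = smallPhantomConfig(),
                        outcome = outcomeModelConfig(coefPerSd = 50))
  g <- records(sim$cohort)$rp_grade
  ev <- deriveEndpoint(g, 2)
  expect_true(all(g[ev] >= 2))
  expect_true(all(g[!ev] <= 1))
  auc <- aucRank(sim$profiles$ratio_nonlav_30, ev)
  expect_gte(auc, 0.98)
})

test_that("fixture directories carry volumes, tables and a manifest", {
  d <- withr::local_tempdir()
  sim <- simulateCohort(n = 10, masterSeed = 21, phantom = smallPhantomConfig(),
                        dir = d, writeVolumes = TRUE)
  expect_true(file.exists(file.path(d, "cohort.csv")))
  expect_true(file.exists(file.path(d, "profiles.csv")))
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  expect_true(file.exists(file.path(d, "P001_ct.nii.gz")))
  man <- yaml::read_yaml(file.path(d, "manifest.yaml"))
  expect_equal(man$n, 10)
  expect_equal(man$nEvents,
               sum(deriveEndpoint(records(sim$cohort)$rp_grade, 2)))
  ct <- readCtVolume(file.path(d, "P001_ct.nii.gz"))
  ph <- generatePhantom(smallPhantomConfig(),
                        seed = EmphyDose:::.patientSeed(21, 1))
  expect_identical(voxels(ct), voxels(ph$ct))
})
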