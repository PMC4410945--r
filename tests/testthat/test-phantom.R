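test_that("generation is deterministic in the seed and truth is SNR-invariant", {
  a <- generatePhantom(smallSpec("3T", seed = 5))
  b <- generatePhantom(smallSpec("3T", seed = 5))
  expect_identical(SummarizedExperiment::assay(a, "signal"),
                   SummarizedExperiment::assay(b, "signal"))
  c2 <- generatePhantom(smallSpec("3T", seed = 6))
  expect_false(identical(SummarizedExperiment::assay(a, "signal"),
                         SummarizedExperiment::assay(c2, "signal")))
  # identical seed, different noise level: identical ground truth
  lo <- generatePhantom(smallSpec("3T", snr = 0.5, seed = 5))
  expect_equal(groundTruth(a), groundTruth(lo))
  expect_error(generatePhantom(smallSpec("3T", snr = -1)), "snr")
})

test_that("tissue geometry covers all classes with enough background", {
  g <- groundTruth(generatePhantom(smallSpec("3T", snr = Inf)))
  tab <- table(g$class)
  expect_setequal(names(tab), c("background", "CSF", "WM", "GM_inactive",
                                "GM_active", "GM_active_pv"))
  expect_gte(tab[["background"]] / sum(tab), 0.2)

  # with heterogeneity switched off, the partial-volume mixture is exact:
  # diluted responses, perfusion between grey and white matter, lower
  # effective M than pure active grey matter
  pm <- phantomParams(perfusionSD = 0, fMotorSD = 0, fHcSD = 0,
                      rMotorSD = 0, MRelSD = 0)
  gh <- groundTruth(generatePhantom(smallSpec("3T", snr = Inf, params = pm)))
  act <- gh$class == "GM_active"; pv <- gh$class == "GM_active_pv"
  basePV <- 0.5 * 1000 + 0.5 * 900
  expect_equal(unique(gh$dBOLD_motor[pv]),
               0.5 * 1000 * unique(gh$dBOLD_motor[act]) / basePV)
  expect_equal(unique(gh$perfusion[pv]), 0.5 * 10 + 0.5 * 3)
  expect_lt(mean(gh$M[pv]), mean(gh$M[act]))
  expect_true(all(gh$f_motor[pv] < unique(gh$f_motor[act])))
})

test_that("a noise-free phantom is recovered through the pipeline to < 0.1%", {
  ph <- generatePhantom(phantomSpec("3T", snr = Inf, seed = 3))
  out <- suppressWarnings(runSubjectPipeline(ph))
  ref <- subjectEstimates(out$kept, trueSummaries(ph), fieldPreset("3T"))
  expect_lt(abs(out$result@M - ref@M) / ref@M, 1e-3)
  expect_lt(abs(out$result@rMotor - ref@rMotor) / ref@rMotor, 1e-3)
  # per-voxel responses match ground truth wherever defined
  g <- groundTruth(ph)
  act <- which(g$class == "GM_active")
  s <- out$summaries
  expect_equal(s$dBOLD_motor[act], g$dBOLD_motor[act], tolerance = 1e-8)
  expect_equal(s$f_motor[act], g$f_motor[act], tolerance = 1e-6)
  expect_equal(s$f_hc[act], g$f_hc[act], tolerance = 1e-6)
})

test_that("measured ASL SNR tracks the target and preserves the field ordering", {
  snrs <- vapply(c("1.5T", "3T", "7T"), function(f) {
    ph <- generatePhantom(phantomSpec(f, seed = 42))
    runSubjectPipeline(ph)$snr
  }, numeric(1))
  targets <- vapply(c("1.5T", "3T", "7T"), snrPreset, numeric(1))
  expect_true(all(abs(snrs / targets - 1) < 0.1))
  expect_true(all(diff(snrs) > 0))
})

test_that("phantoms round-trip exactly through the NIfTI + sidecar writer", {
  dir <- file.path(tempdir(), "boldcal-fixture")
  ph <- generatePhantom(smallSpec("3T", seed = 9))
  writePhantom(ph, dir)
  back <- readPhantom(dir)
  expect_equal(SummarizedExperiment::assay(back, "signal"),
               SummarizedExperiment::assay(ph, "signal"),
               ignore_attr = TRUE)
  # header voxel sizes as configured
  img <- RNifti::readNifti(file.path(dir, "asl_bold.nii.gz"))
  expect_equal(RNifti::pixdim(img)[1:3], c(4.1, 4.1, 5.0),
               tolerance = 1e-6)  # header stores float32
  # truth table has one row per voxel and the paradigm survives
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), prod(c(12, 12, 2)))
  expect_equal(groundTruth(back)$M, groundTruth(ph)$M)
  spec2 <- S4Vectors::metadata(back)$spec
  expect_equal(spec2@paradigm@motorBlocks,
               S4Vectors::metadata(ph)$spec@paradigm@motorBlocks)
  unlink(dir, recursive = TRUE)
})

test_that("baseline difference volume isolates the perfusion amplitude", {
  ph <- generatePhantom(smallSpec("3T", snr = Inf, seed = 2))
  d <- baselineDifferenceVolume(ph)
  g <- groundTruth(ph)
  gm <- g$class == "GM_inactive"
  expect_equal(d[gm], g$perfusion[gm], tolerance = 1e-9)
  expect_equal(d[g$class == "background"], rep(0, sum(g$class == "background")))
})
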