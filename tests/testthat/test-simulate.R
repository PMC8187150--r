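test_that("simulation is deterministic and respects the [0,1] range", {
  cfg <- simulationConfig(nBackgroundProbes = 300,
    disorders = list(list(disorderId = "D1", nSignatureProbes = 30,
                          delta = 0.2, nCases = 5)),
    nControls = 10, technicalSd = 0.02, replicatePairs = 2, seed = 99)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(betaValues(a), betaValues(b))
  v <- betaValues(a)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  # truth labels consistent with sheet roles
  tt <- truthTable(a)
  sheet <- sampleSheet(a)
  expect_identical(tt$role, sheet$role[match(tt$sample_id, sheet$sample_id)])
})

test_that("a zero-disorder config yields controls only", {
  cfg <- simulationConfig(nBackgroundProbes = 50, disorders = list(),
                          nControls = 10, seed = 3)
  co <- simulateCohort(cfg)
  expect_equal(ncol(co), 10)
  expect_true(all(sampleSheet(co)$role == "reference_control"))
  expect_true(all(truthTable(co)$disorder_id == ""))
})

test_that("planted delta is recovered by group means", {
  cfg <- simulationConfig(nBackgroundProbes = 500,
    disorders = list(list(disorderId = "D1", nSignatureProbes = 100,
                          delta = 0.2, nCases = 20)),
    nControls = 50, technicalSd = 0.01, seed = 17)
  co <- simulateCohort(cfg)
  ann <- probeAnnotation(co)
  sheet <- sampleSheet(co)
  sig <- ann$probe_id[ann$gene == "GENE_D1"]
  b <- betaValues(co)
  cases <- sheet$sample_id[sheet$role == "reference_case"]
  ctrls <- sheet$sample_id[sheet$role == "reference_control"]
  emp <- mean(b[sig, cases]) - mean(b[sig, ctrls])
  expect_equal(emp, 0.2, tolerance = 0.01)
})

test_that("mixMosaic is the exact linear mixture", {
  case <- c(0.9, 0.8, 0.7); ctrl <- c(0.5, 0.5, 0.5)
  expect_identical(mixMosaic(case, ctrl, 0), ctrl)
  expect_identical(mixMosaic(case, ctrl, 1), case)
  expect_equal(mixMosaic(0.9, 0.5, 0.2), 0.58)
  expect_error(mixMosaic(case, ctrl, 1.2), class = "episcreen_range_error")
  expect_error(mixMosaic(case, ctrl[1:2], 0.5), class = "episcreen_format_error")
  # signature-mean displacement proportional to fraction (exact, pre-noise)
  fr <- seq(0, 1, 0.1)
  disp <- vapply(fr, function(f) mean(mixMosaic(case, ctrl, f) - ctrl), 0)
  expect_equal(disp, fr * mean(case - ctrl), tolerance = 1e-12)
})

test_that("technical noise has the configured SD, clips, and reproduces", {
  p <- rep(0.5, 10000)
  out1 <- applyTechnicalNoise(p, 0.01, seed = 4)
  out2 <- applyTechnicalNoise(p, 0.01, seed = 4)
  expect_identical(out1, out2)
  expect_equal(sd(out1 - p), 0.01, tolerance = 0.1)  # within 10% of nominal
  expect_identical(applyTechnicalNoise(p, 0, seed = 4), p)
  hi <- rep(0.999, 1000)
  noisy <- applyTechnicalNoise(hi, 0.05, seed = 1)
  expect_true(all(noisy >= 0 & noisy <= 1))
  expect_error(applyTechnicalNoise(p, -1, seed = 1),
               class = "episcreen_range_error")
})

test_that("replicate pairs share biology and converge as noise vanishes", {
  mk <- function(sd) simulateCohort(simulationConfig(
    nBackgroundProbes = 400,
    disorders = list(list(disorderId = "D1", nSignatureProbes = 40,
                          delta = 0.2, nCases = 5)),
    nControls = 10, technicalSd = sd, replicatePairs = 5, seed = 31))
  for (sd in c(0.02, 0.002)) {
    co <- mk(sd)
    b <- betaValues(co)
    sheet <- sampleSheet(co)
    reps <- sheet[sheet$role == "replicate", ]
    r <- vapply(seq_len(nrow(reps)), function(i)
      cor(b[, reps$sample_id[i]], b[, reps$replicate_of[i]]), 0)
    if (sd == 0.02) r_wide <- mean(r) else r_tight <- mean(r)
  }
  expect_gt(r_tight, r_wide)
  expect_gt(r_tight, 0.999)
})

test_that("mosaic and dilution samples land between case and control profiles", {
  cfg <- simulationConfig(nBackgroundProbes = 200,
    disorders = list(list(disorderId = "D1", nSignatureProbes = 50,
                          delta = 0.2, nCases = 8)),
    nControls = 15, technicalSd = 0.005,
    mosaicSamples = list(list(disorderId = "D1", fraction = 0.5)),
    dilutionSamples = list(list(disorderId = "D1", dosageFactor = 0.5)),
    seed = 8)
  co <- simulateCohort(cfg)
  ann <- probeAnnotation(co)
  sig <- ann$probe_id[ann$gene == "GENE_D1"]
  b <- betaValues(co)
  sheet <- sampleSheet(co)
  ctrls <- sheet$sample_id[sheet$role == "reference_control"]
  shift <- function(id) mean(b[sig, id]) - mean(b[sig, ctrls])
  # both 50% constructs shift the signature mean by about half the delta
  expect_equal(shift("mosaic_D1_01"), 0.1, tolerance = 0.02)
  expect_equal(shift("dilut_D1_01"), 0.1, tolerance = 0.02)
})
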