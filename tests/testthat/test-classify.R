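test_that("Platt fit recovers symmetry, degeneracy, and antisymmetry", {
  # perfectly symmetric, balanced, separable decisions
  d <- c(rep(-1, 20), rep(1, 20))
  lab <- c(rep(FALSE, 20), rep(TRUE, 20))
  pp <- fitPlatt(d, lab)
  expect_lt(pp@A, 0)                               # probability increases with f
  expect_equal(mvpFromDecision(0, pp), 0.5, tolerance = 0.01)
  expect_lt(abs(pp@B), 0.05)

  # identical decisions for both classes: no information in f
  pp2 <- fitPlatt(rep(0.5, 40), lab)
  # fitted probability equals the smoothed class prior everywhere
  tbar <- mean(c(rep(1 / 22, 20), rep(21 / 22, 20)))
  expect_equal(mvpFromDecision(0.5, pp2), tbar, tolerance = 0.01)

  # swapping the labels flips the slope's sign
  pp3 <- fitPlatt(d, !lab)
  expect_equal(pp3@A, -pp@A, tolerance = 1e-4)

  expect_error(fitPlatt(d, rep(TRUE, 40)),
               class = "episcreen_calibration_error")
})

test_that("MVP link matches the closed form and saturates without overflow", {
  pp <- methods::new("PlattParams", A = -2, B = 0)
  expect_identical(mvpFromDecision(0, pp), 0.5)
  expect_gt(mvpFromDecision(10, pp), 0.999)
  pp2 <- methods::new("PlattParams", A = -1.5, B = 0.2)
  expect_equal(mvpFromDecision(1.0, pp2), 1 / (1 + exp(-1.3)), tolerance = 1e-12)
  # strict monotonicity in f when A < 0
  f <- seq(-5, 5, 0.25)
  expect_true(all(diff(mvpFromDecision(f, pp)) > 0))
  # extreme decisions stay inside [0,1]
  expect_true(all(mvpFromDecision(c(-1e4, 1e4), pp) >= 0 &
                  mvpFromDecision(c(-1e4, 1e4), pp) <= 1))
})

test_that("threshold banding is strict outside, closed inside", {
  th <- thresholdConfig()
  expect_identical(callCategory(0.9, th), "positive")
  expect_identical(callCategory(0.05, th), "negative")
  expect_identical(callCategory(0.2, th), "inconclusive")
  expect_identical(callCategory(0.5, th), "inconclusive")
  expect_identical(callCategory(0.1, th), "inconclusive")
  expect_error(callCategory(1.2, th), class = "episcreen_range_error")
  expect_error(thresholdConfig(tPos = 0.1, tNeg = 0.5))
})

test_that("one-vs-rest training separates disorders on held-in references", {
  panel <- smallPanel()
  sheet <- sampleSheet(panel$cohort)
  sc <- scoreCohort(panel$clfs, panel$cohort)
  sc$role <- sheet$role[match(sc$sample_id, sheet$sample_id)]
  sc$lab <- sheet$disorder_label[match(sc$sample_id, sheet$sample_id)]
  own <- sc[sc$role == "reference_case" & sc$lab == sc$disorder_id, ]
  other <- sc[sc$role == "reference_case" & sc$lab != sc$disorder_id, ]
  ctrl <- sc[sc$role == "reference_control", ]
  expect_true(all(own$mvp > 0.5))
  expect_true(all(other$mvp < 0.1))
  expect_true(all(ctrl$mvp < 0.1))
})

test_that("training errors on degenerate class structure", {
  panel <- smallPanel()
  co <- panel$cohort
  sheet <- sampleSheet(co)
  onlyCases <- co[, sheet$role == "reference_case" & sheet$disorder_label == "DA"]
  expect_error(trainClassifiers(onlyCases, panel$sigs["DA"], cvFolds = 3),
               class = "episcreen_training_error")
  expect_error(trainClassifiers(co, panel$sigs["DA"], cvFolds = 50),
               class = "episcreen_fold_error")
})

test_that("permuted labels yield no class separation", {
  cfg <- simulationConfig(nBackgroundProbes = 500,
    disorders = list(list(disorderId = "D1", nSignatureProbes = 50,
                          delta = 0.15, nCases = 15)),
    nControls = 30, technicalSd = 0.01, seed = 71)
  co <- simulateCohort(cfg)
  sig <- selectSignatureProbes(co, "D1")
  sheet <- sampleSheet(co)
  # hold out case-like and control-like samples, permute the training labels
  caselike <- utils::tail(sheet$sample_id[sheet$role == "reference_case"], 5)
  ctrllike <- utils::tail(sheet$sample_id[sheet$role == "reference_control"], 10)
  held <- c(caselike, ctrllike)
  base <- sheet[!sheet$sample_id %in% held, 1:8]
  gaps <- vapply(1:20, function(ps) {
    set.seed(ps)
    perm <- sample(nrow(base))
    trainSheet <- base
    trainSheet$role <- base$role[perm]
    trainSheet$disorder_label <- base$disorder_label[perm]
    co2 <- validateCohort(betaValues(co)[, trainSheet$sample_id], trainSheet)
    clf <- trainClassifiers(co2, list(sig), cvFolds = 5, seed = 2)
    sc <- scoreCohort(clf, co, held)
    mean(sc$mvp[sc$sample_id %in% caselike]) -
      mean(sc$mvp[sc$sample_id %in% ctrllike])
  }, 0)
  # permuted training carries no class signal: gaps centre on zero
  expect_lt(abs(mean(gaps)), 0.1)
})

test_that("scoring handles coverage failure per disorder, not per sample", {
  panel <- smallPanel()
  v <- betaValues(panel$cohort)[, "case_DA_001"]
  # blank out 95% of DA's signature -> DA flagged, others still scored
  daProbes <- probeIds(panel$sigs$DA)
  v[daProbes[seq_len(ceiling(0.95 * length(daProbes)))]] <- NA
  sc <- scoreSample(panel$kdb, v)
  expect_identical(sc$category[sc$disorder_id == "DA"], "coverage_error")
  expect_false(sc$coverage_ok[sc$disorder_id == "DA"])
  expect_true(all(sc$coverage_ok[sc$disorder_id != "DA"]))
  # a small number of missing probes is imputed from the control reference
  v2 <- betaValues(panel$cohort)[, "case_DA_001"]
  v2[daProbes[1:3]] <- NA
  sc2 <- scoreSample(panel$kdb, v2)
  expect_true(sc2$coverage_ok[sc2$disorder_id == "DA"])
  expect_gt(sc2$mvp[sc2$disorder_id == "DA"], 0.5)
  # the exact control-mean profile scores negative everywhere
  ref <- controlReference(panel$kdb)
  prof <- stats::setNames(ref$mean, ref$probe_id)
  sc3 <- scoreSample(panel$kdb, prof)
  expect_true(all(sc3$mvp < 0.1))
})

test_that("MVP is monotone in mosaic fraction and linear in dosage", {
  panel <- smallPanel()
  for (d in names(panel$clfs)) {
    pr <- panelProfiles(panel, d)
    clf <- panel$clfs[[d]]
    fr <- seq(0, 1, 0.1)
    mvp <- vapply(fr, function(f) {
      mix <- mixMosaic(pr$case, pr$control, f)
      scoreSample(list(clf), mix)$mvp
    }, 0)
    expect_true(all(diff(mvp) >= 0))
    # dosage 0.5: decision value at the exact midpoint (linearity)
    dAt <- function(v) scoreSample(list(clf), v)$decision
    half <- pr$control + 0.5 * (pr$case - pr$control)
    mid <- (dAt(pr$case) + dAt(pr$control)) / 2
    expect_equal(dAt(half), mid, tolerance = 1e-9)
  }
})
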