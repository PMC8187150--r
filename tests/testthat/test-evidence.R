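test_that("classical MDS preserves simple geometries", {
  # three mutually equidistant samples embed as an equilateral triangle
  X <- diag(3) * sqrt(2) / 2
  colnames(X) <- c("a", "b", "c"); rownames(X) <- c("p1", "p2", "p3")
  emb <- mdsEmbed(X)
  dEmb <- as.numeric(dist(emb))
  expect_lt(max(dEmb) - min(dEmb), 1e-6)
  # a duplicated sample lands on coincident coordinates
  X2 <- cbind(X, a2 = X[, "a"])
  emb2 <- mdsEmbed(X2)
  expect_equal(unname(emb2["a", ]), unname(emb2["a2", ]), tolerance = 1e-9)
  expect_error(mdsEmbed(X[, 1:2]), class = "episcreen_embedding_error")
})

test_that("embedding places a case-like test sample with the cases", {
  panel <- smallPanel()
  sig <- panel$sigs$DA
  sheet <- sampleSheet(panel$cohort)
  caseIds <- sheet$sample_id[sheet$disorder_label == "DA"]
  ctrlIds <- sheet$sample_id[sheet$role == "reference_control"]
  b <- betaValues(panel$cohort)
  testId <- caseIds[1]
  refCases <- caseIds[-1]
  X <- b[probeIds(sig), c(refCases, ctrlIds, testId)]
  emb <- mdsEmbed(X, caseIds = refCases)
  cc <- colMeans(emb[refCases, , drop = FALSE])
  kc <- colMeans(emb[ctrlIds, , drop = FALSE])
  expect_lt(sum((emb[testId, ] - cc)^2), sum((emb[testId, ] - kc)^2))
  # sign convention: case centroid on the positive first axis
  expect_gt(cc[1], 0)
  # rank order of the large pairwise distances is preserved (the small
  # within-group distances are noise-dominated and carry no group signal)
  din <- as.numeric(dist(t(X)))
  dout <- as.numeric(dist(emb))
  big <- din > stats::median(din)
  expect_gt(cor(din[big], dout[big], method = "spearman"), 0.9)
})

test_that("cluster assignment calls cases, controls, and mosaics correctly", {
  panel <- smallPanel()
  sig <- panel$sigs$DA
  co <- panel$cohort
  sheet <- sampleSheet(co)
  caseIds <- sheet$sample_id[sheet$disorder_label == "DA"]

  evCase <- clusterAssign(co, sig, caseIds[1])
  expect_identical(evCase@call, "with_cases")
  expect_gt(evCase@margin, 0.2)

  evCtrl <- clusterAssign(co, sig, "ctrl_001")
  expect_identical(evCtrl@call, "with_controls")
  expect_lt(evCtrl@margin, -0.2)

  # a 50/50 mosaic of the reference mean profiles plots between the groups
  pr <- panelProfiles(panel, "DA")
  mixed <- mixMosaic(pr$case, pr$control, 0.5)
  b <- betaValues(co)
  probes <- probeIds(sig)
  b2 <- cbind(b, mix50 = NA)
  b2[probes, "mix50"] <- mixed
  sheet2 <- rbind(sheet[, 1:8], tinySheet("mix50"))
  co2 <- validateCohort(b2, sheet2)
  evMix <- clusterAssign(co2, sig, "mix50")
  expect_identical(evMix@call, "intermediate")
  expect_lt(abs(evMix@margin), 0.2)
})

test_that("cluster assignment is invariant to sample and probe order", {
  panel <- smallPanel()
  sig <- panel$sigs$DB
  co <- panel$cohort
  ev1 <- clusterAssign(co, sig, "case_DB_002")
  set.seed(9)
  coShuf <- co[sample(nrow(co)), sample(ncol(co))]
  ev2 <- clusterAssign(coShuf, sig, "case_DB_002")
  expect_identical(ev2@call, ev1@call)
  expect_equal(ev2@margin, ev1@margin, tolerance = 1e-9)
})

test_that("margin grows monotonically with mosaic fraction", {
  panel <- smallPanel()
  sig <- panel$sigs$DC
  pr <- panelProfiles(panel, "DC")
  co <- panel$cohort
  b <- betaValues(co)
  sheet <- sampleSheet(co)
  margins <- vapply(seq(0, 1, 0.25), function(f) {
    mixed <- mixMosaic(pr$case, pr$control, f)
    b2 <- cbind(b, mix = NA)
    b2[probeIds(sig), "mix"] <- mixed
    co2 <- validateCohort(b2, rbind(sheet[, 1:8], tinySheet("mix")))
    clusterAssign(co2, sig, "mix")@margin
  }, 0)
  expect_true(all(diff(margins) >= -1e-9))
})

test_that("degenerate references trigger a separability error", {
  # cases and controls share one tight cloud; a far-away test point makes the
  # k=2 cut isolate the test sample, leaving both reference groups together
  set.seed(2)
  n <- 8
  X <- matrix(0.5 + rnorm(20 * 2 * n, 0, 0.001), 20, 2 * n)
  colnames(X) <- c(sprintf("case_%d", 1:n), sprintf("ctrl_%d", 1:n))
  rownames(X) <- sprintf("cg%08d", 1:20)
  X <- cbind(X, far = rep(0.99, 20))
  sheet <- tinySheet(colnames(X),
                     roles = c(rep("reference_case", n),
                               rep("reference_control", n), "test"),
                     disorders = c(rep("DX", n), rep("", n + 1)))
  co <- validateCohort(X, sheet)
  sig <- methods::new("Episignature", disorderId = "DX", version = "1",
                      probeIds = rownames(X), controlMean = rep(0.5, 20),
                      caseMean = rep(0.5, 20), delta = rep(0, 20),
                      selectionStat = rep(1, 20), granularity = "gene",
                      sensitivityClass = "moderate", nCases = as.integer(n),
                      nControls = as.integer(n))
  expect_error(clusterAssign(co, sig, "far"),
               class = "episcreen_separability_error")
})
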