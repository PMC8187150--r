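mkScores <- function(mvp, ids = paste0("D", seq_along(mvp))) {
  data.frame(disorder_id = ids, decision = stats::qlogis(pmin(pmax(mvp, 1e-6), 1 - 1e-6)),
             mvp = mvp, category = callCategory(mvp),
             coverage = 1, coverage_ok = TRUE, stringsAsFactors = FALSE)
}

mkEvidence <- function(disorder, call, margin,
                       assignment = if (margin >= 0) "case_side" else "control_side") {
  methods::new("ClusterEvidence", disorderId = disorder, sampleId = "S1",
               embedding = matrix(0, 1, 2), assignment = assignment,
               margin = margin, marginFloor = 0.2, call = call)
}

mkLocus <- function(call, locus = "DMR1") {
  assessLocus(switch(call, normal = 0.5, hypomethylated = 0.05,
                     hypermethylated = 0.95, indeterminate = 0.41),
              0.5, 0.02, "imprinted_dmr", locusName = locus)
}

test_that("report composition follows the evidence-combination rules", {
  # confirmed positive
  r1 <- composeReport(mkScores(c(0.95, 0.02)),
                      list(mkEvidence("D1", "with_cases", 0.8)),
                      sampleId = "S1")
  expect_identical(finalStatus(r1), "positive")
  expect_identical(matchedDisorders(r1), "D1")

  # positive score but clusters with controls -> inconclusive, flagged
  r2 <- composeReport(mkScores(c(0.95, 0.02)),
                      list(mkEvidence("D1", "with_controls", -0.5)),
                      sampleId = "S1")
  expect_identical(finalStatus(r2), "inconclusive")
  expect_match(reviewFlags(r2), "discordant", all = FALSE)

  # inconclusive-band score, everything else negative
  r3 <- composeReport(mkScores(c(0.2, 0.02)), sampleId = "S1")
  expect_identical(finalStatus(r3), "inconclusive")
  expect_match(reviewFlags(r3), "inconclusive band", all = FALSE)

  # all scores negative, clustering plots the sample between the groups
  r4 <- composeReport(mkScores(c(0.03, 0.01)),
                      list(mkEvidence("D1", "intermediate", 0.1)),
                      sampleId = "S1")
  expect_identical(finalStatus(r4), "inconclusive")
  expect_match(reviewFlags(r4), "between", all = FALSE)

  # clean negative
  r5 <- composeReport(mkScores(c(0.03, 0.01)),
                      list(mkEvidence("D1", "with_controls", -0.9)),
                      mkLocus("normal"), sampleId = "S1")
  expect_identical(finalStatus(r5), "negative")
  expect_length(matchedDisorders(r5), 0)

  # locus screening drives its own positives
  r6 <- composeReport(mkScores(c(0.03, 0.01)),
                      list(mkEvidence("D1", "with_controls", -0.9)),
                      mkLocus("hypomethylated"), sampleId = "S1")
  expect_identical(finalStatus(r6), "positive")
  expect_identical(matchedDisorders(r6), "DMR1")

  # evidence for a different sample is refused
  expect_error(composeReport(mkScores(0.9),
                             list(mkEvidence("D1", "with_cases", 0.8)),
                             sampleId = "OTHER"),
               class = "episcreen_composition_error")
})

test_that("every evidence combination maps to exactly one status", {
  bands <- c(0.03, 0.2, 0.95)              # negative / band / positive score
  calls <- c("with_cases", "with_controls", "intermediate", "none")
  locus <- c("normal", "hypomethylated", "indeterminate", "none")
  grid <- expand.grid(mvp = bands, cl = calls, lc = locus,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    ev <- if (grid$cl[i] == "none") list()
          else list(mkEvidence("D1", grid$cl[i],
                               switch(grid$cl[i], with_cases = 0.8,
                                      with_controls = -0.8, intermediate = 0.1)))
    lr <- if (grid$lc[i] == "none") NULL else mkLocus(grid$lc[i])
    r <- composeReport(mkScores(grid$mvp[i], "D1"), ev, lr, sampleId = "S1")
    expect_true(finalStatus(r) %in% c("positive", "negative", "inconclusive"))
    expect_identical(finalStatus(r) == "positive",
                     length(matchedDisorders(r)) > 0)
  }
})

test_that("report content is deterministic apart from the timestamp", {
  a <- composeReport(mkScores(c(0.95, 0.02)),
                     list(mkEvidence("D1", "with_cases", 0.8)), sampleId = "S1")
  b <- composeReport(mkScores(c(0.95, 0.02)),
                     list(mkEvidence("D1", "with_cases", 0.8)), sampleId = "S1")
  la <- reportAsList(a); lb <- reportAsList(b)
  la$timestamp <- lb$timestamp <- NULL
  expect_identical(la, lb)
})

test_that("replicate concordance applies the score tolerance and categories", {
  r1 <- mkScores(c(0.93, 0.01, 0.02), c("DA", "DB", "DC"))
  r2 <- mkScores(c(0.90, 0.02, 0.01), c("DA", "DB", "DC"))
  cc <- checkReplicateConcordance(r1, r2)
  expect_true(cc$concordant)
  expect_equal(cc$maxDelta, 0.03)
  expect_true(checkReplicateConcordance(r1, r1)$concordant)
  # 0.52 vs 0.45: delta 0.07 above tolerance and the category flips
  r3 <- mkScores(c(0.52, 0.01, 0.02), c("DA", "DB", "DC"))
  r4 <- mkScores(c(0.45, 0.01, 0.02), c("DA", "DB", "DC"))
  cd <- checkReplicateConcordance(r3, r4)
  expect_false(cd$concordant)
  expect_identical(cd$offenders, "DA")
  expect_error(checkReplicateConcordance(r1, mkScores(0.5, "DX")),
               class = "episcreen_comparison_error")
})

mkReport <- function(id, status, cohort) {
  methods::new("EpisignReport", sampleId = id, kdbVersion = "1",
               finalStatus = status,
               matchedDisorders = if (status == "positive") "D1" else character(),
               scores = data.frame(), clusterEvidence = list(),
               locusResults = data.frame(), reviewFlags = character(),
               timestamp = Sys.time())
}

test_that("cohort summaries count and percentage outcomes per cohort tag", {
  statuses <- c(rep("positive", 3), rep("negative", 5), rep("inconclusive", 2))
  reports <- lapply(seq_along(statuses), function(i)
    mkReport(paste0("s", i), statuses[i]))
  sheet <- tinySheet(paste0("s", 1:10),
                     cohort = rep(c("targeted", "screening"), each = 5))
  out <- summarizeCohort(reports, sheet)
  ov <- out[out$cohort == "overall", ]
  expect_equal(ov$positive, 3)
  expect_equal(ov$pct_positive, 30.0)
  expect_equal(ov$pct_positive + ov$pct_negative + ov$pct_inconclusive,
               100, tolerance = 0.1)
  expect_equal(nrow(out), 3)
  # empty input: empty table, no division by zero
  expect_equal(nrow(summarizeCohort(list())), 0)
})

test_that("half-up rounding matches printed-percentage conventions", {
  expect_equal(percentHalfUp(100 * 48 / 136), 35.3)
  expect_equal(percentHalfUp(100 * 8 / 71), 11.3)
  expect_equal(percentHalfUp(100 * 4 / 207), 1.9)
  expect_equal(percentHalfUp(100 * 134 / 136), 98.5)
  expect_equal(percentHalfUp(27.55), 27.6)   # half rounds up, not to even
  expect_equal(percentHalfUp(27.45), 27.5)
})
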