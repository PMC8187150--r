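# One-vs-rest linear SVM classifiers with Platt-calibrated MVP scores.
#
# For each disorder the positive class is its reference cases and the
# negative class is every other disorder's cases plus all controls. The
# maximum-margin fit is delegated to e1071::svm (linear kernel, C = 1,
# balanced class weights, no rescaling); weights and bias are extracted so a
# stored classifier scores by a plain dot product. Platt parameters are
# fitted on out-of-fold decision values from stratified cross-validation to
# avoid calibration optimism, then the final weights are refitted on all
# data.

#' Construct reporting thresholds
#'
#' @param tPos positive threshold: scores strictly above are positive
#'   (default 0.5).
#' @param tNeg negative threshold: scores strictly below are negative
#'   (default 0.1); the closed band [tNeg, tPos] is inconclusive.
#' @param replicateTol maximum MVP difference tolerated between technical
#'   replicates (default 0.05).
#' @return a \linkS4class{ThresholdConfig}.
#' @export
thresholdConfig <- function(tPos = 0.5, tNeg = 0.1, replicateTol = 0.05) {
  methods::new("ThresholdConfig", tPos = tPos, tNeg = tNeg,
               replicateTol = replicateTol)
}

#' Fit Platt calibration parameters
#'
#' Maximizes the Bernoulli likelihood of the logistic link
#' \eqn{P(f) = 1/(1 + exp(A f + B))} over decision values \eqn{f}, with
#' Platt's smoothed targets \eqn{t_+ = (N_+ + 1)/(N_+ + 2)} and
#' \eqn{t_- = 1/(N_- + 2)} as regularization against overconfidence on
#' separable data. \code{A} comes out negative whenever the positive class
#' has the larger decision values.
#'
#' @param decisions numeric decision values.
#' @param labels logical (TRUE = positive) or a vector coercible to it via
#'   \code{labels == "pos"}.
#' @return a \linkS4class{PlattParams}.
#' @export
fitPlatt <- function(decisions, labels) {
  if (!is.logical(labels)) labels <- labels == "pos"
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    .stopc("episcreen_calibration_error",
           "both classes required for calibration (pos=%d, neg=%d)", np, nn)
  t <- ifelse(labels, (np + 1) / (np + 2), 1 / (nn + 2))
  f <- as.numeric(decisions)
  log1pexp <- function(z) ifelse(z > 35, z, log1p(exp(pmin(z, 35))))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    sum(log1pexp(z) - (1 - t) * z)
  }
  grad <- function(par) {
    z <- par[1] * f + par[2]
    r <- t - 1 / (1 + exp(pmin(pmax(z, -35), 35)))  # t - p
    c(sum(r * f), sum(r))
  }
  init <- c(0, log((nn + 1) / (np + 1)))
  fit <- stats::optim(init, nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  methods::new("PlattParams", A = fit$par[1], B = fit$par[2])
}

#' Map a decision value to an MVP score
#'
#' \eqn{MVP = 1/(1 + exp(A f + B))}, evaluated through the numerically
#' guarded logistic so arbitrarily large |f| saturate to the asymptotes
#' instead of overflowing.
#'
#' @param f decision value(s).
#' @param platt a \linkS4class{PlattParams}.
#' @return MVP score(s) in [0,1].
#' @export
mvpFromDecision <- function(f, platt) {
  stats::plogis(-(platt@A * f + platt@B))
}

#' Map an MVP score to a reporting category
#'
#' Scores strictly above \code{tPos} are \code{"positive"}, strictly below
#' \code{tNeg} \code{"negative"}, and the closed band between them
#' \code{"inconclusive"} (so the boundary values 0.1 and 0.5 themselves are
#' inconclusive).
#'
#' @param score MVP score(s) in [0,1].
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @return character vector of categories.
#' @export
callCategory <- function(score, thresholds = thresholdConfig()) {
  if (any(is.na(score) | score < 0 | score > 1))
    .stopc("episcreen_range_error", "MVP score outside [0,1]")
  ifelse(score > thresholds@tPos, "positive",
         ifelse(score < thresholds@tNeg, "negative", "inconclusive"))
}

# fit a linear SVM and extract (weights, bias) oriented so the positive
# class has the larger decision values
.linearSVM <- function(X, pos) {
  y <- factor(ifelse(pos, "case", "other"), levels = c("case", "other"))
  n <- length(pos)
  cw <- c(case = n / (2 * sum(pos)), other = n / (2 * sum(!pos)))
  m <- e1071::svm(x = X, y = y, kernel = "linear", cost = 1, scale = FALSE,
                  class.weights = cw)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  d <- drop(X %*% w) + b
  if (mean(d[pos]) < mean(d[!pos])) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

.stratifiedFolds <- function(pos, k, seed) {
  fold <- integer(length(pos))
  .withSeed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(pos == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Train one-vs-rest classifiers for a set of signatures
#'
#' For each signature: restrict the beta matrix to the signature probes
#' (missing values mean-imputed from the reference controls), fit the linear
#' maximum-margin classifier of that disorder's cases against all other
#' cases plus controls, collect out-of-fold decision values from stratified
#' cross-validation, fit Platt parameters on them, and refit the final
#' weights on all reference samples.
#'
#' @param cohort a \linkS4class{MethylCohort} with reference samples.
#' @param signatures list of \linkS4class{Episignature}.
#' @param cvFolds stratified cross-validation folds for calibration
#'   (default 10).
#' @param seed integer seed for fold assignment.
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @param kdbVersion version string recorded in training metadata.
#' @return named list of \linkS4class{TrainedClassifier}.
#' @export
trainClassifiers <- function(cohort, signatures, cvFolds = 10, seed = 1,
                             thresholds = thresholdConfig(),
                             kdbVersion = "1") {
  cohort <- validateCohort(cohort)
  sheet <- sampleSheet(cohort)
  ref <- sheet$role %in% c("reference_case", "reference_control")
  refSheet <- sheet[ref, , drop = FALSE]
  b <- betaValues(cohort)[, refSheet$sample_id, drop = FALSE]
  ctrlIds <- refSheet$sample_id[refSheet$role == "reference_control"]
  out <- list()
  for (sig in signatures) {
    did <- disorderId(sig)
    probes <- intersect(probeIds(sig), rownames(b))
    if (length(probes) < length(probeIds(sig)))
      .stopc("episcreen_integrity_error",
             "cohort lacks %d signature probe(s) for %s",
             length(probeIds(sig)) - length(probes), did)
    X <- t(b[probes, , drop = FALSE])
    # mean-impute missing values from the reference controls
    if (anyNA(X)) {
      cm <- colMeans(X[ctrlIds, , drop = FALSE], na.rm = TRUE)
      for (j in which(colSums(is.na(X)) > 0))
        X[is.na(X[, j]), j] <- cm[j]
    }
    pos <- refSheet$role == "reference_case" & refSheet$disorder_label == did
    if (sum(pos) == 0 || sum(!pos) == 0)
      .stopc("episcreen_training_error",
             "disorder %s needs both classes (pos=%d, neg=%d)",
             did, sum(pos), sum(!pos))
    if (cvFolds > sum(pos))
      .stopc("episcreen_fold_error",
             "cvFolds (%d) exceeds positive-class size (%d) for %s",
             cvFolds, sum(pos), did)
    fold <- .stratifiedFolds(pos, cvFolds, .deriveSeed(seed, "folds", did))
    oofD <- numeric(length(pos))
    for (k in seq_len(cvFolds)) {
      tr <- fold != k
      svmFit <- .linearSVM(X[tr, , drop = FALSE], pos[tr])
      oofD[!tr] <- drop(X[!tr, , drop = FALSE] %*% svmFit$w) + svmFit$b
    }
    platt <- fitPlatt(oofD, pos)
    final <- .linearSVM(X, pos)
    out[[did]] <- methods::new("TrainedClassifier",
      disorderId = did, probeIds = probes, weights = unname(final$w),
      bias = final$b, platt = platt, thresholds = thresholds,
      trainingMeta = list(n_cases = sum(pos), n_others = sum(!pos & refSheet$role == "reference_case"),
                          n_controls = length(ctrlIds), cv_folds = cvFolds,
                          seed = seed, kdb_version = kdbVersion))
  }
  out
}

#' Score one sample against a set of classifiers
#'
#' Computes, per disorder, the decision value \eqn{w \cdot \beta + b} over
#' the signature probes, the Platt-calibrated MVP score, and the threshold
#' category. A disorder whose signature has less than \code{coverageMin} of
#' its probes observed is flagged (\code{coverage_ok = FALSE}, score NA)
#' rather than scored; missing probes above that floor are mean-imputed from
#' the control reference.
#'
#' @param classifiers named list of \linkS4class{TrainedClassifier} or a
#'   \linkS4class{KnowledgeDatabase}.
#' @param sampleBeta named numeric vector of beta values (names = probe ids).
#' @param controlReference optional data.frame (probe_id, mean) used for
#'   imputation; taken from the KDB when one is supplied.
#' @param coverageMin minimum fraction of signature probes that must be
#'   observed (default 0.9).
#' @return data.frame with columns disorder_id, decision, mvp, category,
#'   coverage, coverage_ok.
#' @export
scoreSample <- function(classifiers, sampleBeta, controlReference = NULL,
                        coverageMin = 0.9) {
  if (methods::is(classifiers, "KnowledgeDatabase")) {
    controlReference <- controlReference %||% classifiers@controlReference
    classifiers <- classifiers@classifiers
  }
  rows <- lapply(classifiers, function(clf) {
    probes <- clf@probeIds
    v <- sampleBeta[probes]
    names(v) <- probes
    cov <- mean(!is.na(v))
    if (cov < coverageMin)
      return(data.frame(disorder_id = clf@disorderId, decision = NA_real_,
                        mvp = NA_real_, category = "coverage_error",
                        coverage = cov, coverage_ok = FALSE))
    if (anyNA(v)) {
      if (is.null(controlReference) || !nrow(controlReference))
        .stopc("episcreen_integrity_error",
               "missing probes but no control reference for imputation")
      idx <- match(probes[is.na(v)], controlReference$probe_id)
      v[is.na(v)] <- controlReference$mean[idx]
    }
    f <- sum(clf@weights * v) + clf@bias
    mvp <- mvpFromDecision(f, clf@platt)
    data.frame(disorder_id = clf@disorderId, decision = f, mvp = mvp,
               category = callCategory(mvp, clf@thresholds),
               coverage = cov, coverage_ok = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score every sample of a cohort
#'
#' @param kdb a \linkS4class{KnowledgeDatabase} (or named classifier list).
#' @param cohort a \linkS4class{MethylCohort}.
#' @param sampleIds samples to score (default: all).
#' @param coverageMin see \code{\link{scoreSample}}.
#' @return long-format data.frame (sample_id, disorder_id, decision, mvp,
#'   category, coverage, coverage_ok).
#' @export
scoreCohort <- function(kdb, cohort, sampleIds = NULL, coverageMin = 0.9) {
  cohort <- validateCohort(cohort)
  b <- betaValues(cohort)
  if (is.null(sampleIds)) sampleIds <- colnames(b)
  out <- do.call(rbind, lapply(sampleIds, function(id) {
    cbind(sample_id = id, scoreSample(kdb, b[, id], coverageMin = coverageMin))
  }))
  rownames(out) <- NULL
  out
}
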