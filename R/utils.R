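# Internal helpers shared across modules.

# classed conditions so callers can catch specific failure modes
.stopc <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "episcreen_error", "error", "condition")))
}

.warnc <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "episcreen_warning", "warning", "condition")))
}

.clip01 <- function(x) pmin(1, pmax(0, x))

#' Round a percentage half-up
#'
#' Rounds half-up (0.05 -> 0.1) rather than to even, matching the convention
#' used for printed diagnostic-yield percentages.
#'
#' @param x numeric vector of percentages.
#' @param digits decimal places to keep (default 1).
#' @return rounded numeric vector.
#' @export
#' @examples
#' percentHalfUp(100 * 48 / 136)  # 35.3
percentHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stable 31-bit string hash; used to derive per-sample RNG streams so that
# adding a sample never perturbs the draws of existing ones
.hashString <- function(s) {
  v <- utf8ToInt(enc2utf8(s))
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

.deriveSeed <- function(seed, ...) {
  .hashString(paste(c(format(seed), vapply(list(...), format, "")), collapse = "\r"))
}

# evaluate expr under a temporary RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# Row-wise Welch two-sample t-test, NA-aware.
# x, y: matrices probes x samples (same rows). Returns per-probe statistics;
# p-values carried in log space so extreme separations keep a finite ranking.
.rowWelch <- function(x, y) {
  nx <- rowSums(!is.na(x))
  ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE)
  my <- rowMeans(y, na.rm = TRUE)
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  se2 <- vx / nx + vy / ny
  delta <- mx - my
  tstat <- delta / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * pmax(nx - 1, 1)) + vy^2 / (ny^2 * pmax(ny - 1, 1)))
  # degenerate rows: no spread in either group
  zero <- !is.finite(tstat)
  tstat[zero] <- ifelse(abs(delta[zero]) > 0, Inf * sign(delta[zero]), 0)
  df[!is.finite(df)] <- pmax(nx + ny - 2, 1)[!is.finite(df)]
  logp <- stats::pt(-abs(tstat), df, log.p = TRUE) + log(2)
  logp[is.infinite(tstat)] <- -Inf
  list(delta = delta, meanCase = mx, meanControl = my,
       t = tstat, df = df, p = exp(logp), neglog10p = -logp / log(10))
}
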