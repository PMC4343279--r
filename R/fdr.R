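## Multiple-testing corrections: Benjamini-Hochberg step-up, q-values with
## spline pi0 estimation, and local FDR via a Grenander density estimate.

.checkPvec <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p
}

.newAdjusted <- function(method, values, alpha, pi0) {
  values <- pmin(pmax(values, 0), 1)
  ## strict "< alpha" rule, guarded against 1-ulp noise from the
  ## q_i = p_i * m / i arithmetic: a value within 1e-12 of alpha is
  ## treated as equal to it, hence not rejected
  new("AdjustedPvalues", method = method, values = values,
      alpha = alpha, pi0 = pi0, reject = (alpha - values) > 1e-12)
}

#' @rdname AdjustedPvalues-accessors
#' @name AdjustedPvalues-accessors
#' @title AdjustedPvalues accessors
#' @param x an [AdjustedPvalues] object.
NULL

#' @rdname AdjustedPvalues-accessors
#' @export
setMethod("adjustedValues", "AdjustedPvalues", function(x) x@values)

#' @rdname AdjustedPvalues-accessors
#' @export
setMethod("rejected", "AdjustedPvalues", function(x) x@reject)

setMethod("show", "AdjustedPvalues", function(object) {
  cat("AdjustedPvalues:", object@method, "| m =", length(object@values),
      "| alpha =", object@alpha, "| rejected:", sum(object@reject))
  if (!is.na(object@pi0)) cat(" | pi0 =", round(object@pi0, 4))
  cat("\n")
})

## Raw step-up machinery shared by BH and QV: p_(i) * m / i on the sorted
## sequence, running minimum from the largest rank, capped at 1, mapped
## back to the input order.
.stepUp <- function(p, scale = 1) {
  m <- length(p)
  o <- order(p, method = "radix")
  q <- scale * p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' The classic step-up procedure: sort the m p-values ascending, compute
#' `q_i = p_(i) * m / i`, enforce monotonicity by taking the running
#' minimum from the largest rank down, cap at 1 and map back to the input
#' order. A hypothesis is rejected when its adjusted value falls strictly
#' below `alpha`; this reproduces the textbook rule of rejecting all
#' hypotheses up to the largest rank whose q-value is below the
#' threshold.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param alpha rejection threshold on the adjusted scale.
#' @return an [AdjustedPvalues] object (method `"BH"`).
#' @examples
#' adjustedValues(bhAdjust(c(0.01, 0.02, 0.03, 0.04, 0.05)))  # all 0.05
#' @export
bhAdjust <- function(p, alpha = 0.05) {
  p <- .checkPvec(p)
  .newAdjusted("BH", .stepUp(p), alpha, pi0 = 1)
}

#' Estimate the proportion of true null hypotheses
#'
#' Under a mixture model the p-values are drawn from nulls (uniform) and
#' alternatives (concentrated near 0) in proportion `pi0 : 1 - pi0`. For
#' each lambda on a grid (0.05 to 0.90 in steps of 0.05) the naive
#' estimate `pi0(lambda) = count(p > lambda) / (m * (1 - lambda))` is
#' computed; these become unbiased as lambda grows but noisy, so a
#' natural cubic smoothing spline with 3 degrees of freedom is fitted to
#' `pi0(lambda)` versus lambda — mirroring the p-value-histogram spline
#' approach — and the estimate is the spline value at the largest lambda,
#' clamped to (0, 1].
#'
#' With fewer than 20 p-values, or a degenerate all-equal vector, the
#' estimator falls back to the conservative `pi0 = 1` and flags it in
#' `method_note`.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return a list with elements `pi0`, `lambda_grid`, `pi0_lambda` and
#'   `method_note`.
#' @export
estimatePi0 <- function(p) {
  p <- .checkPvec(p)
  m <- length(p)
  lambda <- seq(0.05, 0.90, by = 0.05)
  if (m < 20L)
    return(list(pi0 = 1, lambda_grid = lambda, pi0_lambda = NULL,
                method_note = "fallback: fewer than 20 p-values, pi0 = 1"))
  if (length(unique(p)) == 1L) {
    warning("degenerate all-equal p-value vector; falling back to pi0 = 1")
    return(list(pi0 = 1, lambda_grid = lambda, pi0_lambda = NULL,
                method_note = "fallback: degenerate p-values, pi0 = 1"))
  }
  pi0l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  pi0 <- min(max(pi0, 1 / m), 1)
  list(pi0 = pi0, lambda_grid = lambda, pi0_lambda = pi0l,
       method_note = "Storey-type lambda grid, cubic smoothing spline df = 3")
}

#' Q-value adjusted p-values
#'
#' Scales the Benjamini-Hochberg step-up quantities by the estimated null
#' proportion: `Q_i = pi0 * p_(i) * m / i`, with the same monotonization
#' and cap. With `pi0 = 1` this reduces exactly to [bhAdjust()]; since
#' `pi0 <= 1` the q-values never exceed the BH values, making the
#' procedure less conservative when many hypotheses are non-null.
#'
#' @inheritParams bhAdjust
#' @param pi0 optional null-proportion override; estimated from `p` with
#'   [estimatePi0()] when `NULL`.
#' @return an [AdjustedPvalues] object (method `"QV"`, slot `pi0` filled).
#' @export
qvalueAdjust <- function(p, alpha = 0.05, pi0 = NULL) {
  p <- .checkPvec(p)
  if (is.null(pi0)) pi0 <- estimatePi0(p)$pi0
  stopifnot(length(pi0) == 1L, pi0 > 0, pi0 <= 1)
  .newAdjusted("QV", .stepUp(p, scale = pi0), alpha, pi0 = pi0)
}

## Grenander estimator: the slopes of the least concave majorant of the
## empirical CDF on [0, 1] give the maximum-likelihood monotone
## non-increasing density of the observed p-values.
.grenander <- function(p) {
  m <- length(p)
  ps <- sort(p, method = "radix")
  x <- c(0, ps)
  F <- c(0, seq_len(m) / m)
  if (ps[m] < 1) { x <- c(x, 1); F <- c(F, 1) }
  ## collapse ties: keep the last (largest F) point at each x
  keep <- c(x[-1L] != x[-length(x)], TRUE)
  x <- x[keep]; F <- F[keep]
  ## least concave majorant via a Graham-scan style stack over slopes
  hx <- x[1L]; hF <- F[1L]
  for (i in 2L:length(x)) {
    hx <- c(hx, x[i]); hF <- c(hF, F[i])
    nh <- length(hx)
    while (nh >= 3L) {
      s1 <- (hF[nh - 1L] - hF[nh - 2L]) / (hx[nh - 1L] - hx[nh - 2L])
      s2 <- (hF[nh] - hF[nh - 1L]) / (hx[nh] - hx[nh - 1L])
      if (s2 <= s1) break
      hx <- hx[-(nh - 1L)]; hF <- hF[-(nh - 1L)]
      nh <- nh - 1L
    }
  }
  slopes <- diff(hF) / diff(hx)
  ## f(p): slope of the majorant segment containing p
  seg <- findInterval(p, hx, left.open = TRUE, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg > length(slopes)] <- length(slopes)
  slopes[seg]
}

#' Local false discovery rate
#'
#' The empirical-Bayes posterior probability that a hypothesis with
#' p-value `p` is null: `localFDR(p) = pi0 * f0(p) / f(p)` with a uniform
#' null density `f0 = 1`. The marginal density `f` is estimated by the
#' Grenander estimator — the slopes of the least concave majorant of the
#' empirical CDF — which is the maximum-likelihood estimate under the
#' natural assumption that the p-value density is non-increasing. Values
#' are clamped to `[0, 1]`. Under a pure-null (uniform) sample both
#' `pi0` and `f` approach 1, so the local FDR approaches 1 everywhere.
#'
#' @inheritParams qvalueAdjust
#' @return an [AdjustedPvalues] object (method `"lFDR"`).
#' @export
localFdr <- function(p, alpha = 0.05, pi0 = NULL) {
  p <- .checkPvec(p)
  if (length(p) < 20L)
    stop("local FDR needs at least 20 p-values; ",
         "use bhAdjust() for small families")
  if (is.null(pi0)) pi0 <- estimatePi0(p)$pi0
  f <- .grenander(p)
  lfdr <- pi0 / pmax(f, .Machine$double.eps)
  .newAdjusted("lFDR", lfdr, alpha, pi0 = pi0)
}

#' P-value distribution diagnostics
#'
#' Advisory summary to help choose a correction method: decile histogram
#' counts of the p-values and the Kolmogorov-Smirnov distance from the
#' uniform distribution. A near-flat histogram (small distance) indicates
#' mostly null hypotheses, where BH is appropriate; a spike near zero
#' indicates a substantial alternative fraction, where the q-value or
#' local FDR make better use of the signal.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return list with `decile_counts` (named integer vector of 10 bins),
#'   `ks_distance` and `looks_uniform` (distance below 1.36/sqrt(m), the
#'   5% KS critical value).
#' @export
pvalueDiagnostics <- function(p) {
  p <- .checkPvec(p)
  m <- length(p)
  breaks <- seq(0, 1, by = 0.1)
  counts <- table(cut(p, breaks = breaks, include.lowest = TRUE))
  ps <- sort(p, method = "radix")
  d <- max(pmax(seq_len(m) / m - ps, ps - (seq_len(m) - 1L) / m))
  list(decile_counts = stats::setNames(as.integer(counts), names(counts)),
       ks_distance = d,
       looks_uniform = d < 1.36 / sqrt(m))
}

#' Write / read p-value and adjusted-value tables
#'
#' P-values travel as TSV with columns `id`, `p`; adjusted results as TSV
#' with columns `id`, `p`, `method`, `adjusted`, `reject`.
#'
#' @param ids identifier vector aligned to `p`.
#' @param p raw p-values.
#' @param x an [AdjustedPvalues] object.
#' @param file path.
#' @name fdr-io
NULL

#' @rdname fdr-io
#' @export
writePvalues <- function(ids, p, file) {
  .writeTsv(data.frame(id = as.character(ids), p = as.numeric(p),
                       stringsAsFactors = FALSE), file)
}

#' @rdname fdr-io
#' @export
readPvalues <- function(file) {
  df <- .readTsv(file, colClasses = c(id = "character", p = "numeric"))
  .requireCols(df, file, c("id", "p"))
  df
}

#' @rdname fdr-io
#' @export
writeAdjusted <- function(ids, p, x, file) {
  stopifnot(is(x, "AdjustedPvalues"))
  .writeTsv(data.frame(id = as.character(ids), p = as.numeric(p),
                       method = x@method, adjusted = x@values,
                       reject = x@reject, stringsAsFactors = FALSE), file)
}
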