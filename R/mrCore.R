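.CI_MULT <- 1.959964

.mkEstimate <- function(method, theta, se, nSnps, pvalue = NULL,
                        ciMult = .CI_MULT, seInflated = NA_real_,
                        scale = "per_unit_increment",
                        unitLabel = "1 unit exposure") {
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(theta / se))
  lo <- theta - ciMult * se
  hi <- theta + ciMult * se
  new("MrEstimate", method = method, theta = theta, seTheta = se,
      seThetaInflated = seInflated, ciLow = lo, ciHigh = hi,
      oddsRatio = exp(theta), orCiLow = exp(lo), orCiHigh = exp(hi),
      pvalue = pvalue, nSnps = as.integer(nSnps), scale = scale,
      unitLabel = unitLabel)
}

#' Wald ratio causal estimate from a single instrument
#'
#' `theta = betaOutcome / betaExposure`, with the first-order delta-method
#' standard error `seOutcome / |betaExposure|` (which ignores the exposure
#' effect's uncertainty; a second-order version adding the
#' `betaOutcome^2 * seExposure^2 / betaExposure^4` term is available behind
#' `secondOrder`). Confidence bounds use the 1.959964 normal multiplier and
#' the p-value a standard normal reference.
#'
#' @param betaExposure,seExposure SNP-exposure effect and standard error.
#' @param betaOutcome,seOutcome SNP-outcome effect and standard error.
#' @param secondOrder use the second-order delta-method standard error.
#' @param unitLabel exposure unit recorded on the estimate.
#' @return An [MrEstimate-class] with `method = "wald_ratio"`,
#'   increment-scaled.
#' @export
waldRatio <- function(betaExposure, seExposure, betaOutcome, seOutcome,
                      secondOrder = FALSE, unitLabel = "1 unit exposure") {
  if (betaExposure == 0) stop("Wald ratio undefined: betaExposure = 0")
  if (seExposure <= 0 || seOutcome <= 0) stop("standard errors must be positive")
  theta <- betaOutcome / betaExposure
  se <- if (secondOrder)
    sqrt(seOutcome^2 / betaExposure^2 +
           betaOutcome^2 * seExposure^2 / betaExposure^4)
  else seOutcome / abs(betaExposure)
  .mkEstimate("wald_ratio", theta, se, 1L, unitLabel = unitLabel)
}

#' Inverse-variance-weighted causal estimate
#'
#' Zero-intercept weighted regression of the SNP-outcome effects on the
#' SNP-exposure effects with weights `1 / seOutcome^2`:
#' `theta = sum(w bx by) / sum(w bx^2)`, fixed-effect
#' `se = 1 / sqrt(sum(w bx^2))`. The random-effects variant (the
#' multiplicative convention) inflates the fixed-effect standard error by
#' `max(1, sqrt(Q / (J - 1)))` where `Q` is Cochran's statistic at the
#' pooled estimate. With a single instrument the call dispatches to
#' [waldRatio()].
#'
#' @param h a [HarmonizedSet-class].
#' @param mode `"random"` (default, the primary analysis method) or
#'   `"fixed"`.
#' @param unitLabel exposure unit recorded on the estimate.
#' @return An [MrEstimate-class], increment-scaled.
#' @export
ivw <- function(h, mode = c("random", "fixed"), unitLabel = "1 unit exposure") {
  mode <- match.arg(mode)
  stopifnot(is(h, "HarmonizedSet"))
  J <- nVariants(h)
  if (J == 0L) stop("empty harmonized set")
  if (J == 1L)
    return(waldRatio(h@betaExposure, h@seExposure, h@betaOutcome,
                     h@seOutcome, unitLabel = unitLabel))
  bx <- h@betaExposure; by <- h@betaOutcome
  w <- 1 / h@seOutcome^2
  swx2 <- sum(w * bx^2)
  if (swx2 == 0) stop("all exposure effects are zero")
  theta <- sum(w * bx * by) / swx2
  se <- 1 / sqrt(swx2)
  if (mode == "random") {
    Q <- sum(w * (by - theta * bx)^2)
    se <- se * max(1, sqrt(Q / (J - 1)))
  }
  .mkEstimate(paste0("ivw_", mode), theta, se, J, unitLabel = unitLabel)
}

#' Cochran's Q heterogeneity statistic for per-SNP ratio estimates
#'
#' `Q = sum_j w_j (theta_j - theta)^2` with ratio estimates
#' `theta_j = by_j / bx_j` and weights `w_j = (bx_j / seOutcome_j)^2`
#' (equivalently the weighted residual sum of squares of the zero-intercept
#' IVW regression). The p-value is the upper tail of a chi-square with
#' `J - 1` degrees of freedom.
#'
#' @param h a [HarmonizedSet-class] with at least two instruments and no
#'   zero exposure effects.
#' @param theta pooled estimate to test against; defaults to the
#'   fixed-effect IVW estimate.
#' @return A [HeterogeneityResult-class].
#' @export
cochranQ <- function(h, theta = NULL) {
  stopifnot(is(h, "HarmonizedSet"))
  J <- nVariants(h)
  if (J < 2L) stop("Cochran's Q needs at least 2 instruments")
  if (any(h@betaExposure == 0)) stop("zero exposure effect: ratio undefined")
  if (is.null(theta)) theta <- ivw(h, mode = "fixed")@theta
  ratios <- h@betaOutcome / h@betaExposure
  w <- (h@betaExposure / h@seOutcome)^2
  Q <- sum(w * (ratios - theta)^2)
  new("HeterogeneityResult", Q = Q, df = J - 1L,
      pvalue = pchisq(Q, df = J - 1L, lower.tail = FALSE))
}

#' MR-Egger regression: pleiotropy intercept test and causal slope
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept and weights `1 / seOutcome^2`, after
#' orienting every instrument so its exposure effect is non-negative. A
#' non-zero intercept signals directional pleiotropy. Standard errors carry
#' the weighted-least-squares residual variance (J - 2 df) and p-values and
#' confidence bounds use the matching t reference, the convention of the
#' standard two-sample MR implementations.
#'
#' @param h a [HarmonizedSet-class] with at least three instruments.
#' @param unitLabel exposure unit recorded on the slope estimate.
#' @return list with `estimate` (slope [MrEstimate-class], method
#'   `"egger_slope"`) and `pleiotropy` (a [PleiotropyResult-class]).
#' @export
mrEgger <- function(h, unitLabel = "1 unit exposure") {
  stopifnot(is(h, "HarmonizedSet"))
  J <- nVariants(h)
  if (J < 3L) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(h@betaExposure)
  flip[flip == 0] <- 1
  bx <- h@betaExposure * flip
  by <- h@betaOutcome * flip
  w <- 1 / h@seOutcome^2

  X <- cbind(intercept = 1, slope = bx)
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  if (abs(det(XtWX)) < .Machine$double.eps * sum(w)^2 ||
      var(bx) == 0)
    stop("degenerate design: exposure effects carry no spread")
  coefs <- drop(solve(XtWX, XtW %*% by))
  res <- by - drop(X %*% coefs)
  df <- J - 2L
  # exact interpolation gives zero residual variance; keep SEs positive
  sigma2 <- max(sum(w * res^2) / df, .Machine$double.xmin)
  covb <- sigma2 * solve(XtWX)
  ses <- sqrt(diag(covb))
  tstats <- coefs / ses
  pvals <- 2 * pt(-abs(tstats), df = df)

  est <- .mkEstimate("egger_slope", unname(coefs["slope"]),
                     unname(ses["slope"]), J, pvalue = unname(pvals["slope"]),
                     ciMult = qt(0.975, df = df), unitLabel = unitLabel)
  pleio <- new("PleiotropyResult", intercept = unname(coefs["intercept"]),
               seIntercept = unname(ses["intercept"]),
               pvalue = unname(pvals["intercept"]), df = df)
  list(estimate = est, pleiotropy = pleio)
}

#' IVW estimate for correlated instruments (generalized least squares)
#'
#' Zero-intercept generalized weighted regression accounting for LD between
#' instruments: with `Omega[j,k] = seOutcome_j * seOutcome_k * rho[j,k]`,
#' `theta = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by` and
#' `se = sqrt((bx' Omega^-1 bx)^-1)`. When `Omega`'s condition number
#' exceeds 1e10 its diagonal is regularized by 1e-8. A heterogeneity-
#' inflated standard error (`max(1, sqrt(Q_GLS / (J - 1)))` times the
#' model-based one) is reported alongside in `seThetaInflated`; the p-value
#' and confidence bounds use the model-based standard error and the normal
#' reference.
#'
#' @param h a [HarmonizedSet-class] carrying an LD matrix.
#' @param unitLabel exposure unit recorded on the estimate.
#' @return An [MrEstimate-class] with `method = "ivw_correlated"`.
#' @export
ivwCorrelated <- function(h, unitLabel = "1 unit exposure") {
  stopifnot(is(h, "HarmonizedSet"))
  if (is.null(h@ld))
    stop("ivwCorrelated requires an LD matrix on the harmonized set")
  J <- nVariants(h)
  if (J < 2L) stop("correlated-instrument estimation needs >= 2 instruments")
  bx <- h@betaExposure; by <- h@betaOutcome
  Omega <- outer(h@seOutcome, h@seOutcome) * h@ld
  if (kappa(Omega, exact = FALSE) > 1e10)
    Omega <- Omega + diag(1e-8, J)
  Oinv <- tryCatch(solve(Omega),
                   error = function(e) stop("singular instrument covariance ",
                                            "after regularization"))
  prec <- drop(t(bx) %*% Oinv %*% bx)
  if (prec <= 0) stop("non-positive-definite instrument covariance")
  theta <- drop(t(bx) %*% Oinv %*% by) / prec
  se <- sqrt(1 / prec)
  res <- by - theta * bx
  Q <- drop(t(res) %*% Oinv %*% res)
  seInfl <- se * max(1, sqrt(Q / (J - 1)))
  .mkEstimate("ivw_correlated", theta, se, J, seInflated = seInfl,
              unitLabel = unitLabel)
}

#' Rescale an estimate to the per-unit-decrement (drug-effect) direction
#'
#' Glucose-lowering drugs act by decreasing the biomarker, so estimates are
#' reported per unit *decrement* of the exposure: theta and its confidence
#' bounds are negated (bounds swapped), odds ratios re-exponentiated, and
#' the scale and unit label updated. The p-value and standard errors are
#' unchanged. Applying the rescaling to an already decrement-scaled
#' estimate is an error.
#'
#' @param e an increment-scaled [MrEstimate-class].
#' @param unitLabel unit recorded on the rescaled estimate, e.g.
#'   `"1 mmol/L blood glucose"` or `"6.75 mmol/mol (1.09%) HbA1c"`.
#' @return The decrement-scaled [MrEstimate-class].
#' @export
rescalePerUnitDecrement <- function(e, unitLabel = e@unitLabel) {
  stopifnot(is(e, "MrEstimate"))
  if (e@scale != "per_unit_increment")
    stop("estimate is already decrement-scaled")
  lo <- -e@ciHigh; hi <- -e@ciLow
  initialize(e, theta = -e@theta, ciLow = lo, ciHigh = hi,
             oddsRatio = exp(-e@theta), orCiLow = exp(lo), orCiHigh = exp(hi),
             scale = "per_unit_decrement", unitLabel = unitLabel)
}

#' Per-test Bonferroni significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha = 0.05, m = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}
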