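#' Wakefield log approximate Bayes factor for a single association
#'
#' With `V = se^2`, `W = priorSd^2` and `Z = beta / se`:
#' `log ABF = 0.5 * log(V / (V + W)) + Z^2 * W / (2 * (V + W))`,
#' the approximate Bayes factor of association against the null under a
#' normal effect prior with standard deviation `priorSd`. Vectorized over
#' `beta` and `se`.
#'
#' @param beta,se association effect and standard error (se > 0).
#' @param priorSd prior standard deviation of the true effect (> 0).
#' @return numeric vector of log approximate Bayes factors.
#' @export
wakefieldLogABF <- function(beta, se, priorSd) {
  if (any(se <= 0)) stop("se must be positive")
  if (priorSd <= 0) stop("priorSd must be positive")
  V <- se^2
  W <- priorSd^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + z2 * W / (2 * (V + W))
}

.logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.colocBetaSe <- function(x, label) {
  if (is(x, "SummaryDataset"))
    return(list(id = x@records$variant_id, beta = x@records$beta,
                se = x@records$se, type = x@traitType))
  if (is.data.frame(x) && all(c("beta", "se") %in% names(x)))
    return(list(id = if ("variant_id" %in% names(x)) x$variant_id
                     else paste0("v", seq_len(nrow(x))),
                beta = x$beta, se = x$se, type = "quantitative"))
  stop(label, " must be a SummaryDataset or a data.frame with beta and se")
}

#' Five-hypothesis approximate-Bayes-factor colocalization
#'
#' Tests whether two traits share one causal variant in a region, assuming
#' at most one causal variant per trait. Per-variant Wakefield log Bayes
#' factors feed the hypothesis sums `H1 ~ p1 * sum(B1_j)`,
#' `H2 ~ p2 * sum(B2_j)`, `H3 ~ p1 * p2 * sum over j != k of B1_j * B2_k`,
#' `H4 ~ p12 * sum(B1_j * B2_j)` and `H0 ~ 1`, normalized to posterior
#' probabilities. All accumulation is in log space via log-sum-exp.
#' Single-variant regions are allowed (the H3 sum is then empty and
#' `PP.H3 = 0`).
#'
#' The H1/H2 labels follow the argument order and swap under trait
#' relabeling; outputs carry the region label so the orientation is
#' explicit.
#'
#' @param trait1,trait2 regional association slices over identical variant
#'   sets: [SummaryDataset-class] objects or data.frames with `beta`, `se`
#'   (and optionally `variant_id`) columns. `trait2` is reordered to
#'   `trait1`'s variant order when ids are available.
#' @param priors a [ColocPriors-class]; defaults to the conventional
#'   p1 = p2 = 1e-4, p12 = 1e-5.
#' @param priorSd1,priorSd2 effect-prior standard deviations; default 0.15
#'   for quantitative traits and 0.20 for binary (log-OR) traits.
#' @param regionLabel annotation stored on the result.
#' @return A [ColocPosterior-class].
#' @export
colocABF <- function(trait1, trait2, priors = colocPriors(),
                     priorSd1 = NULL, priorSd2 = NULL,
                     regionLabel = "region") {
  t1 <- .colocBetaSe(trait1, "trait1")
  t2 <- .colocBetaSe(trait2, "trait2")
  if (length(t1$id) != length(t2$id) || !setequal(t1$id, t2$id))
    stop("trait1 and trait2 must cover identical variant sets")
  ord <- match(t1$id, t2$id)
  t2$beta <- t2$beta[ord]; t2$se <- t2$se[ord]
  n <- length(t1$id)
  if (n < 1L) stop("empty region")

  if (is.null(priorSd1)) priorSd1 <- if (t1$type == "binary") 0.20 else 0.15
  if (is.null(priorSd2)) priorSd2 <- if (t2$type == "binary") 0.20 else 0.15
  l1 <- wakefieldLogABF(t1$beta, t1$se, priorSd1)
  l2 <- wakefieldLogABF(t2$beta, t2$se, priorSd2)

  S1 <- .logsumexp(l1)
  S2 <- .logsumexp(l2)
  S12 <- .logsumexp(l1 + l2)
  # sum over ordered pairs j != k equals S1 + S2 minus the diagonal sum
  d <- S12 - (S1 + S2)
  lH3pairs <- if (n == 1L || d >= 0) -Inf else S1 + S2 + log1p(-exp(d))

  lh <- c(H0 = 0,
          H1 = log(priors@p1) + S1,
          H2 = log(priors@p2) + S2,
          H3 = log(priors@p1) + log(priors@p2) + lH3pairs,
          H4 = log(priors@p12) + S12)
  pp <- exp(lh - .logsumexp(lh))
  pp <- pp / sum(pp)
  new("ColocPosterior", pp = pp, nVariants = as.integer(n),
      labfTrait1 = l1, labfTrait2 = l2, regionLabel = regionLabel)
}

#' Colocalization decision rule on the shared-variant posterior
#'
#' @param p a [ColocPosterior-class].
#' @param threshold decision threshold; evidence for a shared causal
#'   variant is declared when `PP.H4` strictly exceeds it (default 0.7).
#' @return `TRUE` iff `PP.H4 > threshold`.
#' @export
classifyColoc <- function(p, threshold = 0.7) {
  stopifnot(is(p, "ColocPosterior"))
  unname(p@pp["H4"] > threshold)
}

#' Per-variant regional association table for external plotting
#'
#' Restricts both traits to the region (+/- flank), harmonizing nothing:
#' rows pair variants by id and report positions, -log10 p-values and
#' Wakefield log Bayes factors per trait, sorted by position.
#'
#' @param trait1,trait2 [SummaryDataset-class] objects covering the region.
#' @param region single-range `GRanges`.
#' @param flankBp flank in base pairs.
#' @param priorSd1,priorSd2 effect-prior standard deviations as in
#'   [colocABF()].
#' @return `data.frame` with columns `variant_id`, `position`,
#'   `neglog10p_trait1`, `neglog10p_trait2`, `labf_trait1`, `labf_trait2`.
#' @export
exportRegionalTable <- function(trait1, trait2, region, flankBp = 0L,
                                priorSd1 = NULL, priorSd2 = NULL) {
  s1 <- extractCisWindow(trait1, region, flankBp)
  s2 <- extractCisWindow(trait2, region, flankBp)
  common <- intersect(variantIds(s1), variantIds(s2))
  if (!length(common)) stop("empty region after windowing")
  r1 <- s1@records[match(common, s1@records$variant_id), ]
  r2 <- s2@records[match(common, s2@records$variant_id), ]
  if (is.null(priorSd1)) priorSd1 <- if (trait1@traitType == "binary") 0.20 else 0.15
  if (is.null(priorSd2)) priorSd2 <- if (trait2@traitType == "binary") 0.20 else 0.15
  out <- data.frame(variant_id = common,
                    position = r1$position,
                    neglog10p_trait1 = -log10(r1$pvalue),
                    neglog10p_trait2 = -log10(r2$pvalue),
                    labf_trait1 = wakefieldLogABF(r1$beta, r1$se, priorSd1),
                    labf_trait2 = wakefieldLogABF(r2$beta, r2$se, priorSd2),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  out
}
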